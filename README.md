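# hemaclone

Copy-number calling and clonal lineage inference for sparse whole-genome
sequencing of cytogenetically sorted hematopoietic cell pools.

## The problem

When two hematologic malignancies co-exist in one marrow (for example a
plasma-cell neoplasm alongside acute myeloid leukemia), bulk sequencing
mixes the genomes of unrelated clones. One way out is to sort small pools
(tens of cells) of cytogenetically identified populations — plasma cells
tagged by cytoplasmic-Ig FISH, myeloblasts tagged by interphase FISH on a
destained smear, granulocytes/erythrocytes/megakaryocytes by morphology —
and sequence each pool shallowly. `hemaclone` implements the computational
side of that workflow for laboratory hematologists and computational
biologists:

- **Copy-number calling from sparse WGS.** The genome is divided into
  *variable-size bins* holding an equal expected number of uniquely
  mapped reads (10,000 bins genome-wide by default), so bin read density
  is proportional to copy number. Per-bin counts are GC-normalized
  (lowess fit of count vs. GC, divided out), scaled to chromosomal copy
  number by the near-diploid assumption `cn_i = 2 · d_i / median(d)`,
  segmented by circular binary segmentation (recursive max-t splits
  calibrated by a seeded permutation null), post-processed by
  MergeLevels (Wilcoxon rank-sum merging of indistinguishable segment
  levels), and called to integers by round-half-even of level means.
  Calls are reported as whole-chromosome ("polysomy 8"), arm-level
  ("20q deletion"), or focal events.
- **QC.** Bin-uniformity metrics: CV = sd/mean, and MAPD on
  mean-scaled adjacent differences `d_i = (x[i+1] − x[i]) / mean(x)` in
  both of its readings, `median(|d − median(d)|)` and `median(|d|)`.
- **Variant analysis.** Panel-style filters (drop synonymous,
  non-coding, >1% MAF; require alt ≥ 10, VAF ≥ 5%, depth ≥ 250) with a
  serial-specimen *rescue rule* that keeps sub-threshold early time
  points of a variant that fully passes later; read-level variant
  presence calls for shallow libraries; VAF-trajectory labels
  (persisting / cleared / emergent).
- **Cytogenetics.** An ISCN karyotype parser (clones, `idem`/`sl`/`slxN`
  stemline resolution, composite `[cpN]` clones, modal ranges), FISH
  tally percentages with half-up rounding, non-PC:PC ratios, and
  probe-specific positivity cutoffs at 100/200/300 scored cells.
- **Lineage inference.** Aberration-group × population matrices tested
  for perfect-phylogeny compatibility (pairwise nested-or-disjoint
  supports), deterministic clone-tree construction, and mapping of each
  clonal change onto classical or composite hematopoiesis scaffolds
  (HSC → MPP → LMPP/CMP → MLP/GMP/MEP → mature cells).
- **Synthetic data.** Seeded generators for genomes with GC/mappability
  tracks, negative-binomial bin counts under a known copy-number truth,
  reads at a variant locus, and multinomial FISH tallies — so the whole
  pipeline runs and is validated without external data.

## Worked example

Simulate a 500-bin genome with a whole-chromosome trisomy and an arm-level
loss, then recover both:

```r
library(hemaclone)

genome <- make_genome(
  c(chr1 = 50e6, chr2 = 50e6, chr3 = 50e6, chr4 = 50e6, chr5 = 50e6),
  gc = list(model = "sinusoid", mean = 0.45, amplitude = 0.08, period = 3.1e6),
  window_size = 1e5)
binmap <- build_variable_bins(genome, n_bins = 500)
truth <- truth_profile(data.frame(
  chrom = c("chr2", "chr4"), start = c(0, 25e6), end = c(50e6, 50e6),
  cn = c(3L, 1L)))                       # trisomy 2; chr4q monosomy
counts <- simulate_bin_counts(genome, binmap, truth, total_reads = 1e6,
                              gc_bias = c(0.2, 2.5, -2.0),
                              dispersion = 0.02, seed = 11)
qc_report(counts$counts, "demo")
#> qc_report 'demo' (500 bins, counts): CV 0.3016, MAPD 0.1346 (MAD form) / 0.1341 (median |d|)

profile <- call_copy_number(counts, binmap, seed = 11)
profile$segments
#>   chrom first_bin last_bin      mean level level_mean cn_call
#> 1  chr1         1      100 1.9143813     2  1.9656054       2
#> 2  chr2       101      200 2.9652219     3  2.9652219       3
#> 3  chr3       201      300 1.9609370     2  1.9656054       2
#> 4  chr4       301      350 1.9871607     2  1.9656054       2
#> 5  chr4       351      400 0.9809079     1  0.9809079       1
#> 6  chr5       401      500 2.0107203     2  1.9656054       2

arms <- data.frame(chrom = paste0("chr", 1:5), centromere = 25e6)
extract_aberrations(profile, binmap, arms = arms)
#>                    kind chrom  arm cn       label
#> 1 whole-chromosome gain  chr2 <NA>  3  polysomy 2
#> 2        arm-level loss  chr4    q  1 4q deletion
```

The injected trisomy comes back as one segment at level mean 2.97 called
CN 3 ("polysomy 2"), the q-arm loss as a segment at 0.98 called CN 1
("4q deletion"), with the breakpoint at the true bin boundary (bin
350|351); the remaining genome merges into one diploid level.

The cytogenetic side works from clinical inputs directly:

```r
parse_iscn("47,XX,+8,del(20)(q11.2)[7]/48,idem,+19[8]/46,XX[9]")
#> karyotype: 47,XX,+8,del(20)(q11.2)[7]/48,idem,+19[8]/46,XX[9]
#>   clone 1: modal 47, XX, 7 cell(s): +8, del(20)(q11.2)
#>   clone 2: modal 48, XX, 8 cell(s): +19, +8, del(20)(q11.2)
#>   clone 3: modal 46, XX, 9 cell(s): normal

tally_fish(44, 200)   # 44 positive of 200 scored cells
#> [1] 22

cm <- read_character_matrix(system.file("extdata",
        "case_character_matrix.tsv", package = "hemaclone"))
tree <- infer_clone_tree(cm)
tree
#> clone_tree: 9 character edge(s), 8 population(s)
#> ((((nPC_1)1+C,(nPC_2)2+D)B,((MB_1)3+F,MB_2)E)A,((neutrophil)H,eosinophil)G,(erythrocyte)I,megakaryocyte)root;
map_to_template(tree, hematopoiesis_template("classical"))
#>   label            cell_types template_node
#> 1     A                 MB,PC          LMPP
#> 2     B                    PC            PC
#> 3     E                    MB            MB
#> 4     G eosinophil,neutrophil           GMP
#> ...
```

The tree says: both neoplastic plasma-cell populations and both
myeloblast populations descend from one clone carrying character group A,
which maps to the lymphoid-primed multipotent progenitor — the deepest
compartment shared by the lymphoid and granulocytic branches — while the
granulocyte changes (G, H) and the erythrocyte change (I) arose on
separate normal-karyotype branches.

A thin command-line front end over these functions ships in
`inst/cli/hemaclone.R` (subcommands `simulate`, `bins`, `cna`, `qc`,
`variants`, `fish`, `lineage`, `report`, each driven by a JSON config).

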