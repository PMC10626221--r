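---
title: "Methods: copy-number calling and clonal lineage inference for sorted marrow cell pools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: copy-number calling and clonal lineage inference for sorted marrow cell pools}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hemaclone)
```

## Scope

`hemaclone` implements the computational side of a workflow in which small
pools (tens of cells) of cytogenetically identified bone-marrow cells —
plasma cells tagged by cytoplasmic-Ig FISH, myeloblasts tagged by
interphase FISH on a destained smear, and morphologically identified
granulocytes, erythrocytes and megakaryocytes — are sequenced shallowly at
the whole-genome level, and the resulting copy-number profiles are combined
with karyotypes, FISH tallies and targeted-sequencing variants to place
each clonal change on the hematopoietic tree. The package covers five
areas: sparse-WGS copy-number calling, bin-uniformity QC, variant filtering
and read-level presence calling, ISCN/FISH cytogenetics, and
perfect-phylogeny lineage inference, plus a seeded synthetic-data generator
that makes the entire pipeline testable without any external download.

## Copy-number model

### Variable binning

Sparse libraries cannot support fixed fine-grained windows, so the genome
is divided into bins holding an **equal expected number of uniquely mapped
reads**: under a copy-neutral genome every bin should receive the same
count, and copy number is then proportional to bin read density. On the
human reference this construction classically yields 10,000 genome-wide
bins with a median size of a few hundred kbp; 10,000 is the package
default. The median-size figure is a property of real mappability tracks
and is therefore documented, not asserted, for synthetic genomes.

`build_variable_bins()` first apportions the bin count to chromosomes by
largest-remainder rounding on chromosome mappability mass (at least one bin
per chromosome), then splits each chromosome's cumulative weight into equal
quanta. Boundaries snap to track-window edges: a bin closes at the first
window whose inclusion meets its cumulative target and the residual weight
carries forward. Two consequences, both deliberate: bins never cross
chromosome boundaries, and equal weight is exact up to one window's weight
within a chromosome (across chromosomes the quanta differ by at most the
apportionment rounding). A brute-force cumulative-sum oracle reproduces the
boundaries exactly on small genomes, which the tests exercise.

Reads are assigned to bins by start position under 0-based half-open
conventions — the natural convention for single-end density counting; the
package does not attempt fragment-midpoint assignment.

### Normalization and scaling

Raw counts depend on bin GC content. `gc_normalize()` fits
count-versus-GC with `lowess` (span 0.3 by default; a quadratic
polynomial fit is the fallback) and divides it out. Fitted values are
floored at the 1st percentile of positive fits so a handful of
extreme-GC bins cannot produce unbounded ratios; with fewer than 10
bins, or a degenerate GC track, the function falls back to global-mean
normalization with a warning. The normalized density is rescaled to
mean 1.

`to_copy_number_scale()` converts density to chromosomal copy number by
dividing by the median density and multiplying by the baseline ploidy
(default 2). This is the near-diploidy assumption: the median bin is
taken to sit at the baseline. It fails gracefully (and an analyst should
expect it to) for genomes where more than half the bins are aberrant.
The operation is idempotent, which the tests check.

### Segmentation

`cbs_segment()` performs recursive binary segmentation per chromosome.
Within a candidate segment the breakpoint maximizing the pooled
two-sample t statistic is located (vectorized over breakpoints with
cumulative sums), and its significance is assessed against a permutation
null obtained by shuffling the segment's values; the split is accepted
iff the permutation p-value is below `alpha` (default 0.01, 1000
permutations, minimum segment width 3 bins) and recursion continues on
both parts. The permutation loop stops early as soon as the p-value can
no longer fall below `alpha`, which is what keeps 1000 permutations
affordable. All permutation randomness flows from one seed, so
segmentations are reproducible.

This is the breakpoint form of circular binary segmentation — the
statistic is maximized over single split points rather than over all
circular arcs. For the profiles this package targets (whole-chromosome
and arm-level events in near-diploid genomes, where chromosome edges are
natural boundaries) the two formulations find the same changepoints, and
the breakpoint form has an exactly checkable oracle: an exhaustive
scan of the t statistic, which the tests run against 50 random
single-step series.

### Level merging and integer calls

Segmentation on noisy data fragments the genome into more levels than
copy-number states. `merge_levels()` repeatedly takes the pair of
distinct levels with the closest means, compares their member bins with
a Wilcoxon rank-sum test, and merges them when the test cannot tell
them apart (p > 1e-4, the customary default of the procedure); it stops
when the closest pair differs significantly. Segment boundaries are
never moved — only the level labels coarsen, and the level count is
monotone in the threshold. Merging operates in copy-number-ratio space
rather than log-ratio space; at the near-diploid ratios this package
works with, the rank-sum test is invariant to that monotone choice of
scale.

The mean copy-number ratio over a level's bins is taken as the level's
true copy number, and the integer call is its round-half-even value
(floored at 0). Half-even avoids the systematic upward bias that
half-up rounding would introduce exactly at x.5 level means.

`extract_aberrations()` turns per-bin integer calls into cytogenetic-style
labels: a whole-chromosome call when ≥ 90% of a chromosome's bins share an
off-baseline integer copy number ("polysomy 8", "monosomy 7"), an
arm-level call at the same threshold within an arm when centromere
positions are supplied ("20q deletion"), and focal calls for the rest.
Without arm annotation, only whole-chromosome calls are made and a notice
is logged.

### Validation by parameter recovery

The segmentation stack is validated end to end on simulated data at a
desk scale chosen once: five 50-Mbp chromosomes with 100-kbp track
windows, 500 bins, one million reads, negative-binomial dispersion 0.02,
and a truth profile carrying one whole-chromosome trisomy and one q-arm
monosomy. At these settings the pipeline recovers ≥ 95% of per-bin
integer calls and places the interior breakpoint within two bins, which
the acceptance tests assert. The GC track for this study is sinusoidal
(mean 0.45, amplitude 0.08, period 3.1 Mbp): a track whose period is
short relative to segment length, so every copy-number state is observed
across the whole GC range. A monotone GC gradient along each chromosome
would confound GC with segment position and let the GC fit absorb real
copy-number signal — a genuine failure mode of GC normalization worth
knowing about, but not the regime the method is designed for.

## QC metrics

Two bin-uniformity summaries are computed on counts (or ratios):

- **CV** — sample standard deviation (n−1 denominator) over the mean.
- **MAPD** — adjacent-bin differences scaled by the mean,
  `d_i = (x[i+1] − x[i]) / mean(x)`, summarized either as
  `median(|d − median(d)|)` (the MAD of the scaled differences) or as
  `median(|d|)` (the field-standard form).

The two MAPD readings genuinely differ: for any arithmetic progression
all `d_i` are equal, so the MAD form is exactly 0 while the standard
form returns |step|/mean; for a strictly alternating series of even
length the positive differences outnumber the negative by one, so the
MAD form again collapses to 0 where the standard form gives the
magnitude of the scaled step. Because published MAPD definitions are
frequently garbled in methods prose, the package computes **both** and
reports both in every `qc_report()`; the default `variant = "mad"` is
the MAD form, with `variant = "median"` for the field-standard form.
Both are scale invariant, and the standard form rises monotonically
with simulated overdispersion, which the tests verify.

## Variant analysis

Annotation-level filtering excludes synonymous and non-coding variants
and those with population MAF above 1% (exclusion is strictly "> 1%", so
exactly 1% is retained). Somatic filtering requires, per specimen,
alt depth ≥ 10 AND VAF ≥ 5% AND total depth ≥ 250.

The **rescue rule** addresses serial specimens: a variant failing the
thresholds in some specimens is retained everywhere if the identical
variant (matched by chromosome, position and alleles — never by gene
symbol) fully passes in at least one specimen of the same case. This is
what keeps the early sub-threshold time points of a variant that later
rises: a VAF series like 3.6 → 4.4 → 9.5 → 12.4 (%) keeps its first two
records as "rescued". The clause could also be read as "any one
criterion met in any specimen suffices"; that laxer OR-reading is
implemented behind `rescue = "any_criterion"` but is not the default,
because with typical panel depths the total-depth criterion alone would
then rescue everything and the filter would lose its teeth. Rescue never
demotes: a passing record is never touched, and the filter is
idempotent.

Read-level presence in shallow (direct library preparation) data is
deliberately simple: after dropping bases below Q20, a variant is
present with ≥ 1 alt read (both floors exposed as parameters), absent
with coverage but fewer alt reads, uncallable without coverage. At
`min_alt_reads = 2` the false-presence rate at VAF 0, depth 30 and
error rate 1e-3 is about `choose(30,2) * 1e-6 ≈ 4e-4`, which a
10,000-replicate simulation in the acceptance suite bounds below 1e-3.

VAF trajectories are ordered by days after diagnosis and labeled from
first/last detection only: persisting, cleared, emergent, or
not_detected. No monotonicity in between is required — the label is a
bookkeeping device for report tables, not a model of clonal kinetics.

## Cytogenetics

`parse_iscn()` covers the ISCN subset needed for routine hematologic
karyotypes: modal counts and ranges (hyphen or en-dash), sex
designations, ±N gains/losses, structural tokens of the form
`del(20)(q11.2)` (also dup/inv/t), `?` qualifiers, `xN` multipliers,
cell counts `[7]`, composite counts `[cp3]`, and the stemline shorthands
`idem`/`sl`/`sdl`/`slxN`, which resolve against the first clone
(`slx2` doubles the stemline's aberration multiplicities, as in a
47→94 near-tetraploid doubling). Unparseable tokens are kept verbatim
in an `unparsed` list with a warning — never dropped silently. Full
ISCN 2016 is out of scope. `iscn_format()` serializes with stemline
references materialized, so a parse → format → parse cycle preserves
the resolved clone sets; the four packaged serial karyotypes round-trip
this way in the tests.

FISH tallies are rendered the way clinical tables render them: percent
= 100·positive/scored, rounded **half-up** to one decimal (report
rendering convention; the integer copy-number calls above use half-even
for the opposite reason). Positivity is judged against probe-specific
cutoffs at the 100/200/300 scored-cell brackets, shipped verbatim as a
JSON table; a percentage exactly at the cutoff is positive, and
off-bracket scored counts use the nearest bracket with a notice. The
non-PC:PC ratio is the direct quotient of positive counts, undefined
when no positive plasma cells were scored. Two cells of the clinical
report the packaged tallies were transcribed from differ from direct
arithmetic (a ratio rendered 7.0 where 20:3 divides to 6.7, and one
12.0 where 37:3 gives 12.3, likely rounded from percentage ratios
rather than counts); the package computes the direct quotient and the
tests record the divergence rather than imitating it.

## Lineage inference

Aberration groups × sorted populations form a binary character matrix.
Under the perfect-phylogeny model each character arises exactly once on
a rooted tree, which holds iff all pairwise character supports are
nested or disjoint (a laminar family); `check_perfect_phylogeny()`
returns every violating pair. `infer_clone_tree()` then builds the tree
deterministically: characters with identical support merge into one
edge labeled with the sorted member characters, edges nest by
support containment (laminarity makes the containment chain
unambiguous; ties between the root and a character carried by every
population resolve to the deeper node), populations attach below the
deepest edge they carry, and sibling order is lexicographic. The
defining invariant — the union of edge labels on a population's root
path equals its character set exactly — is asserted inside the function
and property-tested on random laminar matrices built from random
recursive partitions.

`map_to_template()` annotates each character edge with the deepest
compartment of a hematopoiesis scaffold consistent with the cell types
carrying it: the template LCA of the leaf slots of all populations below
the edge. Two scaffolds ship as JSON, a classical one (lymphoid-primed
branch under the multipotent progenitor, megakaryocyte/erythroid branch
under the common myeloid progenitor) and a composite one (the
megakaryocyte/erythroid branch leaving directly below the multipotent
progenitor); both encode only branch structure, nothing quantitative. A
character shared by plasma-cell and myeloblast populations therefore
lands at the lymphoid-primed multipotent progenitor in the classical
scaffold; a character private to erythrocytes lands on the erythrocyte
slot below the megakaryocyte/erythroid progenitor; populations with no
characters belong to the normal-karyotype root lineage. Annotation
never alters topology, and adding a carrier population can only move a
character's assignment rootward (an LCA property the tests check). The
packaged example matrix enters the granulocyte characters without the
neoplastic trunk character, since the granulocyte FISH evidence does
not establish it; entering them with it would move only their own
private edges, not the trunk.

## Synthetic data

The generator produces exactly the inputs the pipeline consumes, under
known truth:

- **Genomes** with parametric GC (constant / linear / sinusoid) and
  mappability (uniform / step) tracks on a fixed window grid (1 kbp
  default).
- **Bin counts**: expected count ∝ (CN/ploidy) × mappability ×
  max(0, b0 + b1·GC + b2·GC²), rescaled to the requested total, drawn
  negative-binomially with variance μ + αμ² (α = 0 degenerates to
  Poisson). The GC bias is multiplicative and clipped at 0, matching
  what the downstream normalization divides out. Real dispersion for
  20–30-cell pools is not documented anywhere we could anchor it, so α
  is a free knob; 0.02 is used in the validation studies as a
  realistic-looking noise level for shallow libraries, and the QC tests
  sweep α over 0–0.1.
- **Locus reads**: alt with probability VAF, then a sequencing error
  flips the observed allele at the error rate; base qualities around
  Q36.
- **FISH tallies**: multinomial draws per scored cell class.

Every simulator takes one explicit seed and is bit-reproducible; no
global RNG state leaks between calls. What the generator does **not**
emulate — amplification bias, fixation damage, alignment artifacts,
GC-mappability correlation, contamination — bounds what the passing
tests show: they demonstrate that the algorithms recover truth under
their own noise model at the stated settings, not that the workflow is
robust to every artifact of stained, fixed, laser-sorted material.

## Parameter summary

| Parameter | Default | Where | Why |
|---|---|---|---|
| `n_bins` | 10000 | binning | genome-wide bin count of the classical construction |
| `span` | 0.3 | GC lowess | smooth enough to keep CN signal out of the fit |
| `alpha` | 0.01 | CBS | split acceptance level, common CBS practice |
| `n_permutations` | 1000 | CBS | p-value resolution ~1e-3, early-stopped |
| `min_width` | 3 bins | CBS | smallest callable segment |
| `merge_p_threshold` | 1e-4 | MergeLevels | customary default of the procedure |
| `ploidy` | 2 | scaling | near-diploid baseline |
| `maf_threshold` | 0.01 | annotation filter | "> 1% MAF" exclusion |
| `alt_depth_min`, `vaf_min`, `total_depth_min` | 10, 5%, 250 | somatic filter | panel thresholds |
| `min_alt_reads`, `min_baseq` | 1, 20 | presence call | shallow-library presence floor |
| `dispersion` | 0 (sim), 0.02 (studies) | generator | free knob, see above |

## Known limitations

- The near-diploid scaling breaks on genomes that are mostly aberrant;
  no joint purity/ploidy estimation is attempted.
- Segmentation is breakpoint-form CBS; profiles dominated by short
  interior arcs at equal means on both flanks would favor the full
  circular statistic.
- No allele-specific copy number, no base-pair breakpoint refinement.
- The ISCN parser covers the reporting subset described above, not the
  full nomenclature.
- Lineage inference is combinatorial presence/absence placement; it does
  not deconvolve bulk VAFs, model mutation rates, or time events.
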