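Package: hemaclone
Title: Copy-Number Calling and Clonal Lineage Inference for Sorted
    Hematopoietic Cell Pools
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis workflow for sparse whole-genome sequencing of
    small, cytogenetically sorted pools of hematopoietic cells. Builds
    variable-size genomic bins with equal expected mappable read mass,
    GC-normalizes bin read densities, scales them to a near-diploid
    chromosomal copy-number scale, segments them with circular binary
    segmentation calibrated by permutation, merges statistically
    indistinguishable segment levels, and calls integer copy numbers and
    chromosome-, arm-, and focal-level aberrations. Companion modules
    compute bin-uniformity quality metrics (CV and MAPD), apply
    depth/VAF variant filters with a serial-specimen rescue rule, call
    read-level variant presence in shallow libraries, parse ISCN
    karyotype strings, evaluate FISH tallies against probe-specific
    cutoffs, and infer a rooted clone tree from a binary
    aberration-by-population matrix under the perfect-phylogeny model,
    mapped onto classical or composite hematopoiesis templates. A
    seeded synthetic-data generator produces bin counts, locus reads,
    and FISH tallies under known ground truth so the full pipeline can
    be exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    ape,
    vcfR,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
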