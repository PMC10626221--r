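# Small genomes/profiles shared across tests; everything generated in
# code so no fixture files are needed.

uniform_genome <- function(length_bp = 10e6, window = 1000, gc = 0.41) {
  make_genome(c(chr1 = length_bp),
              gc = list(model = "constant", value = gc),
              mappability = list(model = "uniform", weight = 1),
              window_size = window)
}

# the five-chromosome desk-scale recovery setting: whole-chromosome
# trisomy on chr2, q-arm monosomy on chr4, sinusoidal GC so GC is not
# confounded with segment position
recovery_setting <- function(n_bins = 500) {
  genome <- make_genome(
    c(chr1 = 50e6, chr2 = 50e6, chr3 = 50e6, chr4 = 50e6, chr5 = 50e6),
    gc = list(model = "sinusoid", mean = 0.45, amplitude = 0.08, period = 3.1e6),
    mappability = list(model = "uniform", weight = 1),
    window_size = 1e5)
  truth <- truth_profile(data.frame(
    chrom = c("chr2", "chr4"), start = c(0, 25e6), end = c(50e6, 50e6),
    cn = c(3L, 1L)))
  list(genome = genome,
       binmap = build_variable_bins(genome, n_bins),
       truth = truth,
       arms = data.frame(chrom = paste0("chr", 1:5), centromere = 25e6))
}
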