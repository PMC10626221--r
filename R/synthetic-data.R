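#' Synthetic genome model with GC and mappability tracks
#'
#' Builds an idealized genome for simulation: an ordered set of
#' chromosomes tiled by fixed-size windows (default 1 kbp), each window
#' carrying a GC fraction and a non-negative expected uniquely-mapped
#' read weight ("mappability"). The tracks stand in for the reference
#' genome context that real variable binning is computed from; they are
#' generated from simple parametric models so every downstream value has
#' a known closed form.
#'
#' GC models (\code{gc$model}):
#' \describe{
#'   \item{constant}{\code{value} everywhere.}
#'   \item{linear}{gradient from \code{from} at the chromosome start to
#'     \code{to} at the end.}
#'   \item{sinusoid}{\code{mean + amplitude * sin(2*pi*pos/period)},
#'     clipped to [0, 1]; \code{period} in bp.}
#' }
#' Mappability models (\code{mappability$model}):
#' \describe{
#'   \item{uniform}{constant \code{weight} (default 1).}
#'   \item{step}{\code{before} on the first \code{breakpoint} fraction
#'     of each chromosome, \code{after} on the rest.}
#' }
#'
#' @param lengths numeric vector of chromosome lengths in bp; names are
#'   chromosome names (default \code{chr1}, \code{chr2}, ...).
#' @param gc list describing the GC model (see Details).
#' @param mappability list describing the mappability model.
#' @param window_size track window size in bp (default 1000).
#' @param seed integer seed recorded with the model; the parametric
#'   track models are deterministic, so the seed matters only for model
#'   extensions that draw random tracks.
#' @return an object of class \code{genome_model}: a list with
#'   \code{chromosomes} (data.frame name/length), \code{window_size},
#'   and \code{windows} (data.frame chrom/start/end/gc/mappability,
#'   0-based half-open).
#' @examples
#' g <- make_genome(c(chrA = 1e6), gc = list(model = "constant", value = 0.41))
#' head(g$windows)
#' @export
make_genome <- function(lengths,
                        gc = list(model = "constant", value = 0.41),
                        mappability = list(model = "uniform", weight = 1),
                        window_size = 1000,
                        seed = 1L) {
  assert_that(length(lengths) >= 1, "at least one chromosome required")
  if (is.null(names(lengths))) names(lengths) <- paste0("chr", seq_along(lengths))
  bad <- names(lengths)[lengths <= 0]
  assert_that(length(bad) == 0,
              "non-positive length for chromosome(s): %s",
              paste(bad, collapse = ", "))
  assert_that(window_size >= 1, "window_size must be >= 1")

  win <- do.call(rbind, lapply(names(lengths), function(chr) {
    len <- lengths[[chr]]
    start <- seq(0, len - 1, by = window_size)
    end <- pmin(start + window_size, len)
    mid <- (start + end) / 2
    gcv <- switch(gc$model,
      constant = rep(gc$value, length(start)),
      linear   = gc$from + (gc$to - gc$from) * mid / len,
      sinusoid = gc$mean + gc$amplitude * sin(2 * pi * mid / gc$period),
      stop("unknown gc model: ", gc$model)
    )
    gcv <- pmin(pmax(gcv, 0), 1)
    mpv <- switch(mappability$model,
      uniform = rep(mappability$weight %||% 1, length(start)),
      step    = ifelse(mid < (mappability$breakpoint %||% 0.5) * len,
                       mappability$before, mappability$after),
      stop("unknown mappability model: ", mappability$model)
    )
    data.frame(chrom = chr, start = start, end = end,
               gc = gcv, mappability = mpv, stringsAsFactors = FALSE)
  }))
  assert_that(all(is.finite(win$mappability)) && all(win$mappability >= 0),
              "mappability weights must be finite and non-negative")
  assert_that(all(tapply(win$mappability, win$chrom, max) > 0),
              "every chromosome needs at least one positive-mappability window")

  structure(list(
    chromosomes = data.frame(name = names(lengths),
                             length = unname(as.numeric(lengths)),
                             stringsAsFactors = FALSE),
    window_size = window_size,
    windows = win,
    seed = as.integer(seed)
  ), class = "genome_model")
}

#' @export
print.genome_model <- function(x, ...) {
  cat(sprintf("genome_model: %d chromosome(s), %.1f Mbp, %d windows of %d bp\n",
              nrow(x$chromosomes), sum(x$chromosomes$length) / 1e6,
              nrow(x$windows), x$window_size))
  invisible(x)
}

#' Ground-truth integer copy-number profile
#'
#' Describes the simulated truth as non-overlapping half-open segments
#' with integer copy number; any region not covered by a segment sits at
#' the baseline ploidy (default 2, i.e. near-diploid).
#'
#' @param segments data.frame with columns \code{chrom}, \code{start},
#'   \code{end} (bp, 0-based half-open) and \code{cn} (integer >= 0).
#'   May have zero rows for an all-baseline genome.
#' @param ploidy baseline integer copy number for uncovered regions.
#' @return object of class \code{truth_profile}.
#' @export
truth_profile <- function(segments = NULL, ploidy = 2L) {
  if (is.null(segments)) {
    segments <- data.frame(chrom = character(), start = numeric(),
                           end = numeric(), cn = integer())
  }
  assert_that(all(c("chrom", "start", "end", "cn") %in% names(segments)),
              "segments need columns chrom, start, end, cn")
  assert_that(all(segments$cn >= 0), "copy numbers must be >= 0")
  assert_that(all(segments$end > segments$start), "segments must have end > start")
  for (chr in unique(segments$chrom)) {
    s <- segments[segments$chrom == chr, , drop = FALSE]
    s <- s[order(s$start), , drop = FALSE]
    if (nrow(s) > 1 && any(s$start[-1] < s$end[-nrow(s)]))
      stop("overlapping truth segments on ", chr)
  }
  structure(list(segments = segments, ploidy = as.integer(ploidy)),
            class = "truth_profile")
}

#' True copy number of each bin under a truth profile
#'
#' Length-weighted mean of the truth copy number over each bin, so a bin
#' straddling a truth breakpoint gets the proportional mixture.
#'
#' @param truth a \code{truth_profile}.
#' @param binmap a \code{bin_map} (see \code{\link{build_variable_bins}}).
#' @return numeric vector of per-bin true copy numbers.
#' @export
truth_bin_cn <- function(truth, binmap) {
  b <- binmap$bins
  cn <- rep(as.numeric(truth$ploidy), nrow(b))
  seg <- truth$segments
  if (nrow(seg) == 0) return(cn)
  for (i in seq_len(nrow(seg))) {
    sel <- b$chrom == seg$chrom[i] & b$end > seg$start[i] & b$start < seg$end[i]
    if (!any(sel)) next
    ov <- pmin(b$end[sel], seg$end[i]) - pmax(b$start[sel], seg$start[i])
    frac <- ov / (b$end[sel] - b$start[sel])
    cn[sel] <- cn[sel] + frac * (seg$cn[i] - truth$ploidy)
  }
  cn
}

#' Simulate per-bin read counts under a known copy-number truth
#'
#' The expected count of bin i is proportional to
#' \code{(CN_i / ploidy) * weight_i * max(0, b0 + b1*gc_i + b2*gc_i^2)},
#' rescaled so expectations sum to \code{total_reads}. Counts are drawn
#' from a negative binomial parameterized by mean \code{mu} and
#' dispersion \code{alpha} (variance \code{mu + alpha*mu^2});
#' \code{dispersion = 0} degenerates to Poisson.
#'
#' @param genome a \code{genome_model} the bin map was built on.
#' @param binmap a \code{bin_map}.
#' @param truth a \code{truth_profile}.
#' @param total_reads expected total read count (> 0).
#' @param gc_bias numeric length-3 \code{(b0, b1, b2)}: quadratic
#'   multiplicative GC bias on expected counts; default no bias.
#' @param dispersion overdispersion alpha >= 0.
#' @param seed integer seed; all randomness flows from it.
#' @return object of class \code{bin_counts}: list with \code{sample},
#'   \code{counts} (integer vector aligned to the bin map) and the
#'   simulation settings.
#' @export
simulate_bin_counts <- function(genome, binmap, truth, total_reads,
                                gc_bias = c(1, 0, 0), dispersion = 0,
                                seed = 1L, sample_id = "sim") {
  assert_that(total_reads > 0, "total_reads must be > 0")
  assert_that(dispersion >= 0, "dispersion must be >= 0")
  b <- binmap$bins
  chrlen <- stats::setNames(genome$chromosomes$length, genome$chromosomes$name)
  assert_that(all(b$chrom %in% names(chrlen)), "bin map chromosome not in genome")
  assert_that(all(b$end <= chrlen[b$chrom] + 1e-9), "bin extends beyond chromosome end")

  cn <- truth_bin_cn(truth, binmap)
  bias <- pmax(0, gc_bias[1] + gc_bias[2] * b$gc + gc_bias[3] * b$gc^2)
  e <- (cn / truth$ploidy) * b$weight * bias
  assert_that(sum(e) > 0, "all expected counts are zero")
  mu <- total_reads * e / sum(e)

  set.seed(as.integer(seed))
  counts <- if (dispersion == 0) {
    stats::rpois(length(mu), mu)
  } else {
    stats::rnbinom(length(mu), size = 1 / dispersion, mu = mu)
  }
  structure(list(sample = sample_id, counts = as.integer(counts),
                 settings = list(total_reads = total_reads, gc_bias = gc_bias,
                                 dispersion = dispersion, seed = as.integer(seed))),
            class = "bin_counts")
}

#' Simulate reads overlapping a variant locus
#'
#' Each read's true allele is alt with probability \code{vaf}; a
#' sequencing error then flips the observed allele (ref to alt or alt to
#' ref) with probability \code{error_rate}. Base qualities are drawn
#' around Q36.
#'
#' @param depth number of reads at the locus; 0 yields an empty read set.
#' @param vaf variant allele fraction in [0, 1].
#' @param error_rate per-base error probability in [0, 0.5).
#' @param seed integer seed.
#' @return data.frame with columns \code{allele} ("ref"/"alt") and
#'   \code{baseq}.
#' @export
simulate_locus_reads <- function(depth, vaf, error_rate = 0.001, seed = 1L) {
  assert_that(vaf >= 0 && vaf <= 1, "vaf must be in [0, 1]")
  assert_that(error_rate >= 0 && error_rate < 0.5, "error_rate must be in [0, 0.5)")
  if (depth == 0) {
    return(data.frame(allele = character(), baseq = numeric()))
  }
  set.seed(as.integer(seed))
  alt <- stats::runif(depth) < vaf
  flip <- stats::runif(depth) < error_rate
  alt <- xor(alt, flip)
  baseq <- pmin(pmax(round(stats::rnorm(depth, mean = 36, sd = 3)), 2), 41)
  data.frame(allele = ifelse(alt, "alt", "ref"), baseq = baseq,
             stringsAsFactors = FALSE)
}

#' Simulate a FISH cell tally
#'
#' Draws, for each scored cell class (e.g. TNC, PC), a multinomial tally
#' of signal patterns from the class's true pattern fractions.
#'
#' @param true_fractions named numeric vector of pattern fractions
#'   summing to 1, or a named list of such vectors (one per class).
#' @param n_cells named integer vector: cells scored per class.
#' @param seed integer seed.
#' @return data.frame with columns \code{class}, \code{pattern},
#'   \code{count}; counts within each class sum to that class's
#'   \code{n_cells}.
#' @export
simulate_fish_tally <- function(true_fractions, n_cells, seed = 1L) {
  if (is.null(names(n_cells))) names(n_cells) <- paste0("class", seq_along(n_cells))
  set.seed(as.integer(seed))
  out <- lapply(names(n_cells), function(cl) {
    fr <- if (is.list(true_fractions)) true_fractions[[cl]] else true_fractions
    assert_that(!is.null(fr), "no pattern fractions for class %s", cl)
    assert_that(abs(sum(fr) - 1) < 1e-9,
                "pattern fractions for class %s must sum to 1", cl)
    k <- stats::rmultinom(1, size = n_cells[[cl]], prob = fr)[, 1]
    data.frame(class = cl, pattern = names(fr), count = as.integer(k),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Write a genome model to disk
#'
#' Chromosome table and window size go to JSON; the GC and mappability
#' tracks to a TSV (chrom, start, end, gc, mappability).
#'
#' @param genome a \code{genome_model}.
#' @param json_path,track_path output paths.
#' @export
write_genome_model <- function(genome, json_path, track_path) {
  jsonlite::write_json(list(chromosomes = genome$chromosomes,
                            window_size = genome$window_size,
                            seed = genome$seed),
                       json_path, auto_unbox = TRUE, digits = NA)
  utils::write.table(genome$windows, track_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(genome)
}

#' Read a genome model written by \code{write_genome_model}
#' @param json_path,track_path input paths.
#' @return a \code{genome_model}.
#' @export
read_genome_model <- function(json_path, track_path) {
  meta <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  win <- utils::read.delim(track_path, stringsAsFactors = FALSE)
  structure(list(chromosomes = as.data.frame(meta$chromosomes),
                 window_size = meta$window_size,
                 windows = win,
                 seed = as.integer(meta$seed %||% 1L)),
            class = "genome_model")
}
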