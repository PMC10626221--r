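#' Build variable-size bins with equal expected mappable read mass
#'
#' Partitions the genome into \code{n_bins} bins such that every bin
#' carries (nearly) the same total mappability weight, i.e. the same
#' expected number of uniquely mapped reads under a copy-neutral
#' genome. Bin counts are first apportioned to chromosomes in
#' proportion to their total weight (largest-remainder rounding, at
#' least one bin per chromosome with positive weight), then each
#' chromosome's cumulative weight is split into equal quanta. Bin
#' boundaries snap to track-window edges: a bin closes at the first
#' window whose inclusion meets its cumulative target, and any residual
#' weight carries into the next bin. Bins never cross chromosome
#' boundaries, tile each chromosome exactly, and are 0-based half-open.
#'
#' In deep-sequenced human data this construction yields the familiar
#' genome-wide grids (e.g. 10,000 bins with a median size of a few
#' hundred kbp); on synthetic genomes the bin sizes follow the supplied
#' mappability model exactly.
#'
#' @param genome a \code{genome_model}.
#' @param n_bins number of bins (default 10000).
#' @return object of class \code{bin_map}: list with \code{bins}
#'   (data.frame chrom/start/end/gc/weight) and \code{n_bins}.
#' @export
build_variable_bins <- function(genome, n_bins = 10000) {
  assert_that(n_bins >= 1, "n_bins must be >= 1")
  win <- genome$windows
  total_w <- sum(win$mappability)
  assert_that(total_w > 0, "genome has no positive mappability")

  chroms <- genome$chromosomes$name
  chrom_w <- vapply(chroms, function(ch) sum(win$mappability[win$chrom == ch]), 0)
  pos_ch <- chroms[chrom_w > 0]
  n_pos_windows <- vapply(pos_ch, function(ch)
    sum(win$chrom == ch & win$mappability > 0), 0L)
  assert_that(n_bins <= sum(n_pos_windows),
              "n_bins (%d) exceeds the %d positive-weight windows",
              n_bins, sum(n_pos_windows))
  assert_that(n_bins >= length(pos_ch),
              "need at least one bin per chromosome with positive weight (%d)",
              length(pos_ch))

  # largest-remainder apportionment of bins to chromosomes
  share <- n_bins * chrom_w[pos_ch] / sum(chrom_w[pos_ch])
  alloc <- pmax(floor(share), 1)
  rem <- n_bins - sum(alloc)
  if (rem > 0) {
    ord <- order(share - floor(share), decreasing = TRUE)
    take <- head(ord[alloc[ord] < n_pos_windows[ord]], rem)
    alloc[take] <- alloc[take] + 1
  } else if (rem < 0) {
    ord <- order(share - floor(share))
    take <- head(ord[alloc[ord] > 1], -rem)
    alloc[take] <- alloc[take] - 1
  }
  assert_that(sum(alloc) == n_bins, "bin apportionment failed")
  assert_that(all(alloc <= n_pos_windows),
              "a chromosome was allotted more bins than positive windows")

  bins <- do.call(rbind, lapply(seq_along(pos_ch), function(ci) {
    ch <- pos_ch[ci]
    w <- win[win$chrom == ch, , drop = FALSE]
    k <- alloc[ci]
    quantum <- sum(w$mappability) / k
    cum <- cumsum(w$mappability)
    # first window index at which each cumulative target is met
    cut_idx <- integer(k)
    j <- 1L
    for (b in seq_len(k - 1)) {
      target <- b * quantum
      while (cum[j] < target * (1 - 1e-12)) j <- j + 1L
      cut_idx[b] <- j
      j <- j + 1L
      if (j > nrow(w)) j <- nrow(w)
    }
    cut_idx[k] <- nrow(w)
    cut_idx <- pmin(cummax(cut_idx), nrow(w))
    first <- c(1L, head(cut_idx, -1) + 1L)
    last <- cut_idx
    len <- w$end - w$start
    data.frame(
      chrom = ch,
      start = w$start[first],
      end = w$end[last],
      gc = vapply(seq_len(k), function(b) {
        i <- first[b]:last[b]
        sum(w$gc[i] * len[i]) / sum(len[i])
      }, 0),
      weight = vapply(seq_len(k), function(b)
        sum(w$mappability[first[b]:last[b]]), 0),
      stringsAsFactors = FALSE
    )
  }))
  rownames(bins) <- NULL
  structure(list(bins = bins, n_bins = nrow(bins)), class = "bin_map")
}

#' @export
print.bin_map <- function(x, ...) {
  sz <- x$bins$end - x$bins$start
  cat(sprintf("bin_map: %d bins on %d chromosome(s), median size %.0f bp\n",
              x$n_bins, length(unique(x$bins$chrom)), stats::median(sz)))
  invisible(x)
}

#' Per-bin GC content
#'
#' Length-weighted mean of track-window GC over each bin. Because bin
#' boundaries snap to window edges, every window contributes wholly to
#' one bin.
#'
#' @param genome the \code{genome_model} the bins were built on.
#' @param binmap a \code{bin_map}.
#' @return numeric vector of per-bin GC fractions in [0, 1].
#' @export
compute_bin_gc <- function(genome, binmap) {
  b <- binmap$bins
  win <- genome$windows
  out <- numeric(nrow(b))
  for (ch in unique(b$chrom)) {
    wi <- win[win$chrom == ch, , drop = FALSE]
    bi <- which(b$chrom == ch)
    idx <- findInterval(wi$start, b$start[bi])
    len <- wi$end - wi$start
    keep <- idx >= 1
    num <- tapply(wi$gc[keep] * len[keep], idx[keep], sum)
    den <- tapply(len[keep], idx[keep], sum)
    out[bi[as.integer(names(num))]] <- num / den
  }
  out
}

#' Count read start positions in bins
#'
#' Assigns each read to the unique bin whose half-open interval
#' contains its start position. Reads outside any bin are dropped from
#' the tally (their number is reported in the returned object).
#'
#' @param reads data.frame with columns \code{chrom} and \code{pos}
#'   (0-based read start). Unsorted input is sorted internally with a
#'   notice.
#' @param binmap a \code{bin_map}.
#' @param sample_id label stored with the counts.
#' @return object of class \code{bin_counts}.
#' @export
count_reads_in_bins <- function(reads, binmap, sample_id = "sample") {
  b <- binmap$bins
  if (nrow(reads) > 1) {
    o <- order(reads$chrom, reads$pos)
    if (any(o != seq_len(nrow(reads)))) {
      message("count_reads_in_bins: input not sorted; sorting internally")
      reads <- reads[o, , drop = FALSE]
    }
  }
  counts <- integer(nrow(b))
  dropped <- 0L
  for (ch in unique(reads$chrom)) {
    bi <- which(b$chrom == ch)
    pos <- reads$pos[reads$chrom == ch]
    if (length(bi) == 0) { dropped <- dropped + length(pos); next }
    idx <- findInterval(pos, b$start[bi])
    ok <- idx >= 1 & pos < b$end[bi][pmax(idx, 1)]
    dropped <- dropped + sum(!ok)
    tab <- tabulate(idx[ok], nbins = length(bi))
    counts[bi] <- counts[bi] + tab
  }
  structure(list(sample = sample_id, counts = counts,
                 settings = list(n_reads = nrow(reads), dropped = dropped)),
            class = "bin_counts")
}

#' @export
print.bin_counts <- function(x, ...) {
  cat(sprintf("bin_counts '%s': %d bins, total %d reads\n",
              x$sample, length(x$counts), sum(x$counts)))
  invisible(x)
}

#' Write a bin map as BED5
#'
#' Columns: chrom, start, end, name (bin index), score (GC x 1000).
#'
#' @param binmap a \code{bin_map}.
#' @param path output path.
#' @export
write_bin_map <- function(binmap, path) {
  b <- binmap$bins
  bed <- data.frame(chrom = b$chrom,
                    start = format(b$start, scientific = FALSE, trim = TRUE),
                    end = format(b$end, scientific = FALSE, trim = TRUE),
                    name = paste0("bin_", seq_len(nrow(b))),
                    score = round(b$gc * 1000))
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(binmap)
}

#' Read a bin map from BED5
#'
#' If a \code{genome_model} is supplied, per-bin GC and mappability
#' weight are recomputed from its tracks; otherwise GC is taken from
#' the score column and weights default to 1 (equal by construction).
#'
#' @param path BED5 file from \code{\link{write_bin_map}}.
#' @param genome optional \code{genome_model}.
#' @return a \code{bin_map}.
#' @export
read_bin_map <- function(path, genome = NULL) {
  bed <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  bins <- data.frame(chrom = bed[[1]], start = bed[[2]], end = bed[[3]],
                     gc = bed[[5]] / 1000, weight = 1,
                     stringsAsFactors = FALSE)
  bm <- structure(list(bins = bins, n_bins = nrow(bins)), class = "bin_map")
  if (!is.null(genome)) {
    bm$bins$gc <- compute_bin_gc(genome, bm)
    win <- genome$windows
    bm$bins$weight <- vapply(seq_len(nrow(bins)), function(i) {
      sel <- win$chrom == bins$chrom[i] & win$start >= bins$start[i] &
        win$start < bins$end[i]
      sum(win$mappability[sel])
    }, 0)
  }
  bm
}

#' Write bin counts as TSV (chrom, start, end, count)
#' @param counts a \code{bin_counts}.
#' @param binmap the matching \code{bin_map}.
#' @param path output path.
#' @export
write_bin_counts <- function(counts, binmap, path) {
  assert_that(length(counts$counts) == binmap$n_bins,
              "counts and bin map lengths differ")
  df <- data.frame(chrom = binmap$bins$chrom,
                   start = format(binmap$bins$start, scientific = FALSE, trim = TRUE),
                   end = format(binmap$bins$end, scientific = FALSE, trim = TRUE),
                   count = counts$counts)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(counts)
}

#' Read bin counts from TSV written by \code{write_bin_counts}
#' @param path input path.
#' @param sample_id label for the counts.
#' @return a \code{bin_counts}.
#' @export
read_bin_counts <- function(path, sample_id = "sample") {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  structure(list(sample = sample_id, counts = as.integer(df$count),
                 settings = list(path = path)),
            class = "bin_counts")
}
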