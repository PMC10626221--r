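#' GC-normalize bin read counts
#'
#' Fits the dependence of counts on bin GC content and divides it out,
#' returning a normalized read density rescaled to mean 1. The default
#' smoother is lowess with span 0.3; a quadratic polynomial fit is
#' available as a fallback for very small or degenerate inputs. Fitted
#' values are floored at the 1st percentile of the positive fits so a
#' few extreme-GC bins cannot blow up the ratio.
#'
#' @param counts a \code{bin_counts} object or numeric vector of raw
#'   per-bin counts.
#' @param gc per-bin GC fractions aligned to \code{counts}.
#' @param method "lowess" (default) or "quadratic".
#' @param span lowess span (fraction of points), default 0.3.
#' @return numeric vector of normalized densities (mean 1).
#' @export
gc_normalize <- function(counts, gc, method = c("lowess", "quadratic"),
                         span = 0.3) {
  method <- match.arg(method)
  x <- if (inherits(counts, "bin_counts")) counts$counts else counts
  assert_that(length(x) == length(gc), "counts and gc lengths differ")
  if (length(x) < 10) {
    warning("fewer than 10 bins: falling back to global-mean normalization")
    return(x / mean(x))
  }
  if (stats::sd(gc) < 1e-12) {
    fitted <- rep(mean(x), length(x))
  } else if (method == "lowess") {
    fit <- stats::lowess(gc, x, f = span)
    fitted <- stats::approx(fit$x, fit$y, xout = gc, rule = 2, ties = mean)$y
  } else {
    fitted <- stats::fitted(stats::lm(x ~ gc + I(gc^2)))
  }
  pos <- fitted[fitted > 0]
  if (length(pos) == 0) {
    warning("GC fit non-positive everywhere: falling back to global mean")
    fitted <- rep(mean(x), length(x))
  } else {
    fitted <- pmax(fitted, stats::quantile(pos, 0.01))
  }
  dens <- x / fitted
  dens / mean(dens)
}

#' Scale normalized density to chromosomal copy number
#'
#' Divides the density by its median and multiplies by the baseline
#' ploidy, so the median bin sits exactly at the baseline. This assumes
#' the sample is near-diploid: most of the genome at the baseline copy
#' number.
#'
#' @param density per-bin normalized density (from
#'   \code{\link{gc_normalize}}).
#' @param ploidy baseline integer copy number (default 2).
#' @return per-bin copy-number ratios with median exactly \code{ploidy}.
#' @export
to_copy_number_scale <- function(density, ploidy = 2L) {
  med <- stats::median(density)
  assert_that(med > 0, "median density is not positive (all-zero input?)")
  ploidy * density / med
}

# max two-sample t over breakpoints of a series; returns c(stat, k)
# pooled-variance t between x[1:k] and x[(k+1):n], k in [min_width, n-min_width]
max_t_split <- function(x, min_width) {
  n <- length(x)
  if (n < 2 * min_width) return(c(stat = -Inf, k = NA))
  ks <- min_width:(n - min_width)
  cs <- cumsum(x)
  css <- cumsum(x^2)
  m1 <- cs[ks] / ks
  m2 <- (cs[n] - cs[ks]) / (n - ks)
  ss1 <- css[ks] - cs[ks]^2 / ks
  ss2 <- (css[n] - css[ks]) - (cs[n] - cs[ks])^2 / (n - ks)
  sp2 <- pmax((ss1 + ss2) / (n - 2), 0)
  se <- sqrt(sp2 * (1 / ks + 1 / (n - ks)))
  tt <- ifelse(se > 0, abs(m1 - m2) / se,
               ifelse(abs(m1 - m2) > 0, Inf, 0))
  i <- which.max(tt)
  c(stat = tt[i], k = ks[i])
}

# permutation p-value of the max-t split with early stopping
perm_split_p <- function(x, t_obs, n_permutations, alpha, min_width) {
  hits <- 0L
  # once hits can no longer yield p < alpha, stop
  stop_at <- ceiling(alpha * (n_permutations + 1))
  for (i in seq_len(n_permutations)) {
    tp <- max_t_split(sample(x), min_width)[["stat"]]
    if (tp >= t_obs) hits <- hits + 1L
    if (hits >= stop_at) return((hits + 1) / (i + 1))
  }
  (hits + 1) / (n_permutations + 1)
}

#' Segment copy-number ratios by circular binary segmentation
#'
#' Recursive binary splitting per chromosome: within each candidate
#' segment the breakpoint maximizing the pooled two-sample t statistic
#' is found, its significance is assessed against a permutation null
#' (values shuffled within the segment), and the split is accepted iff
#' the permutation p-value is below \code{alpha} and both parts have at
#' least \code{min_width} bins. Accepted splits recurse until no
#' further significant change point exists. Chromosomes are segmented
#' independently.
#'
#' @param cn per-bin copy-number ratios.
#' @param chrom per-bin chromosome labels aligned to \code{cn}.
#' @param alpha significance level for accepting a split (default 0.01).
#' @param n_permutations permutations per test (default 1000; fewer
#'   than 100 triggers a warning about unstable p-values). Permutation
#'   loops stop early once the p-value is decided.
#' @param min_width minimum bins per segment (default 3).
#' @param seed integer seed for the permutation RNG.
#' @return data.frame of segments with columns \code{chrom},
#'   \code{first_bin}, \code{last_bin} (1-based inclusive global bin
#'   indices) and \code{mean} (arithmetic mean of the segment's bins).
#' @export
cbs_segment <- function(cn, chrom, alpha = 0.01, n_permutations = 1000,
                        min_width = 3, seed = 1L) {
  assert_that(length(cn) == length(chrom), "cn and chrom lengths differ")
  if (n_permutations < 100)
    warning("n_permutations < 100: permutation p-values will be unstable")
  set.seed(as.integer(seed))

  split_rec <- function(x, offset) {
    n <- length(x)
    res <- max_t_split(x, min_width)
    accept <- FALSE
    if (is.finite(res[["stat"]]) && res[["stat"]] > 0) {
      p <- perm_split_p(x, res[["stat"]], n_permutations, alpha, min_width)
      accept <- p < alpha
    }
    if (!accept) {
      return(data.frame(first_bin = offset + 1L, last_bin = offset + n,
                        mean = mean(x)))
    }
    k <- res[["k"]]
    rbind(split_rec(x[1:k], offset),
          split_rec(x[(k + 1):n], offset + k))
  }

  out <- do.call(rbind, lapply(unique(chrom), function(ch) {
    idx <- which(chrom == ch)
    assert_that(length(idx) >= 2, "chromosome %s has fewer than 2 bins", ch)
    segs <- split_rec(cn[idx], idx[1] - 1L)
    segs$chrom <- ch
    segs
  }))
  rownames(out) <- NULL
  out[, c("chrom", "first_bin", "last_bin", "mean")]
}

#' Merge segment levels that are statistically indistinguishable
#'
#' Post-segmentation merging to suppress false-positive copy-number
#' levels: starting from one level per segment, the pair of distinct
#' levels with the closest means is compared by a Wilcoxon rank-sum
#' test on their member bins' copy-number ratios. If the test cannot
#' distinguish them (p > \code{threshold}), the two levels merge and
#' means are recomputed; the procedure repeats until the closest pair
#' differs significantly. Segment boundaries are never changed, only
#' the level assignment is coarsened.
#'
#' @param segments segment data.frame from \code{\link{cbs_segment}}.
#' @param cn per-bin copy-number ratios the segments were built from.
#' @param threshold p-value above which levels are merged (default
#'   1e-4, the procedure's customary default).
#' @return the segment data.frame with an added integer \code{level}
#'   column (levels numbered by increasing mean) and \code{level_mean}.
#' @export
merge_levels <- function(segments, cn, threshold = 1e-4) {
  seg <- segments
  level <- seq_len(nrow(seg))
  bins_of <- function(lv) {
    unlist(lapply(which(level == lv), function(i)
      seg$first_bin[i]:seg$last_bin[i]))
  }
  repeat {
    lvs <- unique(level)
    if (length(lvs) < 2) break
    means <- vapply(lvs, function(lv) mean(cn[bins_of(lv)]), 0)
    o <- order(means)
    gaps <- diff(means[o])
    j <- which.min(gaps)
    a <- lvs[o[j]]; b <- lvs[o[j + 1]]
    p <- suppressWarnings(
      stats::wilcox.test(cn[bins_of(a)], cn[bins_of(b)], exact = FALSE)$p.value)
    if (is.na(p)) p <- 1
    if (p > threshold) {
      level[level == b] <- a
    } else break
  }
  lvs <- unique(level)
  means <- vapply(lvs, function(lv) mean(cn[bins_of(lv)]), 0)
  renum <- stats::setNames(rank(means, ties.method = "first"), lvs)
  seg$level <- as.integer(renum[as.character(level)])
  lv_mean <- stats::setNames(means, renum[as.character(lvs)])
  seg$level_mean <- as.numeric(lv_mean[as.character(seg$level)])
  seg
}

#' Assemble a copy-number profile and call integer copy numbers
#'
#' The mean copy-number ratio over all bins of a (merged) level is
#' taken as the level's true copy number; the integer call is its
#' round-half-even value, floored at zero. Both the real-valued level
#' mean and the integer call are stored per segment.
#'
#' @param sample_id sample label.
#' @param density per-bin normalized density.
#' @param cn per-bin copy-number ratios.
#' @param segments merged segment data.frame (from
#'   \code{\link{merge_levels}}; plain \code{\link{cbs_segment}} output
#'   is accepted, each segment then being its own level).
#' @return object of class \code{copy_number_profile}.
#' @export
call_segment_cn <- function(sample_id, density, cn, segments) {
  seg <- segments
  if (is.null(seg$level)) {
    seg$level <- seq_len(nrow(seg))
    seg$level_mean <- seg$mean
  }
  seg$cn_call <- pmax(as.integer(round(seg$level_mean)), 0L)
  structure(list(sample = sample_id, density = density, cn = cn,
                 segments = seg),
            class = "copy_number_profile")
}

#' @export
print.copy_number_profile <- function(x, ...) {
  cat(sprintf("copy_number_profile '%s': %d bins, %d segments, %d levels\n",
              x$sample, length(x$cn), nrow(x$segments),
              length(unique(x$segments$level))))
  invisible(x)
}

#' Per-bin integer copy-number calls of a profile
#' @param profile a \code{copy_number_profile}.
#' @return integer vector, one call per bin.
#' @export
profile_bin_calls <- function(profile) {
  seg <- profile$segments
  out <- integer(length(profile$cn))
  for (i in seq_len(nrow(seg)))
    out[seg$first_bin[i]:seg$last_bin[i]] <- seg$cn_call[i]
  out
}

#' Full bin-counts-to-profile pipeline
#'
#' Convenience wrapper chaining GC normalization, copy-number scaling,
#' segmentation, level merging, and integer calling.
#'
#' @param counts a \code{bin_counts} object or numeric vector.
#' @param binmap the matching \code{bin_map}.
#' @param ploidy baseline ploidy (default 2).
#' @param gc_method,gc_span passed to \code{\link{gc_normalize}}.
#' @param alpha,n_permutations,min_width,seed passed to
#'   \code{\link{cbs_segment}}.
#' @param merge_threshold passed to \code{\link{merge_levels}}.
#' @return a \code{copy_number_profile}.
#' @export
call_copy_number <- function(counts, binmap, ploidy = 2L,
                             gc_method = "lowess", gc_span = 0.3,
                             alpha = 0.01, n_permutations = 1000,
                             min_width = 3, merge_threshold = 1e-4,
                             seed = 1L) {
  sample_id <- if (inherits(counts, "bin_counts")) counts$sample else "sample"
  density <- gc_normalize(counts, binmap$bins$gc, method = gc_method,
                          span = gc_span)
  cn <- to_copy_number_scale(density, ploidy)
  segs <- cbs_segment(cn, binmap$bins$chrom, alpha = alpha,
                      n_permutations = n_permutations,
                      min_width = min_width, seed = seed)
  segs <- merge_levels(segs, cn, threshold = merge_threshold)
  call_segment_cn(sample_id, density, cn, segs)
}

#' Extract chromosome-, arm-, and focal-level aberration calls
#'
#' A whole-chromosome call is made when at least 90% of a chromosome's
#' bins share the same off-baseline integer copy number; an arm-level
#' call when at least 90% of an arm's bins do (requires centromere
#' annotation); remaining off-baseline segments become focal calls.
#' Labels follow cytogenetic usage: "polysomy 8" for a whole-chromosome
#' gain, "monosomy 7" for a loss, "20q deletion" / "5p gain" for arms.
#'
#' @param profile a \code{copy_number_profile}.
#' @param binmap the matching \code{bin_map}.
#' @param arms optional data.frame with columns \code{chrom} and
#'   \code{centromere} (bp); when missing, only whole-chromosome calls
#'   are made and a notice is logged.
#' @param ploidy baseline ploidy (default 2).
#' @param min_fraction fraction of bins that must share the call
#'   (default 0.9).
#' @return data.frame with columns \code{kind}, \code{chrom},
#'   \code{arm}, \code{cn}, \code{label} (zero rows if all baseline).
#' @export
extract_aberrations <- function(profile, binmap, arms = NULL, ploidy = 2L,
                                min_fraction = 0.9) {
  bin_cn <- profile_bin_calls(profile)
  b <- binmap$bins
  if (is.null(arms)) message("no arm annotation: whole-chromosome calls only")
  calls <- list()
  add <- function(kind, chrom, arm, cn, label) {
    calls[[length(calls) + 1]] <<- data.frame(
      kind = kind, chrom = chrom, arm = arm, cn = cn, label = label,
      stringsAsFactors = FALSE)
  }
  chrom_num <- function(ch) sub("^chr", "", ch)

  for (ch in unique(b$chrom)) {
    idx <- which(b$chrom == ch)
    vals <- bin_cn[idx]
    off <- vals[vals != ploidy]
    done <- FALSE
    if (length(off) > 0) {
      mode_cn <- as.integer(names(sort(table(off), decreasing = TRUE))[1])
      if (mean(vals == mode_cn) >= min_fraction) {
        kind <- if (mode_cn > ploidy) "whole-chromosome gain" else "whole-chromosome loss"
        lab <- if (mode_cn > ploidy) paste("polysomy", chrom_num(ch))
               else paste("monosomy", chrom_num(ch))
        add(kind, ch, NA, mode_cn, lab)
        done <- TRUE
      }
    }
    if (done || length(off) == 0) next

    arm_bins <- rep(NA_character_, length(idx))
    if (!is.null(arms) && ch %in% arms$chrom) {
      cen <- arms$centromere[match(ch, arms$chrom)]
      arm_bins <- ifelse(b$start[idx] < cen, "p", "q")
      for (a in c("p", "q")) {
        ai <- idx[arm_bins == a]
        if (length(ai) == 0) next
        av <- bin_cn[ai]
        aoff <- av[av != ploidy]
        if (length(aoff) == 0) next
        mode_cn <- as.integer(names(sort(table(aoff), decreasing = TRUE))[1])
        if (mean(av == mode_cn) >= min_fraction) {
          kind <- if (mode_cn > ploidy) "arm-level gain" else "arm-level loss"
          lab <- if (mode_cn > ploidy)
            paste0(chrom_num(ch), a, " gain")
          else paste0(chrom_num(ch), a, " deletion")
          add(kind, ch, a, mode_cn, lab)
          arm_bins[arm_bins == a] <- "called"
        }
      }
    }
    # focal calls: runs of off-baseline segments not covered above
    seg <- profile$segments[profile$segments$chrom == ch, , drop = FALSE]
    for (i in seq_len(nrow(seg))) {
      if (seg$cn_call[i] == ploidy) next
      sb <- seg$first_bin[i]:seg$last_bin[i]
      covered <- arm_bins[match(sb, idx)] == "called"
      if (all(covered %in% TRUE)) next
      add("focal", ch, NA, seg$cn_call[i],
          sprintf("focal %s:%s-%s CN %d", chrom_num(ch),
                  format(b$start[sb[1]], scientific = FALSE),
                  format(b$end[sb[length(sb)]], scientific = FALSE),
                  seg$cn_call[i]))
    }
  }
  if (length(calls) == 0) {
    return(data.frame(kind = character(), chrom = character(),
                      arm = character(), cn = integer(), label = character()))
  }
  out <- do.call(rbind, calls)
  rownames(out) <- NULL
  out
}

#' Write profile segments as BED-like TSV
#'
#' Columns: chrom, start, end, mean_cn (segment mean), integer_cn,
#' level.
#'
#' @param profile a \code{copy_number_profile}.
#' @param binmap the matching \code{bin_map}.
#' @param path output path.
#' @export
write_segments <- function(profile, binmap, path) {
  seg <- profile$segments
  b <- binmap$bins
  df <- data.frame(chrom = seg$chrom,
                   start = format(b$start[seg$first_bin], scientific = FALSE, trim = TRUE),
                   end = format(b$end[seg$last_bin], scientific = FALSE, trim = TRUE),
                   mean_cn = round(seg$mean, 4),
                   integer_cn = seg$cn_call,
                   level = seg$level)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(profile)
}
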