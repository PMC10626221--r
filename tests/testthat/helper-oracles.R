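# Independent oracles, deliberately written as plain loops over the
# textbook formulas so they share no code with the package internals.

# best single changepoint by the pooled two-sample t statistic
oracle_best_split <- function(x, min_width = 3) {
  n <- length(x)
  best <- c(stat = -Inf, k = NA)
  for (k in min_width:(n - min_width)) {
    a <- x[1:k]; b <- x[(k + 1):n]
    sp2 <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) / (n - 2)
    se <- sqrt(sp2 * (1 / k + 1 / (n - k)))
    tt <- if (se > 0) abs(mean(a) - mean(b)) / se
          else if (mean(a) != mean(b)) Inf else 0
    if (tt > best[["stat"]]) best <- c(stat = tt, k = k)
  }
  best
}

# brute-force variable-bin boundaries: cumulative walk to k*quantum
oracle_bin_boundaries <- function(weights, ends, n_bins) {
  quantum <- sum(weights) / n_bins
  bounds <- numeric(n_bins)
  cum <- 0
  k <- 1
  for (i in seq_along(weights)) {
    cum <- cum + weights[i]
    while (k < n_bins && cum >= k * quantum * (1 - 1e-12)) {
      bounds[k] <- ends[i]
      k <- k + 1
      break
    }
  }
  bounds[n_bins] <- ends[length(ends)]
  bounds
}

# pairwise nested-or-disjoint check, straight from the definition
oracle_laminar <- function(mat) {
  nc <- ncol(mat)
  if (nc < 2) return(TRUE)
  for (i in 1:(nc - 1)) {
    for (j in (i + 1):nc) {
      s1 <- which(mat[, i] == 1)
      s2 <- which(mat[, j] == 1)
      inter <- intersect(s1, s2)
      if (length(inter) > 0 &&
          !all(s1 %in% s2) && !all(s2 %in% s1)) return(FALSE)
    }
  }
  TRUE
}

# random laminar (perfect-phylogeny compatible) matrix: recursively
# partition the populations into a random tree; every block of the
# recursion is laminar with every other, and characters are hung on
# randomly chosen blocks (with replacement, so identical support sets
# can occur and must merge into shared edges)
random_laminar_matrix <- function(n_pops, n_chars, seed) {
  set.seed(seed)
  sets <- list()
  recurse <- function(s) {
    sets[[length(sets) + 1]] <<- s
    if (length(s) >= 2 && stats::runif(1) < 0.85) {
      k <- sample(length(s) - 1, 1)
      a <- sort(sample(s, k))
      recurse(a)
      recurse(sort(setdiff(s, a)))
    }
  }
  recurse(seq_len(n_pops))
  take <- sample(length(sets), n_chars, replace = TRUE)
  mat <- matrix(0L, n_pops, n_chars,
                dimnames = list(paste0("p", seq_len(n_pops)),
                                paste0("c", seq_len(n_chars))))
  for (j in seq_along(take)) mat[sets[[take[j]]], j] <- 1L
  mat
}

mk_cm <- function(mat) {
  types <- stats::setNames(rep("other", nrow(mat)), rownames(mat))
  character_matrix(mat, types)
}

case_matrix <- function() {
  read_character_matrix(system.file("extdata", "case_character_matrix.tsv",
                                    package = "hemaclone"))
}

case_karyotypes <- function() {
  utils::read.delim(system.file("extdata", "case_karyotypes.tsv",
                                package = "hemaclone"),
                    stringsAsFactors = FALSE)$karyotype
}
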