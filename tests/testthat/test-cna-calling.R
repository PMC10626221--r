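test_that("GC normalization removes injected bias and preserves flat input", {
  set.seed(1)
  gc <- seq(0.3, 0.6, length.out = 200)
  # counts independent of GC: flat stays flat within 1%
  flat <- gc_normalize(rep(500, 200), gc)
  expect_true(all(abs(flat - 1) < 0.01))
  expect_equal(mean(flat), 1, tolerance = 1e-6)

  # noiseless linear bias is recovered by the fit
  biased <- 100 * (1 + 2 * (gc - 0.5))
  norm <- gc_normalize(biased, gc)
  expect_true(all(abs(norm - 1) < 0.01))
  norm_q <- gc_normalize(biased, gc, method = "quadratic")
  expect_true(all(abs(norm_q - 1) < 0.01))

  # all-equal counts on scattered gc stay equal
  gc2 <- stats::runif(50, 0.3, 0.6)
  expect_true(all(abs(gc_normalize(rep(7, 50), gc2) - 1) < 0.01))

  expect_warning(gc_normalize(rep(5, 5), stats::runif(5)), "fewer than 10")
})

test_that("copy-number scaling anchors the median at the baseline ploidy", {
  expect_equal(to_copy_number_scale(rep(1.7, 11)), rep(2, 11))
  dens <- c(rep(1, 80), rep(1.5, 20))
  cn <- to_copy_number_scale(dens)
  expect_equal(unique(cn[dens == 1.5]), 3.0)
  # idempotence
  expect_equal(to_copy_number_scale(cn), cn)
  expect_error(to_copy_number_scale(rep(0, 10)), "median")
})

test_that("a simulated trisomy chromosome recovers mean CN near 3", {
  g <- make_genome(c(chr1 = 50e6, chr2 = 50e6, chr3 = 50e6),
                   gc = list(model = "sinusoid", mean = 0.45,
                             amplitude = 0.08, period = 3.1e6),
                   window_size = 1e5)
  bm <- build_variable_bins(g, 300)
  tr <- truth_profile(data.frame(chrom = "chr2", start = 0, end = 50e6, cn = 3L))
  cts <- simulate_bin_counts(g, bm, tr, 1e6, dispersion = 0.02, seed = 5)
  cn <- to_copy_number_scale(gc_normalize(cts, bm$bins$gc))
  expect_gt(mean(cn[bm$bins$chrom == "chr2"]), 2.8)
  expect_lt(mean(cn[bm$bins$chrom == "chr2"]), 3.2)
})

test_that("segmentation finds the planted changepoint at the max-t position", {
  # constant series: one segment per chromosome
  segs <- cbs_segment(rep(2, 60), rep("chr1", 60), seed = 1)
  expect_equal(nrow(segs), 1)
  expect_equal(c(segs$first_bin, segs$last_bin), c(1, 60))

  set.seed(11)
  x <- c(stats::rnorm(50, 2, 0.1), stats::rnorm(50, 3, 0.1))
  segs <- cbs_segment(x, rep("chr1", 100), seed = 11)
  expect_equal(nrow(segs), 2)
  expect_true(segs$last_bin[1] %in% 49:51)
  expect_equal(segs$last_bin[1], unname(oracle_best_split(x)[["k"]]))
})

test_that("two-step profiles are recovered within two bins", {
  hits <- 0
  for (s in 1:100) {
    set.seed(1000 + s)
    x <- c(stats::rnorm(40, 2, 0.1), stats::rnorm(30, 3, 0.1),
           stats::rnorm(30, 2, 0.1))
    segs <- cbs_segment(x, rep("chr1", 100), seed = s)
    bps <- segs$last_bin[-nrow(segs)]
    if (length(bps) == 2 && abs(bps[1] - 40) <= 2 && abs(bps[2] - 70) <= 2)
      hits <- hits + 1
  }
  expect_gte(hits, 95)
})

test_that("segments always partition the bins", {
  for (s in 1:5) {
    set.seed(s)
    n <- sample(20:80, 1)
    x <- stats::rnorm(n, 2, 0.3)
    chrom <- rep(c("chr1", "chr2"), c(floor(n / 2), ceiling(n / 2)))
    segs <- cbs_segment(x, chrom, n_permutations = 200, seed = s)
    covered <- unlist(mapply(seq, segs$first_bin, segs$last_bin,
                             SIMPLIFY = FALSE))
    expect_equal(sort(covered), 1:n)
    expect_true(all(segs$last_bin >= segs$first_bin))
  }
})

test_that("level merging joins indistinguishable segments and stops at real steps", {
  set.seed(3)
  # two segments drawn from the same distribution collapse to one level
  x <- stats::rnorm(100, 2, 0.1)
  segs <- data.frame(chrom = "chr1", first_bin = c(1, 51), last_bin = c(50, 100),
                     mean = c(mean(x[1:50]), mean(x[51:100])))
  m <- merge_levels(segs, x)
  expect_equal(length(unique(m$level)), 1)

  # 2.00 / 2.02 merge, 3.00 stays apart; oracle = direct rank-sum p-values
  set.seed(7)
  y <- c(stats::rnorm(50, 2.00, 0.1), stats::rnorm(50, 2.02, 0.1),
         stats::rnorm(50, 3.00, 0.1))
  segs3 <- data.frame(chrom = "chr1", first_bin = c(1, 51, 101),
                      last_bin = c(50, 100, 150),
                      mean = c(mean(y[1:50]), mean(y[51:100]), mean(y[101:150])))
  p12 <- stats::wilcox.test(y[1:50], y[51:100], exact = FALSE)$p.value
  p23 <- stats::wilcox.test(y[51:100], y[101:150], exact = FALSE)$p.value
  expect_gt(p12, 1e-4) # the oracle says these merge
  expect_lt(p23, 1e-4) # and these do not
  m3 <- merge_levels(segs3, y, threshold = 1e-4)
  expect_equal(m3$level[1], m3$level[2])
  expect_false(m3$level[2] == m3$level[3])
  expect_equal(length(unique(m3$level)), 2)

  # single segment unchanged
  one <- merge_levels(segs3[1, ], y[1:50])
  expect_equal(one$level, 1L)
})

test_that("the number of merged levels never increases with the threshold", {
  set.seed(9)
  y <- c(stats::rnorm(40, 2, 0.15), stats::rnorm(40, 2.3, 0.15),
         stats::rnorm(40, 3, 0.15))
  segs <- data.frame(chrom = "chr1", first_bin = c(1, 41, 81),
                     last_bin = c(40, 80, 120),
                     mean = tapply(y, rep(1:3, each = 40), mean))
  nlev <- vapply(c(1e-8, 1e-4, 1e-2, 0.5),
                 function(th) length(unique(merge_levels(segs, y, th)$level)), 0L)
  expect_true(all(diff(nlev) <= 0))
})

test_that("integer calls use round-half-even on level means", {
  prof <- call_segment_cn("s", rep(1, 4), c(2.97, 2.97, 2.5, 2.5),
                          data.frame(chrom = "chr1", first_bin = c(1, 3),
                                     last_bin = c(2, 4), mean = c(2.97, 2.5)))
  expect_equal(prof$segments$cn_call, c(3L, 2L))
  expect_equal(profile_bin_calls(prof), c(3L, 3L, 2L, 2L))
})

test_that("aberration extraction labels chromosome and arm events", {
  st <- recovery_setting(300)
  cts <- simulate_bin_counts(st$genome, st$binmap, st$truth, 1e6,
                             dispersion = 0.02, seed = 4)
  prof <- call_copy_number(cts, st$binmap, seed = 4)
  ab <- extract_aberrations(prof, st$binmap, arms = st$arms)
  expect_true("polysomy 2" %in% ab$label)
  expect_true("4q deletion" %in% ab$label)
  expect_equal(ab$cn[ab$label == "polysomy 2"], 3L)
  expect_equal(ab$kind[ab$label == "4q deletion"], "arm-level loss")

  # all-baseline profile yields no calls
  flat <- simulate_bin_counts(st$genome, st$binmap, truth_profile(), 1e6,
                              dispersion = 0.02, seed = 4)
  pf <- call_copy_number(flat, st$binmap, seed = 4)
  expect_equal(nrow(extract_aberrations(pf, st$binmap, arms = st$arms)), 0)

  # without arm annotation only whole-chromosome calls are made
  expect_message(ab2 <- extract_aberrations(prof, st$binmap), "whole-chromosome")
  expect_true("polysomy 2" %in% ab2$label)
  expect_false(any(ab2$kind == "arm-level loss"))
})
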