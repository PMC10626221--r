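mk_variants <- function(vaf, total = 1000, specimens = seq_along(vaf),
                        gene = "GENE", chrom = "chr1", pos = 100) {
  data.frame(gene = gene, cdna = "c.1A>G", chrom = chrom, pos = pos,
             ref = "A", alt = "G", consequence = "missense", maf = 0,
             specimen = specimens, total_depth = ifelse(is.na(vaf), NA, total),
             alt_depth = round(vaf * total), vaf = vaf,
             stringsAsFactors = FALSE)
}

test_that("annotation filter drops synonymous, non-coding and common variants", {
  v <- mk_variants(c(0.1, 0.1, 0.1), specimens = 1:3)
  v$consequence <- c("missense", "synonymous", "noncoding")
  v$maf <- c(0.0001, 0, 0)
  f <- filter_annotation(v)
  expect_equal(f$annotation_status,
               c("retained", "excluded:synonymous", "excluded:noncoding"))

  common <- mk_variants(0.1); common$maf <- 0.02
  expect_equal(filter_annotation(common)$annotation_status, "excluded:common")
  # the rule is "> 1%", so exactly 1% is retained
  boundary <- mk_variants(0.1); boundary$maf <- 0.01
  expect_equal(filter_annotation(boundary)$annotation_status, "retained")

  na_maf <- mk_variants(0.1); na_maf$maf <- NA
  expect_message(f2 <- filter_annotation(na_maf), "missing MAF")
  expect_equal(f2$annotation_status, "retained")
})

test_that("somatic thresholds and the serial rescue behave as specified", {
  # alt 15, vaf 6%, total 300 -> pass
  pass <- data.frame(gene = "G", cdna = "c", chrom = "chr1", pos = 1,
                     ref = "A", alt = "T", consequence = "missense", maf = 0,
                     specimen = 1, total_depth = 300, alt_depth = 15, vaf = 0.06)
  expect_equal(filter_somatic(pass)$somatic_status, "pass")

  # alt 8, vaf 4%, total 200, no passing companion -> excluded
  fail <- pass; fail$total_depth <- 200; fail$alt_depth <- 8; fail$vaf <- 0.04
  st <- filter_somatic(fail)$somatic_status
  expect_match(st, "^excluded:")
  expect_match(st, "low_alt_depth")
  expect_match(st, "low_vaf")
  expect_match(st, "low_total_depth")

  # serial VAFs 3.6 -> 4.4 -> 9.5 -> 12.4: later specimens pass, the
  # sub-threshold early ones are rescued
  ser <- mk_variants(c(0.036, 0.044, 0.095, 0.124))
  st <- filter_somatic(ser)$somatic_status
  expect_equal(st, c("rescued", "rescued", "pass", "pass"))

  # never-passing serial variant is excluded everywhere under the
  # default reading but rescued under the any-criterion reading
  low <- mk_variants(c(0.047, 0.026, 0.025))
  expect_true(all(grepl("^excluded:", filter_somatic(low)$somatic_status)))
  expect_true(all(filter_somatic(low, rescue = "any_criterion")$somatic_status
                  == "rescued"))
})

test_that("somatic filtering is idempotent and rescue never demotes", {
  set.seed(2)
  v <- do.call(rbind, lapply(1:6, function(i)
    mk_variants(round(stats::runif(4, 0, 0.15), 3), pos = i * 10,
                total = sample(c(200, 300, 1000), 1))))
  f1 <- filter_somatic(v)
  f2 <- filter_somatic(f1)
  expect_equal(f1$somatic_status, f2$somatic_status)
  # every record that passes on its own keeps status "pass"
  raw_pass <- with(v, !is.na(vaf) & alt_depth >= 10 & vaf >= 0.05 &
                        total_depth >= 250)
  expect_true(all(f1$somatic_status[raw_pass] == "pass"))
})

test_that("duplicate variant/specimen rows are merged with a warning", {
  v <- rbind(mk_variants(0.05, total = 500), mk_variants(0.05, total = 500))
  expect_warning(f <- filter_somatic(v), "duplicate")
  expect_equal(nrow(f), 1)
  expect_equal(f$total_depth, 1000)
})

test_that("read-level presence calls follow the alt-read threshold", {
  none <- data.frame(allele = character(), baseq = numeric())
  expect_equal(dlp_variant_presence(none)$call, "uncallable")

  refs <- data.frame(allele = rep("ref", 10), baseq = 30)
  r <- dlp_variant_presence(refs)
  expect_equal(r$call, "absent")
  expect_equal(r$n_total, 10)

  reads <- simulate_locus_reads(30, vaf = 0.2, error_rate = 0.001, seed = 5)
  r <- dlp_variant_presence(reads, min_alt_reads = 1)
  expect_equal(r$call, "present")
  # alt count within the central 99% binomial band around 30 * 0.2
  band <- stats::qbinom(c(0.005, 0.995), 30, 0.2)
  expect_gte(r$n_alt, band[1])
  expect_lte(r$n_alt, band[2])

  # low-quality bases are excluded before counting
  lowq <- data.frame(allele = c("alt", "ref"), baseq = c(5, 30))
  expect_equal(dlp_variant_presence(lowq)$call, "absent")
  expect_equal(dlp_variant_presence(lowq, min_baseq = 2)$call, "present")
})

test_that("trajectory labels derive from first and last detection", {
  expect_equal(vaf_trajectory(c(3.6, 4.4, 9.5, 12.4))$label, "persisting")
  expect_equal(vaf_trajectory(c(4.7, 2.6, 2.5, NA))$label, "cleared")
  expect_equal(vaf_trajectory(5.0)$label, "persisting")
  expect_equal(vaf_trajectory(c(NA, NA, 3.1, 4.0))$label, "emergent")
  expect_equal(vaf_trajectory(c(NA, NA))$label, "not_detected")
  # ordering by days, not input order
  tr <- vaf_trajectory(c(12.4, 3.6), days = c(364, 0))
  expect_equal(tr$series$vaf, c(3.6, 12.4))
})

test_that("variant tables round-trip through VCF", {
  skip_if_not_installed("vcfR")
  v <- rbind(mk_variants(c(0.036, 0.124), specimens = c("s1", "s2")),
             mk_variants(c(0.08, NA), specimens = c("s1", "s2"),
                         chrom = "chr2", pos = 555))
  p <- tempfile(fileext = ".vcf")
  write_variants_vcf(v, p)
  back <- read_variants_vcf(p)
  for (i in seq_len(nrow(v))) {
    m <- back[back$chrom == v$chrom[i] & back$pos == v$pos[i] &
                back$specimen == v$specimen[i], ]
    expect_equal(nrow(m), 1)
    if (is.na(v$vaf[i])) expect_true(is.na(m$total_depth))
    else {
      expect_equal(m$total_depth, v$total_depth[i])
      expect_equal(m$alt_depth, v$alt_depth[i])
      expect_equal(m$vaf, v$vaf[i], tolerance = 1e-3)
    }
  }
})
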