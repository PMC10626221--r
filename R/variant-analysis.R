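#' Variant tables
#'
#' Variants are handled as a long data.frame with one row per variant
#' per specimen: columns \code{gene}, \code{cdna}, \code{chrom},
#' \code{pos} (1-based), \code{ref}, \code{alt}, \code{consequence}
#' (synonymous / missense / nonsense / noncoding / other), \code{maf}
#' (population minor allele frequency, fraction), \code{specimen},
#' \code{total_depth}, \code{alt_depth}, \code{vaf} (fraction; NA when
#' not detected). Variant identity across specimens is by
#' (chrom, pos, ref, alt), never by gene symbol or HGVS text.
#'
#' @name variant_table
NULL

variant_key <- function(df) {
  paste(df$chrom, df$pos, df$ref, df$alt, sep = ":")
}

#' Annotation-level variant filtering
#'
#' Excludes synonymous variants, non-coding variants, and variants more
#' common than the population MAF threshold (default 1%); everything
#' else is retained. Missing MAF is treated as 0 with a notice.
#'
#' @param variants a variant table (see \code{\link{variant_table}}).
#' @param maf_threshold exclusion threshold: variants with
#'   MAF > \code{maf_threshold} are excluded (default 0.01).
#' @return the table with an added \code{annotation_status} column:
#'   "retained", "excluded:synonymous", "excluded:noncoding" or
#'   "excluded:common".
#' @export
filter_annotation <- function(variants, maf_threshold = 0.01) {
  df <- variants
  if (any(is.na(df$maf))) {
    message("missing MAF treated as 0 for ", sum(is.na(df$maf)), " row(s)")
    df$maf[is.na(df$maf)] <- 0
  }
  status <- rep("retained", nrow(df))
  status[df$consequence == "synonymous"] <- "excluded:synonymous"
  status[df$consequence == "noncoding"] <- "excluded:noncoding"
  status[status == "retained" & df$maf > maf_threshold] <- "excluded:common"
  df$annotation_status <- status
  df
}

#' Depth/VAF somatic filtering with serial-specimen rescue
#'
#' A specimen-level record passes iff alt depth >= \code{alt_depth_min}
#' AND VAF >= \code{vaf_min} AND total depth >= \code{total_depth_min}.
#' A failing record is rescued when the identical variant (matched by
#' chrom/pos/ref/alt) clears the thresholds in at least one other
#' specimen of the same case -- the behaviour that keeps sub-threshold
#' early time points of a variant that later rises above threshold.
#' Under \code{rescue = "any_criterion"} a single met criterion in any
#' specimen suffices instead (a laxer reading of the same rule).
#' Records with NA depths (variant not detected) are marked
#' "not_detected" and never rescued.
#'
#' @param variants a variant table.
#' @param alt_depth_min minimum alt depth (default 10).
#' @param vaf_min minimum VAF as a fraction (default 0.05).
#' @param total_depth_min minimum total depth (default 250).
#' @param rescue "full_pass" (default) or "any_criterion".
#' @return the table with an added \code{somatic_status} column:
#'   "pass", "rescued", "excluded:<reasons>" or "not_detected".
#' @export
filter_somatic <- function(variants, alt_depth_min = 10, vaf_min = 0.05,
                           total_depth_min = 250,
                           rescue = c("full_pass", "any_criterion")) {
  rescue <- match.arg(rescue)
  df <- variants
  key <- variant_key(df)

  dup <- duplicated(paste(key, df$specimen))
  if (any(dup)) {
    warning("merging ", sum(dup), " duplicate variant/specimen row(s)")
    agg_keys <- unique(paste(key, df$specimen)[dup])
    for (ak in agg_keys) {
      rows <- which(paste(key, df$specimen) == ak)
      df$alt_depth[rows[1]] <- sum(df$alt_depth[rows], na.rm = TRUE)
      df$total_depth[rows[1]] <- sum(df$total_depth[rows], na.rm = TRUE)
      df$vaf[rows[1]] <- df$alt_depth[rows[1]] / df$total_depth[rows[1]]
    }
    df <- df[!dup, , drop = FALSE]
    key <- variant_key(df)
  }

  detected <- !is.na(df$vaf) & !is.na(df$total_depth)
  ok_alt <- detected & df$alt_depth >= alt_depth_min
  ok_vaf <- detected & df$vaf >= vaf_min
  ok_tot <- detected & df$total_depth >= total_depth_min
  full_pass <- ok_alt & ok_vaf & ok_tot
  partial <- ok_alt | ok_vaf | ok_tot

  status <- character(nrow(df))
  status[!detected] <- "not_detected"
  status[full_pass] <- "pass"
  for (i in which(detected & !full_pass)) {
    companion <- key == key[i] & seq_len(nrow(df)) != i
    rescued <- if (rescue == "full_pass") any(full_pass[companion])
               else any(partial[companion])
    if (rescued) {
      status[i] <- "rescued"
    } else {
      reasons <- c(if (!ok_alt[i]) "low_alt_depth",
                   if (!ok_vaf[i]) "low_vaf",
                   if (!ok_tot[i]) "low_total_depth")
      status[i] <- paste0("excluded:", paste(reasons, collapse = ","))
    }
  }
  df$somatic_status <- status
  df
}

#' Read-level variant presence call in a shallow library
#'
#' After dropping bases below the quality floor, the variant is present
#' iff at least \code{min_alt_reads} alt-supporting reads remain;
#' absent iff reads cover the locus but fewer alt reads are seen;
#' uncallable with no covering reads.
#'
#' @param reads data.frame with columns \code{allele} ("ref"/"alt"/
#'   "other") and \code{baseq}, e.g. from
#'   \code{\link{simulate_locus_reads}}.
#' @param min_alt_reads alt reads required to call presence (default 1).
#' @param min_baseq base-quality floor (default 20).
#' @return list with \code{call} ("present"/"absent"/"uncallable"),
#'   \code{n_alt} and \code{n_total} (after quality filtering).
#' @export
dlp_variant_presence <- function(reads, min_alt_reads = 1, min_baseq = 20) {
  keep <- reads$baseq >= min_baseq
  n_total <- sum(keep)
  n_alt <- sum(keep & reads$allele == "alt")
  call <- if (n_total == 0) "uncallable"
          else if (n_alt >= min_alt_reads) "present"
          else "absent"
  list(call = call, n_alt = n_alt, n_total = n_total)
}

#' VAF trajectory of one variant across serial specimens
#'
#' Orders observations by days after diagnosis and assigns a course
#' label from the first and last detections: "persisting" (detected at
#' first and last time points), "cleared" (detected early, undetected
#' at the last time point), "emergent" (undetected at first, detected
#' later), or "not_detected".
#'
#' @param vaf numeric VAF fractions (or percentages -- only
#'   detected/undetected matters for the label); NA means not detected.
#' @param days time points (days after diagnosis); defaults to the
#'   observation order.
#' @return list with \code{series} (data.frame days/vaf/detected,
#'   ordered by days) and \code{label}.
#' @export
vaf_trajectory <- function(vaf, days = seq_along(vaf)) {
  assert_that(length(vaf) >= 1, "need at least one specimen")
  o <- order(days)
  vaf <- vaf[o]; days <- days[o]
  detected <- !is.na(vaf) & vaf > 0
  label <- if (!any(detected)) "not_detected"
           else if (detected[1] && detected[length(detected)]) "persisting"
           else if (!detected[length(detected)]) "cleared"
           else "emergent"
  list(series = data.frame(days = days, vaf = vaf, detected = detected),
       label = label)
}

#' Read a variant table from TSV
#' @param path TSV with the \code{\link{variant_table}} columns.
#' @return data.frame.
#' @export
read_variant_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "ref", "alt", "specimen")
  assert_that(all(need %in% names(df)),
              "variant TSV must have columns: %s", paste(need, collapse = ", "))
  df
}

#' Write a variant table as TSV
#' @param variants data.frame.
#' @param path output path.
#' @export
write_variant_table <- function(variants, path) {
  utils::write.table(variants, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(variants)
}

#' Read variants from a VCF (minimal VCF 4.2 subset)
#'
#' Reads CHROM, POS, REF, ALT plus per-sample DP/AD/AF FORMAT fields
#' into the long variant-table layout (one row per variant x sample).
#' Uses the vcfR package.
#'
#' @param path VCF file.
#' @return variant table data.frame.
#' @export
read_variants_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("the vcfR package is required to read VCF")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  dp <- vcfR::extract.gt(v, "DP", as.numeric = TRUE)
  ad <- vcfR::extract.gt(v, "AD")
  samples <- colnames(dp)
  out <- do.call(rbind, lapply(samples, function(s) {
    alt_d <- suppressWarnings(as.numeric(vapply(strsplit(ad[, s], ","),
                                                function(z) z[min(2, length(z))], "")))
    data.frame(gene = NA_character_, cdna = NA_character_,
               chrom = fix$CHROM, pos = as.integer(fix$POS),
               ref = fix$REF, alt = fix$ALT,
               consequence = NA_character_, maf = NA_real_,
               specimen = s,
               total_depth = dp[, s], alt_depth = alt_d,
               vaf = alt_d / dp[, s],
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Write a variant table as a minimal VCF 4.2
#'
#' Emits CHROM POS ID REF ALT QUAL FILTER INFO FORMAT plus one sample
#' column per specimen with DP:AD:AF.
#'
#' @param variants variant table data.frame.
#' @param path output path.
#' @export
write_variants_vcf <- function(variants, path) {
  key <- variant_key(variants)
  uk <- unique(key)
  specimens <- unique(variants$specimen)
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Total depth\">",
           "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
           "##FORMAT=<ID=AF,Number=A,Type=Float,Description=\"Allele fraction\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", specimens), collapse = "\t"))
  rows <- vapply(uk, function(k) {
    r <- variants[key == k, , drop = FALSE][1, ]
    cells <- vapply(specimens, function(s) {
      m <- variants[key == k & variants$specimen == s, , drop = FALSE]
      if (nrow(m) == 0 || is.na(m$total_depth[1])) return("./.")
      sprintf("%d:%d,%d:%.4f", m$total_depth[1],
              m$total_depth[1] - m$alt_depth[1], m$alt_depth[1], m$vaf[1])
    }, "")
    paste(c(r$chrom, r$pos, ".", r$ref, r$alt, ".", ".", ".",
            "DP:AD:AF", cells), collapse = "\t")
  }, "")
  writeLines(c(hdr, rows), path)
  invisible(variants)
}
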