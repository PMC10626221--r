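#' Run configuration
#'
#' A single JSON (or in-memory list) holds every stage parameter plus
#' input/output paths. Unknown keys are rejected so typos cannot
#' silently fall back to defaults; every run echoes the full resolved
#' configuration and package version into its output directory.
#'
#' @param ... configuration values overriding the defaults.
#' @return object of class \code{run_config} (a list).
#' @export
run_config <- function(...) {
  defaults <- list(
    seed = 1L,
    n_bins = 10000L,
    ploidy = 2L,
    gc_method = "lowess", gc_span = 0.3,
    alpha = 0.01, n_permutations = 1000L, min_width = 3L,
    merge_threshold = 1e-4,
    maf_threshold = 0.01,
    alt_depth_min = 10L, vaf_min = 0.05, total_depth_min = 250L,
    rescue = "full_pass",
    min_alt_reads = 1L, min_baseq = 20L,
    template_variant = "classical",
    cutoff_table = NULL,
    counts = NULL, binmap = NULL, genome_json = NULL, genome_tracks = NULL,
    arms = NULL, fish_tallies = NULL, karyotypes = NULL, variants = NULL,
    matrix = NULL, out_dir = "."
  )
  over <- list(...)
  if (length(over) == 1 && is.list(over[[1]]) && is.null(names(over)))
    over <- over[[1]]
  unknown <- setdiff(names(over), names(defaults))
  assert_that(length(unknown) == 0,
              "unknown config key(s): %s", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, over)
  structure(cfg, class = "run_config")
}

#' Read a run configuration from JSON
#' @param path JSON file of config keys.
#' @return a \code{run_config}.
#' @export
read_run_config <- function(path) {
  run_config(jsonlite::read_json(path, simplifyVector = TRUE))
}

config_echo <- function(config) {
  keep <- !vapply(config, is.null, TRUE)
  c(list(package = "hemaclone", version = hc_version()),
    unclass(config)[keep])
}

write_stamped_tsv <- function(df, path, config) {
  stamp <- sprintf("# hemaclone %s %s", hc_version(),
                   jsonlite::toJSON(config_echo(config), auto_unbox = TRUE))
  con <- file(path, "w")
  writeLines(stamp, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  invisible(df)
}

require_path <- function(path, what) {
  assert_that(!is.null(path), "config is missing the %s path", what)
  assert_that(file.exists(path), "%s path does not exist: %s", what, path)
  path
}

#' End-to-end copy-number run
#'
#' Reads bin counts (and the bin map, plus the genome model when
#' available for exact GC/weights), runs GC normalization,
#' copy-number scaling, segmentation, level merging and integer
#' calling, computes the QC report, extracts aberration calls, and
#' writes everything under \code{config$out_dir}: \code{segments.tsv},
#' \code{bins.tsv} (per-bin ratios and calls), \code{qc.json},
#' \code{aberrations.json} and \code{run.json} (config echo). All
#' outputs are deterministic given the config and seed.
#'
#' @param config a \code{run_config} with at least \code{counts} and
#'   \code{binmap} paths set.
#' @return (invisibly) list with \code{profile}, \code{qc},
#'   \code{aberrations}.
#' @export
run_cna <- function(config) {
  cfg <- if (inherits(config, "run_config")) config else run_config(config)
  counts_path <- require_path(cfg$counts, "counts")
  binmap_path <- require_path(cfg$binmap, "binmap")
  genome <- if (!is.null(cfg$genome_json)) {
    read_genome_model(require_path(cfg$genome_json, "genome_json"),
                      require_path(cfg$genome_tracks, "genome_tracks"))
  }
  binmap <- read_bin_map(binmap_path, genome = genome)
  counts <- read_bin_counts(counts_path)
  message("cna: ", binmap$n_bins, " bins, ", sum(counts$counts), " reads")

  profile <- call_copy_number(
    counts, binmap, ploidy = cfg$ploidy,
    gc_method = cfg$gc_method, gc_span = cfg$gc_span,
    alpha = cfg$alpha, n_permutations = cfg$n_permutations,
    min_width = cfg$min_width, merge_threshold = cfg$merge_threshold,
    seed = cfg$seed)
  qc <- qc_report(counts$counts, sample_id = counts$sample, space = "counts")
  arms <- if (!is.null(cfg$arms))
    utils::read.delim(require_path(cfg$arms, "arms"), comment.char = "#")
  ab <- suppressMessages(
    extract_aberrations(profile, binmap, arms = arms, ploidy = cfg$ploidy))
  message("cna: ", nrow(profile$segments), " segments, ",
          nrow(ab), " aberration call(s)")

  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(cfg$out_dir, f)
  seg <- profile$segments
  b <- binmap$bins
  write_stamped_tsv(data.frame(
    chrom = seg$chrom,
    start = format(b$start[seg$first_bin], scientific = FALSE, trim = TRUE),
    end = format(b$end[seg$last_bin], scientific = FALSE, trim = TRUE),
    mean_cn = round(seg$mean, 4), integer_cn = seg$cn_call,
    level = seg$level), out("segments.tsv"), cfg)
  write_stamped_tsv(data.frame(
    chrom = b$chrom,
    start = format(b$start, scientific = FALSE, trim = TRUE),
    end = format(b$end, scientific = FALSE, trim = TRUE),
    count = counts$counts, density = round(profile$density, 6),
    cn_ratio = round(profile$cn, 6),
    cn_call = profile_bin_calls(profile)), out("bins.tsv"), cfg)
  jsonlite::write_json(c(unclass(qc), list(config = config_echo(cfg))),
                       out("qc.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(list(aberrations = ab, config = config_echo(cfg)),
                       out("aberrations.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(config_echo(cfg), out("run.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(profile = profile, qc = qc, aberrations = ab))
}

#' Consolidated case report
#'
#' Combines the cytogenetic and molecular evidence of one case into a
#' report: FISH tally percentages with cutoff flags and non-PC:PC
#' ratios, parsed and resolved karyotypes, annotation + somatic filter
#' statuses and VAF-trajectory labels for the variant table, and the
#' clone tree inferred from the character matrix (written as newick
#' and JSON, with the template mapping). Inputs that are NULL in the
#' config are skipped; an empty variant table yields an empty variant
#' section, not an error.
#'
#' @param config a \code{run_config}; uses \code{fish_tallies},
#'   \code{karyotypes}, \code{variants}, \code{matrix},
#'   \code{cutoff_table}, \code{template_variant}, \code{out_dir}.
#' @return (invisibly) list of the computed sections.
#' @export
run_case_report <- function(config) {
  cfg <- if (inherits(config, "run_config")) config else run_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(cfg$out_dir, f)
  sections <- list()
  cutoffs <- if (is.null(cfg$cutoff_table)) fish_cutoffs()
             else fish_cutoffs(require_path(cfg$cutoff_table, "cutoff_table"))

  if (!is.null(cfg$fish_tallies)) {
    tal <- read_fish_tallies(require_path(cfg$fish_tallies, "fish_tallies"))
    rep <- fish_report(tal, cutoffs)
    # non-PC:PC split of positive TNCs, when the tally carries it
    if (all(c("ratio_nonpc", "ratio_pc") %in% names(rep))) {
      rep$nonpc_pc_ratio <- ifelse(
        !is.na(rep$ratio_nonpc) & !is.na(rep$ratio_pc),
        ratio_nonpc_pc(rep$ratio_nonpc, rep$ratio_pc), NA_real_)
    }
    write_stamped_tsv(rep, out("fish_report.tsv"), cfg)
    sections$fish <- rep
    message("report: ", nrow(rep), " FISH tally row(s)")
  }

  if (!is.null(cfg$karyotypes)) {
    kdf <- utils::read.delim(require_path(cfg$karyotypes, "karyotypes"),
                             comment.char = "#", stringsAsFactors = FALSE)
    parsed <- lapply(kdf$karyotype, parse_iscn)
    kdf$resolved <- vapply(parsed, iscn_format, "")
    write_stamped_tsv(kdf, out("karyotypes_resolved.tsv"), cfg)
    sections$karyotypes <- parsed
    message("report: ", length(parsed), " karyotype(s) parsed")
  }

  if (!is.null(cfg$variants)) {
    v <- read_variant_table(require_path(cfg$variants, "variants"))
    if (nrow(v) > 0) {
      v <- filter_annotation(v, maf_threshold = cfg$maf_threshold)
      v <- filter_somatic(v, alt_depth_min = cfg$alt_depth_min,
                          vaf_min = cfg$vaf_min,
                          total_depth_min = cfg$total_depth_min,
                          rescue = cfg$rescue)
      v$trajectory <- NA_character_
      if (!"days" %in% names(v)) v$days <- match(v$specimen, unique(v$specimen))
      for (k in unique(variant_key(v))) {
        sel <- variant_key(v) == k
        v$trajectory[sel] <- vaf_trajectory(v$vaf[sel], v$days[sel])$label
      }
    }
    write_stamped_tsv(v, out("variants_report.tsv"), cfg)
    sections$variants <- v
    message("report: ", nrow(v), " variant row(s)")
  }

  if (!is.null(cfg$matrix)) {
    cm <- read_character_matrix(require_path(cfg$matrix, "matrix"))
    tree <- infer_clone_tree(cm)
    template <- hematopoiesis_template(cfg$template_variant)
    mapping <- map_to_template(tree, template)
    write_clone_tree(tree, out("clone_tree.nwk"), out("clone_tree.json"))
    write_stamped_tsv(mapping, out("template_mapping.tsv"), cfg)
    sections$tree <- tree
    sections$mapping <- mapping
    message("report: clone tree with ",
            sum(tree$nodes$type == "clone"), " character edge(s)")
  }

  jsonlite::write_json(config_echo(cfg), out("report_run.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(sections)
}
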