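#' Parse an ISCN karyotype string
#'
#' Parses the subset of ISCN nomenclature used in routine hematologic
#' reporting: clones separated by "/", each with a modal chromosome
#' count or range ("55-57", en-dash accepted), sex chromosomes, gains
#' (+8), losses (-7), structural aberrations of the form
#' \code{del(20)(q11.2)} (also dup/inv/t and ?-qualified forms), xN
#' multipliers, cell counts \code{[7]}, composite counts \code{[cp3]},
#' and stemline references \code{idem} / \code{sl} / \code{sdl} /
#' \code{slxN}. Stemline references resolve against the first clone:
#' \code{idem}/\code{sl} inherit its aberrations, \code{slx2} inherits
#' them at doubled multiplicity (a doubled stemline). Tokens that do
#' not parse are recorded verbatim in an \code{unparsed} list with a
#' warning, never silently dropped.
#'
#' @param text karyotype string, e.g.
#'   \code{"47,XX,+8,del(20)(q11.2)[7]/48,idem,+19[8]/46,XX[9]"}.
#' @return object of class \code{karyotype}: list with \code{clones}
#'   (each holding \code{modal_min}, \code{modal_max}, \code{sex},
#'   \code{cells}, \code{composite}, \code{stemline_ref},
#'   \code{stemline_mult}, \code{aberrations} and \code{resolved} --
#'   the materialized aberration set after stemline resolution) and
#'   \code{unparsed}.
#' @export
parse_iscn <- function(text) {
  assert_that(nchar(trimws(text)) > 0, "empty karyotype string")
  clone_strs <- strsplit(text, "/", fixed = TRUE)[[1]]
  unparsed <- character()

  parse_aberration <- function(tok) {
    mult <- 1L
    m <- regmatches(tok, regexec("^(.*)x(\\d+)$", tok))[[1]]
    if (length(m) == 3 && !grepl("^(idem|sl|sdl)$", m[2])) {
      tok2 <- m[2]; mult <- as.integer(m[3])
    } else tok2 <- tok
    uncertain <- grepl("^\\?", tok2)
    core <- sub("^\\?", "", tok2)
    if (grepl("^\\+.+$", core)) {
      return(list(type = "gain", chrom = sub("^\\+", "", core), bands = NA,
                  mult = mult, uncertain = uncertain))
    }
    if (grepl("^[-−].+$", core)) {
      return(list(type = "loss", chrom = sub("^[-−]", "", core), bands = NA,
                  mult = mult, uncertain = uncertain))
    }
    m <- regmatches(core,
      regexec("^([a-z]+)\\(([^)]*)\\)(?:\\(([^)]*)\\))?$", core))[[1]]
    if (length(m) >= 3 && m[1] == core) {
      return(list(type = m[2], chrom = m[3],
                  bands = if (length(m) >= 4 && nzchar(m[4])) m[4] else NA,
                  mult = mult, uncertain = uncertain))
    }
    NULL
  }

  clones <- lapply(clone_strs, function(cs) {
    cs <- trimws(cs)
    cells <- NA_integer_; cells_max <- NA_integer_; composite <- FALSE
    m <- regmatches(cs, regexec("\\s*\\[(cp)?(\\d+)(?:[-–](\\d+))?\\]\\s*$", cs))[[1]]
    if (length(m) > 0) {
      composite <- nzchar(m[2])
      cells <- as.integer(m[3])
      cells_max <- if (nzchar(m[4])) as.integer(m[4]) else cells
      cs <- sub("\\s*\\[(cp)?\\d+([-–]\\d+)?\\]\\s*$", "", cs)
    }
    toks <- trimws(strsplit(cs, ",", fixed = TRUE)[[1]])
    toks <- toks[nzchar(toks)]

    modal_min <- modal_max <- NA_integer_
    sex <- NA_character_
    stemline_ref <- NULL; stemline_mult <- 1L
    abs_list <- list()
    for (i in seq_along(toks)) {
      tok <- toks[i]
      mm <- regmatches(tok, regexec("^(\\d+)(?:[-–](\\d+))?$", tok))[[1]]
      if (length(mm) > 0 && i == 1) {
        modal_min <- as.integer(mm[2])
        modal_max <- if (nzchar(mm[3])) as.integer(mm[3]) else modal_min
        next
      }
      if (grepl("^[XY]+$", tok) && is.na(sex)) { sex <- tok; next }
      sm <- regmatches(tok, regexec("^(idem|sl|sdl)(?:x(\\d+))?$", tok))[[1]]
      if (length(sm) > 0) {
        stemline_ref <- sm[2]
        stemline_mult <- if (nzchar(sm[3])) as.integer(sm[3]) else 1L
        next
      }
      ab <- parse_aberration(tok)
      if (is.null(ab)) {
        unparsed <<- c(unparsed, tok)
      } else {
        abs_list[[length(abs_list) + 1]] <- ab
      }
    }
    list(modal_min = modal_min, modal_max = modal_max, sex = sex,
         cells = cells, cells_max = cells_max, composite = composite,
         stemline_ref = stemline_ref, stemline_mult = stemline_mult,
         aberrations = abs_list)
  })

  aberration_df <- function(lst) {
    if (length(lst) == 0) {
      return(data.frame(type = character(), chrom = character(),
                        bands = character(), mult = integer(),
                        uncertain = logical(), stringsAsFactors = FALSE))
    }
    df <- do.call(rbind, lapply(lst, function(a)
      data.frame(type = a$type, chrom = a$chrom,
                 bands = as.character(a$bands), mult = a$mult,
                 uncertain = a$uncertain, stringsAsFactors = FALSE)))
    # collapse duplicate tokens (e.g. "+9,+9") into one row with summed mult
    k <- paste(df$type, df$chrom, df$bands, df$uncertain)
    agg <- tapply(df$mult, k, sum)
    df <- df[!duplicated(k), , drop = FALSE]
    df$mult <- as.integer(agg[paste(df$type, df$chrom, df$bands, df$uncertain)])
    rownames(df) <- NULL
    df
  }

  stem <- aberration_df(clones[[1]]$aberrations)
  clones <- lapply(clones, function(cl) {
    own <- aberration_df(cl$aberrations)
    if (!is.null(cl$stemline_ref)) {
      inh <- stem
      inh$mult <- inh$mult * cl$stemline_mult
      res <- rbind(inh, own)
      if (is.na(cl$sex)) cl$sex <- clones[[1]]$sex
    } else {
      res <- own
    }
    k <- paste(res$type, res$chrom, res$bands, res$uncertain)
    if (anyDuplicated(k)) {
      agg <- tapply(res$mult, k, sum)
      res <- res[!duplicated(k), , drop = FALSE]
      res$mult <- as.integer(agg[paste(res$type, res$chrom, res$bands, res$uncertain)])
    }
    rownames(res) <- NULL
    cl$resolved <- res
    cl
  })
  if (length(unparsed) > 0)
    warning("unparsed ISCN token(s): ", paste(unparsed, collapse = ", "))
  structure(list(clones = clones, unparsed = unparsed, text = text),
            class = "karyotype")
}

# canonical token for one resolved aberration row
aberration_token <- function(row) {
  base <- switch(row$type,
    gain = paste0("+", row$chrom),
    loss = paste0("-", row$chrom),
    paste0(row$type, "(", row$chrom, ")",
           if (!is.na(row$bands)) paste0("(", row$bands, ")") else ""))
  if (row$uncertain) base <- paste0("?", base)
  if (row$mult > 1) base <- paste0(base, "x", row$mult)
  base
}

#' Resolved aberration tokens of one clone
#' @param karyotype a \code{karyotype}.
#' @param clone clone index.
#' @return character vector of canonical aberration tokens (sorted).
#' @export
clone_aberrations <- function(karyotype, clone = 1) {
  res <- karyotype$clones[[clone]]$resolved
  if (nrow(res) == 0) return(character())
  sort(vapply(seq_len(nrow(res)), function(i)
    aberration_token(res[i, ]), ""))
}

#' Serialize a karyotype with stemline references resolved
#'
#' Writes each clone fully materialized (no idem/sl shorthand), so
#' re-parsing the output reproduces the same resolved clone sets.
#'
#' @param karyotype a \code{karyotype}.
#' @return ISCN-style string.
#' @export
iscn_format <- function(karyotype) {
  paste(vapply(seq_along(karyotype$clones), function(i) {
    cl <- karyotype$clones[[i]]
    modal <- if (cl$modal_min == cl$modal_max) as.character(cl$modal_min)
             else paste0(cl$modal_min, "-", cl$modal_max)
    toks <- c(modal, if (!is.na(cl$sex)) cl$sex,
              clone_aberrations(karyotype, i))
    cnt <- if (is.na(cl$cells)) "" else {
      n <- if (cl$cells == cl$cells_max) as.character(cl$cells)
           else paste0(cl$cells, "-", cl$cells_max)
      paste0("[", if (cl$composite) "cp", n, "]")
    }
    paste0(paste(toks, collapse = ","), cnt)
  }, ""), collapse = "/")
}

#' @export
print.karyotype <- function(x, ...) {
  cat("karyotype:", x$text, "\n")
  for (i in seq_along(x$clones)) {
    cl <- x$clones[[i]]
    cat(sprintf("  clone %d: modal %s%s, %s, %s cell(s): %s\n", i,
                cl$modal_min,
                if (cl$modal_max != cl$modal_min) paste0("-", cl$modal_max) else "",
                cl$sex %||% "?", cl$cells,
                if (nrow(cl$resolved) == 0) "normal"
                else paste(clone_aberrations(x, i), collapse = ", ")))
  }
  if (length(x$unparsed)) cat("  unparsed:", paste(x$unparsed, collapse = ", "), "\n")
  invisible(x)
}

#' FISH tally percentage
#'
#' Percent of positive cells among scored cells, rounded half-up to one
#' decimal -- the rendering convention of clinical FISH reports.
#'
#' @param positive positive-cell count.
#' @param scored scored-cell count (> 0).
#' @return percent, one decimal.
#' @examples
#' tally_fish(44, 200) # 22.0
#' @export
tally_fish <- function(positive, scored) {
  assert_that(all(scored > 0), "scored cell count must be > 0")
  assert_that(all(positive >= 0 & positive <= scored),
              "positive count must be in [0, scored]")
  round_half_up(100 * positive / scored, 1)
}

#' Ratio of non-plasma-cell to plasma-cell positive counts
#'
#' Direct quotient of the positive counts, rounded half-up to one
#' decimal. Undefined (NA) when no positive plasma cells were scored.
#'
#' @param non_pc_positive positive count among non-plasma cells.
#' @param pc_positive positive count among plasma cells.
#' @return ratio to one decimal, or NA if \code{pc_positive} is 0.
#' @export
ratio_nonpc_pc <- function(non_pc_positive, pc_positive) {
  ifelse(pc_positive > 0,
         round_half_up(non_pc_positive / pc_positive, 1),
         NA_real_)
}

#' Probe-specific FISH cutoff table
#'
#' Loads the packaged cutoff table: for each probe pattern, the
#' positivity cutoff (percent) at 100, 200, and 300 scored cells.
#'
#' @param path JSON path; defaults to the table shipped with the
#'   package.
#' @return named list: pattern -> named numeric vector of cutoffs by
#'   scored-cell bracket.
#' @export
fish_cutoffs <- function(path = system.file("extdata", "fish_cutoffs.json",
                                            package = "hemaclone")) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(raw, function(x) unlist(x))
}

#' Evaluate a FISH percentage against its probe cutoff
#'
#' Positive iff the percentage is at or above the cutoff for the probe
#' pattern at the matching scored-cell bracket; when the scored count
#' is not a tabulated bracket the nearest bracket is used with a
#' notice.
#'
#' @param percent tally percentage (as from \code{\link{tally_fish}}).
#' @param pattern probe pattern label, a key of the cutoff table.
#' @param scored scored-cell count.
#' @param cutoffs cutoff table (default the packaged one).
#' @return "positive" or "below_cutoff".
#' @export
apply_cutoff <- function(percent, pattern, scored,
                         cutoffs = fish_cutoffs()) {
  assert_that(pattern %in% names(cutoffs), "unknown probe pattern: %s", pattern)
  tab <- cutoffs[[pattern]]
  brackets <- as.numeric(names(tab))
  if (!scored %in% brackets) {
    message("scored count ", scored, " not a tabulated bracket; using nearest")
  }
  i <- which.min(abs(brackets - scored))
  if (percent >= tab[[i]]) "positive" else "below_cutoff"
}

#' Read FISH tallies from TSV
#'
#' Expected columns: \code{probe}, \code{pattern}, \code{class},
#' \code{positive}, \code{scored}; optional \code{specimen}.
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
read_fish_tallies <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("probe", "pattern", "class", "positive", "scored")
  assert_that(all(need %in% names(df)),
              "FISH TSV must have columns: %s", paste(need, collapse = ", "))
  df
}

#' Percentages and cutoff flags for a FISH tally table
#'
#' Adds \code{percent} (half-up, one decimal) and, where the pattern is
#' in the cutoff table, \code{flag} ("positive"/"below_cutoff"; NA for
#' patterns without a cutoff entry or unscored rows).
#'
#' @param tallies data.frame as from \code{\link{read_fish_tallies}}.
#' @param cutoffs cutoff table.
#' @return the data.frame with added columns.
#' @export
fish_report <- function(tallies, cutoffs = fish_cutoffs()) {
  df <- tallies
  df$percent <- tally_fish(df$positive, df$scored)
  df$flag <- NA_character_
  for (i in seq_len(nrow(df))) {
    if (df$pattern[i] %in% names(cutoffs)) {
      df$flag[i] <- suppressMessages(
        apply_cutoff(df$percent[i], df$pattern[i], df$scored[i], cutoffs))
    }
  }
  df
}
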