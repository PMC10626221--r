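#' Binary aberration-by-population character matrix
#'
#' Rows are sorted cell populations (e.g. two plasma-cell and two
#' myeloblast sub-populations, neutrophils, erythrocytes), columns are
#' aberration groups (copy-number groups such as A..I, SNV groups such
#' as 1..3), entries indicate whether the population carries the group.
#'
#' @param mat 0/1 matrix with populations as rownames and characters as
#'   colnames.
#' @param cell_types named character vector mapping population name to
#'   cell type (PC, MB, neutrophil, eosinophil, erythrocyte,
#'   megakaryocyte, lymphocyte, other).
#' @return object of class \code{character_matrix}.
#' @export
character_matrix <- function(mat, cell_types) {
  mat <- as.matrix(mat)
  assert_that(all(mat %in% c(0, 1)), "entries must be 0/1")
  assert_that(!is.null(rownames(mat)) && !is.null(colnames(mat)),
              "matrix needs population rownames and character colnames")
  assert_that(!anyDuplicated(colnames(mat)), "duplicate character labels")
  assert_that(all(colSums(mat) >= 1),
              "every character must be present in at least one population")
  assert_that(all(rownames(mat) %in% names(cell_types)),
              "every population needs a cell-type tag")
  structure(list(mat = mat, cell_types = cell_types[rownames(mat)]),
            class = "character_matrix")
}

#' Test perfect-phylogeny compatibility
#'
#' A binary character matrix admits a perfect phylogeny (each character
#' arising exactly once on a rooted tree) iff for every pair of
#' characters the supporting population sets are nested or disjoint (a
#' laminar family). All violating pairs are returned.
#'
#' @param cm a \code{character_matrix}.
#' @return list with \code{compatible} (logical) and \code{conflicts}
#'   (data.frame char1/char2, zero rows when compatible).
#' @export
check_perfect_phylogeny <- function(cm) {
  mat <- cm$mat
  chars <- colnames(mat)
  conflicts <- list()
  if (length(chars) >= 2) {
    for (i in 1:(length(chars) - 1)) {
      for (j in (i + 1):length(chars)) {
        a <- mat[, i] == 1; b <- mat[, j] == 1
        inter <- any(a & b)
        if (inter && any(a & !b) && any(b & !a)) {
          conflicts[[length(conflicts) + 1]] <-
            data.frame(char1 = chars[i], char2 = chars[j],
                       stringsAsFactors = FALSE)
        }
      }
    }
  }
  conflicts <- if (length(conflicts)) do.call(rbind, conflicts)
               else data.frame(char1 = character(), char2 = character())
  list(compatible = nrow(conflicts) == 0, conflicts = conflicts)
}

#' Infer the clone tree from a compatible character matrix
#'
#' Characters with identical support sets merge into one edge (label =
#' member characters joined with "+", lexicographic); edges are nested
#' by support-set containment, which the laminar property makes
#' unambiguous. Each population attaches below the deepest character
#' edge it carries (at the root if it carries none), and the union of
#' edge labels on its root path reconstructs its character set exactly.
#' Sibling order is lexicographic, making the output deterministic.
#'
#' @param cm a \code{character_matrix}.
#' @return object of class \code{clone_tree}: list with \code{nodes}
#'   (data.frame id/parent/type/label and a list-column
#'   \code{characters}) and the input matrix.
#' @export
infer_clone_tree <- function(cm) {
  chk <- check_perfect_phylogeny(cm)
  if (!chk$compatible) {
    stop("matrix is not perfect-phylogeny compatible; conflicting pairs: ",
         paste(paste(chk$conflicts$char1, chk$conflicts$char2, sep = "~"),
               collapse = ", "))
  }
  mat <- cm$mat
  supp_key <- apply(mat, 2, paste, collapse = "")
  groups <- split(colnames(mat), supp_key)
  ginfo <- lapply(groups, function(chs) {
    s <- which(mat[, chs[1]] == 1)
    list(chars = sort(chs), support = s,
         label = paste(sort(chs), collapse = "+"))
  })
  ord <- order(-vapply(ginfo, function(g) length(g$support), 0L),
               vapply(ginfo, function(g) g$label, ""))
  ginfo <- ginfo[ord]

  nodes <- data.frame(id = 1L, parent = NA_integer_, type = "root",
                      label = "root", stringsAsFactors = FALSE)
  node_chars <- list(character(0))
  node_support <- list(seq_len(nrow(mat)))

  for (g in ginfo) {
    cand <- which(vapply(seq_len(nrow(nodes)), function(k) {
      nodes$type[k] != "population" &&
        all(g$support %in% node_support[[k]]) &&
        length(node_support[[k]]) > length(g$support)
    }, TRUE))
    # deepest strict superset = smallest candidate support (laminarity
    # makes candidates a chain); on ties (the root and a universal
    # character share the full support) take the most recently added,
    # i.e. deepest, node
    parent <- if (length(cand) == 0) 1L
              else {
                sz <- vapply(cand, function(k) length(node_support[[k]]), 0L)
                max(cand[sz == min(sz)])
              }
    id <- nrow(nodes) + 1L
    nodes <- rbind(nodes, data.frame(id = id, parent = nodes$id[parent],
                                     type = "clone", label = g$label,
                                     stringsAsFactors = FALSE))
    node_chars[[id]] <- g$chars
    node_support[[id]] <- g$support
  }

  for (p in seq_len(nrow(mat))) {
    carrying <- which(vapply(seq_len(nrow(nodes)), function(k)
      nodes$type[k] == "clone" && p %in% node_support[[k]], TRUE))
    parent <- if (length(carrying) == 0) 1L
              else carrying[which.min(vapply(carrying, function(k)
                length(node_support[[k]]), 0L))]
    id <- nrow(nodes) + 1L
    nodes <- rbind(nodes, data.frame(id = id, parent = nodes$id[parent],
                                     type = "population",
                                     label = rownames(mat)[p],
                                     stringsAsFactors = FALSE))
    node_chars[[id]] <- character(0)
    node_support[[id]] <- p
  }

  tree <- structure(list(nodes = nodes, characters = node_chars,
                         matrix = cm), class = "clone_tree")
  # internal consistency: root-path unions must reproduce the rows
  for (p in rownames(mat)) {
    got <- sort(population_characters(tree, p))
    want <- sort(colnames(mat)[mat[p, ] == 1])
    assert_that(identical(got, want),
                "internal error: root path of %s does not match its row", p)
  }
  tree
}

#' Characters on the root path of a population
#' @param tree a \code{clone_tree}.
#' @param population population label.
#' @return character vector (union of edge labels on the root path).
#' @export
population_characters <- function(tree, population) {
  nodes <- tree$nodes
  k <- which(nodes$type == "population" & nodes$label == population)
  assert_that(length(k) == 1, "unknown population: %s", population)
  out <- character()
  while (!is.na(nodes$parent[k])) {
    out <- c(out, tree$characters[[k]])
    k <- which(nodes$id == nodes$parent[k])
  }
  out
}

#' @export
print.clone_tree <- function(x, ...) {
  n <- x$nodes
  cat(sprintf("clone_tree: %d character edge(s), %d population(s)\n",
              sum(n$type == "clone"), sum(n$type == "population")))
  cat(clone_tree_newick(x), "\n")
  invisible(x)
}

#' Newick serialization of a clone tree
#'
#' Populations are tips; internal nodes carry their merged character
#' labels as node labels. Deterministic (lexicographic sibling order).
#'
#' @param tree a \code{clone_tree}.
#' @return newick string (with trailing semicolon).
#' @export
clone_tree_newick <- function(tree) {
  nodes <- tree$nodes
  recurse <- function(id) {
    k <- which(nodes$id == id)
    kids <- which(nodes$parent == id)
    kids <- kids[order(nodes$type[kids] != "clone", nodes$label[kids])]
    lab <- gsub("[ ,():;]", "_", nodes$label[k])
    if (length(kids) == 0) return(lab)
    paste0("(", paste(vapply(nodes$id[kids], recurse, ""), collapse = ","),
           ")", lab)
  }
  paste0(recurse(1L), ";")
}

#' Write a clone tree to newick and/or JSON
#' @param tree a \code{clone_tree}.
#' @param newick_path,json_path output paths (NULL to skip either).
#' @export
write_clone_tree <- function(tree, newick_path = NULL, json_path = NULL) {
  if (!is.null(newick_path)) writeLines(clone_tree_newick(tree), newick_path)
  if (!is.null(json_path)) {
    n <- tree$nodes
    n$characters <- vapply(tree$characters, paste, "", collapse = "+")
    jsonlite::write_json(n, json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(tree)
}

#' Load a hematopoiesis template
#'
#' Rooted scaffolds of progenitor compartments (HSC, MPP, LMPP, MLP,
#' CMP, GMP, MEP) with leaf slots per mature cell type, shipped with
#' the package in two variants: "classical" (lymphoid-primed branch
#' splitting off the multipotent progenitor, megakaryocyte/erythroid
#' branch under the common myeloid progenitor) and "composite"
#' (megakaryocyte/erythroid branch leaving directly below the
#' multipotent progenitor).
#'
#' @param variant "classical" or "composite".
#' @param path optional JSON path overriding the packaged template.
#' @return object of class \code{hematopoiesis_template}: list with
#'   \code{name}, \code{parent} (named vector: node -> parent node) and
#'   \code{leaf_slots} (named vector: cell type -> template node).
#' @export
hematopoiesis_template <- function(variant = c("classical", "composite"),
                                   path = NULL) {
  variant <- match.arg(variant)
  if (is.null(path)) {
    path <- system.file("extdata",
                        paste0("template_", variant, ".json"),
                        package = "hemaclone")
  }
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(name = raw$name, parent = unlist(raw$parent),
                 leaf_slots = unlist(raw$leaf_slots)),
            class = "hematopoiesis_template")
}

template_path_to_root <- function(template, node) {
  out <- node
  while (node %in% names(template$parent)) {
    node <- template$parent[[node]]
    out <- c(out, node)
  }
  out
}

template_lca <- function(template, nodes) {
  paths <- lapply(nodes, function(n) rev(template_path_to_root(template, n)))
  common <- paths[[1]]
  for (p in paths[-1]) {
    m <- min(length(common), length(p))
    eq <- which(common[seq_len(m)] == p[seq_len(m)])
    common <- common[seq_len(max(eq))]
  }
  common[length(common)]
}

#' Map clone-tree character edges onto a hematopoiesis template
#'
#' Each character edge is assigned the deepest template compartment
#' consistent with the cell types that carry it: the lowest common
#' ancestor, in the template, of the leaf slots of all populations
#' below the edge. A character shared by plasma-cell and myeloblast
#' populations therefore lands at or above the lymphoid-primed
#' multipotent progenitor in the classical template, while a character
#' private to erythrocytes lands on the erythrocyte slot below the
#' megakaryocyte/erythroid progenitor. Populations without characters
#' belong to the normal-karyotype root lineage. The annotation never
#' alters the clone-tree topology.
#'
#' @param tree a \code{clone_tree}.
#' @param template a \code{hematopoiesis_template}.
#' @return data.frame with one row per character edge: \code{label},
#'   \code{cell_types} (comma-joined), \code{template_node}.
#' @export
map_to_template <- function(tree, template) {
  ct <- tree$matrix$cell_types
  missing <- setdiff(unique(ct), names(template$leaf_slots))
  assert_that(length(missing) == 0,
              "cell type(s) absent from template: %s",
              paste(missing, collapse = ", "))
  nodes <- tree$nodes
  clone_ids <- nodes$id[nodes$type == "clone"]
  descendants_pops <- function(id) {
    kids <- nodes$id[!is.na(nodes$parent) & nodes$parent == id]
    pops <- nodes$label[nodes$id %in% kids & nodes$type == "population"]
    for (k in kids[nodes$type[match(kids, nodes$id)] == "clone"])
      pops <- c(pops, descendants_pops(k))
    pops
  }
  out <- do.call(rbind, lapply(clone_ids, function(id) {
    pops <- descendants_pops(id)
    types <- unique(unname(ct[pops]))
    slots <- unique(unname(template$leaf_slots[types]))
    data.frame(label = nodes$label[nodes$id == id],
               cell_types = paste(sort(types), collapse = ","),
               template_node = template_lca(template, slots),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Member aberrations of the packaged aberration groups
#'
#' The copy-number groups (A..I) and SNV groups (1..3) used as
#' characters in the packaged example matrix, with their member
#' aberrations.
#'
#' @param path JSON path; defaults to the packaged table.
#' @return named list: group id -> character vector of members.
#' @export
aberration_groups <- function(path = system.file("extdata",
                                                 "aberration_groups.json",
                                                 package = "hemaclone")) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Read a character matrix from TSV
#'
#' First column \code{population}, second \code{cell_type}, remaining
#' columns one per character with 0/1 entries.
#'
#' @param path TSV path.
#' @return a \code{character_matrix}.
#' @export
read_character_matrix <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  assert_that(all(c("population", "cell_type") %in% names(df)),
              "matrix TSV needs population and cell_type columns")
  mat <- as.matrix(df[, setdiff(names(df), c("population", "cell_type")),
                      drop = FALSE])
  rownames(mat) <- df$population
  character_matrix(mat, stats::setNames(df$cell_type, df$population))
}

#' Write a character matrix as TSV
#' @param cm a \code{character_matrix}.
#' @param path output path.
#' @export
write_character_matrix <- function(cm, path) {
  df <- data.frame(population = rownames(cm$mat),
                   cell_type = unname(cm$cell_types),
                   cm$mat, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(cm)
}
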