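# local re-implementation of the template root path, used as an oracle
template_path_to_root_test <- function(tpl, node) {
  out <- node
  while (node %in% names(tpl$parent)) {
    node <- tpl$parent[[node]]
    out <- c(out, node)
  }
  out
}

test_that("laminar support sets are compatible, crossing ones conflict", {
  rows <- list(c("A", "B", "C"), c("A", "B", "D"), c("A", "E", "F"), c("A", "E"))
  chars <- sort(unique(unlist(rows)))
  mat <- t(vapply(rows, function(r) as.integer(chars %in% r),
                  integer(length(chars))))
  dimnames(mat) <- list(paste0("p", 1:4), chars)
  expect_true(check_perfect_phylogeny(mk_cm(mat))$compatible)

  bad <- matrix(c(1, 0, 1,
                  0, 1, 1), nrow = 3, dimnames = list(paste0("p", 1:3),
                                                      c("X", "Y")))
  res <- check_perfect_phylogeny(mk_cm(bad))
  expect_false(res$compatible)
  expect_equal(nrow(res$conflicts), 1)
  expect_setequal(unlist(res$conflicts[1, ]), c("X", "Y"))
  expect_error(infer_clone_tree(mk_cm(bad)), "X~Y")

  single <- matrix(c(1, 1), nrow = 1,
                   dimnames = list("p1", c("A", "B")))
  expect_true(check_perfect_phylogeny(mk_cm(single))$compatible)
})

test_that("the packaged matrix yields the expected clone hierarchy", {
  cm <- case_matrix()
  expect_true(check_perfect_phylogeny(cm)$compatible)
  tree <- infer_clone_tree(cm)
  neoplastic <- c("nPC_1", "nPC_2", "MB_1", "MB_2")
  # the only character shared by all four neoplastic populations is A,
  # and it sits on a single edge directly under the root
  shared <- Reduce(intersect, lapply(neoplastic,
                                     function(p) population_characters(tree, p)))
  expect_equal(shared, "A")
  nodes <- tree$nodes
  a_node <- which(nodes$type == "clone" & nodes$label == "A")
  expect_equal(nodes$parent[a_node], nodes$id[nodes$type == "root"])
  # B hangs below A on the plasma-cell branch, E on the myeloblast branch
  b_node <- which(nodes$label == "B")
  e_node <- which(nodes$label == "E")
  expect_equal(nodes$parent[b_node], nodes$id[a_node])
  expect_equal(nodes$parent[e_node], nodes$id[a_node])
})

test_that("characters with identical support share one edge", {
  m <- matrix(c(1, 1), nrow = 1, dimnames = list("p1", c("A", "B")))
  tree <- infer_clone_tree(mk_cm(m))
  expect_equal(sum(tree$nodes$type == "clone"), 1)
  expect_equal(tree$nodes$label[tree$nodes$type == "clone"], "A+B")
  expect_setequal(population_characters(tree, "p1"), c("A", "B"))
})

test_that("root-path unions reconstruct every input row", {
  for (s in 1:20) {
    mat <- random_laminar_matrix(n_pops = sample(3:8, 1),
                                 n_chars = sample(2:8, 1), seed = s)
    cm <- mk_cm(mat)
    expect_true(check_perfect_phylogeny(cm)$compatible)
    tree <- infer_clone_tree(cm)
    for (p in rownames(mat)) {
      expect_setequal(population_characters(tree, p),
                      colnames(mat)[mat[p, ] == 1])
    }
  }
})

test_that("compatibility agrees with the brute-force laminar oracle", {
  # full enumeration of all 3x3 binary matrices with no empty character
  for (code in 0:511) {
    bits <- as.integer(intToBits(code))[1:9]
    mat <- matrix(bits, nrow = 3, dimnames = list(paste0("p", 1:3),
                                                  paste0("c", 1:3)))
    keep <- colSums(mat) >= 1
    if (sum(keep) == 0) next
    mat <- mat[, keep, drop = FALSE]
    expect_equal(check_perfect_phylogeny(mk_cm(mat))$compatible,
                 oracle_laminar(mat))
  }
  # random matrices up to 6x6
  set.seed(99)
  for (i in 1:200) {
    mat <- matrix(stats::rbinom(36, 1, 0.4), nrow = 6,
                  dimnames = list(paste0("p", 1:6), paste0("c", 1:6)))
    keep <- colSums(mat) >= 1
    if (sum(keep) == 0) next
    mat <- mat[, keep, drop = FALSE]
    expect_equal(check_perfect_phylogeny(mk_cm(mat))$compatible,
                 oracle_laminar(mat))
  }
})

test_that("newick output is well-formed and deterministic", {
  cm <- case_matrix()
  tree <- infer_clone_tree(cm)
  nwk <- clone_tree_newick(tree)
  expect_identical(nwk, clone_tree_newick(infer_clone_tree(cm)))
  skip_if_not_installed("ape")
  ph <- ape::read.tree(text = nwk)
  expect_setequal(ph$tip.label, rownames(cm$mat))
})

test_that("template mapping places shared characters at shared progenitors", {
  cm <- case_matrix()
  tree <- infer_clone_tree(cm)
  tpl <- hematopoiesis_template("classical")
  mp <- map_to_template(tree, tpl)
  # A is carried by both PC and MB populations -> lymphoid-primed
  # multipotent progenitor in the classical scaffold
  expect_equal(mp$template_node[mp$label == "A"], "LMPP")
  # I is private to erythrocytes -> below the megakaryocyte/erythroid
  # progenitor
  ery <- mp$template_node[mp$label == "I"]
  expect_true("MEP" %in% template_path_to_root_test(tpl, ery))
  expect_equal(ery, "erythrocyte")
  # megakaryocytes carry nothing: no character maps to their lineage
  expect_false(any(grepl("megakaryocyte", mp$cell_types)))
  # G is shared by neutrophils and eosinophils -> GMP
  expect_equal(mp$template_node[mp$label == "G"], "GMP")

  # composite template still places A above both branches
  mp2 <- map_to_template(tree, hematopoiesis_template("composite"))
  expect_equal(mp2$template_node[mp2$label == "A"], "LMPP")

  # unknown cell type is rejected by name
  bad <- character_matrix(matrix(1, 1, 1, dimnames = list("x", "A")),
                          c(x = "astrocyte"))
  expect_error(map_to_template(infer_clone_tree(bad), tpl), "astrocyte")
})

test_that("adding a carrier population can only move a character rootward", {
  tpl <- hematopoiesis_template("classical")
  depth <- function(node) length(template_path_to_root_test(tpl, node))
  m1 <- matrix(1, 1, 1, dimnames = list("e1", "X"))
  t1 <- map_to_template(infer_clone_tree(character_matrix(
    m1, c(e1 = "erythrocyte"))), tpl)
  m2 <- matrix(1, 2, 1, dimnames = list(c("e1", "n1"), "X"))
  t2 <- map_to_template(infer_clone_tree(character_matrix(
    m2, c(e1 = "erythrocyte", n1 = "neutrophil"))), tpl)
  expect_lt(depth(t2$template_node), depth(t1$template_node))
  m3 <- matrix(1, 3, 1, dimnames = list(c("e1", "n1", "p1"), "X"))
  t3 <- map_to_template(infer_clone_tree(character_matrix(
    m3, c(e1 = "erythrocyte", n1 = "neutrophil", p1 = "PC"))), tpl)
  expect_lte(depth(t3$template_node), depth(t2$template_node))
})

test_that("character matrices round-trip through TSV", {
  cm <- case_matrix()
  p <- tempfile(fileext = ".tsv")
  write_character_matrix(cm, p)
  cm2 <- read_character_matrix(p)
  expect_equal(cm2$mat, cm$mat)
  expect_equal(cm2$cell_types, cm$cell_types)
})
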