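# Distances, neighbor joining, bootstrap supports, monophyly, and
# clustering of RT-free aRNH copies.

test_that("Poisson-corrected distance matches its closed form", {
  expect_equal(protein_distance("ACDEF", "ACDEF"), 0)
  # p = 0.1 over 10 comparable columns
  a <- "AAAAAAAAAA"
  b <- "CAAAAAAAAA"
  expect_equal(protein_distance(a, b), -log(0.9), tolerance = 1e-12)
  # gapped columns are excluded
  expect_equal(protein_distance("A-CD", "AGCD"), 0)
  expect_error(protein_distance("--", "AA"), "comparable")
  expect_equal(protein_distance("--", "AA", on_empty = "cap"), 10)
  # saturation capped
  expect_equal(protein_distance("AAAA", "CCCC"), 10)

  # random pairs against direct recomputation from the definition
  set.seed(19)
  for (i in 1:20) {
    x <- strsplit(random_protein_str(60), "")[[1]]
    y <- strsplit(random_protein_str(60), "")[[1]]
    gaps <- sample(60, 8)
    x[gaps[1:4]] <- "-"
    y[gaps[5:8]] <- "-"
    ok <- x != "-" & y != "-"
    p <- sum(x[ok] != y[ok]) / sum(ok)
    expect_equal(
      protein_distance(paste(x, collapse = ""), paste(y, collapse = "")),
      if (p >= 1 - exp(-10)) 10 else -log(1 - p),
      tolerance = 1e-12)
  }
})

test_that("neighbor joining recovers additive trees and 3-taxon lengths", {
  skip_if_not_installed("phangorn")
  set.seed(29)
  for (i in 1:6) {
    n <- sample(6:12, 1)
    tr <- ape::rtree(n)
    tr$edge.length <- tr$edge.length + 0.05
    D <- ape::cophenetic.phylo(tr)
    nj <- nj_tree(D)
    expect_equal(phangorn::RF.dist(ape::unroot(tr), nj), 0)
  }

  # 3 taxa: closed-form branch lengths
  D <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  t3 <- nj_tree(D)
  bl <- setNames(t3$edge.length, t3$tip.label[t3$edge[, 2]])
  expect_equal(unname(bl["a"]), (3 + 4 - 5) / 2)
  expect_equal(unname(bl["b"]), (3 + 5 - 4) / 2)
  expect_equal(unname(bl["c"]), (4 + 5 - 3) / 2)

  expect_error(nj_tree(D[1:2, 1:2]), "3 taxa")

  # permuting labels leaves the unrooted topology unchanged
  skip_if_not_installed("phangorn")
  set.seed(31)
  tr <- ape::rtree(8)
  tr$edge.length <- tr$edge.length + 0.05
  D <- ape::cophenetic.phylo(tr)
  perm <- sample(rownames(D))
  expect_equal(phangorn::RF.dist(nj_tree(D), nj_tree(D[perm, perm])), 0)
})

test_that("bootstrap supports are seeded, reproducible and sane", {
  profs <- default_profiles()
  v <- retromine:::group_variants()
  set.seed(37)
  rows <- c(
    setNames(lapply(1:4, function(i)
      retromine:::mutate_protein(v$aRNH$Archon, 0.05)), paste0("A", 1:4)),
    setNames(lapply(1:4, function(i)
      retromine:::mutate_protein(v$aRNH$L1, 0.05)), paste0("B", 1:4)))
  aln <- align_to_profile(profs$aRNH, unlist(rows))
  bs1 <- bootstrap_support(aln, n_reps = 100, seed = 3)
  bs2 <- bootstrap_support(aln, n_reps = 100, seed = 3)
  expect_identical(bs1$support, bs2$support)
  key <- paste(paste0("B", 1:4), collapse = "|")
  expect_gte(bs1$support[[key]], 90)
  expect_true(is_monophyletic(bs1$tree, paste0("A", 1:4)))

  bs0 <- bootstrap_support(aln, n_reps = 0)
  expect_true(all(is.na(bs0$support)))
})

test_that("monophyly is an unrooted bipartition test", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1,(E:1,F:1):1);")
  expect_true(is_monophyletic(tr, "A"))
  expect_true(is_monophyletic(tr, c("A", "B", "C", "D", "E", "F")))
  expect_true(is_monophyletic(tr, c("A", "B")))
  expect_true(is_monophyletic(tr, c("C", "D", "E", "F")))  # complement
  expect_false(is_monophyletic(tr, c("A", "C")))
  expect_error(is_monophyletic(tr, "Z"), "unknown leaf")
  expect_error(is_monophyletic(tr, character(0)), "empty")
})

test_that("individual aRNHs cluster with their source group or found a
           novel clade", {
  profs <- default_profiles()
  v <- retromine:::group_variants()
  set.seed(41)
  inds <- c(
    archon_rem = retromine:::mutate_protein(v$aRNH$Archon, 0.08),
    l1_rem = retromine:::mutate_protein(v$aRNH$L1, 0.08),
    alien = retromine:::mutate_protein(v$aRNH$outgroup, 0.05))
  cl <- cluster_individual_arnh(inds, profs$aRNH, seed = 11)
  expect_equal(unname(cl$labels["archon_rem"]), "Archon")
  expect_equal(unname(cl$labels["l1_rem"]), "L1")
  expect_equal(unname(cl$labels["alien"]), "novel")

  # single sequence: deterministic nearest-reference label
  one <- cluster_individual_arnh(inds["archon_rem"], profs$aRNH, seed = 11)
  expect_equal(unname(one$labels), "Archon")
})
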