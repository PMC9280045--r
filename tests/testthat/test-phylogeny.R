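aln_from <- function(...) {
  seqs <- c(...)
  seq_records(names(seqs), seqs, alphabet = "protein-aligned")
}

test_that("pairwise distances use pairwise gap deletion", {
  aln <- aln_from(a = "AAAA", b = "AATT")
  expect_equal(pairwise_distance(aln)["a", "b"], 0.5)

  aln2 <- aln_from(a = "A-AA", b = "AGAT")
  expect_equal(pairwise_distance(aln2)["a", "b"], 1 / 3)

  aln3 <- aln_from(a = "MKWV", b = "MKWV")
  expect_equal(pairwise_distance(aln3)["a", "b"], 0)
  expect_equal(pairwise_distance(aln3, "poisson")["a", "b"], 0)

  expect_equal(pairwise_distance(aln, "poisson")["a", "b"], -log(0.5))
  expect_error(pairwise_distance(aln_from(a = "A-", b = "-A")),
               "no comparable columns.*a / b")
  expect_error(pairwise_distance(aln_from(a = "AA", b = "TT"), "poisson"),
               "saturated")
})

test_that("three-taxon NJ reproduces the closed-form star lengths", {
  D <- matrix(c(0, 2, 3, 2, 0, 5, 3, 5, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- neighbor_joining(D)
  bl <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(bl[["a"]], (2 + 3 - 5) / 2)
  expect_equal(bl[["b"]], (2 + 5 - 3) / 2)
  expect_equal(bl[["c"]], (3 + 5 - 2) / 2)
})

test_that("NJ recovers the four-point additive example exactly", {
  # tree ((A:1,B:2):1,(C:3,D:4)) -> dAB=3 dCD=7 dAC=5 dAD=6 dBC=6 dBD=7
  lab <- c("A", "B", "C", "D")
  D <- matrix(c(0, 3, 5, 6,
                3, 0, 6, 7,
                5, 6, 0, 7,
                6, 7, 7, 0), 4, 4, dimnames = list(lab, lab))
  tr <- neighbor_joining(D)
  # AB|CD bipartition and exact path lengths
  expect_equal(nj_splits(tr), sort(paste(c("C", "D"), collapse = "\r")))
  expect_lt(max(abs(as.matrix(ape::cophenetic.phylo(tr))[lab, lab] - D)),
            1e-9)
})

test_that("NJ is invariant to taxon input order and matches ape's nj", {
  ra <- random_additive(7, seed = 42)
  tr1 <- neighbor_joining(ra$D)
  perm <- c(4, 1, 7, 3, 6, 2, 5)
  tr2 <- neighbor_joining(ra$D[perm, perm])
  expect_equal(nj_splits(tr1), nj_splits(tr2))
  expect_equal(as.matrix(ape::cophenetic.phylo(tr1))[rownames(ra$D),
                                                     rownames(ra$D)],
               as.matrix(ape::cophenetic.phylo(tr2))[rownames(ra$D),
                                                     rownames(ra$D)],
               tolerance = 1e-9)
  # independent implementation agreement on topology
  expect_equal(nj_splits(tr1), sort(woxkit:::.tree_splits(ape::nj(ra$D))))
})

test_that("NJ branch lengths are clamped to be non-negative", {
  set.seed(10)
  for (i in 1:5) {
    n <- 6
    ra <- random_additive(n, seed = i)
    noisy <- ra$D + matrix(stats::runif(n * n, 0, 0.3), n, n)
    noisy <- (noisy + t(noisy)) / 2
    diag(noisy) <- 0
    tr <- neighbor_joining(noisy)
    expect_true(all(tr$edge.length >= 0))
  }
})

test_that("NJ topology equals the exhaustive least-squares optimum (small n)", {
  for (i in 1:8) {
    n <- sample(5:6, 1)
    ra <- random_additive(n, seed = 100 + i)
    expect_equal(nj_splits(neighbor_joining(ra$D)), ls_optimal_splits(ra$D))
    expect_equal(nj_splits(neighbor_joining(ra$D)), sort(ra$splits))
  }
})

test_that("bootstrap supports behave at the degenerate corners", {
  # 50 copies of a single column pattern: every resample is the same
  # alignment, so every bipartition is supported at 100
  aln <- aln_from(a = strrep("A", 50), b = strrep("A", 50),
                  c = strrep("C", 50), d = strrep("C", 50))
  tr <- bootstrap_support(aln, n_reps = 30, seed = 4)
  sup <- as.numeric(tr$node.label[tr$node.label != ""])
  expect_true(all(sup == 100))

  sim <- simulate_alignment_on_tree(three_clade_tree(2L), n_columns = 60L,
                                    subs_rate = 1, seed = 2L)
  tr1 <- bootstrap_support(sim$records, n_reps = 1, seed = 9)
  sup1 <- as.numeric(tr1$node.label[tr1$node.label != ""])
  expect_true(all(sup1 %in% c(0, 100)))

  # determinism under a fixed seed
  tr_a <- bootstrap_support(sim$records, n_reps = 25, seed = 31)
  tr_b <- bootstrap_support(sim$records, n_reps = 25, seed = 31)
  expect_identical(tr_a$node.label, tr_b$node.label)
})

test_that("clade assignment labels by nearest anchor with tie -> ambiguous", {
  lab <- c("anc1", "int1", "g_near", "g_tie")
  D <- matrix(0, 4, 4, dimnames = list(lab, lab))
  D["anc1", "g_near"] <- D["g_near", "anc1"] <- 0
  D["int1", "g_near"] <- D["g_near", "int1"] <- 0.5
  D["anc1", "g_tie"] <- D["g_tie", "anc1"] <- 0.3
  D["int1", "g_tie"] <- D["g_tie", "int1"] <- 0.3
  D["anc1", "int1"] <- D["int1", "anc1"] <- 0.8
  cl <- assign_clades(D, c(anc1 = "ancient", int1 = "intermediate"))
  expect_equal(cl$clade[cl$gene_id == "g_near"], "ancient")
  expect_gt(cl$margin[cl$gene_id == "g_near"], 0)
  expect_equal(cl$clade[cl$gene_id == "g_tie"], "ambiguous")
  expect_error(assign_clades(D, c(missing = "ancient")), "missing")
})

test_that("simulated three-clade families are fully recovered at low rate", {
  tree <- three_clade_tree(n_genes = 4L)
  sim <- simulate_alignment_on_tree(tree, n_columns = 400L, subs_rate = 0.5,
                                    seed = 8L)
  D <- pairwise_distance(sim$records)
  anchors <- c(anchor_ancient = "ancient",
               anchor_intermediate = "intermediate",
               anchor_modern = "modern")
  cl <- assign_clades(D, anchors)
  truth <- c(anc = "ancient", int = "intermediate", mod = "modern")
  expect_equal(cl$clade, unname(truth[substr(cl$gene_id, 1, 3)]))
})

test_that("clade proportions round half away from zero to one decimal", {
  pct <- clade_proportions(c(modern = 38L, intermediate = 12L, ancient = 9L))
  expect_equal(unname(pct[c("modern", "intermediate", "ancient")]),
               c(64.4, 20.3, 15.3))
  expect_equal(unname(clade_proportions(c(a = 1L, b = 7L))[c("a", "b")]),
               c(12.5, 87.5))
})
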