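test_that("codon counting is frame-0, additive, and skips ambiguous triplets", {
  cc <- count_codons(c("ATGTAA"))
  expect_equal(unname(cc$counts[c("AUG", "UAA")]), c(1L, 1L))
  expect_equal(cc$n_total, 2L)

  cc2 <- count_codons(c("ATGNNGTAA"))
  expect_equal(unname(cc2$counts[c("AUG", "UAA")]), c(1L, 1L))
  expect_equal(cc2$n_skipped, 1L)

  cc3 <- count_codons(rep("ATGGCAGCATAA", 2))
  expect_equal(unname(cc3$counts[c("GCA", "AUG", "UAA")]), c(4L, 2L, 2L))

  expect_error(count_codons("ATGA"), "divisible by 3")
})

test_that("RSCU/RFSC arithmetic and the high-frequency rule", {
  # two-codon family with counts (3, 1): forced arithmetic
  counts <- count_codons(c(paste(rep("GAT", 3), collapse = ""), "GAC"))
  u <- compute_usage(counts)
  d <- u[u$amino_acid == "D", ]
  expect_equal(d$rscu, c(0.5, 1.5))   # GAC, GAU alphabetical
  expect_equal(d$rfsc, c(25, 75))
  expect_equal(d$bias, c("negative", "positive"))
  expect_equal(d$high_frequency, c(FALSE, TRUE))  # 75 >= 1.5 * 50, > 60
  # family with zero total is undefined throughout
  expect_true(all(u$bias[u$amino_acid == "A"] == "undefined"))
  expect_true(all(is.na(u$rscu[u$amino_acid == "A"])))
})

test_that("printed table rows classify as in the published table", {
  fx <- load_fixture_tables()
  jc <- fx$usage[fx$usage$species == "JcWOX", ]
  t_jc <- usage_table_from_values(jc$codon, jc$rscu, jc$rfsc, "JcWOX")
  gca <- t_jc[t_jc$codon == "GCA", ]
  expect_equal(gca$rscu, 2.09)
  expect_equal(gca$bias, "positive")
  expect_true(gca$high_frequency)     # 52.26 >= 1.5 * 25
  aug <- t_jc[t_jc$codon == "AUG", ]
  expect_true(is.na(aug$high_frequency))  # k = 1 never classified
  expect_equal(aug$bias, "none")          # printed 1.00 exactly

  hb <- fx$usage[fx$usage$species == "HbWOX", ]
  t_hb <- usage_table_from_values(hb$codon, hb$rscu, hb$rfsc, "HbWOX")
  acu <- t_hb[t_hb$codon == "ACU", ]
  expect_equal(acu$rfsc, 37.50)
  expect_true(acu$high_frequency)     # exact 1.5x boundary is inclusive
})

test_that("bias partition counts agreement and reacts to single flips", {
  counts <- count_codons(c("GATGATGATGACTTATTG"))
  tab <- compute_usage(counts)
  four <- list(tab, tab, tab, tab)
  bp <- bias_partition(four)
  expect_equal(sum(bp), 64)
  flipped <- tab
  i <- which(flipped$codon == "GAU")
  flipped$rscu[i] <- 0.5
  flipped$bias[i] <- "negative"
  bp2 <- bias_partition(list(tab, tab, tab, flipped))
  expect_equal(unname(bp2["differing"] - bp["differing"]), 1L)
  expect_equal(unname(bp["positive"] - bp2["positive"]), 1L)

  bad <- tab[tab$codon != "GAU", ]
  expect_error(bias_partition(list(tab, bad)), "different codon sets")
})

test_that("high-frequency consensus is the intersection of per-table sets", {
  counts <- count_codons(c("GATGATGATGAC"))
  tab <- compute_usage(counts)
  own <- tab$codon[tab$high_frequency %in% TRUE]
  expect_equal(consensus_high_frequency(list(tab)), own)
  other <- tab
  other$high_frequency[] <- FALSE
  expect_equal(length(consensus_high_frequency(list(tab, other))), 0L)
})

test_that("per-mille frequencies normalize and are scale invariant", {
  cc <- count_codons("ATGATGATG")
  f <- codon_frequency(cc)
  expect_equal(unname(f["AUG"]), 1000)
  expect_equal(sum(f), 1000)

  cc1 <- count_codons("GATGACTTA")
  cc2 <- count_codons(rep("GATGACTTA", 7))
  expect_equal(codon_frequency(cc1), codon_frequency(cc2))

  empty <- count_codons(character())
  expect_error(codon_frequency(empty), "no codons")
})

test_that("ratio classification band is inclusive and reciprocal-symmetric", {
  expect_equal(classify_ratio(c(0.5, 0.51, 1, 1.99, 2, NA)),
               c("divergent", "similar", "similar", "similar", "divergent",
                 "undefined"))
  set.seed(5)
  f1 <- codon_frequency(count_codons(simulate_cds_set(5, 200, seed = 1)$records))
  f2 <- codon_frequency(count_codons(simulate_cds_set(5, 200, seed = 2)$records))
  fwd <- ratio_compare(f1, f2)
  rev <- ratio_compare(f2, f1)
  both <- !is.na(fwd$ratio) & !is.na(rev$ratio)
  expect_equal(fwd$class[both] == "divergent", rev$class[both] == "divergent")

  ident <- ratio_compare(f1, f1)
  expect_true(all(ident$ratio[!is.na(ident$ratio)] == 1))
  expect_true(all(ident$class[!is.na(ident$ratio)] == "similar"))
})

test_that("zero reference frequencies classify as divergent or undefined", {
  f <- codon_frequency(count_codons("ATGGATTAA"))
  ref <- f
  ref["GAU"] <- 0
  rt <- ratio_compare(f, ref)
  expect_equal(rt$class[rt$codon == "GAU"], "divergent")
  expect_true(is.na(rt$ratio[rt$codon == "GAU"]))
  # both zero -> undefined
  expect_equal(rt$class[rt$codon == "GCA"], "undefined")
})

test_that("host ranking orders by divergent count then mean |log2 ratio|", {
  f <- codon_frequency(count_codons(simulate_cds_set(5, 300, seed = 9)$records))
  r <- rank_hosts(f, list(self = f, other = f * 2))
  expect_equal(r$label[1], "self")
  expect_equal(r$n_divergent[1], 0L)

  # equal divergent counts, unequal mean |log2 r|: tie broken by the mean
  near <- f * 1.1   # all ratios 1/1.1, none divergent
  nearer <- f * 1.01
  r2 <- rank_hosts(f, list(a_worse = near, b_better = nearer))
  expect_equal(r2$n_divergent, c(0L, 0L))
  expect_equal(r2$label, c("b_better", "a_worse"))
})

test_that("RSCU converges to k * p on large simulated CDS sets", {
  probs <- uniform_family_probs(
    override = list(A = c(GCT = 0.4, GCC = 0.3, GCA = 0.2, GCG = 0.1)))
  sim <- simulate_cds_set(n_genes = 100L, len_codons = 4000L,
                          family_probs = probs, seed = 123L)
  u <- compute_usage(count_codons(sim$records))
  a <- u[u$amino_acid == "A", ]
  expected <- 4 * c(GCA = 0.2, GCC = 0.3, GCG = 0.1, GCU = 0.4)
  expect_lt(max(abs(a$rscu - expected[a$codon])), 0.05)
  # uniform sense-codon families sit near RSCU 1 (TER sees only one stop
  # per gene, far too few draws for this bound)
  others <- u[!u$amino_acid %in% c("A", "M", "W", "TER") & !is.na(u$rscu), ]
  expect_lt(max(abs(others$rscu - 1)), 0.05)
})
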