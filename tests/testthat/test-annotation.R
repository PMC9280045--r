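toy_model <- function(strand = "+", exons, cds, utr5 = NULL, utr3 = NULL,
                      id = "g") {
  gene_model(id, "chr", strand, exons = exons, cds = cds,
             utr5 = utr5, utr3 = utr3)
}

test_that("structure statistics count exons, introns, UTRs and span", {
  m <- toy_model(exons = rbind(c(101, 400), c(600, 900), c(1100, 1300)),
                 cds = rbind(c(150, 400, 0), c(600, 900, 0), c(1100, 1250, 0)),
                 utr5 = rbind(c(101, 149)), utr3 = rbind(c(1251, 1300)))
  st <- structure_stats(m)
  expect_equal(st$n_exons, 3L)
  expect_equal(st$n_introns, 2L)
  expect_true(st$has_utr5 && st$has_utr3)
  expect_equal(st$span_bp, 1200)
  expect_false(st$long_gene)

  single <- toy_model(exons = rbind(c(1, 300)), cds = rbind(c(1, 300, 0)))
  expect_equal(structure_stats(single)$n_introns, 0L)

  long <- toy_model(exons = rbind(c(1, 200), c(3300, 3500)),
                    cds = rbind(c(1, 200, 0), c(3300, 3402, 0)))
  expect_true(structure_stats(long)$long_gene)   # span 3500 > 3 kb
  # boundary: exactly 3000 bp is not "more than 3 kb"
  exact <- toy_model(exons = rbind(c(1, 300), c(2800, 3000)),
                     cds = rbind(c(1, 300, 0), c(2800, 2901, 0)))
  expect_false(structure_stats(exact)$long_gene)
})

test_that("promoter extraction is strand-aware and truncates at contig edges", {
  set.seed(1)
  contig <- paste(sample(c("A", "C", "G", "T"), 4000, replace = TRUE),
                  collapse = "")
  genome <- seq_records("chr", contig, alphabet = "dna")
  m <- toy_model(exons = rbind(c(2001, 2300)), cds = rbind(c(2001, 2300, 0)))
  pr <- extract_promoter(genome, m, 2000)
  expect_equal(pr$sequence, substr(contig, 1, 2000))
  expect_false(pr$truncated)

  m2 <- toy_model(exons = rbind(c(500, 700)), cds = rbind(c(500, 700, 0)))
  pr2 <- extract_promoter(genome, m2, 2000)
  expect_equal(nchar(pr2$sequence), 499)
  expect_true(pr2$truncated)

  m3 <- toy_model(exons = rbind(c(1, 300)), cds = rbind(c(1, 300, 0)))
  expect_error(extract_promoter(genome, m3), "zero-length promoter")
})

test_that("minus-strand promoters are the reverse complement of the 3' flank", {
  # 30 bp toy contig, CDS on minus strand at 11..22, promoter length 10:
  # plus-strand bases 23..30 (8 nt, truncated), reverse-complemented
  contig <- "AAAAAAAAAACATTTTTTTTTTGGCCGGTT"
  genome <- seq_records("chr", contig, alphabet = "dna")
  m <- toy_model(strand = "-", exons = rbind(c(11, 22)),
                 cds = rbind(c(11, 22, 0)))
  pr <- extract_promoter(genome, m, 10)
  expect_equal(pr$sequence, "AACCGGCC")  # revcomp("GGCCGGTT")
  expect_true(pr$truncated)

  pr5 <- extract_promoter(genome, m, 5)
  expect_equal(pr5$sequence, "CGGCC")    # revcomp of bases 23..27 "GGCCG"
  expect_false(pr5$truncated)
})

test_that("IUPAC scanning finds degenerate and minus-strand matches in order", {
  motifs <- demo_motifs()
  hits <- scan_motifs("TTAAACCATT", motifs[motifs$name == "ARE", ])
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$start, 3L)
  expect_equal(hits$strand, "+")
  expect_equal(hits$match, "AAACCA")

  myc <- motifs[motifs$name == "MYC", ]   # CANNTG, an rc-palindromic consensus
  hits2 <- scan_motifs("GCATGTGC", myc)
  expect_equal(hits2$match, c("CATGTG", "CATGTG"))
  expect_equal(hits2$start, c(2L, 2L))
  expect_equal(hits2$strand, c("+", "-"))  # ordered + before - at equal start

  # a non-palindromic motif planted once in reverse orientation
  abre <- data.frame(name = "ABRE", iupac = "ACGTGGC", category = "hormone")
  prom <- paste0(strrep("T", 10), "GCCACGT", strrep("T", 10))  # revcomp planted
  hits3 <- scan_motifs(prom, abre)
  expect_equal(nrow(hits3), 1L)
  expect_equal(hits3$strand, "-")
  expect_equal(hits3$start, 11L)

  expect_error(scan_motifs("ACGT", data.frame(name = "bad", iupac = "AC1T",
                                              category = "stress")),
               "invalid IUPAC")
})

test_that("scanning a promoter and its reverse complement mirrors hits", {
  sim <- simulate_promoters(
    plant_spec = matrix(c(3L, 2L), 1, 2,
                        dimnames = list("g1", c("ARE", "G-box"))),
    motifs = demo_motifs(), length = 300L, seed = 5L)
  prom <- sim$promoters[["g1"]]
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(prom)))
  fwd <- scan_motifs(prom, demo_motifs(), gene_id = "g1")
  rev <- scan_motifs(rc, demo_motifs(), gene_id = "g1")
  expect_equal(nrow(fwd), nrow(rev))
  key <- function(h, L) {
    k <- paste(h$motif,
               ifelse(h$strand == "+", "-", "+"),
               L - (h$start + nchar(h$match) - 1L) + 1L)
    sort(k)
  }
  expect_equal(sort(paste(fwd$motif, fwd$strand, fwd$start)),
               key(rev, nchar(prom)))
})

test_that("element summaries count per gene and category, keeping zero genes", {
  motifs <- demo_motifs()
  hits <- data.frame(gene_id = c(rep("g1", 5)),
                     motif = c("ARE", "ARE", "ARE", "ABRE", "ABRE"),
                     category = c(rep("stress", 3), rep("hormone", 2)),
                     start = 1:5, strand = "+", match = "x",
                     stringsAsFactors = FALSE)
  summ <- summarize_elements(hits, motifs, gene_ids = c("g1", "g2"))
  expect_equal(summ$by_category["g1", "stress"], 3)
  expect_equal(summ$by_category["g1", "hormone"], 2)
  expect_equal(sum(unlist(summ$by_motif["g2", ])), 0)
  expect_equal(unname(summ$category_totals["stress"]), 3)

  empty <- summarize_elements(hits[0, ], motifs, gene_ids = c("g1", "g2"))
  expect_true(all(unlist(empty$by_motif) == 0))

  rogue <- hits
  rogue$motif[1] <- "UNKNOWN"
  expect_error(summarize_elements(rogue, motifs), "undefined motif")
})

test_that("planted motifs are recovered exactly on a disjoint background", {
  # motif letters {A,T}; background {C,G}: no spurious matches possible
  motif <- data.frame(name = "WBOX", iupac = "ATTATA", category = "stress",
                      stringsAsFactors = FALSE)
  spec <- matrix(c(4L, 0L, 2L), 3, 1,
                 dimnames = list(c("g1", "g2", "g3"), "WBOX"))
  sim <- simulate_promoters(spec, motif, length = 500L,
                            background = c("C", "G"), seed = 13L)
  hits <- scan_promoters(sim$promoters, motif)
  counts <- table(factor(hits$gene_id, levels = rownames(spec)))
  expect_equal(unname(as.integer(counts)), c(4L, 0L, 2L))
  # positions and strands match the planted truth
  pl <- sim$truth$placements
  expect_equal(sort(paste(hits$gene_id, hits$start, hits$strand)),
               sort(paste(pl$gene_id, pl$start, pl$strand)))
})
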