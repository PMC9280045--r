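# Codon usage bias: codon counting, relative synonymous codon usage (RSCU),
# relative frequency of synonymous codons (RFSC), the high-frequency rule,
# cross-species bias partition and consensus, per-mille codon frequencies,
# frequency-ratio comparison against reference genomes and expression-host
# ranking.
#
# Codons are reported in RNA form (AUG, GCA, ...) as codon-usage tables are
# conventionally printed; DNA input is converted on counting. Stop codons
# form a TER family of size 3 and participate in all 64-codon statistics.

.to_rna <- function(x) chartr("T", "U", x)
.to_dna <- function(x) chartr("U", "T", x)

#' Synonymous codon families
#'
#' Partition of the 64 codons into synonymous families (one per amino acid,
#' plus the TER family of the three stop codons), each of size k.
#'
#' @return A data frame with columns `amino_acid` (`"TER"` for stops),
#'   `codon` (RNA form) and `k` (family size); 64 rows.
#' @export
synonymous_families <- function() {
  map <- codon_table()$map
  aa <- ifelse(map == "*", "TER", map)
  fam <- data.frame(amino_acid = unname(aa), codon = .to_rna(names(map)),
                    stringsAsFactors = FALSE)
  fam$k <- as.integer(table(fam$amino_acid)[fam$amino_acid])
  fam <- fam[order(fam$amino_acid != "TER", fam$amino_acid, fam$codon), ]
  rownames(fam) <- NULL
  fam
}

#' Count codons across a set of coding sequences
#'
#' Frame-0 triplets are counted over all records. Triplets containing
#' non-ACGT characters are skipped and tallied separately; stop codons are
#' counted (TER family).
#'
#' @param cds_set A `seq_records` (dna) object or character vector of CDS,
#'   each with length divisible by 3.
#' @param label Name for the gene set.
#' @return A `codon_counts` list: `label`, `counts` (named integer vector
#'   over the 64 RNA codons), `n_total`, `n_skipped`.
#' @export
count_codons <- function(cds_set, label = "cds_set") {
  seqs <- if (inherits(cds_set, "seq_records")) cds_set$residues
          else toupper(as.character(cds_set))
  bad <- which(nchar(seqs) %% 3L != 0L)
  if (length(bad))
    stop("record ", bad[1L], " has length not divisible by 3")
  fam <- synonymous_families()
  counts <- stats::setNames(integer(64L), fam$codon)
  n_skipped <- 0L
  if (length(seqs)) {
    codons <- unlist(lapply(seqs, .split_codons), use.names = FALSE)
    ok <- grepl("^[ACGT]{3}$", codons)
    n_skipped <- sum(!ok)
    tab <- table(.to_rna(codons[ok]))
    counts[names(tab)] <- as.integer(tab)
  }
  structure(list(label = label, counts = counts,
                 n_total = sum(counts), n_skipped = n_skipped),
            class = "codon_counts")
}

.classify_bias <- function(rscu, eps = 1e-9) {
  ifelse(is.na(rscu), "undefined",
         ifelse(rscu > 1 + eps, "positive",
                ifelse(rscu < 1 - eps, "negative", "none")))
}

.classify_hf <- function(rfsc, k, hf_percent = 60, hf_mult = 1.5) {
  # high-frequency rule: RFSC strictly above 60%, or at least 1.5x the
  # family-average frequency 100/k; single-codon families not classified
  ifelse(k < 2L | is.na(rfsc), NA,
         rfsc > hf_percent | rfsc >= hf_mult * (100 / k))
}

#' Compute an RSCU/RFSC codon-usage table
#'
#' For codon i in a synonymous family of size k with counts X:
#' RSCU_i = X_i * k / sum(X) and RFSC_i = 100 * X_i / sum(X). A codon has
#' positive bias when RSCU > 1 and negative bias when RSCU < 1 (tolerance
#' `eps` around 1). A codon is high-frequency when RFSC exceeds
#' `hf_percent` (strict) or is at least `hf_mult` times the family-average
#' frequency 100/k; families of size 1 are not classified. Families with
#' zero total are `undefined`/`NA` throughout.
#'
#' @param counts A `codon_counts` object from [count_codons()].
#' @param eps Equality tolerance for the bias classification.
#' @param hf_percent,hf_mult High-frequency rule thresholds.
#' @return A `codon_usage_table` data frame with columns `amino_acid`,
#'   `codon`, `k`, `count`, `rscu`, `rfsc`, `bias`, `high_frequency`.
#' @export
compute_usage <- function(counts, eps = 1e-9, hf_percent = 60,
                          hf_mult = 1.5) {
  stopifnot(inherits(counts, "codon_counts"))
  fam <- synonymous_families()
  x <- counts$counts[fam$codon]
  fam_tot <- stats::ave(x, fam$amino_acid, FUN = sum)
  rscu <- ifelse(fam_tot > 0, x * fam$k / fam_tot, NA_real_)
  rfsc <- ifelse(fam_tot > 0, 100 * x / fam_tot, NA_real_)
  out <- data.frame(amino_acid = fam$amino_acid, codon = fam$codon,
                    k = fam$k, count = as.integer(x),
                    rscu = rscu, rfsc = rfsc,
                    bias = .classify_bias(rscu, eps),
                    high_frequency = .classify_hf(rfsc, fam$k, hf_percent,
                                                  hf_mult),
                    stringsAsFactors = FALSE)
  attr(out, "label") <- counts$label
  class(out) <- c("codon_usage_table", "data.frame")
  out
}

#' Build a codon-usage table from printed RSCU/RFSC values
#'
#' Used to classify transcribed published tables: the given two-decimal
#' values are taken verbatim (no re-rounding) and classified with exact
#' comparisons (`eps = 0`), so a printed RSCU of 1.00 is "none".
#'
#' @param codon Character vector of codons (RNA or DNA form).
#' @param rscu,rfsc Numeric vectors of printed values.
#' @param label Name for the gene set.
#' @return A `codon_usage_table` data frame (counts are `NA`).
#' @export
usage_table_from_values <- function(codon, rscu, rfsc, label = "printed") {
  fam <- synonymous_families()
  codon <- .to_rna(toupper(codon))
  if (!setequal(codon, fam$codon))
    stop("codon set must cover the 64 codons exactly")
  i <- match(fam$codon, codon)
  out <- data.frame(amino_acid = fam$amino_acid, codon = fam$codon,
                    k = fam$k, count = NA_integer_,
                    rscu = rscu[i], rfsc = rfsc[i],
                    bias = .classify_bias(rscu[i], eps = 0),
                    high_frequency = .classify_hf(rfsc[i], fam$k),
                    stringsAsFactors = FALSE)
  attr(out, "label") <- label
  class(out) <- c("codon_usage_table", "data.frame")
  out
}

#' Partition codons by cross-species agreement of bias
#'
#' Over a list of codon-usage tables (one per species), counts the codons
#' whose bias class is "positive" in all tables, "negative" in all tables,
#' "none" in all tables, and the remainder whose class differs between
#' species. The four counts sum to 64.
#'
#' @param tables A list of `codon_usage_table` objects over the same codons.
#' @return Named integer vector `c(positive, negative, none, differing)`.
#' @export
bias_partition <- function(tables) {
  stopifnot(length(tables) >= 1L)
  codons <- tables[[1L]]$codon
  cls <- vapply(tables, function(t) {
    if (!identical(sort(t$codon), sort(codons)))
      stop("tables cover different codon sets")
    t$bias[match(codons, t$codon)]
  }, character(length(codons)))
  cls <- matrix(cls, nrow = length(codons))
  all_eq <- function(lbl) apply(cls, 1L, function(r) all(r == lbl))
  n_pos <- sum(all_eq("positive"))
  n_neg <- sum(all_eq("negative"))
  n_none <- sum(all_eq("none"))
  c(positive = n_pos, negative = n_neg, none = n_none,
    differing = length(codons) - n_pos - n_neg - n_none)
}

#' Consensus high-frequency codons across species
#'
#' @param tables A list of `codon_usage_table` objects.
#' @return Character vector: intersection of per-table high-frequency codon
#'   sets, in family order.
#' @export
consensus_high_frequency <- function(tables) {
  stopifnot(length(tables) >= 1L)
  sets <- lapply(tables, function(t) t$codon[t$high_frequency %in% TRUE])
  out <- Reduce(intersect, sets)
  fam <- synonymous_families()
  out[order(match(out, fam$codon))]
}

#' Per-mille codon frequencies
#'
#' @param counts A `codon_counts` object with `n_total > 0`.
#' @return Named numeric vector over the 64 RNA codons: occurrences per
#'   1,000 codons (sums to 1000).
#' @export
codon_frequency <- function(counts) {
  stopifnot(inherits(counts, "codon_counts"))
  if (counts$n_total == 0L) stop("cannot compute frequencies: no codons")
  1000 * counts$counts / counts$n_total
}

#' Classify a codon-frequency ratio
#'
#' The similarity band is (0.50, 2.00), exclusive; ratios at or beyond
#' either bound are divergent. The band is reciprocal-symmetric: r is
#' divergent iff 1/r is.
#'
#' @param r Numeric vector of ratios (NA allowed).
#' @param lo,hi Band bounds (inclusive divergence at both).
#' @return Character vector: `"divergent"`, `"similar"` or `"undefined"`.
#' @export
classify_ratio <- function(r, lo = 0.5, hi = 2.0) {
  ifelse(is.na(r), "undefined",
         ifelse(r <= lo | r >= hi, "divergent", "similar"))
}

#' Compare codon frequencies of a gene set against a reference genome
#'
#' @param freq_set,freq_ref Named per-mille frequency vectors over the 64
#'   codons (see [codon_frequency()]).
#' @param pair_label Label for the comparison.
#' @param lo,hi Divergence band bounds.
#' @return A `ratio_table` data frame with columns `amino_acid`, `codon`,
#'   `freq_set`, `freq_ref`, `ratio`, `class`. A reference frequency of 0
#'   with a nonzero set frequency is divergent with `ratio = NA`; 0/0 is
#'   undefined.
#' @export
ratio_compare <- function(freq_set, freq_ref, pair_label = "set_vs_ref",
                          lo = 0.5, hi = 2.0) {
  fam <- synonymous_families()
  names(freq_set) <- .to_rna(names(freq_set))
  names(freq_ref) <- .to_rna(names(freq_ref))
  if (!all(fam$codon %in% names(freq_set)) ||
      !all(fam$codon %in% names(freq_ref)))
    stop("frequency maps must cover the 64 codons")
  fs <- freq_set[fam$codon]
  fr <- freq_ref[fam$codon]
  ratio <- ifelse(fr > 0, fs / fr, NA_real_)
  cls <- classify_ratio(ratio, lo, hi)
  cls[fr == 0 & fs > 0] <- "divergent"
  cls[fr == 0 & fs == 0] <- "undefined"
  out <- data.frame(amino_acid = fam$amino_acid, codon = fam$codon,
                    freq_set = unname(fs), freq_ref = unname(fr),
                    ratio = unname(ratio), class = cls,
                    stringsAsFactors = FALSE)
  attr(out, "pair_label") <- pair_label
  class(out) <- c("ratio_table", "data.frame")
  out
}

#' Rank candidate heterologous expression hosts
#'
#' Hosts are ranked by how similar their genome-wide codon usage is to the
#' gene set of interest: ascending number of divergent codons, ties broken
#' by mean |log2 ratio| over defined non-stop codons, then label.
#'
#' @param freq_set Named per-mille frequency vector of the gene set.
#' @param candidate_refs Named list of per-mille frequency vectors, one per
#'   candidate host genome.
#' @param lo,hi Divergence band bounds.
#' @return A data frame `label`, `n_divergent`, `mean_abs_log2_ratio`,
#'   best host first.
#' @export
rank_hosts <- function(freq_set, candidate_refs, lo = 0.5, hi = 2.0) {
  stopifnot(length(candidate_refs) >= 1L, !is.null(names(candidate_refs)))
  rows <- lapply(names(candidate_refs), function(lbl) {
    rt <- ratio_compare(freq_set, candidate_refs[[lbl]], lbl, lo, hi)
    use <- rt$amino_acid != "TER" & !is.na(rt$ratio) & rt$ratio > 0
    data.frame(label = lbl,
               n_divergent = sum(rt$class == "divergent"),
               mean_abs_log2_ratio = mean(abs(log2(rt$ratio[use]))),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$n_divergent, out$mean_abs_log2_ratio, out$label), ]
  rownames(out) <- NULL
  out
}
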