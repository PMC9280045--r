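# Gene-structure statistics from gene models and promoter analysis:
# upstream-region extraction and IUPAC consensus scanning of cis-acting
# elements with stress / hormone / growth categorization.

#' Gene structure statistics
#'
#' @param model A `gene_model`.
#' @param long_gene_bp Span threshold (bp) above which a gene is "long"
#'   (default 3000, i.e. more than 3 kb).
#' @return A one-row data frame: `gene_id`, `n_exons`, `n_introns`,
#'   `has_utr5`, `has_utr3`, `span_bp`, `long_gene`.
#' @export
structure_stats <- function(model, long_gene_bp = 3000) {
  span <- range(c(model$exons, model$utr5, model$utr3))
  span_bp <- span[2] - span[1] + 1
  data.frame(gene_id = model$gene_id,
             n_exons = nrow(model$exons),
             n_introns = nrow(model$exons) - 1L,
             has_utr5 = !is.null(model$utr5),
             has_utr3 = !is.null(model$utr3),
             span_bp = span_bp,
             long_gene = span_bp > long_gene_bp,
             stringsAsFactors = FALSE)
}

#' Gene structure statistics for a set of gene models
#'
#' @param models A list of `gene_model` objects.
#' @param long_gene_bp Span threshold in bp.
#' @return A data frame with one row per gene.
#' @export
structure_stats_table <- function(models, long_gene_bp = 3000) {
  out <- do.call(rbind, lapply(models, structure_stats, long_gene_bp))
  rownames(out) <- NULL
  out
}

#' Extract the promoter region upstream of the start codon
#'
#' The promoter is the strand-corrected region of `length` bp ending
#' immediately before the first CDS base in transcript orientation (the
#' ATG). At a contig edge a shorter region is returned with
#' `truncated = TRUE`; a zero-length promoter is an error.
#'
#' @param genome A `seq_records` (dna) object or named character vector.
#' @param model A `gene_model` with a CDS.
#' @param length Requested promoter length in bp (default 2000).
#' @return A `promoter_region` list: `gene_id`, `sequence` (5'->3' in gene
#'   orientation), `requested_length`, `truncated`.
#' @export
extract_promoter <- function(genome, model, length = 2000L) {
  contigs <- .genome_vector(genome)
  if (!model$seq_id %in% names(contigs))
    stop("contig not found in genome: ", model$seq_id)
  contig <- contigs[[model$seq_id]]
  clen <- nchar(contig)
  if (model$strand == "+") {
    atg <- min(model$cds[, 1])
    if (atg <= 1) stop("zero-length promoter: start codon at contig start")
    from <- max(1L, atg - length)
    seq <- substr(contig, from, atg - 1L)
    truncated <- from > atg - length
  } else {
    cds_end <- max(model$cds[, 2])
    if (cds_end >= clen)
      stop("zero-length promoter: start codon at contig end")
    to <- min(clen, cds_end + length)
    seq <- .revcomp(substr(contig, cds_end + 1L, to))
    truncated <- to < cds_end + length
  }
  structure(list(gene_id = model$gene_id, sequence = seq,
                 requested_length = as.integer(length),
                 truncated = truncated),
            class = "promoter_region")
}

.iupac_ok <- function(x) grepl("^[ACGTRYSWKMBDHVN]+$", toupper(x))

#' Demonstration cis-element motif table
#'
#' A small documented motif table for tests and examples. The consensus
#' strings are simplified versions of commonly cited plant promoter
#' elements; a production scan should supply a curated motif table (e.g.
#' derived from a PlantCARE export), which is user input.
#'
#' @return A data frame `name`, `iupac`, `category`.
#' @export
demo_motifs <- function() {
  data.frame(
    name = c("ARE", "MYC", "MYB", "LTR", "ABRE", "G-box", "GT1"),
    iupac = c("AAACCA", "CANNTG", "CNGTTR", "CCGAAA", "ACGTGGC", "CACGTG",
              "GAAAAA"),
    category = c("stress", "stress", "stress", "stress", "hormone",
                 "growth", "growth"),
    stringsAsFactors = FALSE)
}

#' Scan a promoter for IUPAC consensus motifs
#'
#' All matches of each degenerate consensus are reported on both strands;
#' overlapping matches are all kept. Hits are ordered by (start, strand,
#' name) with "+" before "-". Positions are 1-based on the promoter
#' fragment, 5'->3' in gene orientation.
#'
#' @param promoter A `promoter_region` or a single promoter sequence.
#' @param motifs A data frame with columns `name`, `iupac`, `category`.
#' @param gene_id Gene id used when `promoter` is a bare sequence.
#' @return A data frame `gene_id`, `motif`, `category`, `start`, `strand`,
#'   `match` (the promoter bases as written on the plus strand of the
#'   fragment).
#' @export
scan_motifs <- function(promoter, motifs, gene_id = "promoter") {
  if (inherits(promoter, "promoter_region")) {
    gene_id <- promoter$gene_id
    seq <- promoter$sequence
  } else seq <- toupper(as.character(promoter))
  stopifnot(all(c("name", "iupac", "category") %in% names(motifs)))
  bad <- !.iupac_ok(motifs$iupac)
  if (any(bad))
    stop("invalid IUPAC consensus for motif ", motifs$name[bad][1L])
  subject <- Biostrings::DNAString(seq)
  rows <- list()
  for (i in seq_len(nrow(motifs))) {
    pat <- Biostrings::DNAString(toupper(motifs$iupac[i]))
    if (length(pat) > nchar(seq)) next
    for (strand in c("+", "-")) {
      p <- if (strand == "+") pat else Biostrings::reverseComplement(pat)
      hits <- Biostrings::matchPattern(p, subject, fixed = FALSE)
      if (length(hits) == 0L) next
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = gene_id, motif = motifs$name[i],
        category = motifs$category[i],
        start = Biostrings::start(hits), strand = strand,
        match = as.character(hits), stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(gene_id = character(), motif = character(),
                      category = character(), start = integer(),
                      strand = character(), match = character(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out <- out[order(out$start, out$strand, out$motif), ]
  rownames(out) <- NULL
  out
}

#' Scan a set of promoters
#'
#' @param promoters A list of `promoter_region` objects or a named
#'   character vector of promoter sequences.
#' @param motifs A motif table (see [scan_motifs()]).
#' @return A data frame of hits across all promoters.
#' @export
scan_promoters <- function(promoters, motifs) {
  if (is.character(promoters)) {
    ids <- names(promoters)
    hits <- lapply(seq_along(promoters), function(i)
      scan_motifs(promoters[[i]], motifs, gene_id = ids[i]))
  } else {
    hits <- lapply(promoters, scan_motifs, motifs = motifs)
  }
  out <- do.call(rbind, hits)
  rownames(out) <- NULL
  out
}

#' Summarize element hits per gene and category
#'
#' @param hits A hit data frame from [scan_motifs()]/[scan_promoters()].
#' @param motifs The motif table used for the scan.
#' @param gene_ids Genes to include (zero rows kept); defaults to the genes
#'   present in `hits`.
#' @return A list: `by_motif` (gene x motif counts), `by_category` (gene x
#'   category counts), `category_totals`.
#' @export
summarize_elements <- function(hits, motifs, gene_ids = NULL) {
  if (is.null(gene_ids)) gene_ids <- unique(hits$gene_id)
  unknown <- setdiff(unique(hits$motif), motifs$name)
  if (length(unknown)) stop("hits reference undefined motif: ", unknown[1L])
  cats <- unique(motifs$category)
  gm <- table(factor(hits$gene_id, levels = gene_ids),
              factor(hits$motif, levels = motifs$name))
  gc <- table(factor(hits$gene_id, levels = gene_ids),
              factor(motifs$category[match(hits$motif, motifs$name)],
                     levels = cats))
  by_motif <- as.data.frame.matrix(gm)
  by_category <- as.data.frame.matrix(gc)
  list(by_motif = by_motif, by_category = by_category,
       category_totals = colSums(by_category))
}
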