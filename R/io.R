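# Sequence and annotation I/O: FASTA, GFF3, the standard genetic code,
# CDS extraction and translation. Every other module consumes these types.

.alphabets <- list(
  dna               = c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
                        "B", "D", "H", "V", "N"),
  protein           = c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "X", "*"),
  `dna-aligned`     = c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
                        "B", "D", "H", "V", "N", "-"),
  `protein-aligned` = c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "X", "*", "-")
)

#' Build a set of sequence records
#'
#' A `seq_records` object is a data frame with columns `id`, `description`
#' and `residues`, plus an `alphabet` attribute. It is the in-memory form of
#' a FASTA file used throughout the package.
#'
#' @param id Character vector of unique, non-empty record ids.
#' @param residues Character vector of sequences (uppercased on input).
#' @param description Optional character vector of descriptions (the FASTA
#'   header text after the first whitespace).
#' @param alphabet One of `"dna"`, `"protein"`, `"dna-aligned"`,
#'   `"protein-aligned"`.
#' @return A `seq_records` data frame.
#' @export
seq_records <- function(id, residues,
                        description = rep("", length(id)),
                        alphabet = c("dna", "protein", "dna-aligned",
                                     "protein-aligned")) {
  alphabet <- match.arg(alphabet)
  if (length(id) != length(residues))
    stop("'id' and 'residues' must have equal length")
  id <- as.character(id)
  residues <- toupper(as.character(residues))
  if (any(!nzchar(id)) || anyNA(id)) stop("record ids must be non-empty")
  if (anyDuplicated(id)) {
    stop("duplicate record id: ", id[duplicated(id)][1L])
  }
  if (length(id) && any(!nzchar(residues)))
    stop("empty sequence in record: ", id[!nzchar(residues)][1L])
  allowed <- .alphabets[[alphabet]]
  for (i in seq_along(id)) {
    chars <- unique(strsplit(residues[i], "")[[1]])
    bad <- setdiff(chars, allowed)
    if (length(bad))
      stop(sprintf("record '%s' contains character '%s' outside alphabet '%s'",
                   id[i], bad[1L], alphabet))
  }
  if (grepl("aligned", alphabet) && length(id) > 1L &&
      length(unique(nchar(residues))) != 1L)
    stop("aligned records must share equal length")
  out <- data.frame(id = id, description = as.character(description),
                    residues = residues, stringsAsFactors = FALSE)
  attr(out, "alphabet") <- alphabet
  class(out) <- c("seq_records", "data.frame")
  out
}

#' Read a FASTA file
#'
#' Wrapping lines and CRLF endings are handled; residues are uppercased and
#' validated against the declared alphabet. Duplicate ids or characters
#' outside the alphabet are errors.
#'
#' @param path Path to a FASTA file.
#' @param alphabet Declared alphabet of the file (see [seq_records()]).
#' @return A `seq_records` data frame, in file order.
#' @export
read_fasta <- function(path, alphabet = c("dna", "protein", "dna-aligned",
                                          "protein-aligned")) {
  alphabet <- match.arg(alphabet)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) {
    return(seq_records(character(), character(), character(), alphabet))
  }
  headers <- names(set)
  id <- sub("\\s.*$", "", headers)
  description <- ifelse(grepl("\\s", headers),
                        sub("^\\S+\\s+", "", headers), "")
  seq_records(id, as.character(set), description, alphabet)
}

#' Write sequence records to FASTA
#'
#' @param records A `seq_records` data frame.
#' @param path Output file path.
#' @param width Line-wrap width (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60L) {
  con <- file(path, "wb")  # LF endings regardless of platform
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    header <- if (nzchar(records$description[i]))
      paste(records$id[i], records$description[i]) else records$id[i]
    s <- records$residues[i]
    chunks <- substring(s, seq(1L, nchar(s), width),
                        pmin(seq(1L, nchar(s), width) + width - 1L, nchar(s)))
    writeLines(c(paste0(">", header), chunks), con, sep = "\n")
  }
  invisible(path)
}

#' The standard genetic code
#'
#' @return A list with `code_id`, `map` (named character vector over the 64
#'   DNA codons; stop codons map to `"*"`) and `stop_codons`.
#' @export
codon_table <- function() {
  map <- Biostrings::GENETIC_CODE
  list(code_id = "standard", map = map,
       stop_codons = names(map)[map == "*"])
}

.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Construct a gene model
#'
#' Coordinates are GFF3-native: 1-based, inclusive, sorted ascending by
#' genomic start regardless of strand.
#'
#' @param gene_id,seq_id Identifiers of the gene and its contig.
#' @param strand `"+"` or `"-"`.
#' @param exons Two-column matrix (start, end) of exon coordinates.
#' @param cds Three-column matrix (start, end, phase) of CDS segments.
#' @param utr5,utr3 Optional two-column matrices of UTR coordinates.
#' @return A `gene_model` list.
#' @export
gene_model <- function(gene_id, seq_id, strand, exons, cds,
                       utr5 = NULL, utr3 = NULL) {
  stopifnot(strand %in% c("+", "-"))
  exons <- matrix(as.numeric(exons), ncol = 2L,
                  dimnames = list(NULL, c("start", "end")))
  cds <- matrix(as.numeric(cds), ncol = 3L,
                dimnames = list(NULL, c("start", "end", "phase")))
  for (m in list(exons, cds[, 1:2, drop = FALSE])) {
    if (any(m[, 2] < m[, 1])) stop("feature with end < start in ", gene_id)
  }
  exons <- exons[order(exons[, 1]), , drop = FALSE]
  cds <- cds[order(cds[, 1]), , drop = FALSE]
  if (nrow(exons) > 1L && any(exons[-1L, 1] <= exons[-nrow(exons), 2]))
    stop("overlapping exons in ", gene_id)
  if (sum(cds[, 2] - cds[, 1] + 1) <= 0) stop("gene without CDS: ", gene_id)
  # every CDS segment must lie within some exon
  inside <- vapply(seq_len(nrow(cds)), function(i) {
    any(exons[, 1] <= cds[i, 1] & cds[i, 2] <= exons[, 2])
  }, logical(1L))
  if (!all(inside)) stop("CDS outside exon span in ", gene_id)
  norm_utr <- function(u) {
    if (is.null(u) || length(u) == 0L) return(NULL)
    u <- matrix(as.numeric(u), ncol = 2L,
                dimnames = list(NULL, c("start", "end")))
    u[order(u[, 1]), , drop = FALSE]
  }
  structure(list(gene_id = gene_id, seq_id = seq_id, strand = strand,
                 exons = exons, cds = cds,
                 utr5 = norm_utr(utr5), utr3 = norm_utr(utr3)),
            class = "gene_model")
}

#' Read gene models from a GFF3 file
#'
#' Assumes one mRNA per gene; when a gene has several, the first in file
#' order is used and a message is emitted. Parsing is delegated to
#' [rtracklayer::readGFF()].
#'
#' @param path Path to a GFF3 file.
#' @return A named list of `gene_model` objects, in file order.
#' @export
read_gff3 <- function(path) {
  gff <- as.data.frame(rtracklayer::readGFF(path))
  gff$Parent <- vapply(gff$Parent, function(p)
    if (length(p)) as.character(p)[1L] else NA_character_, character(1L))
  if (any(gff$end < gff$start)) {
    bad <- which(gff$end < gff$start)[1L]
    stop("feature with end < start at line for ", gff$type[bad])
  }
  genes <- gff[gff$type == "gene", , drop = FALSE]
  mrnas <- gff[gff$type == "mRNA", , drop = FALSE]
  utr5_types <- c("five_prime_UTR", "5UTR")
  utr3_types <- c("three_prime_UTR", "3UTR")
  out <- list()
  for (i in seq_len(nrow(genes))) {
    gid <- genes$ID[i]
    gm <- mrnas[!is.na(mrnas$Parent) & mrnas$Parent == gid, , drop = FALSE]
    if (nrow(gm) == 0L) stop("gene without mRNA: ", gid)
    if (nrow(gm) > 1L)
      message("gene ", gid, " has ", nrow(gm), " mRNAs; using the first")
    mid <- gm$ID[1L]
    sub <- gff[!is.na(gff$Parent) & gff$Parent == mid, , drop = FALSE]
    ex <- sub[sub$type == "exon", c("start", "end"), drop = FALSE]
    cd <- sub[sub$type == "CDS", , drop = FALSE]
    if (nrow(cd) == 0L) stop("mRNA without CDS: ", mid)
    phase <- suppressWarnings(as.integer(as.character(cd$phase)))
    phase[is.na(phase)] <- 0L
    u5 <- sub[sub$type %in% utr5_types, c("start", "end"), drop = FALSE]
    u3 <- sub[sub$type %in% utr3_types, c("start", "end"), drop = FALSE]
    out[[gid]] <- gene_model(
      gene_id = gid, seq_id = as.character(genes$seqid[i]),
      strand = as.character(genes$strand[i]),
      exons = as.matrix(ex),
      cds = cbind(as.matrix(cd[, c("start", "end")]), phase),
      utr5 = if (nrow(u5)) as.matrix(u5) else NULL,
      utr3 = if (nrow(u3)) as.matrix(u3) else NULL)
  }
  out
}

#' Write gene models to a GFF3 file
#'
#' @param models A list of `gene_model` objects.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(models, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (m in models) {
    span <- range(c(m$exons, m$utr5, m$utr3))
    line <- function(type, start, end, phase, attrs) {
      paste(m$seq_id, "woxkit", type, start, end, ".", m$strand,
            phase, attrs, sep = "\t")
    }
    gid <- m$gene_id
    mid <- paste0(gid, ".t1")
    writeLines(line("gene", span[1], span[2], ".", paste0("ID=", gid)), con)
    writeLines(line("mRNA", span[1], span[2], ".",
                    paste0("ID=", mid, ";Parent=", gid)), con)
    for (i in seq_len(nrow(m$exons)))
      writeLines(line("exon", m$exons[i, 1], m$exons[i, 2], ".",
                      paste0("ID=", mid, ".exon", i, ";Parent=", mid)), con)
    for (i in seq_len(nrow(m$cds)))
      writeLines(line("CDS", m$cds[i, 1], m$cds[i, 2], m$cds[i, 3],
                      paste0("ID=", mid, ".cds;Parent=", mid)), con)
    if (!is.null(m$utr5)) for (i in seq_len(nrow(m$utr5)))
      writeLines(line("five_prime_UTR", m$utr5[i, 1], m$utr5[i, 2], ".",
                      paste0("Parent=", mid)), con)
    if (!is.null(m$utr3)) for (i in seq_len(nrow(m$utr3)))
      writeLines(line("three_prime_UTR", m$utr3[i, 1], m$utr3[i, 2], ".",
                      paste0("Parent=", mid)), con)
  }
  invisible(path)
}

.genome_vector <- function(genome) {
  if (inherits(genome, "seq_records")) {
    stats::setNames(genome$residues, genome$id)
  } else if (is.character(genome)) {
    if (is.null(names(genome))) stop("genome must be named by contig id")
    toupper(genome)
  } else stop("genome must be seq_records or a named character vector")
}

#' Extract the coding sequence of a gene model
#'
#' CDS segments are concatenated in genomic order and the concatenation is
#' reverse-complemented once for minus-strand genes, giving the CDS in
#' transcript orientation.
#'
#' @param genome A `seq_records` object (dna) or named character vector of
#'   contig sequences.
#' @param model A `gene_model`.
#' @return A one-record `seq_records` (dna) named after the gene.
#' @export
extract_cds <- function(genome, model) {
  contigs <- .genome_vector(genome)
  if (!model$seq_id %in% names(contigs))
    stop("contig not found in genome: ", model$seq_id)
  contig <- contigs[[model$seq_id]]
  if (any(model$cds[, 2] > nchar(contig)))
    stop("CDS segment beyond contig end in ", model$gene_id)
  parts <- vapply(seq_len(nrow(model$cds)), function(i)
    substr(contig, model$cds[i, 1], model$cds[i, 2]), character(1L))
  cds <- paste(parts, collapse = "")
  if (model$strand == "-") cds <- .revcomp(cds)
  if (nchar(cds) %% 3L != 0L)
    stop("CDS length not divisible by 3 in ", model$gene_id,
         " (", nchar(cds), " nt)")
  seq_records(model$gene_id, cds, alphabet = "dna")
}

.split_codons <- function(x) {
  n <- nchar(x) %/% 3L
  substring(x, 3L * seq_len(n) - 2L, 3L * seq_len(n))
}

#' Translate a coding sequence
#'
#' One residue per codon; codons containing non-ACGT characters translate to
#' `"X"`; a single trailing stop codon is dropped (recorded in the
#' `"stop_removed"` attribute); an internal stop codon is an error.
#'
#' @param cds A `seq_records` (dna) record, a single character string, or a
#'   multi-record `seq_records` (translated record-wise).
#' @param table A codon table from [codon_table()].
#' @return A `seq_records` (protein) object.
#' @export
translate <- function(cds, table = codon_table()) {
  if (inherits(cds, "seq_records")) {
    ids <- cds$id
    seqs <- cds$residues
  } else {
    seqs <- toupper(as.character(cds))
    ids <- if (!is.null(names(seqs))) names(seqs) else
      paste0("seq", seq_along(seqs))
  }
  stops_removed <- logical(length(seqs))
  prot <- character(length(seqs))
  for (j in seq_along(seqs)) {
    s <- seqs[j]
    if (nchar(s) %% 3L != 0L)
      stop("sequence length not divisible by 3 in ", ids[j])
    codons <- .split_codons(s)
    aa <- ifelse(codons %in% names(table$map), unname(table$map[codons]), "X")
    aa[!grepl("^[ACGT]{3}$", codons)] <- "X"
    n <- length(aa)
    if (n && aa[n] == "*") {
      aa <- aa[-n]
      stops_removed[j] <- TRUE
    }
    internal <- which(aa == "*")
    if (length(internal))
      stop(sprintf("internal stop codon at codon %d in %s",
                   internal[1L], ids[j]))
    prot[j] <- paste(aa, collapse = "")
  }
  out <- seq_records(ids, prot, alphabet = "protein")
  attr(out, "stop_removed") <- stops_removed
  out
}
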