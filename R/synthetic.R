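# Seeded synthetic-data generators. Each generator is a pure function of
# (parameters, seed) and returns the generated inputs together with a
# machine-readable truth object, so every downstream stage can be tested
# with no external data. Generators accept their own seed; expand_seed()
# derives disjoint per-generator substreams from one pipeline seed.

#' Derive a per-generator substream seed from a global seed
#'
#' Fixed offsets per generator keep substreams disjoint, so adding a new
#' generator never perturbs existing datasets.
#'
#' @param seed Global integer seed.
#' @param stream One of the generator names.
#' @return An integer seed below 2^31.
#' @export
expand_seed <- function(seed, stream = c("cds", "alignment", "annotation",
                                         "promoters", "qpcr")) {
  stream <- match.arg(stream)
  offset <- match(stream, c("cds", "alignment", "annotation", "promoters",
                            "qpcr"))
  as.integer((as.numeric(seed) * 48271 + offset * 2654435) %% 2147483647)
}

.sense_fams <- function() {
  fam <- synonymous_families()
  split(.to_dna(fam$codon), fam$amino_acid)
}

#' Simulate CDS sets with controlled synonymous-codon bias
#'
#' Each gene is ATG + iid codons drawn within the synonymous family of a
#' random amino-acid sequence + one stop codon, so there are no internal
#' stops by construction. Per-family codon probabilities are either given
#' or drawn from a symmetric Dirichlet.
#'
#' @param n_genes Number of genes.
#' @param len_codons Codons per gene including start and stop (>= 3).
#' @param family_probs Named list: family (one-letter amino acid or "TER")
#'   -> named probability vector over its codons (DNA form, sums to 1).
#' @param dirichlet_alpha Symmetric Dirichlet concentration used to draw
#'   `family_probs` when not given (default 1).
#' @param seed Integer seed.
#' @return A list `records` (`seq_records`, dna) and `truth` (generator
#'   name, seed, parameters, per-family codon probabilities).
#' @export
simulate_cds_set <- function(n_genes = 10L, len_codons = 300L,
                             family_probs = NULL, dirichlet_alpha = 1,
                             seed = 1L) {
  stopifnot(len_codons >= 3L)
  set.seed(seed)
  fams <- .sense_fams()
  if (is.null(family_probs)) {
    family_probs <- lapply(fams, function(codons) {
      g <- stats::rgamma(length(codons), shape = dirichlet_alpha)
      stats::setNames(g / sum(g), codons)
    })
  }
  for (aa in names(fams)) {
    p <- family_probs[[aa]]
    if (is.null(p) || !setequal(names(p), fams[[aa]]) ||
        any(p < 0) || abs(sum(p) - 1) > 1e-8)
      stop("invalid probability vector for family ", aa)
  }
  aas <- setdiff(names(fams), "TER")
  residues <- vapply(seq_len(n_genes), function(g) {
    aa_seq <- sample(aas, len_codons - 2L, replace = TRUE)
    codons <- vapply(aa_seq, function(aa) {
      p <- family_probs[[aa]]
      sample(names(p), 1L, prob = p)
    }, character(1L))
    stopc <- sample(names(family_probs$TER), 1L, prob = family_probs$TER)
    paste(c("ATG", codons, stopc), collapse = "")
  }, character(1L))
  ids <- sprintf("gene_%03d", seq_len(n_genes))
  list(records = seq_records(ids, residues, alphabet = "dna"),
       truth = list(generator = "cds", seed = seed,
                    params = list(n_genes = n_genes,
                                  len_codons = len_codons),
                    family_probs = family_probs))
}

#' Simulate a protein alignment on a tree
#'
#' The root sequence is uniform over the 20 residues; along each branch,
#' Poisson(rate * branch length * n_columns) substitutions hit uniformly
#' chosen columns and are replaced uniformly by one of the 19 other
#' residues. A uniform replacement model, not an empirical matrix:
#' sufficient for testing distance and topology recovery, not biological.
#'
#' @param tree A `phylo` tree with branch lengths, or a Newick string.
#' @param n_columns Alignment length.
#' @param subs_rate Expected substitutions per site per unit branch length.
#' @param seed Integer seed.
#' @return A list `records` (`seq_records`, protein-aligned) and `truth`
#'   (the tree in Newick).
#' @export
simulate_alignment_on_tree <- function(tree, n_columns = 500L,
                                       subs_rate = 0.1, seed = 1L) {
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  stopifnot(inherits(tree, "phylo"), !is.null(tree$edge.length))
  set.seed(seed)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  seqs <- vector("list", n_tip + tree$Nnode)
  seqs[[root]] <- sample(aa, n_columns, replace = TRUE)
  # preorder edge traversal so parents are simulated before children
  edges <- ape::reorder.phylo(tree, "cladewise")$edge
  lens <- ape::reorder.phylo(tree, "cladewise")$edge.length
  for (e in seq_len(nrow(edges))) {
    parent <- edges[e, 1L]; child <- edges[e, 2L]
    s <- seqs[[parent]]
    nsub <- stats::rpois(1L, subs_rate * lens[e] * n_columns)
    if (nsub > 0L) {
      pos <- sample.int(n_columns, nsub, replace = TRUE)
      for (p in pos) s[p] <- sample(setdiff(aa, s[p]), 1L)
    }
    seqs[[child]] <- s
  }
  residues <- vapply(seq_len(n_tip), function(i)
    paste(seqs[[i]], collapse = ""), character(1L))
  list(records = seq_records(tree$tip.label, residues,
                             alphabet = "protein-aligned"),
       truth = list(generator = "alignment", seed = seed,
                    params = list(n_columns = n_columns,
                                  subs_rate = subs_rate),
                    tree = ape::write.tree(tree)))
}

.random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                        replace = TRUE), collapse = "")

.random_cds <- function(n_codons) {
  tab <- codon_table()
  sense <- setdiff(names(tab$map), c(tab$stop_codons, "ATG"))
  paste(c("ATG", sample(sense, n_codons - 2L, replace = TRUE),
          sample(tab$stop_codons, 1L)), collapse = "")
}

#' Simulate a toy genome with multi-exon gene models
#'
#' Non-overlapping genes on one contig with alternating strands, 2-4 exons
#' by default, UTRs on the terminal exons and intron lengths drawn wide
#' enough that a fraction of gene spans exceeds 3 kb. The stored truth
#' contains the exact CDS of every gene (transcript orientation) and the
#' coordinates, so extraction can be checked to the base.
#'
#' @param n_genes Number of genes.
#' @param exon_count_range Inclusive range of exon counts, within [1, 10].
#' @param seed Integer seed.
#' @param contig_len Total contig length; an error if too short.
#' @return A list `genome` (`seq_records`, one contig), `models` (list of
#'   `gene_model`), and `truth`.
#' @export
simulate_annotation_bundle <- function(n_genes = 6L,
                                       exon_count_range = c(2L, 4L),
                                       seed = 1L, contig_len = 60000L) {
  stopifnot(exon_count_range[1] >= 1L, exon_count_range[2] <= 10L)
  set.seed(seed)
  models <- list()
  truth_genes <- list()
  pieces <- character()
  cursor <- 1L
  add_piece <- function(s) pieces[[length(pieces) + 1L]] <<- s
  for (g in seq_len(n_genes)) {
    gid <- sprintf("gene%02d", g)
    strand <- if (g %% 2L == 1L) "+" else "-"
    gap <- sample(300:2500, 1L)
    add_piece(.random_dna(gap))
    cursor <- cursor + gap
    n_ex <- sample(seq(exon_count_range[1], exon_count_range[2]), 1L)
    cds <- .random_cds(sample(80:150, 1L))
    cds_len <- nchar(cds)
    # split CDS into n_ex chunks of >= 3 nt
    if (n_ex > 1L) {
      cuts <- sort(sample(seq(3L, cds_len - 3L, by = 3L), n_ex - 1L))
      chunk_len <- diff(c(0L, cuts, cds_len))
    } else chunk_len <- cds_len
    utr5_len <- sample(50:200, 1L)
    utr3_len <- sample(50:200, 1L)
    intron_len <- if (n_ex > 1L) sample(60:1500, n_ex - 1L,
                                        replace = TRUE) else integer()
    # transcript-orientation layout within the gene region
    feats <- list()   # local (start, end) in transcript orientation
    pos <- 1L
    region <- character()
    push <- function(type, seq) {
      feats[[length(feats) + 1L]] <<- list(type = type, start = pos,
                                           end = pos + nchar(seq) - 1L)
      region[[length(region) + 1L]] <<- seq
      pos <<- pos + nchar(seq)
    }
    push("utr5", .random_dna(utr5_len))
    off <- 0L
    for (e in seq_len(n_ex)) {
      push("cds", substr(cds, off + 1L, off + chunk_len[e]))
      off <- off + chunk_len[e]
      if (e < n_ex) push("intron", .random_dna(intron_len[e]))
    }
    push("utr3", .random_dna(utr3_len))
    region_seq <- paste(unlist(region), collapse = "")
    lr <- nchar(region_seq)
    plus_seq <- if (strand == "+") region_seq else .revcomp(region_seq)
    to_plus <- function(st, en) {
      if (strand == "+") c(st, en) else c(lr - en + 1L, lr - st + 1L)
    }
    gstart <- cursor
    loc <- lapply(feats, function(f)
      gstart - 1L + to_plus(f$start, f$end))
    types <- vapply(feats, `[[`, character(1L), "type")
    cds_idx <- which(types == "cds")
    # phase per CDS segment, in transcript order
    cum <- c(0L, cumsum(chunk_len))[seq_len(n_ex)]
    phase_tx <- (3L - cum %% 3L) %% 3L
    cds_mat <- do.call(rbind, lapply(seq_along(cds_idx), function(i)
      c(loc[[cds_idx[i]]], phase_tx[i])))
    utr5_mat <- do.call(rbind, loc[types == "utr5"])
    utr3_mat <- do.call(rbind, loc[types == "utr3"])
    # exons = CDS chunks extended by flanking UTR on the terminal exons
    exon_tx <- list()
    for (i in seq_along(cds_idx)) {
      f <- feats[[cds_idx[i]]]
      st <- f$start; en <- f$end
      if (i == 1L) st <- 1L                       # absorb 5' UTR
      if (i == length(cds_idx)) en <- lr          # absorb 3' UTR
      exon_tx[[i]] <- c(st, en)
    }
    exon_mat <- do.call(rbind, lapply(exon_tx, function(x)
      gstart - 1L + to_plus(x[1], x[2])))
    models[[gid]] <- gene_model(gid, "contig_1", strand,
                                exons = exon_mat, cds = cds_mat,
                                utr5 = utr5_mat, utr3 = utr3_mat)
    truth_genes[[gid]] <- list(strand = strand, n_exons = n_ex,
                               span_bp = lr, cds = cds,
                               start = gstart, end = gstart + lr - 1L)
    add_piece(plus_seq)
    cursor <- cursor + lr
  }
  tail_len <- contig_len - (cursor - 1L)
  if (tail_len < 0L) stop("contig too short for requested genes")
  if (tail_len > 0L) add_piece(.random_dna(tail_len))
  genome <- seq_records("contig_1", paste(pieces, collapse = ""),
                        alphabet = "dna")
  list(genome = genome, models = models,
       truth = list(generator = "annotation", seed = seed,
                    params = list(n_genes = n_genes,
                                  exon_count_range = exon_count_range),
                    genes = truth_genes))
}

.instantiate_iupac <- function(iupac) {
  codes <- list(A = "A", C = "C", G = "G", T = "T", R = c("A", "G"),
                Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
                K = c("G", "T"), M = c("A", "C"), B = c("C", "G", "T"),
                D = c("A", "G", "T"), H = c("A", "C", "T"),
                V = c("A", "C", "G"), N = c("A", "C", "G", "T"))
  paste(vapply(strsplit(toupper(iupac), "")[[1]], function(ch) {
    opts <- codes[[ch]]
    if (length(opts) == 1L) opts else sample(opts, 1L)
  }, character(1L)), collapse = "")
}

#' Simulate promoters with planted cis-element motifs
#'
#' Motif instances (degenerate positions instantiated at random) are
#' planted at random non-overlapping positions and strands on an iid
#' background; the truth table records the planted count per gene and
#' motif. With a background alphabet disjoint from the motif letters, a
#' scan recovers the planted counts exactly.
#'
#' @param plant_spec Integer matrix or data frame: genes (rows, named) x
#'   motifs (columns, named by motif name), planted counts.
#' @param motifs Motif table with `name`, `iupac`, `category`.
#' @param length Promoter length (default 2000).
#' @param background Characters for the background (default A/C/G/T).
#' @param seed Integer seed.
#' @return A list `promoters` (named character vector), `truth` (planted
#'   counts and placements).
#' @export
simulate_promoters <- function(plant_spec, motifs, length = 2000L,
                               background = c("A", "C", "G", "T"),
                               seed = 1L) {
  set.seed(seed)
  plant_spec <- as.matrix(plant_spec)
  stopifnot(!is.null(rownames(plant_spec)), !is.null(colnames(plant_spec)))
  if (any(!colnames(plant_spec) %in% motifs$name))
    stop("plant_spec names a motif not in the motif table")
  promoters <- character(nrow(plant_spec))
  names(promoters) <- rownames(plant_spec)
  placements <- list()
  for (g in rownames(plant_spec)) {
    chars <- sample(background, length, replace = TRUE)
    occupied <- logical(length)
    for (mn in colnames(plant_spec)) {
      iupac <- motifs$iupac[motifs$name == mn]
      w <- nchar(iupac)
      for (rep in seq_len(plant_spec[g, mn])) {
        placed <- FALSE
        for (try in seq_len(2000L)) {
          st <- sample.int(length - w + 1L, 1L)
          if (any(occupied[st:(st + w - 1L)])) next
          inst <- .instantiate_iupac(iupac)
          strand <- sample(c("+", "-"), 1L)
          ins <- if (strand == "+") inst else .revcomp(inst)
          chars[st:(st + w - 1L)] <- strsplit(ins, "")[[1]]
          occupied[st:(st + w - 1L)] <- TRUE
          placements[[length(placements) + 1L]] <- data.frame(
            gene_id = g, motif = mn, start = st, strand = strand,
            stringsAsFactors = FALSE)
          placed <- TRUE
          break
        }
        if (!placed) stop("infeasible motif packing for gene ", g)
      }
    }
    promoters[[g]] <- paste(chars, collapse = "")
  }
  list(promoters = promoters,
       truth = list(generator = "promoters", seed = seed,
                    counts = plant_spec,
                    placements = do.call(rbind, placements)))
}

#' Simulate a qPCR Ct table with known fold changes
#'
#' Target Ct = ref_ct + baseline_delta - log2(true fold) + N(0, noise_sd);
#' both reference genes sit at ref_ct + N(0, noise_sd). True folds are
#' relative to the calibrator sample, whose column must be 1.
#'
#' @param true_folds Numeric matrix genes x samples (dimnames required),
#'   all > 0, calibrator column all 1.
#' @param calibrator Calibrator sample id (default: first column).
#' @param ref_ct Reference-gene Ct level (default 20).
#' @param noise_sd Gaussian Ct noise sd (>= 0).
#' @param replicates Replicates per (gene, sample) (default 3).
#' @param references Ids for the two simulated reference genes.
#' @param baseline_delta Baseline target-minus-reference Ct offset.
#' @param seed Integer seed.
#' @return A list `ct` (data frame `gene_id`, `sample_id`, `replicate`,
#'   `ct`) and `truth`.
#' @export
simulate_ct_table <- function(true_folds,
                              calibrator = colnames(true_folds)[1L],
                              ref_ct = 20, noise_sd = 0.05,
                              replicates = 3L,
                              references = c("RefG1", "RefG2"),
                              baseline_delta = 2, seed = 1L) {
  true_folds <- as.matrix(true_folds)
  stopifnot(!is.null(rownames(true_folds)), !is.null(colnames(true_folds)),
            all(true_folds > 0), noise_sd >= 0)
  if (any(abs(true_folds[, calibrator] - 1) > 1e-12))
    stop("true folds must be 1 in the calibrator sample")
  set.seed(seed)
  rows <- list()
  for (s in colnames(true_folds)) {
    for (g in rownames(true_folds)) {
      mu <- ref_ct + baseline_delta - log2(true_folds[g, s])
      for (r in seq_len(replicates))
        rows[[length(rows) + 1L]] <- data.frame(
          gene_id = g, sample_id = s, replicate = r,
          ct = mu + stats::rnorm(1L, 0, noise_sd),
          stringsAsFactors = FALSE)
    }
    for (g in references) for (r in seq_len(replicates))
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = g, sample_id = s, replicate = r,
        ct = ref_ct + stats::rnorm(1L, 0, noise_sd),
        stringsAsFactors = FALSE)
  }
  list(ct = do.call(rbind, rows),
       truth = list(generator = "qpcr", seed = seed,
                    folds = true_folds, calibrator = calibrator,
                    references = references, noise_sd = noise_sd,
                    replicates = replicates))
}
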