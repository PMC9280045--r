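# Distance-based phylogeny: pairwise distances on protein alignments,
# Saitou-Nei neighbor joining with deterministic tie-breaking, bootstrap
# supports on leaf bipartitions, and anchor-based clade assignment.

.aln_matrix <- function(alignment) {
  if (inherits(alignment, "seq_records")) {
    labels <- alignment$id
    seqs <- alignment$residues
  } else if (is.matrix(alignment)) {
    return(alignment)
  } else stop("alignment must be seq_records or a character matrix")
  if (length(unique(nchar(seqs))) != 1L)
    stop("alignment records must share equal length")
  m <- do.call(rbind, strsplit(seqs, ""))
  rownames(m) <- labels
  m
}

#' Pairwise distances on a protein alignment
#'
#' Pairwise gap deletion: for each pair, only columns where neither
#' sequence has a gap ("-") are compared. `p` is the proportion of
#' mismatching compared columns; `poisson` applies d = -ln(1 - p).
#'
#' @param alignment A `seq_records` (protein-aligned) object or character
#'   matrix (rows = taxa).
#' @param model `"p"` (default) or `"poisson"`.
#' @return A symmetric distance matrix with taxon labels.
#' @export
pairwise_distance <- function(alignment, model = c("p", "poisson")) {
  model <- match.arg(model)
  m <- .aln_matrix(alignment)
  n <- nrow(m)
  if (n < 2L) stop("need at least 2 taxa")
  labels <- rownames(m)
  d <- matrix(0, n, n, dimnames = list(labels, labels))
  gap <- m == "-"
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    cmp <- !gap[i, ] & !gap[j, ]
    nc <- sum(cmp)
    if (nc == 0L)
      stop(sprintf("no comparable columns for pair %s / %s",
                   labels[i], labels[j]))
    p <- sum(m[i, cmp] != m[j, cmp]) / nc
    if (model == "poisson") {
      if (p >= 1)
        stop(sprintf("saturated pair %s / %s: p = 1 undefined under poisson",
                     labels[i], labels[j]))
      p <- -log(1 - p)
    }
    d[i, j] <- d[j, i] <- p
  }
  d
}

#' Neighbor-joining tree construction
#'
#' Saitou-Nei agglomeration: at each step the pair minimizing
#' Q(i,j) = (n-2) d(i,j) - sum_k d(i,k) - sum_k d(j,k) is joined; Q ties are
#' broken by the lexicographically smallest pair of cluster labels (a
#' cluster is labelled by its smallest leaf), making the result
#' deterministic and independent of input order. Negative branch lengths
#' are clamped to zero with the deficit moved to the sister branch, so the
#' joined pair's path length is preserved.
#'
#' @param D Symmetric distance matrix with at least 3 labelled taxa.
#' @return An unrooted `phylo` tree (trifurcating root node).
#' @export
neighbor_joining <- function(D) {
  D <- as.matrix(D)
  labels <- rownames(D)
  if (is.null(labels)) stop("distance matrix must have row names")
  n <- nrow(D)
  if (n < 3L) stop("neighbor joining needs at least 3 taxa")
  if (max(abs(D - t(D))) > 1e-12) stop("distance matrix must be symmetric")
  fmt <- function(x) sprintf("%.15g", x)
  nwk <- labels          # newick string per active cluster
  minleaf <- labels      # smallest leaf label per cluster, for tie-breaks
  while (n > 3L) {
    r <- rowSums(D)
    Q <- (n - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q - qmin <= 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    key <- apply(cand, 1L, function(ij) {
      lab <- sort(c(minleaf[ij[1]], minleaf[ij[2]]))
      paste(lab, collapse = "\r")
    })
    pick <- cand[order(key)[1L], ]
    i <- pick[1L]; j <- pick[2L]
    bi <- 0.5 * D[i, j] + (r[i] - r[j]) / (2 * (n - 2))
    bj <- D[i, j] - bi
    if (bi < 0) { bj <- D[i, j]; bi <- 0 }
    if (bj < 0) { bi <- D[i, j]; bj <- 0 }
    new_nwk <- sprintf("(%s:%s,%s:%s)", nwk[i], fmt(bi), nwk[j], fmt(bj))
    new_min <- min(minleaf[i], minleaf[j])
    du <- 0.5 * (D[i, ] + D[j, ] - D[i, j])
    keep <- setdiff(seq_len(n), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], du[keep]),
               c(du[keep], 0))
    nwk <- c(nwk[keep], new_nwk)
    minleaf <- c(minleaf[keep], new_min)
    n <- n - 1L
    rownames(D) <- colnames(D) <- minleaf
  }
  a <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  b <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  c3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  bl <- pmax(c(a, b, c3), 0)
  txt <- sprintf("(%s:%s,%s:%s,%s:%s);", nwk[1], fmt(bl[1]),
                 nwk[2], fmt(bl[2]), nwk[3], fmt(bl[3]))
  ape::read.tree(text = txt)
}

# canonical keys for the non-trivial leaf bipartitions of an unrooted tree:
# each internal edge splits the leaves in two; the side not containing the
# alphabetically first taxon is sorted and pasted.
.tree_splits <- function(tree) {
  all_tips <- sort(tree$tip.label)
  parts <- ape::prop.part(tree)
  lab <- attr(parts, "labels")
  keys <- character(0)
  for (i in seq_along(parts)) {
    if (i == 1L) next  # root "clade" = all tips, not an edge
    side <- sort(lab[parts[[i]]])
    if (length(side) <= 1L || length(side) >= length(all_tips) - 1L) next
    if (all_tips[1L] %in% side) side <- setdiff(all_tips, side)
    keys <- c(keys, paste(side, collapse = "\r"))
  }
  keys
}

#' Neighbor-joining tree with bootstrap supports
#'
#' Alignment columns are resampled with replacement `n_reps` times; the
#' support of an internal edge is the percentage of replicate trees
#' containing the same leaf bipartition. Replicates in which some pair has
#' no comparable columns are dropped (with a warning). Reproducible for a
#' fixed seed.
#'
#' @param alignment A `seq_records` (protein-aligned) object.
#' @param model Distance model (see [pairwise_distance()]).
#' @param n_reps Number of bootstrap replicates (>= 1).
#' @param seed Integer seed (required).
#' @return The full-alignment NJ `phylo` tree with `node.label` set to
#'   bipartition support percentages ("" for the root).
#' @export
bootstrap_support <- function(alignment, model = "p", n_reps = 1000L, seed) {
  if (missing(seed)) stop("a seed is required")
  stopifnot(n_reps >= 1L)
  m <- .aln_matrix(alignment)
  main <- neighbor_joining(pairwise_distance(m, model))
  main_keys <- .tree_splits(main)
  set.seed(seed)
  counts <- stats::setNames(numeric(length(main_keys)), main_keys)
  dropped <- 0L
  used <- 0L
  for (rep in seq_len(n_reps)) {
    cols <- sample.int(ncol(m), ncol(m), replace = TRUE)
    rep_tree <- tryCatch(
      neighbor_joining(pairwise_distance(m[, cols, drop = FALSE], model)),
      error = function(e) NULL)
    if (is.null(rep_tree)) { dropped <- dropped + 1L; next }
    used <- used + 1L
    hit <- main_keys %in% .tree_splits(rep_tree)
    counts[hit] <- counts[hit] + 1
  }
  if (dropped > 0L)
    warning(dropped, " bootstrap replicate(s) dropped (incomparable pair)")
  support <- if (used > 0L) 100 * counts / used else counts * NA
  # node order in prop.part matches internal node numbering used for labels
  parts <- ape::prop.part(main)
  lab <- attr(parts, "labels")
  all_tips <- sort(main$tip.label)
  node_lab <- character(main$Nnode)
  for (i in seq_along(parts)) {
    if (i == 1L) { node_lab[i] <- ""; next }
    side <- sort(lab[parts[[i]]])
    if (all_tips[1L] %in% side) side <- setdiff(all_tips, side)
    key <- paste(side, collapse = "\r")
    node_lab[i] <- if (key %in% names(counts))
      format(round(support[[key]], 1)) else ""
  }
  main$node.label <- node_lab
  attr(main, "n_replicates_used") <- used
  main
}

#' Assign genes to clades by nearest anchor
#'
#' Each non-anchor gene is labelled with the clade of its nearest anchor in
#' the distance matrix. The margin is the difference between the best
#' distances of the two closest clades; a zero margin (equidistant clades)
#' gives the label "ambiguous".
#'
#' @param D Symmetric distance matrix over genes and anchors.
#' @param anchors Named character vector: anchor id -> clade label.
#' @return A data frame `gene_id`, `clade`, `nearest_anchor`, `margin`.
#' @export
assign_clades <- function(D, anchors) {
  D <- as.matrix(D)
  ids <- rownames(D)
  missing_anchor <- setdiff(names(anchors), ids)
  if (length(missing_anchor))
    stop("anchor ids missing from distance matrix: ",
         paste(missing_anchor, collapse = ", "))
  if (length(unique(anchors)) < 1L) stop("need at least one clade")
  genes <- setdiff(ids, names(anchors))
  rows <- lapply(genes, function(g) {
    d_anchor <- D[g, names(anchors)]
    clade_min <- tapply(d_anchor, anchors, min)
    o <- order(clade_min)
    best <- names(clade_min)[o[1L]]
    margin <- if (length(clade_min) > 1L)
      unname(clade_min[o[2L]] - clade_min[o[1L]]) else Inf
    nearest <- names(d_anchor)[which.min(d_anchor)]
    data.frame(gene_id = g,
               clade = if (margin == 0) "ambiguous" else best,
               nearest_anchor = nearest, margin = margin,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# round half away from zero
.round_half_up <- function(x, digits = 1L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Clade proportions as printed percentages
#'
#' @param x Either a character vector of per-gene clade labels or a named
#'   integer vector of clade sizes.
#' @return Named numeric vector of percentages, rounded half away from zero
#'   to one decimal, in decreasing order.
#' @export
clade_proportions <- function(x) {
  counts <- if (is.character(x)) table(x) else x
  pct <- .round_half_up(100 * as.numeric(counts) / sum(counts), 1L)
  names(pct) <- names(counts)
  sort(pct, decreasing = TRUE)
}
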