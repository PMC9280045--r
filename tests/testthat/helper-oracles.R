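# Independent oracles and small builders shared across tests.

# --- exhaustive unrooted-topology enumeration -------------------------------
# Trees are edge matrices over node ids; leaves are 1..n (indexing `labels`),
# internal nodes n+1, n+2, ... Built by inserting each new leaf into every
# edge of every smaller tree (3 leaves -> star).
enum_unrooted <- function(n) {
  trees <- list(list(edges = rbind(c(n + 1L, 1L), c(n + 1L, 2L),
                                   c(n + 1L, 3L)),
                     next_node = n + 2L))
  for (k in setdiff(seq_len(n), 1:3)) {
    new <- list()
    for (tr in trees) {
      for (e in seq_len(nrow(tr$edges))) {
        m <- tr$next_node
        a <- tr$edges[e, 1L]; b <- tr$edges[e, 2L]
        new[[length(new) + 1L]] <- list(
          edges = rbind(tr$edges[-e, , drop = FALSE],
                        c(a, m), c(m, b), c(m, k)),
          next_node = m + 1L)
      }
    }
    trees <- new
  }
  trees
}

# leaves reachable from `start` when edge `drop` is removed
.side_leaves <- function(edges, start, drop, n) {
  adj <- split(rbind(edges, edges[, 2:1])[, 2L],
               rbind(edges, edges[, 2:1])[, 1L])
  blocked <- edges[drop, ]
  seen <- start
  queue <- start
  while (length(queue)) {
    u <- queue[1L]; queue <- queue[-1L]
    for (v in adj[[as.character(u)]]) {
      if (u %in% blocked && v %in% blocked) next
      if (!v %in% seen) { seen <- c(seen, v); queue <- c(queue, v) }
    }
  }
  sort(seen[seen <= n])
}

# canonical bipartition keys of an edge-list tree (same convention as the
# package: the side not containing the alphabetically first label)
edge_tree_splits <- function(edges, labels) {
  n <- length(labels)
  all_sorted <- sort(labels)
  keys <- character(0)
  for (e in seq_len(nrow(edges))) {
    side <- labels[.side_leaves(edges, edges[e, 1L], e, n)]
    if (length(side) <= 1L || length(side) >= n - 1L) next
    side <- sort(side)
    if (all_sorted[1L] %in% side) side <- setdiff(all_sorted, side)
    keys <- c(keys, paste(side, collapse = "\r"))
  }
  sort(unique(keys))
}

# ordinary-least-squares fit of branch lengths for a fixed topology:
# SSQ of (path-length matrix - D) minimized over branch lengths
ols_ssq <- function(edges, D) {
  n <- nrow(D)
  pairs <- which(upper.tri(D), arr.ind = TRUE)
  A <- matrix(0, nrow(pairs), nrow(edges))
  path_edges <- function(from, to) {
    # DFS over edges
    stack <- list(list(node = from, used = integer()))
    repeat {
      cur <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      if (cur$node == to) return(cur$used)
      for (e in seq_len(nrow(edges))) {
        if (e %in% cur$used) next
        if (edges[e, 1L] == cur$node)
          stack[[length(stack) + 1L]] <- list(node = edges[e, 2L],
                                              used = c(cur$used, e))
        else if (edges[e, 2L] == cur$node)
          stack[[length(stack) + 1L]] <- list(node = edges[e, 1L],
                                              used = c(cur$used, e))
      }
      if (!length(stack)) stop("no path found")
    }
  }
  for (p in seq_len(nrow(pairs)))
    A[p, path_edges(pairs[p, 1L], pairs[p, 2L])] <- 1
  d <- D[pairs]
  b <- qr.coef(qr(A), d)
  b[is.na(b)] <- 0
  sum((A %*% b - d)^2)
}

# exhaustive least-squares-optimal topology: split keys of the SSQ argmin
ls_optimal_splits <- function(D) {
  labels <- rownames(D)
  trees <- enum_unrooted(length(labels))
  ssq <- vapply(trees, function(tr) ols_ssq(tr$edges, D), numeric(1L))
  edge_tree_splits(trees[[which.min(ssq)]]$edges, labels)
}

# random additive distance matrix from a random binary tree with positive
# branch lengths; returns the matrix and the generating topology's splits
random_additive <- function(n, seed) {
  set.seed(seed)
  tree <- ape::rtree(n, br = NULL)
  tree$edge.length <- stats::runif(nrow(tree$edge), 0.1, 1)
  D <- as.matrix(ape::cophenetic.phylo(tree))
  D <- D[sort(rownames(D)), sort(rownames(D))]
  list(D = D, splits = sort(woxkit:::.tree_splits(ape::unroot(tree))))
}

nj_splits <- function(tree) sort(woxkit:::.tree_splits(tree))

# uniform per-family codon probabilities, with optional overrides
uniform_family_probs <- function(override = list()) {
  fam <- synonymous_families()
  fams <- split(chartr("U", "T", fam$codon), fam$amino_acid)
  probs <- lapply(fams, function(codons)
    stats::setNames(rep(1 / length(codons), length(codons)), codons))
  for (aa in names(override)) probs[[aa]] <- override[[aa]]
  probs
}

# three-clade anchor tree used by the clade-recovery tests: one anchor and
# `n_genes` extra genes per clade, long branches between clades
three_clade_tree <- function(n_genes = 3L) {
  clade_txt <- function(prefix, anchor) {
    tips <- c(sprintf("%s:0.08", anchor),
              sprintf("%s_g%d:0.08", prefix, seq_len(n_genes)))
    paste0("(", paste(tips, collapse = ","), "):0.6")
  }
  txt <- sprintf("(%s,%s,%s);",
                 clade_txt("anc", "anchor_ancient"),
                 clade_txt("int", "anchor_intermediate"),
                 clade_txt("mod", "anchor_modern"))
  ape::read.tree(text = txt)
}
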