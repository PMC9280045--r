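# Expression analysis: 2^-ddCt relative expression with dual reference
# genes for qPCR Ct tables, heatmap-style matrix transforms, and simple
# per-gene stage profiles.

#' Relative expression by the 2^-ddCt method
#'
#' Per gene and sample, dCt is the mean target Ct minus the mean over the
#' reference genes of their replicate-mean Ct (arithmetic mean of two
#' reference genes, equivalent to the geometric mean of their linear
#' quantities); ddCt subtracts the calibrator sample's dCt, and the fold
#' change is 2^-ddCt (amplification efficiency fixed at 2). Significance
#' against the calibrator is a two-sided Student's t-test on
#' replicate-level dCt values at `alpha` (no multiple-testing correction).
#' With a single replicate the fold is computed and the test skipped.
#'
#' @param ct Data frame with columns `gene_id`, `sample_id`, `replicate`,
#'   `ct` (Ct > 0), containing target and reference genes.
#' @param references Character vector of reference gene ids (present in
#'   every sample).
#' @param calibrator Sample id of the calibrator.
#' @param alpha Significance level (default 0.01).
#' @return A data frame `gene_id`, `sample_id`, `delta_ct`,
#'   `delta_delta_ct`, `fold`, `p_value`, `significant`, `test_skipped`;
#'   the calibrator's fold is 1 by construction.
#' @export
relative_expression <- function(ct, references, calibrator, alpha = 0.01) {
  stopifnot(all(c("gene_id", "sample_id", "replicate", "ct") %in% names(ct)))
  if (any(ct$ct <= 0)) stop("Ct values must be positive")
  samples <- unique(ct$sample_id)
  if (!calibrator %in% samples) stop("calibrator sample not found")
  for (s in samples) {
    present <- unique(ct$gene_id[ct$sample_id == s])
    miss <- setdiff(references, present)
    if (length(miss))
      stop("reference gene ", miss[1L], " missing in sample ", s)
  }
  targets <- setdiff(unique(ct$gene_id), references)

  # replicate-level reference mean per (sample, replicate)
  is_ref <- ct$gene_id %in% references
  ref_rep <- stats::aggregate(ct ~ sample_id + replicate, data = ct[is_ref, ],
                              FUN = mean)
  names(ref_rep)[3L] <- "ref_ct"
  # sample-level reference mean: mean over reference genes of their
  # replicate-mean Ct
  ref_gene <- stats::aggregate(ct ~ sample_id + gene_id,
                               data = ct[is_ref, ], FUN = mean)
  ref_sample <- stats::aggregate(ct ~ sample_id, data = ref_gene, FUN = mean)
  names(ref_sample)[2L] <- "ref_ct"

  rep_dct <- function(g, s) {
    sub <- ct[ct$gene_id == g & ct$sample_id == s, ]
    rr <- ref_rep[ref_rep$sample_id == s, ]
    sub$ct - rr$ref_ct[match(sub$replicate, rr$replicate)]
  }
  rows <- list()
  for (g in targets) {
    dct <- vapply(samples, function(s) {
      mean(ct$ct[ct$gene_id == g & ct$sample_id == s]) -
        ref_sample$ref_ct[ref_sample$sample_id == s]
    }, numeric(1L))
    names(dct) <- samples
    dct_cal_rep <- rep_dct(g, calibrator)
    for (s in samples) {
      ddct <- dct[[s]] - dct[[calibrator]]
      d_rep <- rep_dct(g, s)
      skipped <- length(d_rep) < 2L || length(dct_cal_rep) < 2L
      p <- NA_real_
      if (!skipped && s != calibrator) {
        p <- tryCatch(stats::t.test(d_rep, dct_cal_rep)$p.value,
                      error = function(e) {
                        # zero-variance case: identical means are null
                        if (isTRUE(all.equal(mean(d_rep),
                                             mean(dct_cal_rep)))) 1 else 0
                      })
      }
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = g, sample_id = s, delta_ct = unname(dct[[s]]),
        delta_delta_ct = unname(ddct), fold = 2^(-ddct),
        p_value = p,
        significant = !is.na(p) & p < alpha,
        test_skipped = skipped, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Heatmap-style expression matrix transforms
#'
#' `log2p1` maps x to log2(x + 1). `row_z` applies `log2p1` and then
#' standardizes each row to mean 0 and (sample) sd 1; rows with zero
#' variance are set to 0 and recorded in the `"constant_rows"` attribute.
#'
#' @param expr Non-negative numeric matrix (genes x samples).
#' @param mode `"log2p1"` or `"row_z"`.
#' @return The transformed matrix.
#' @export
transform_matrix <- function(expr, mode = c("log2p1", "row_z")) {
  mode <- match.arg(mode)
  expr <- as.matrix(expr)
  if (any(expr < 0)) stop("expression matrix must be non-negative")
  lg <- log2(expr + 1)
  if (mode == "log2p1") return(lg)
  sds <- apply(lg, 1L, stats::sd)
  z <- t(scale(t(lg)))
  constant <- sds == 0
  z[constant, ] <- 0
  dimnames(z) <- dimnames(expr)
  attr(z, "constant_rows") <- rownames(expr)[constant]
  z
}

#' Per-gene stage profile
#'
#' Reports the sample with the maximal value per gene (ties resolved to the
#' earliest sample) and whether the profile is strictly decreasing across
#' the sample order.
#'
#' @param expr Numeric matrix (genes x ordered samples), >= 2 samples.
#' @return A data frame `gene_id`, `max_sample`, `decreasing`.
#' @export
stage_profile <- function(expr) {
  expr <- as.matrix(expr)
  if (ncol(expr) < 2L) stop("need at least 2 samples")
  samples <- colnames(expr)
  if (is.null(samples)) samples <- paste0("S", seq_len(ncol(expr)))
  data.frame(
    gene_id = if (is.null(rownames(expr)))
      paste0("gene", seq_len(nrow(expr))) else rownames(expr),
    max_sample = samples[apply(expr, 1L, which.max)],
    decreasing = apply(expr, 1L, function(x) all(diff(x) < 0)),
    stringsAsFactors = FALSE)
}
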