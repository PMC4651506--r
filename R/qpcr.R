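#' Relative expression by the 2^-ddCT method
#'
#' For one target gene: `dCT_sample = CT_target - mean(CT_ref1, CT_ref2)`,
#' `ddCT = dCT_sample - mean(dCT over baseline-stage samples)`, relative
#' expression `= 2^(-ddCT)`. The calibrator is the mean dCT across all
#' baseline-stage replicates, so the *geometric* mean of the baseline
#' relative expression equals 1 exactly. Averaging the two reference CTs
#' corresponds to normalizing by the geometric mean of their abundances.
#'
#' @param ct A `qpcr_ct` object from [generate_qpcr_ct()], or a genes x
#'   samples CT matrix (then `stages` is required).
#' @param target_gene Target gene id (must not be a reference).
#' @param reference_genes Character vector of reference gene ids present
#'   in the CT table.
#' @param baseline_stage Calibrator stage; defaults to the object's
#'   baseline.
#' @param stages Named character vector of per-sample stages when `ct` is
#'   a plain matrix.
#' @return Named numeric vector of per-sample relative expression.
#' @export
delta_delta_ct <- function(ct, target_gene, reference_genes = NULL,
                           baseline_stage = NULL, stages = NULL) {
  if (inherits(ct, "qpcr_ct")) {
    if (is.null(reference_genes)) reference_genes <- ct$reference_genes
    if (is.null(baseline_stage)) baseline_stage <- ct$baseline
    if (is.null(stages)) stages <- ct$stages
    ct <- ct$ct
  }
  if (is.null(stages) || is.null(baseline_stage) || is.null(reference_genes)) {
    stop("stages, baseline_stage and reference_genes are required")
  }
  if (target_gene %in% reference_genes) {
    stop("target gene '", target_gene, "' is a reference gene")
  }
  for (g in c(target_gene, reference_genes)) {
    if (!g %in% rownames(ct)) stop("gene '", g, "' missing from the CT table")
  }
  stages <- stages[colnames(ct)]
  if (!baseline_stage %in% stages) {
    stop("baseline stage '", baseline_stage, "' absent from the samples")
  }
  block <- ct[c(target_gene, reference_genes), , drop = FALSE]
  if (anyNA(block)) {
    idx <- which(is.na(block), arr.ind = TRUE)[1L, ]
    stop("missing CT for gene '", rownames(block)[idx[1L]], "', sample '",
         colnames(block)[idx[2L]], "'")
  }
  dct <- ct[target_gene, ] -
    colMeans(ct[reference_genes, , drop = FALSE])
  ddct <- dct - mean(dct[stages == baseline_stage])
  2^(-ddct)
}

#' 2^-ddCT relative expression for all target genes
#'
#' @inheritParams delta_delta_ct
#' @return A list of class `qpcr_result`: `relative_expression` (targets x
#'   samples matrix of 2^-ddCT values), `stages`, `baseline_stage`,
#'   `reference_genes`.
#' @export
relative_expression <- function(ct, reference_genes = NULL,
                                baseline_stage = NULL, stages = NULL) {
  if (inherits(ct, "qpcr_ct")) {
    if (is.null(reference_genes)) reference_genes <- ct$reference_genes
    if (is.null(baseline_stage)) baseline_stage <- ct$baseline
    if (is.null(stages)) stages <- ct$stages
    mat <- ct$ct
  } else mat <- ct
  targets <- setdiff(rownames(mat), reference_genes)
  rel <- t(vapply(targets, function(g) {
    delta_delta_ct(mat, g, reference_genes, baseline_stage, stages)
  }, numeric(ncol(mat))))
  dimnames(rel) <- list(targets, colnames(mat))
  structure(
    list(relative_expression = rel, stages = stages[colnames(mat)],
         baseline_stage = baseline_stage, reference_genes = reference_genes),
    class = "qpcr_result"
  )
}

#' @export
print.qpcr_result <- function(x, ...) {
  cat("2^-ddCT relative expression: ", nrow(x$relative_expression),
      " target gene(s) x ", ncol(x$relative_expression), " samples\n",
      sep = "")
  cat("baseline (calibrator) stage: ", x$baseline_stage,
      "; references: ", paste(x$reference_genes, collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

#' FDR-filtered signed Pearson correlation network
#'
#' All-pairs Pearson correlation across samples, two-sided p-values via
#' `t = r * sqrt((n - 2) / (1 - r^2))`, Benjamini-Hochberg adjustment over
#' all pairs jointly; edges are kept at adjusted p below `alpha` and carry
#' the correlation sign. By default the correlation is computed on the
#' log2 of the relative expression (multiplicative fold changes become
#' additive); use `scale = "raw"` for the 2^-ddCT scale itself.
#'
#' @param rel A `qpcr_result`, or a genes x samples matrix of relative
#'   expression (positive values when `scale = "log2"`).
#' @param alpha FDR threshold (default 0.05).
#' @param scale `"log2"` (default) or `"raw"`.
#' @param per_stage If `TRUE`, correlate per-stage means instead of
#'   per-sample values (requires stage information).
#' @param stages Named stage vector when `rel` is a plain matrix and
#'   `per_stage = TRUE`.
#' @return A data.frame of class `correlation_edges`: `gene_a`, `gene_b`,
#'   `r`, `p_value`, `fdr_adjusted_p`, `sign` — one row per retained
#'   unordered pair. The number of pairs tested is in attribute
#'   `n_pairs_tested`.
#' @export
correlation_network <- function(rel, alpha = 0.05,
                                scale = c("log2", "raw"),
                                per_stage = FALSE, stages = NULL) {
  scale <- match.arg(scale)
  if (inherits(rel, "qpcr_result")) {
    if (is.null(stages)) stages <- rel$stages
    rel <- rel$relative_expression
  }
  if (!is.matrix(rel) || !is.numeric(rel)) {
    stop("`rel` must be a numeric matrix")
  }
  x <- if (scale == "log2") {
    if (any(rel <= 0)) stop("log2 scale requires positive relative expression")
    log2(rel)
  } else rel
  if (per_stage) {
    if (is.null(stages)) stop("per-stage correlation requires stage labels")
    stages <- stages[colnames(x)]
    lv <- unique(stages)
    x <- vapply(lv, function(s) rowMeans(x[, stages == s, drop = FALSE]),
                numeric(nrow(x)))
    colnames(x) <- lv
  }
  if (ncol(x) < 3L) stop("need >= 3 samples (or stages) per gene")
  sds <- apply(x, 1L, stats::sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " constant gene(s) excluded: ",
            paste(rownames(x)[sds == 0], collapse = ", "))
    x <- x[sds > 0, , drop = FALSE]
  }
  if (nrow(x) < 2L) stop("need >= 2 non-constant genes")
  n <- ncol(x)
  r <- stats::cor(t(x))
  ut <- which(upper.tri(r), arr.ind = TRUE)
  rv <- r[ut]
  tv <- rv * sqrt((n - 2) / pmax(1 - rv^2, .Machine$double.eps))
  pv <- 2 * stats::pt(-abs(tv), n - 2)
  pv[abs(rv) >= 1] <- 0
  padj <- bh_adjust(pv)
  keep <- padj < alpha
  res <- data.frame(
    gene_a = rownames(r)[ut[keep, 1L]],
    gene_b = rownames(r)[ut[keep, 2L]],
    r = rv[keep], p_value = pv[keep], fdr_adjusted_p = padj[keep],
    sign = ifelse(rv[keep] > 0, "positive", "negative"),
    stringsAsFactors = FALSE
  )
  rownames(res) <- NULL
  structure(res, class = c("correlation_edges", "data.frame"),
            n_pairs_tested = nrow(ut), alpha = alpha)
}
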