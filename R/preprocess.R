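#' Quantile normalization
#'
#' Forces every sample (column) to share the same distribution of values:
#' the value at rank r in each column becomes the mean, across columns, of
#' each column's rank-r value. Ties are resolved by averaging the reference
#' values across the tied rank span (the standard dialect).
#'
#' @param m Numeric matrix (genes x samples), >= 2 columns, no missing
#'   values.
#' @return Matrix of the same shape and dimnames.
#' @export
quantile_normalize <- function(m) {
  if (!is.matrix(m) || !is.numeric(m)) stop("`m` must be a numeric matrix")
  if (ncol(m) < 2L) stop("quantile normalization needs >= 2 samples")
  if (anyNA(m)) stop("missing values are not allowed (no imputation)")
  if (nrow(m) == 1L) {   # single gene: the reference is its row mean
    out <- m
    out[] <- mean(m)
    return(out)
  }
  out <- limma::normalizeQuantiles(m, ties = TRUE)
  dimnames(out) <- dimnames(m)
  out
}

#' Median-polish probe summarization
#'
#' Summarizes probe-level intensities into one expression measure per gene
#' by Tukey's median polish: for each gene's probes x samples block,
#' alternating row/column median sweeps are run to convergence and the
#' gene's per-sample summary is the overall effect plus that sample's
#' column effect. Per-probe additive offsets are absorbed by the row
#' effects and do not influence the summary.
#'
#' @param probe_matrix Numeric matrix, probes x samples.
#' @param probe_to_gene Character vector mapping probe rownames to gene
#'   ids; either named by probe id or aligned with the rows.
#' @param tol Convergence tolerance of the polish (default 1e-6).
#' @param max_iter Maximum sweep iterations (default 10).
#' @return Numeric matrix, genes x samples, genes in first-appearance
#'   order.
#' @export
median_polish_summarize <- function(probe_matrix, probe_to_gene,
                                    tol = 1e-6, max_iter = 10L) {
  if (!is.matrix(probe_matrix) || !is.numeric(probe_matrix)) {
    stop("`probe_matrix` must be a numeric matrix")
  }
  if (!is.null(names(probe_to_gene))) {
    missing <- setdiff(rownames(probe_matrix), names(probe_to_gene))
    if (length(missing)) {
      stop("probes without a gene mapping: ", paste(missing, collapse = ", "))
    }
    probe_to_gene <- probe_to_gene[rownames(probe_matrix)]
  } else if (length(probe_to_gene) != nrow(probe_matrix)) {
    stop("`probe_to_gene` must have one entry per probe row")
  }
  genes <- unique(probe_to_gene)
  out <- matrix(NA_real_, length(genes), ncol(probe_matrix),
                dimnames = list(genes, colnames(probe_matrix)))
  for (g in genes) {
    block <- probe_matrix[probe_to_gene == g, , drop = FALSE]
    if (nrow(block) == 0L) stop("gene '", g, "' has no probes")
    if (nrow(block) == 1L) {
      out[g, ] <- block[1L, ]
    } else {
      mp <- suppressWarnings(
        stats::medpolish(block, eps = tol, maxiter = max_iter,
                         trace.iter = FALSE)
      )
      out[g, ] <- mp$overall + mp$col
    }
  }
  out
}

#' Elementwise log2 transform
#'
#' @param m Numeric matrix with strictly positive entries.
#' @return `log2(m)`.
#' @export
log2_transform <- function(m) {
  if (!is.matrix(m) || !is.numeric(m)) stop("`m` must be a numeric matrix")
  bad <- which(!(m > 0), arr.ind = TRUE)
  if (nrow(bad)) {
    rn <- if (is.null(rownames(m))) bad[1L, 1L] else rownames(m)[bad[1L, 1L]]
    cn <- if (is.null(colnames(m))) bad[1L, 2L] else colnames(m)[bad[1L, 2L]]
    stop("non-positive value at gene '", rn, "', sample '", cn, "'")
  }
  log2(m)
}
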