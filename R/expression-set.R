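#' Construct an expression set
#'
#' The central container of the pipeline: a genes x samples matrix of
#' log2-scale expression values together with the stage label of every
#' sample and the baseline (calibrator) stage.
#'
#' @param values Numeric matrix, genes in rows (unique rownames required),
#'   samples in columns (colnames required). No missing values allowed.
#' @param stages Character vector of stage labels, either named by sample id
#'   or aligned with the columns of `values`.
#' @param baseline Baseline stage label. Defaults to the first stage in
#'   order of appearance.
#'
#' @return An object of class `expr_set`: a list with elements `values`,
#'   `stages` (character, aligned to columns) and `baseline`.
#' @export
expression_set <- function(values, stages, baseline = NULL) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("`values` must have gene rownames and sample colnames")
  }
  if (anyDuplicated(rownames(values))) {
    dup <- rownames(values)[duplicated(rownames(values))][1L]
    stop("duplicate gene id: ", dup)
  }
  if (anyNA(values)) stop("expression values must not contain missing values")
  stages <- as.character(stages)
  if (!is.null(names(stages))) {
    missing <- setdiff(colnames(values), names(stages))
    if (length(missing)) {
      stop("samples without a stage assignment: ",
           paste(missing, collapse = ", "))
    }
    stages <- stages[colnames(values)]
  } else if (length(stages) != ncol(values)) {
    stop("`stages` must have one entry per sample")
  }
  names(stages) <- colnames(values)
  if (is.null(baseline)) baseline <- stages[[1L]]
  if (!baseline %in% stages) {
    stop("baseline stage '", baseline, "' not present among sample stages")
  }
  structure(
    list(values = values, stages = stages, baseline = baseline),
    class = "expr_set"
  )
}

#' @export
print.expr_set <- function(x, ...) {
  tab <- table(x$stages)[unique(x$stages)]
  cat("Expression set: ", nrow(x$values), " genes x ", ncol(x$values),
      " samples\n", sep = "")
  cat("Stages (replicates): ",
      paste0(names(tab), " (", tab, ")", collapse = ", "), "\n", sep = "")
  cat("Baseline stage: ", x$baseline, "\n", sep = "")
  invisible(x)
}

#' @export
dim.expr_set <- function(x) dim(x$values)

#' Stage labels of an expression set in order of appearance
#' @param expr An `expr_set`.
#' @return Character vector of unique stage labels.
#' @export
stage_levels <- function(expr) {
  stopifnot(inherits(expr, "expr_set"))
  unique(expr$stages)
}

#' Per-stage mean expression
#'
#' Averages replicates within each stage, yielding the genes x stages
#' matrix of temporal profiles used by fold-change and clustering stages.
#'
#' @param expr An `expr_set`.
#' @return Numeric matrix, genes x stages (stage order = order of
#'   appearance in the sample annotation).
#' @export
stage_means <- function(expr) {
  stopifnot(inherits(expr, "expr_set"))
  lv <- stage_levels(expr)
  out <- vapply(lv, function(s) {
    rowMeans(expr$values[, expr$stages == s, drop = FALSE])
  }, numeric(nrow(expr$values)))
  # vapply drops dims for a single gene
  out <- matrix(out, nrow = nrow(expr$values), ncol = length(lv),
                dimnames = list(rownames(expr$values), lv))
  out
}

#' Subset an expression set by gene and/or sample
#' @param x An `expr_set`.
#' @param genes Gene ids or indices (optional).
#' @param samples Sample ids or indices (optional).
#' @return An `expr_set` restricted to the requested rows/columns.
#' @export
subset_expression <- function(x, genes = NULL, samples = NULL) {
  stopifnot(inherits(x, "expr_set"))
  v <- x$values
  if (!is.null(genes)) {
    if (is.character(genes)) {
      bad <- setdiff(genes, rownames(v))
      if (length(bad)) stop("unknown gene id: ", paste(bad, collapse = ", "))
    }
    v <- v[genes, , drop = FALSE]
  }
  st <- x$stages
  if (!is.null(samples)) {
    v <- v[, samples, drop = FALSE]
    st <- st[colnames(v)]
  }
  baseline <- if (x$baseline %in% st) x$baseline else st[[1L]]
  expression_set(v, st, baseline)
}
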