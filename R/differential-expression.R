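# Welch statistics for many genes at once. A and B are genes x samples
# matrices holding the two groups; returns t, Welch-Satterthwaite df and
# the two-sided p-value per row. The zero-variance/equal-means degenerate
# case yields t = 0, p = 1 (no evidence against the null); zero variance
# with unequal means yields p = 0.
.welch_rows <- function(A, B) {
  na <- ncol(A); nb <- ncol(B)
  ma <- rowMeans(A); mb <- rowMeans(B)
  va <- rowSums((A - ma)^2) / (na - 1)
  vb <- rowSums((B - mb)^2) / (nb - 1)
  se2 <- va / na + vb / nb
  t <- (ma - mb) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * stats::pt(-abs(t), df)
  degen <- se2 == 0
  if (any(degen)) {
    eq <- degen & (ma == mb)
    t[eq] <- 0; p[eq] <- 1; df[eq] <- na + nb - 2
    ne <- degen & (ma != mb)
    t[ne] <- sign(ma - mb)[ne] * Inf; p[ne] <- 0; df[ne] <- na + nb - 2
  }
  list(t_statistic = t, welch_df = df, p_value = p)
}

#' Unpaired Welch t-test
#'
#' Two-sample t-test with unequal variances:
#' `t = (mean(a) - mean(b)) / sqrt(s2_a/n_a + s2_b/n_b)` with
#' Welch-Satterthwaite degrees of freedom and a two-sided p-value. When both
#' groups have zero variance and equal means the test returns t = 0, p = 1.
#'
#' @param group_a,group_b Numeric vectors of length >= 2, finite values.
#' @return List with `t_statistic`, `welch_df`, `p_value`.
#' @export
welch_t_test <- function(group_a, group_b) {
  if (length(group_a) < 2L || length(group_b) < 2L) {
    stop("each group needs >= 2 values")
  }
  if (!all(is.finite(group_a)) || !all(is.finite(group_b))) {
    stop("groups must contain only finite values")
  }
  res <- .welch_rows(matrix(group_a, 1L), matrix(group_b, 1L))
  lapply(res, unname)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up false-discovery-rate adjustment:
#' `adj_i = min over p_(j) >= p_(i) of p_(j) * m / rank(j)`, capped at 1.
#'
#' @param p_values Numeric vector with entries in `[0, 1]`.
#' @return Adjusted p-values in the input order.
#' @export
bh_adjust <- function(p_values) {
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Log2 fold change between two stages
#'
#' Difference of stage-mean log2 expression (later minus baseline), which
#' equals the log2 ratio of the (geometric mean) expression levels since
#' the values are already on the log2 scale.
#'
#' @param expr An [expression_set()].
#' @param gene Gene id.
#' @param later_stage,baseline_stage Stage labels present in `expr`.
#' @return A single number.
#' @export
log2_fold_change <- function(expr, gene, later_stage, baseline_stage) {
  stopifnot(inherits(expr, "expr_set"))
  for (s in c(later_stage, baseline_stage)) {
    if (!s %in% expr$stages) stop("unknown stage: ", s)
  }
  if (!gene %in% rownames(expr$values)) stop("unknown gene: ", gene)
  x <- expr$values[gene, ]
  mean(x[expr$stages == later_stage]) - mean(x[expr$stages == baseline_stage])
}

#' Call differentially expressed genes against the baseline stage
#'
#' For every later stage, each gene is tested against the baseline stage
#' with the unpaired Welch t-test; Benjamini-Hochberg adjustment is applied
#' within that comparison, and genes with adjusted p below `alpha` are
#' reported with their direction (up if the log2 fold change is positive,
#' down otherwise).
#'
#' @param expr An [expression_set()] with >= 2 replicates per stage.
#' @param baseline_stage Baseline stage label (defaults to `expr$baseline`).
#' @param alpha FDR threshold (default 0.05).
#' @param keep_all If `TRUE`, return statistics for all genes (significant
#'   or not); default `FALSE` keeps only significant records.
#' @return A data.frame of class `deg_table` with columns `gene_id`,
#'   `stage`, `baseline`, `log2_fold_change`, `t_statistic`, `welch_df`,
#'   `p_value`, `fdr_adjusted_p`, `direction`.
#' @export
call_degs <- function(expr, baseline_stage = NULL, alpha = 0.05,
                      keep_all = FALSE) {
  stopifnot(inherits(expr, "expr_set"))
  if (is.null(baseline_stage)) baseline_stage <- expr$baseline
  if (!baseline_stage %in% expr$stages) {
    stop("baseline stage '", baseline_stage, "' absent from the data")
  }
  if (alpha < 0 || alpha > 1) stop("alpha must be in [0, 1]")
  tab <- table(expr$stages)
  if (any(tab < 2L)) stop("every stage needs >= 2 replicates")
  later <- setdiff(stage_levels(expr), baseline_stage)
  B <- expr$values[, expr$stages == baseline_stage, drop = FALSE]
  out <- vector("list", length(later))
  for (i in seq_along(later)) {
    s <- later[[i]]
    A <- expr$values[, expr$stages == s, drop = FALSE]
    w <- .welch_rows(A, B)
    lfc <- rowMeans(A) - rowMeans(B)
    padj <- bh_adjust(w$p_value)
    rec <- data.frame(
      gene_id = rownames(expr$values), stage = s, baseline = baseline_stage,
      log2_fold_change = unname(lfc), t_statistic = unname(w$t_statistic),
      welch_df = unname(w$welch_df), p_value = unname(w$p_value),
      fdr_adjusted_p = unname(padj),
      direction = ifelse(lfc > 0, "up", "down"),
      stringsAsFactors = FALSE
    )
    out[[i]] <- if (keep_all) rec else rec[rec$fdr_adjusted_p < alpha, ]
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  structure(res, class = c("deg_table", "data.frame"),
            baseline = baseline_stage, alpha = alpha)
}

#' Partition DEG calls into stage-specific and shared sets
#'
#' Genes significant in exactly one baseline comparison are assigned to
#' that stage's up- or down-regulated set; genes significant at two or more
#' stages form the shared set.
#'
#' @param records A `deg_table` from [call_degs()] (significant records).
#' @return A list of class `deg_partition` with `stage_specific` (named
#'   list `<stage>.<direction>` of gene ids), `shared` (gene ids) and
#'   `total_unique` (count of distinct DEGs).
#' @export
partition_degs <- function(records) {
  stopifnot(is.data.frame(records))
  if (nrow(records) && length(unique(records$baseline)) > 1L) {
    stop("records must come from a single baseline comparison family")
  }
  genes <- unique(records$gene_id)
  n_comp <- table(factor(records$gene_id, levels = genes))
  shared <- genes[n_comp >= 2L]
  once <- records[records$gene_id %in% genes[n_comp == 1L], , drop = FALSE]
  stages <- unique(records$stage)
  stage_specific <- list()
  for (s in stages) {
    for (d in c("up", "down")) {
      key <- paste0(s, ".", d)
      stage_specific[[key]] <-
        once$gene_id[once$stage == s & once$direction == d]
    }
  }
  structure(
    list(stage_specific = stage_specific, shared = shared,
         total_unique = length(genes)),
    class = "deg_partition"
  )
}

#' @export
print.deg_partition <- function(x, ...) {
  cat("DEG partition: ", x$total_unique, " unique genes (",
      length(x$shared), " shared across >= 2 stages)\n", sep = "")
  for (key in names(x$stage_specific)) {
    cat("  ", key, ": ", length(x$stage_specific[[key]]), "\n", sep = "")
  }
  invisible(x)
}
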