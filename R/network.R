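#' Correlation and soft-thresholded adjacency
#'
#' Computes the Pearson correlation between the expression profiles of all
#' gene pairs across samples and transforms it into a connection strength
#' by the power rule `a_ij = |r_ij^2|^beta` (equivalently `|r_ij|^(2*beta)`),
#' the dialect printed in the source methodology. Set
#' `dialect = "conventional"` for the usual `|r|^beta`. The diagonal is set
#' to 0 so connectivity sums exclude self-connections. Constant genes have
#' undefined correlation and are excluded with a warning.
#'
#' @param expr An [expression_set()] or a plain genes x samples matrix
#'   (>= 3 samples).
#' @param beta Soft-threshold power, >= 1.
#' @param dialect `"squared"` (default, `|r|^(2*beta)`) or `"conventional"`
#'   (`|r|^beta`).
#' @return List of class `coexpr_adjacency` with `correlation`,
#'   `adjacency`, `beta`, `dialect`.
#' @export
pearson_adjacency <- function(expr, beta, dialect = c("squared", "conventional")) {
  dialect <- match.arg(dialect)
  v <- if (inherits(expr, "expr_set")) expr$values else expr
  if (!is.matrix(v) || !is.numeric(v)) stop("expression must be a numeric matrix")
  if (ncol(v) < 3L) stop("need >= 3 samples for correlation")
  if (beta < 1) stop("beta must be >= 1")
  sds <- apply(v, 1L, stats::sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " constant gene(s) excluded from the network: ",
            paste(utils::head(rownames(v)[sds == 0], 5L), collapse = ", "))
    v <- v[sds > 0, , drop = FALSE]
  }
  r <- stats::cor(t(v))
  power <- if (dialect == "squared") 2 * beta else beta
  a <- abs(r)^power
  diag(a) <- 0
  structure(list(correlation = r, adjacency = a, beta = beta,
                 dialect = dialect),
            class = "coexpr_adjacency")
}

#' Whole-network connectivity
#'
#' `k_i = sum_{j != i} a_ij`: the sum of a gene's connection strengths to
#' every other gene in the network.
#'
#' @param a A `coexpr_adjacency` or an adjacency matrix with zero diagonal.
#' @return Named numeric vector of per-gene connectivity.
#' @export
connectivity <- function(a) {
  m <- if (inherits(a, "coexpr_adjacency")) a$adjacency else a
  if (!is.matrix(m)) stop("`a` must be an adjacency matrix")
  rowSums(m)
}

#' Scale-free topology fit of a connectivity distribution
#'
#' Bins the connectivity values into `n_bins` equal-width bins and
#' regresses `log10 p(k)` on `log10 k` over the non-empty bins (`p(k)` =
#' fraction of genes per bin, `k` = bin-mean connectivity). A high
#' coefficient of determination with negative slope indicates approximate
#' scale-free topology.
#'
#' @param k Numeric vector of positive connectivities.
#' @param n_bins Number of equal-width bins (default 10).
#' @return List with `r_squared` and `slope`.
#' @export
scale_free_fit <- function(k, n_bins = 10L) {
  k <- k[k > 0]
  if (!length(k)) stop("connectivity vector has no positive entries")
  if (diff(range(k)) == 0) stop("degenerate connectivity: single bin only")
  breaks <- seq(min(k), max(k), length.out = n_bins + 1L)
  bin <- findInterval(k, breaks, rightmost.closed = TRUE)
  counts <- tabulate(bin, n_bins)
  nonempty <- which(counts > 0L)
  if (length(nonempty) < 3L) stop("fewer than 3 non-empty bins: fit undefined")
  bin_mean <- vapply(nonempty, function(b) mean(k[bin == b]), numeric(1))
  p <- counts[nonempty] / length(k)
  y <- log10(p)
  fit <- stats::lm(y ~ log10(bin_mean))
  r2 <- 1 - sum(stats::residuals(fit)^2) / sum((y - mean(y))^2)
  list(r_squared = r2, slope = unname(stats::coef(fit)[2L]))
}

#' Soft-threshold power selection by the scale-free topology criterion
#'
#' Evaluates the scale-free fit of the network connectivity for each
#' candidate power and picks the smallest candidate reaching
#' `r_squared >= r2_target` with negative slope. If no candidate
#' qualifies, the candidate maximizing the fit is used with a warning.
#'
#' @param expr An [expression_set()] or genes x samples matrix.
#' @param beta_candidates Candidate powers (default 1:10; note the default
#'   adjacency dialect already squares the correlation, so power 1 equals
#'   the conventional power 2).
#' @param r2_target Target coefficient of determination (default 0.9, the conventional scale-free criterion threshold).
#' @param n_bins Bins for [scale_free_fit()] (default 10).
#' @param dialect Adjacency dialect, see [pearson_adjacency()].
#' @return List of class `scale_free_pick`: `chosen_beta`,
#'   `beta_candidates`, `r_squared`, `slope`, `mean_connectivity`,
#'   `r2_target`.
#' @export
pick_soft_threshold <- function(expr, beta_candidates = 1:10,
                                r2_target = 0.9, n_bins = 10L,
                                dialect = c("squared", "conventional")) {
  dialect <- match.arg(dialect)
  if (!length(beta_candidates)) stop("empty candidate set")
  beta_candidates <- sort(unique(beta_candidates))
  v <- if (inherits(expr, "expr_set")) expr$values else expr
  sds <- apply(v, 1L, stats::sd)
  if (any(sds == 0)) v <- v[sds > 0, , drop = FALSE]
  r <- stats::cor(t(v))
  ar <- abs(r); diag(ar) <- 0
  r2 <- slope <- meank <- rep(NA_real_, length(beta_candidates))
  for (i in seq_along(beta_candidates)) {
    power <- if (dialect == "squared") 2 * beta_candidates[i] else beta_candidates[i]
    kk <- rowSums(ar^power)
    meank[i] <- mean(kk)
    fit <- tryCatch(scale_free_fit(kk, n_bins), error = function(e) NULL)
    if (!is.null(fit)) { r2[i] <- fit$r_squared; slope[i] <- fit$slope }
  }
  qualifies <- !is.na(r2) & r2 >= r2_target & slope < 0
  if (any(qualifies)) {
    chosen <- beta_candidates[which(qualifies)[1L]]
  } else {
    warning("no candidate power reached the scale-free target R^2 = ",
            r2_target, "; using the best-fitting candidate")
    chosen <- beta_candidates[which.max(r2)]
  }
  structure(list(chosen_beta = chosen, beta_candidates = beta_candidates,
                 r_squared = r2, slope = slope, mean_connectivity = meank,
                 r2_target = r2_target, dialect = dialect),
            class = "scale_free_pick")
}

#' @export
print.scale_free_pick <- function(x, ...) {
  cat("Scale-free soft-threshold selection (target R^2 = ", x$r2_target,
      ")\n", sep = "")
  print(data.frame(beta = x$beta_candidates, r_squared = round(x$r_squared, 3),
                   slope = round(x$slope, 3),
                   mean_k = signif(x$mean_connectivity, 4)),
        row.names = FALSE)
  cat("chosen beta: ", x$chosen_beta, "\n", sep = "")
  invisible(x)
}

#' Topological overlap matrix
#'
#' `omega_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' `l_ij = sum_u a_iu a_uj`: the overlap of two genes reflects how similar
#' their neighbourhoods are, beyond their direct connection. The diagonal
#' is 1 and `1 - omega` is the dissimilarity used for module detection.
#'
#' @param a A `coexpr_adjacency` or adjacency matrix (zero diagonal,
#'   entries in `[0, 1]`).
#' @return List of class `tom_matrix` with `omega` and `dissimilarity`.
#' @export
tom_similarity <- function(a) {
  m <- if (inherits(a, "coexpr_adjacency")) a$adjacency else a
  if (!is.matrix(m) || !isTRUE(all.equal(m, t(m)))) {
    stop("adjacency must be a symmetric matrix")
  }
  k <- rowSums(m)
  L <- m %*% m        # zero diagonal makes this the shared-neighbour sum
  kmin <- outer(k, k, pmin)
  omega <- (L + m) / (kmin + 1 - m)
  omega <- pmin(omega, 1)
  diag(omega) <- 1
  structure(list(omega = omega, dissimilarity = 1 - omega),
            class = "tom_matrix")
}

.module_colours <- c("turquoise", "blue", "brown", "yellow", "green", "red",
                     "black", "pink", "magenta", "purple", "greenyellow",
                     "tan", "salmon", "cyan", "midnightblue", "lightcyan")

#' Module detection by average-linkage clustering of TOM dissimilarity
#'
#' Builds the average-linkage dendrogram on `1 - omega` and applies a
#' static cut at `cut_height`; branches with at least `min_module_size`
#' genes become modules, labelled with colour names in decreasing size
#' order (turquoise, blue, brown, yellow, green, ...). Genes in smaller
#' branches are assigned to `"background"`.
#'
#' @param tom A `tom_matrix` from [tom_similarity()] (or a dissimilarity
#'   matrix).
#' @param cut_height Static cut height on the dendrogram (default 0.94).
#' @param min_module_size Minimum branch size to form a module
#'   (default 30).
#' @return List of class `module_set` with `modules` (named character per
#'   gene), `n_modules`, `sizes`, `dendrogram` (hclust), `cut_height`,
#'   `min_module_size`.
#' @export
detect_modules <- function(tom, cut_height = 0.94, min_module_size = 30L) {
  d <- if (inherits(tom, "tom_matrix")) tom$dissimilarity else tom
  if (!is.matrix(d)) stop("`tom` must be a tom_matrix or dissimilarity matrix")
  tree <- stats::hclust(stats::as.dist(d), method = "average")
  branch <- stats::cutree(tree, h = cut_height)
  sizes <- table(branch)
  keep <- as.integer(names(sizes)[sizes >= min_module_size])
  modules <- rep("background", nrow(d))
  names(modules) <- rownames(d)
  if (length(keep)) {
    ord <- keep[order(-sizes[as.character(keep)])]
    for (i in seq_along(ord)) {
      lab <- if (i <= length(.module_colours)) .module_colours[i] else
        paste0("module", i)
      modules[branch == ord[i]] <- lab
    }
  } else {
    warning("no branch reached the minimum module size; all genes background")
  }
  msizes <- table(modules[modules != "background"])
  structure(
    list(modules = modules, n_modules = length(keep),
         sizes = sort(msizes, decreasing = TRUE),
         dendrogram = tree, cut_height = cut_height,
         min_module_size = min_module_size),
    class = "module_set"
  )
}

#' @export
print.module_set <- function(x, ...) {
  cat("TOM module detection: static cut at ", x$cut_height,
      ", min size ", x$min_module_size, "\n", sep = "")
  cat(x$n_modules, " module(s); ", sum(x$modules == "background"),
      " background gene(s)\n", sep = "")
  if (x$n_modules) {
    print(data.frame(module = names(x$sizes), size = as.integer(x$sizes)),
          row.names = FALSE)
  }
  invisible(x)
}

#' Signed scaled intramodular connectivity and hub calling
#'
#' Splits each gene's connectivity by the sign of the underlying
#' correlation: `k_positive` sums adjacency over positively correlated
#' partners, `k_negative` over negatively correlated ones. Both are scaled
#' by their maximum within the gene's module, so each module's top gene
#' shows scaled K = 1 per sign. A gene is called a hub when its maximal
#' scaled K exceeds 0.9 and it has more than 10 connected partners
#' (adjacency at or above `edge_threshold`); background genes are never
#' hubs.
#'
#' @param adjacency A `coexpr_adjacency` from [pearson_adjacency()].
#' @param modules A `module_set` from [detect_modules()] (or a named
#'   character vector of module labels).
#' @param edge_threshold Minimum adjacency for two genes to count as
#'   connected (default 0.02).
#' @param scaled_k_cut Scaled-K hub threshold (default 0.9).
#' @param min_connected Connected-partner hub threshold (default 10).
#' @return A data.frame of class `hub_table`: `gene_id`, `module`,
#'   `k_positive`, `k_negative`, `scaled_k_positive`, `scaled_k_negative`,
#'   `connected_node_count`, `is_hub`.
#' @export
signed_scaled_connectivity <- function(adjacency, modules,
                                       edge_threshold = 0.02,
                                       scaled_k_cut = 0.9,
                                       min_connected = 10L) {
  stopifnot(inherits(adjacency, "coexpr_adjacency"))
  mod <- if (inherits(modules, "module_set")) modules$modules else modules
  a <- adjacency$adjacency
  r <- adjacency$correlation
  genes <- rownames(a)
  mod <- mod[genes]
  if (anyNA(mod)) stop("module assignment missing for some network genes")
  pos <- a * (r > 0); diag(pos) <- 0
  neg <- a * (r < 0)
  k_pos <- rowSums(pos)
  k_neg <- rowSums(neg)
  scale_in <- function(k) {
    out <- rep(NA_real_, length(k))
    for (g in unique(mod)) {
      i <- mod == g
      mx <- max(k[i])
      out[i] <- if (mx > 0) k[i] / mx else 0
    }
    out
  }
  skp <- scale_in(k_pos)
  skn <- scale_in(k_neg)
  connected <- rowSums(a >= edge_threshold)
  res <- data.frame(
    gene_id = genes, module = unname(mod),
    k_positive = unname(k_pos), k_negative = unname(k_neg),
    scaled_k_positive = unname(skp), scaled_k_negative = unname(skn),
    connected_node_count = unname(connected),
    stringsAsFactors = FALSE
  )
  res$is_hub <- res$module != "background" &
    pmax(res$scaled_k_positive, res$scaled_k_negative) > scaled_k_cut &
    res$connected_node_count > min_connected
  rownames(res) <- NULL
  structure(res, class = c("hub_table", "data.frame"),
            edge_threshold = edge_threshold)
}

#' Build the full weighted co-expression network
#'
#' Convenience wrapper tying the network stage together: soft-threshold
#' selection (unless `beta` is given), adjacency, connectivity, TOM,
#' module detection and the signed scaled-connectivity hub table.
#'
#' @param expr An [expression_set()] or genes x samples matrix.
#' @param beta Soft-threshold power or `"auto"` (default) for scale-free
#'   selection.
#' @param cut_height,min_module_size Passed to [detect_modules()].
#' @param edge_threshold Passed to [signed_scaled_connectivity()].
#' @param dialect Adjacency dialect, see [pearson_adjacency()].
#' @param beta_candidates,r2_target Passed to [pick_soft_threshold()] when
#'   `beta = "auto"`.
#' @return List of class `coexpression_network` with `soft_threshold`,
#'   `adjacency`, `connectivity`, `tom`, `modules`, `hubs`.
#' @export
build_network <- function(expr, beta = "auto", cut_height = 0.94,
                          min_module_size = 30L, edge_threshold = 0.02,
                          dialect = c("squared", "conventional"),
                          beta_candidates = 1:10, r2_target = 0.9) {
  dialect <- match.arg(dialect)
  pick <- NULL
  if (identical(beta, "auto")) {
    pick <- pick_soft_threshold(expr, beta_candidates, r2_target,
                                dialect = dialect)
    beta <- pick$chosen_beta
  }
  adj <- pearson_adjacency(expr, beta, dialect)
  k <- connectivity(adj)
  tomm <- tom_similarity(adj)
  mods <- detect_modules(tomm, cut_height, min_module_size)
  hubs <- signed_scaled_connectivity(adj, mods, edge_threshold)
  structure(
    list(soft_threshold = pick, beta = beta, adjacency = adj,
         connectivity = k, tom = tomm, modules = mods, hubs = hubs),
    class = "coexpression_network"
  )
}

#' @export
print.coexpression_network <- function(x, ...) {
  cat("Weighted co-expression network (beta = ", x$beta, ", dialect = ",
      x$adjacency$dialect, ")\n", sep = "")
  print(x$modules)
  cat(sum(x$hubs$is_hub), " hub gene(s) (scaled |K| > 0.9, > 10 connected nodes)\n",
      sep = "")
  invisible(x)
}
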