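#' Standardize temporal profiles
#'
#' Averages replicates within each stage and scales every gene's stage
#' profile to mean 0 and standard deviation 1, so that clustering compares
#' the *shape* of temporal regulation rather than absolute level or
#' amplitude (any positive affine transform of a profile standardizes to
#' the same vector; in particular the log base used upstream is
#' irrelevant). Genes with a constant stage profile carry no shape
#' information and are dropped with a warning.
#'
#' @param expr An [expression_set()].
#' @param genes Optional character vector restricting to a gene set
#'   (typically the DEG union).
#' @return Numeric matrix, genes x stages, each row mean 0 / sd 1.
#' @export
standardize_profiles <- function(expr, genes = NULL) {
  stopifnot(inherits(expr, "expr_set"))
  prof <- stage_means(expr)
  if (!is.null(genes)) {
    bad <- setdiff(genes, rownames(prof))
    if (length(bad)) stop("unknown gene id: ", paste(bad, collapse = ", "))
    prof <- prof[genes, , drop = FALSE]
  }
  sds <- apply(prof, 1L, stats::sd)
  const <- sds == 0
  if (any(const)) {
    warning(sum(const), " constant profile(s) dropped: ",
            paste(utils::head(rownames(prof)[const], 5L), collapse = ", "),
            if (sum(const) > 5L) ", ..." else "")
    prof <- prof[!const, , drop = FALSE]
    sds <- sds[!const]
  }
  (prof - rowMeans(prof)) / sds
}

# squared Euclidean distances between rows of X (n x d) and rows of V (c x d)
.sqdist <- function(X, V) {
  outer(rowSums(X^2), rep(1, nrow(V))) +
    outer(rep(1, nrow(X)), rowSums(V^2)) - 2 * tcrossprod(X, V)
}

# k-means++-style seeding: first centroid uniform, then each next centroid
# drawn with probability proportional to squared distance to the nearest
# centroid chosen so far
.seed_centroids <- function(X, c) {
  n <- nrow(X)
  idx <- integer(c)
  idx[1L] <- sample.int(n, 1L)
  if (c > 1L) {
    d2 <- rowSums((X - rep(X[idx[1L], ], each = n))^2)
    for (k in 2L:c) {
      prob <- if (sum(d2) > 0) d2 else rep(1, n)
      idx[k] <- sample.int(n, 1L, prob = prob)
      d2 <- pmin(d2, rowSums((X - rep(X[idx[k], ], each = n))^2))
    }
  }
  X[idx, , drop = FALSE]
}

.fcm_once <- function(X, c, m, tol, max_iter) {
  V <- .seed_centroids(X, c)
  e <- 1 / (m - 1)
  trace <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    D2 <- pmax(.sqdist(X, V), 0)
    W <- D2^(-e)
    # profiles sitting exactly on a centroid get crisp membership there
    zero <- rowSums(D2 == 0) > 0 | !is.finite(rowSums(W))
    U <- W / rowSums(W)
    if (any(zero)) {
      U[zero, ] <- 0
      U[cbind(which(zero), max.col(-D2[zero, , drop = FALSE],
                                   ties.method = "first"))] <- 1
    }
    Um <- U^m
    trace[it] <- sum(Um * D2)
    V_new <- crossprod(Um, X) / colSums(Um)
    delta <- max(abs(V_new - V))
    V <- V_new
    if (delta < tol) { converged <- TRUE; break }
  }
  list(centroids = V, membership = U, objective = trace[length(trace)],
       objective_trace = trace, iterations = length(trace),
       converged = converged)
}

#' Fuzzy c-means clustering of standardized profiles
#'
#' Soft partitioning by the fuzzy c-means algorithm with Euclidean
#' distance: memberships `u_ik = 1 / sum_j (d_ik / d_jk)^(2/(m-1))` and
#' centroids `v_k = sum_i u_ik^m x_i / sum_i u_ik^m` are updated
#' alternately until the maximum centroid change falls below `tol`. The
#' objective `J = sum_ik u_ik^m d_ik^2` is non-increasing across
#' iterations. Centroids are seeded from data rows (k-means++ style) under
#' the given seed; with `nstart > 1` the run with the lowest final
#' objective is kept. Ties in the hard assignment go to the lowest cluster
#' index.
#'
#' @param profiles Numeric matrix (genes x stages), typically from
#'   [standardize_profiles()].
#' @param c Number of clusters (>= 1, <= number of profiles).
#' @param m Fuzzification parameter, > 1.
#' @param seed Integer seed for centroid seeding.
#' @param tol Convergence tolerance on centroid change (default 1e-6).
#' @param max_iter Iteration cap (default 200).
#' @param nstart Number of random restarts (default 1).
#' @return An object of class `fcm_fit`: list with `c`, `m`, `centroids`
#'   (c x stages), `membership` (genes x c, rows summing to 1),
#'   `objective`, `objective_trace`, `iterations`, `converged` and
#'   `cluster` (hard assignment by maximal membership).
#' @export
fcm_cluster <- function(profiles, c, m, seed = 1L, tol = 1e-6,
                        max_iter = 200L, nstart = 1L) {
  if (!is.matrix(profiles) || !is.numeric(profiles)) {
    stop("`profiles` must be a numeric matrix")
  }
  c <- as.integer(c)
  if (c < 1L) stop("c must be >= 1")
  if (c > nrow(profiles)) stop("c exceeds the number of profiles")
  if (m <= 1) stop("m must be > 1")
  set.seed(as.integer(seed))
  best <- NULL
  for (run in seq_len(max(1L, as.integer(nstart)))) {
    if (c == 1L) {
      V <- matrix(colMeans(profiles), 1L, ncol(profiles))
      D2 <- pmax(.sqdist(profiles, V), 0)
      fit <- list(centroids = V,
                  membership = matrix(1, nrow(profiles), 1L),
                  objective = sum(D2), objective_trace = sum(D2),
                  iterations = 1L, converged = TRUE)
    } else {
      fit <- .fcm_once(profiles, c, m, tol, max_iter)
    }
    if (is.null(best) || fit$objective < best$objective) best <- fit
  }
  dimnames(best$centroids) <- list(paste0("C", seq_len(c)), colnames(profiles))
  dimnames(best$membership) <- list(rownames(profiles), paste0("C", seq_len(c)))
  best$cluster <- stats::setNames(
    max.col(best$membership, ties.method = "first"), rownames(profiles))
  best$c <- c; best$m <- m
  class(best) <- "fcm_fit"
  best
}

#' @export
print.fcm_fit <- function(x, ...) {
  cat("Fuzzy c-means fit: c = ", x$c, ", m = ", format(x$m), "\n", sep = "")
  cat(nrow(x$membership), " profiles over ", ncol(x$centroids),
      " stages; ", x$iterations, " iterations (",
      if (x$converged) "converged" else "iteration cap reached", ")\n",
      sep = "")
  cat("objective J = ", format(x$objective), "; cluster sizes: ",
      paste(tabulate(x$cluster, x$c), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Data-driven selection of the FCM cluster number and fuzzifier
#'
#' Two diagnostics select the parameters:
#'
#' * **Fuzzifier m** — each candidate is evaluated on structure-destroyed
#'   data (every profile's stage values independently permuted). The
#'   chosen m is the smallest candidate for which the randomized data
#'   yield near-uniform memberships (mean maximal membership within
#'   `uniform_margin` of the uniform value 1/c), so that apparent clusters
#'   cannot arise from noise alone, while real structure can still
#'   concentrate memberships.
#' * **Cluster number c** — for each candidate c the minimum pairwise
#'   centroid distance D(c) is recorded. Once c exceeds the number of
#'   genuine patterns, surplus centroids split existing clusters and D(c)
#'   collapses; the chosen c is the largest candidate whose D(c) stays
#'   above `threshold` (by default the geometric midpoint
#'   `sqrt(max(D) * min(D))` of the observed curve, which sits between the
#'   separated and the collapsed regime).
#'
#' @param profiles Standardized profiles matrix.
#' @param c_range Integer candidates for c (default 2:15).
#' @param m_candidates Numeric candidates for m (default
#'   `c(1.1, 1.25, 1.5, 1.75, 2, 2.5, 3)`).
#' @param seed Integer seed.
#' @param nstart Restarts per FCM fit during the c scan (default 2).
#' @param threshold Collapse threshold for D(c); `NULL` (default) uses the
#'   geometric midpoint rule.
#' @param uniform_margin Fraction of the gap between 1/c and 1 tolerated
#'   above the uniform membership level (default 0.1).
#' @return List with `c`, `m` and `diagnostics` (the m and c curves and
#'   the threshold used).
#' @export
select_parameters <- function(profiles, c_range = 2:15,
                              m_candidates = c(1.1, 1.25, 1.5, 1.75, 2, 2.5, 3),
                              seed = 1L, nstart = 2L, threshold = NULL,
                              uniform_margin = 0.1) {
  if (!length(c_range) || !length(m_candidates)) {
    stop("empty candidate range")
  }
  c_range <- sort(unique(as.integer(c_range)))
  if (min(c_range) < 2L || max(c_range) > nrow(profiles) - 1L) {
    stop("c_range must lie within [2, number of profiles - 1]")
  }
  m_candidates <- sort(m_candidates)
  set.seed(as.integer(seed))

  # --- fuzzifier: randomized-data control ---------------------------------
  perm <- t(apply(profiles, 1L, sample))
  c_ref <- as.integer(round(stats::median(c_range)))
  uniform_cut <- 1 / c_ref + uniform_margin * (1 - 1 / c_ref)
  mean_max <- numeric(length(m_candidates))
  for (i in seq_along(m_candidates)) {
    fit <- fcm_cluster(perm, c_ref, m_candidates[i],
                       seed = sample.int(.Machine$integer.max, 1L))
    mean_max[i] <- mean(apply(fit$membership, 1L, max))
  }
  ok <- mean_max <= uniform_cut
  m_sel <- if (any(ok)) m_candidates[which(ok)[1L]] else {
    warning("no fuzzifier candidate uniformized the randomized data; ",
            "using the largest candidate")
    m_candidates[length(m_candidates)]
  }

  # --- cluster number: minimum centroid distance --------------------------
  min_dist <- numeric(length(c_range))
  for (i in seq_along(c_range)) {
    fit <- fcm_cluster(profiles, c_range[i], m_sel,
                       seed = sample.int(.Machine$integer.max, 1L),
                       nstart = nstart)
    min_dist[i] <- min(stats::dist(fit$centroids))
  }
  if (is.null(threshold)) {
    threshold <- sqrt(max(min_dist) * max(min(min_dist), 1e-12))
  }
  above <- min_dist > threshold
  c_sel <- if (any(above)) max(c_range[above]) else c_range[which.max(min_dist)]

  list(
    c = c_sel, m = m_sel,
    diagnostics = list(
      m_curve = data.frame(m = m_candidates,
                           randomized_mean_max_membership = mean_max,
                           uniform_cut = uniform_cut),
      c_curve = data.frame(c = c_range, min_centroid_distance = min_dist),
      threshold = threshold
    )
  )
}
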