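# Independent brute-force oracles used to cross-check the vectorised
# implementations on small instances.

# connectivity by explicit double loop
brute_connectivity <- function(a) {
  n <- nrow(a)
  k <- numeric(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j) k[i] <- k[i] + a[i, j]
    }
  }
  names(k) <- rownames(a)
  k
}

# topological overlap by explicit triple loop
brute_tom <- function(a) {
  n <- nrow(a)
  k <- brute_connectivity(a)
  omega <- diag(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      l <- 0
      for (u in seq_len(n)) {
        if (u != i && u != j) l <- l + a[i, u] * a[u, j]
      }
      omega[i, j] <- (l + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
    }
  }
  omega
}

# Benjamini-Hochberg by the literal step-up definition:
# adj_(i) = min_{j >= i} p_(j) * m / j, in sorted order, capped at 1
brute_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  adj <- numeric(m)
  for (i in seq_len(m)) {
    adj[i] <- min(1, min(ps[i:m] * m / (i:m)))
  }
  out <- numeric(m)
  out[ord] <- adj
  out
}

# all permutations of 1..n as rows of a matrix
combinat_perms <- function(n) {
  if (n == 1) return(matrix(1L))
  sub <- combinat_perms(n - 1L)
  out <- matrix(0L, 0L, n)
  for (i in seq_len(n)) {
    rest <- setdiff(seq_len(n), i)
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub))))
  }
  unname(out)
}

# a random symmetric adjacency with zero diagonal, entries in [0, 1]
random_adjacency <- function(n) {
  a <- matrix(stats::runif(n * n), n)
  a <- (a + t(a)) / 2
  diag(a) <- 0
  dimnames(a) <- list(paste0("g", seq_len(n)), paste0("g", seq_len(n)))
  a
}

# small expression set with exactly known values
toy_expression <- function(values, stages, baseline = stages[[1L]]) {
  m <- as.matrix(values)
  if (is.null(rownames(m))) rownames(m) <- paste0("g", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- paste0("s", seq_len(ncol(m)))
  expression_set(m, stats::setNames(stages, colnames(m)), baseline)
}
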