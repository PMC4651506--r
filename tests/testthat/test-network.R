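# two genes with an exact correlation r, plus optional extras
exact_cor_pair <- function(r, n = 12) {
  x <- scale(seq_len(n))[, 1]
  z <- stats::resid(stats::lm(rnorm(n) ~ x))
  z <- z / sqrt(sum(z^2) / (n - 1))
  y <- r * x + sqrt(1 - r^2) * z
  rbind(g1 = x, g2 = y)
}

test_that("adjacency follows the printed power rule |r^2|^beta", {
  set.seed(41)
  m <- exact_cor_pair(0.5)
  colnames(m) <- paste0("s", 1:12)
  adj <- pearson_adjacency(m, beta = 3)
  expect_equal(adj$correlation["g1", "g2"], 0.5, tolerance = 1e-12)
  expect_equal(adj$adjacency["g1", "g2"], 0.25^3, tolerance = 1e-12)
  expect_equal(diag(adj$adjacency), c(g1 = 0, g2 = 0))
  # r = 1 and r = -1 give adjacency 1 under any beta
  perfect <- rbind(a = 1:6, b = 2 * (1:6) + 3, d = -(1:6))
  colnames(perfect) <- paste0("s", 1:6)
  padj <- pearson_adjacency(perfect, beta = 4)$adjacency
  expect_equal(padj["a", "b"], 1, tolerance = 1e-12)
  expect_equal(padj["a", "d"], 1, tolerance = 1e-12)
  # conventional dialect: |r|^beta
  conv <- pearson_adjacency(m, beta = 3, dialect = "conventional")
  expect_equal(conv$adjacency["g1", "g2"], 0.5^3, tolerance = 1e-12)
  # constant genes are excluded with a warning
  withconst <- rbind(m, flat = rep(1, 12))
  expect_warning(out <- pearson_adjacency(withconst, 2), "constant")
  expect_false("flat" %in% rownames(out$adjacency))
})

test_that("connectivity equals the brute-force row sum", {
  set.seed(42)
  for (i in 1:3) {
    a <- random_adjacency(10)
    expect_equal(connectivity(a), brute_connectivity(a), tolerance = 1e-12)
  }
  # complete graph: k = n - 1 everywhere
  ones <- matrix(1, 7, 7); diag(ones) <- 0
  expect_equal(unname(connectivity(ones)), rep(6, 7))
  expect_equal(unname(connectivity(diag(0, 4))), rep(0, 4))
})

test_that("scale-free fit is exact on an exact power law", {
  # counts proportional to k^-2 at bin-aligned values 1, 2, 3, 6
  k <- rep(c(1, 2, 3, 6), times = c(36, 9, 4, 1))
  fit <- scale_free_fit(k, n_bins = 10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
  expect_equal(fit$slope, -2, tolerance = 1e-10)
  expect_error(scale_free_fit(rep(2, 10)), "single bin")
  expect_error(scale_free_fit(c(1, 1, 1, 10), n_bins = 2), "3 non-empty")
})

test_that("scale-free R^2 separates modular from unstructured networks", {
  set.seed(43)
  sim <- generate_expression_matrix(config = synthetic_module_config(seed = 43))
  pick <- suppressWarnings(pick_soft_threshold(sim$expr))
  expect_true(any(pick$r_squared >= 0.8, na.rm = TRUE))
  # mean connectivity strictly decreases with beta
  expect_true(all(diff(pick$mean_connectivity) < 0))
  # an unstructured (null) network never fits as well at the chosen beta
  nullsim <- generate_expression_matrix(config = synthetic_config(
    n_genes = 1000, frac_null = 1, seed = 44))
  i <- match(pick$chosen_beta, pick$beta_candidates)
  nullfit <- scale_free_fit(
    connectivity(pearson_adjacency(nullsim$expr, pick$chosen_beta)))
  expect_gt(pick$r_squared[i], nullfit$r_squared)
  # single candidate: returned as-is
  single <- suppressWarnings(pick_soft_threshold(sim$expr, beta_candidates = 6))
  expect_equal(single$chosen_beta, 6)
})

test_that("TOM matches hand values and the brute-force oracle", {
  tri <- matrix(1, 3, 3); diag(tri) <- 0
  dimnames(tri) <- list(paste0("g", 1:3), paste0("g", 1:3))
  omega <- tom_similarity(tri)$omega
  expect_equal(omega["g1", "g2"], 1)   # (1 + 1) / (2 + 1 - 1)
  # disconnected genes with no shared neighbours have overlap 0
  iso <- diag(0, 4)
  iso[1, 2] <- iso[2, 1] <- 0.9
  iso[3, 4] <- iso[4, 3] <- 0.8
  om <- tom_similarity(iso)$omega
  expect_equal(om[1, 3], 0)
  set.seed(45)
  for (i in 1:5) {
    a <- random_adjacency(8)
    t1 <- tom_similarity(a)$omega
    expect_equal(t1, brute_tom(a), tolerance = 1e-12,
                 ignore_attr = TRUE)
    # fuzz invariants: symmetry and range
    expect_equal(t1, t(t1), tolerance = 1e-12)
    expect_true(all(t1 >= 0 & t1 <= 1))
  }
})

test_that("module detection separates perfect blocks and respects the cut", {
  # two blocks of identical profiles, zero cross-correlation
  set.seed(46)
  p1 <- sin(seq(0, 2 * pi, length.out = 9))
  p2 <- stats::resid(stats::lm(rnorm(9) ~ p1))
  m <- rbind(matrix(rep(p1, 12), 12, byrow = TRUE),
             matrix(rep(p2, 12), 12, byrow = TRUE))
  m <- m + matrix(rnorm(24 * 9, sd = 1e-4), 24)
  rownames(m) <- paste0("g", 1:24); colnames(m) <- paste0("s", 1:9)
  adj <- pearson_adjacency(m, beta = 3)
  mods <- detect_modules(tom_similarity(adj), cut_height = 0.94,
                         min_module_size = 5)
  expect_equal(mods$n_modules, 2)
  expect_equal(unname(mods$sizes), c(12, 12), ignore_attr = TRUE)
  # blocks stay intact
  expect_equal(length(unique(mods$modules[1:12])), 1)
  expect_equal(length(unique(mods$modules[13:24])), 1)
  expect_true(all(mods$modules[1:12] != mods$modules[13:24]))
  # labels are size-ordered colour names
  expect_setequal(unique(mods$modules), c("turquoise", "blue"))
  # cut at 0: nothing merges, everything is background
  expect_warning(none <- detect_modules(tom_similarity(adj), cut_height = 0,
                                        min_module_size = 5), "background")
  expect_equal(none$n_modules, 0)
})

test_that("module detection is invariant to gene input order", {
  skip_if_not_installed("mclust")
  sim <- generate_expression_matrix(config = synthetic_module_config(
    n_genes = 300, seed = 47))
  adj <- pearson_adjacency(sim$expr, beta = 6)
  m1 <- detect_modules(tom_similarity(adj), min_module_size = 10)
  set.seed(48)
  perm <- sample(nrow(sim$expr$values))
  adj2 <- pearson_adjacency(sim$expr$values[perm, ], beta = 6)
  m2 <- detect_modules(tom_similarity(adj2), min_module_size = 10)
  common <- names(m1$modules)
  expect_equal(
    mclust::adjustedRandIndex(m1$modules[common], m2$modules[common]), 1)
})

test_that("signed scaled connectivity splits by correlation sign", {
  # one gene anti-correlated with every partner has zero positive K
  m <- rbind(g1 = 1:8, g2 = 2 * (1:8), g3 = -(1:8) + 20)
  m <- m + matrix(rnorm(24, sd = 1e-5), 3)
  colnames(m) <- paste0("s", 1:8)
  adj <- pearson_adjacency(m, beta = 2)
  hubs <- signed_scaled_connectivity(
    adj, stats::setNames(rep("turquoise", 3), rownames(m)))
  g3 <- hubs[hubs$gene_id == "g3", ]
  expect_equal(g3$k_positive, 0, tolerance = 1e-6)
  expect_gt(g3$k_negative, 0)
  expect_equal(max(hubs$scaled_k_positive), 1)
  expect_equal(max(hubs$scaled_k_negative), 1)
})

test_that("planted modules and hubs are recovered on generator output", {
  skip_if_not_installed("mclust")
  for (s in 1:3) {
    sim <- generate_expression_matrix(config = synthetic_module_config(seed = s))
    tr <- sim$truth$genes
    net <- suppressWarnings(build_network(sim$expr))
    expect_equal(net$modules$n_modules, 5)
    ari <- mclust::adjustedRandIndex(net$modules$modules[tr$gene_id],
                                     tr$module)
    expect_gte(ari, 0.75)
    # scaled K tops out at exactly 1 per module, both signs
    h <- net$hubs[net$hubs$module != "background", ]
    for (mod in unique(h$module)) {
      expect_identical(max(h$scaled_k_positive[h$module == mod]), 1)
      expect_identical(max(h$scaled_k_negative[h$module == mod]), 1)
    }
    # the planted hub is the top positively connected gene of its module
    tops <- vapply(split(h, h$module),
                   function(x) x$gene_id[which.max(x$scaled_k_positive)],
                   character(1))
    expect_true(all(tops %in% tr$gene_id[tr$is_hub]))
    # hub rule: scaled K > 0.9 and > 10 connected nodes
    expect_true(all(
      (pmax(h$scaled_k_positive, h$scaled_k_negative) > 0.9 &
         h$connected_node_count > 10) == h$is_hub))
  }
})
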