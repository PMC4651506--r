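toy_ct <- function() {
  # 2 stages x 2 replicates; references flat at CT 25
  ct <- rbind(
    tgt  = c(30, 30, 29, 29),
    ref1 = c(25, 25, 25, 25),
    ref2 = c(25, 25, 25, 25))
  colnames(ct) <- c("D12_r1", "D12_r2", "D15_r1", "D15_r2")
  ct
}

test_that("2^-ddCT reproduces hand-computed cases", {
  stages <- stats::setNames(c("D12", "D12", "D15", "D15"), colnames(toy_ct()))
  rel <- delta_delta_ct(toy_ct(), "tgt", c("ref1", "ref2"), "D12", stages)
  # baseline samples sit at the calibrator: relative expression 1
  expect_equal(unname(rel[1:2]), c(1, 1))
  # dCT = 4 at D15 vs baseline mean dCT = 5: 2^-(4-5) = 2
  expect_equal(unname(rel[3:4]), c(2, 2))
  # geometric mean of baseline relative expression is exactly 1
  expect_equal(exp(mean(log(rel[1:2]))), 1)
})

test_that("ddCT is invariant to sample-wide efficiency shifts", {
  stages <- stats::setNames(c("D12", "D12", "D15", "D15"), colnames(toy_ct()))
  base <- delta_delta_ct(toy_ct(), "tgt", c("ref1", "ref2"), "D12", stages)
  shifted <- toy_ct()
  shifted[, "D15_r1"] <- shifted[, "D15_r1"] + 3  # shifts target AND refs
  expect_equal(delta_delta_ct(shifted, "tgt", c("ref1", "ref2"), "D12", stages),
               base, tolerance = 1e-12)
})

test_that("ddCT input validation names the offender", {
  stages <- stats::setNames(c("D12", "D12", "D15", "D15"), colnames(toy_ct()))
  bad <- toy_ct(); bad["tgt", "D15_r2"] <- NA
  expect_error(delta_delta_ct(bad, "tgt", c("ref1", "ref2"), "D12", stages),
               "tgt.*D15_r2")
  expect_error(delta_delta_ct(toy_ct(), "ref1", c("ref1", "ref2"), "D12",
                              stages), "reference")
  expect_error(delta_delta_ct(toy_ct(), "nope", c("ref1", "ref2"), "D12",
                              stages), "nope")
})

test_that("relative expression round-trips noiseless synthetic CTs", {
  sim <- generate_expression_matrix(config = synthetic_config(
    n_genes = 6, frac_null = 0, noise_sd = 0, seed = 51))
  ct <- generate_qpcr_ct(sim$expr, ct_noise_sd = 0)
  rel <- relative_expression(ct)
  v <- sim$expr$values
  for (g in rownames(v)) {
    expected <- 2^(v[g, ] - mean(v[g, sim$expr$stages == "D12"]))
    expect_equal(rel$relative_expression[g, ], expected, tolerance = 1e-9)
  }
  # baseline geometric mean is 1 for every gene
  basecols <- rel$stages == "D12"
  gm <- exp(rowMeans(log(rel$relative_expression[, basecols])))
  expect_equal(unname(gm), rep(1, 6), tolerance = 1e-12)
})

test_that("correlation network keeps exact relationships with signs", {
  x <- 1:18
  m <- rbind(gA = 2^x, gB = 2^(x + 3), gC = 2^(-x + 20))
  colnames(m) <- paste0("s", 1:18)
  edges <- correlation_network(m, alpha = 0.05)
  ab <- edges[edges$gene_a == "gA" & edges$gene_b == "gB", ]
  expect_equal(ab$r, 1, tolerance = 1e-12)
  expect_equal(ab$sign, "positive")
  ac <- edges[edges$gene_a == "gA" & edges$gene_b == "gC", ]
  expect_equal(ac$r, -1, tolerance = 1e-12)
  expect_equal(ac$sign, "negative")
  # each unordered pair appears exactly once
  key <- apply(edges[, c("gene_a", "gene_b")], 1,
               function(z) paste(sort(z), collapse = "|"))
  expect_equal(anyDuplicated(key), 0)
  expect_equal(attr(edges, "n_pairs_tested"), 3)
})

test_that("correlation p-values match the reference test", {
  set.seed(52)
  m <- matrix(rnorm(5 * 18), 5)
  rownames(m) <- paste0("g", 1:5); colnames(m) <- paste0("s", 1:18)
  edges <- correlation_network(2^m, alpha = 1.01)  # keep all pairs
  for (i in seq_len(nrow(edges))) {
    ref <- stats::cor.test(m[edges$gene_a[i], ], m[edges$gene_b[i], ])
    expect_equal(edges$r[i], unname(ref$estimate), tolerance = 1e-10)
    expect_equal(edges$p_value[i], ref$p.value, tolerance = 1e-10)
  }
})

test_that("correlation network controls false edges on independent genes", {
  set.seed(53)
  frac <- replicate(20, {
    m <- 2^matrix(rnorm(10 * 18), 10,
                  dimnames = list(paste0("g", 1:10), paste0("s", 1:18)))
    nrow(correlation_network(m)) / choose(10, 2)
  })
  se <- sd(frac) / sqrt(length(frac))
  expect_lte(mean(frac), 0.05 + 2 * se)
})

test_that("constant genes are excluded from the correlation network", {
  m <- rbind(gA = 2^(1:10), gB = 2^(10:1), flat = rep(1, 10))
  colnames(m) <- paste0("s", 1:10)
  expect_warning(edges <- correlation_network(m), "constant")
  expect_false("flat" %in% c(edges$gene_a, edges$gene_b))
})

test_that("planted sign structure survives the ddCT round trip", {
  # hub + same-module partners: positive mutual correlation; an
  # anti-regulated gene flips sign
  sim <- generate_expression_matrix(config = synthetic_config(
    n_genes = 8, frac_null = 0, noise_sd = 0, seed = 54))
  expr <- sim$expr
  expr$values["g2", ] <- expr$values["g1", ] * 1  # duplicate archetype
  expr$values["g3", ] <- 16 - expr$values["g1", ] + 16  # mirrored
  sub <- subset_expression(expr, genes = c("g1", "g2", "g3"))
  ct <- generate_qpcr_ct(sub, ct_noise_sd = 0)
  edges <- correlation_network(relative_expression(ct))
  e12 <- edges[edges$gene_a == "g1" & edges$gene_b == "g2", ]
  e13 <- edges[edges$gene_a == "g1" & edges$gene_b == "g3", ]
  expect_equal(e12$sign, "positive")
  expect_equal(e13$sign, "negative")
})
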