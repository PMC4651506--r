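test_that("zero-noise archetype genes follow their stage curve exactly", {
  cfg <- synthetic_config(n_genes = 16, frac_null = 0, noise_sd = 0, seed = 1)
  sim <- generate_expression_matrix(config = cfg)
  expr <- sim$expr
  # replicates within a stage are identical when noise_sd = 0
  for (s in stage_levels(expr)) {
    block <- expr$values[, expr$stages == s, drop = FALSE]
    expect_true(all(block == block[, 1]))
  }
  # and the stage profile is the standardized archetype curve times effect
  A <- archetype_profiles(6, 8)
  prof <- stage_means(expr)
  g1 <- prof["g01", ] - mean(prof["g01", ])
  expect_equal(unname(g1), unname(A[1, ] - mean(A[1, ])), tolerance = 1e-12)
})

test_that("frac_null = 1 yields only null genes with no planted structure", {
  sim <- generate_expression_matrix(config = synthetic_config(
    n_genes = 50, frac_null = 1, seed = 2))
  expect_true(all(sim$truth$genes$archetype == "null"))
  expect_true(all(sim$truth$genes$module == "background"))
  expect_false(any(sim$truth$genes$is_hub))
  expect_false(any(sim$truth$deg_flags))
})

test_that("same seed reproduces bit-identical data, different seeds differ", {
  a <- generate_expression_matrix(config = synthetic_module_config(
    n_genes = 100, seed = 5))
  b <- generate_expression_matrix(config = synthetic_module_config(
    n_genes = 100, seed = 5))
  d <- generate_expression_matrix(config = synthetic_module_config(
    n_genes = 100, seed = 6))
  expect_identical(a$expr$values, b$expr$values)
  expect_false(identical(a$expr$values, d$expr$values))
})

test_that("within-module correlation is calibrated to the configured target", {
  cfg <- synthetic_module_config(seed = 1)
  sim <- generate_expression_matrix(config = cfg)
  tr <- sim$truth$genes
  for (m in unique(tr$module[tr$module != "background"])) {
    g <- tr$gene_id[tr$module == m]
    r <- stats::cor(t(sim$expr$values[g, ]))
    mean_abs_r <- mean(abs(r[upper.tri(r)]))
    expect_lt(abs(mean_abs_r - cfg$within_module_correlation), 0.1)
  }
})

test_that("planted truth is internally consistent", {
  sim <- generate_expression_matrix(config = synthetic_config(
    n_genes = 300, frac_null = 0.4, module_sizes = c(40, 40), seed = 3))
  tr <- sim$truth$genes
  # every hub belongs to a non-background module
  expect_true(all(tr$module[tr$is_hub] != "background"))
  # null-archetype genes are never flagged differential
  nulls <- tr$gene_id[tr$archetype == "null"]
  expect_false(any(sim$truth$deg_flags[nulls, ]))
  # archetype and module genes are flagged at some stage
  struct <- tr$gene_id[tr$archetype != "null"]
  expect_true(all(rowSums(sim$truth$deg_flags[struct, , drop = FALSE]) > 0))
})

test_that("invalid configurations are rejected", {
  expect_error(synthetic_config(n_genes = 100, frac_null = 0.5,
                                module_sizes = c(40, 40)),
               "exceed")
  expect_error(synthetic_config(within_module_correlation = 1.2), "between")
  expect_error(synthetic_config(within_module_correlation = 0.9,
                                loading_spread = 0.1), "spread")
  expect_error(study_design(stage_labels = "D12"), "2 distinct")
  expect_error(study_design(replicates_per_stage = 1), ">= 2")
  expect_error(study_design(baseline_stage = "D999"), "baseline")
})

test_that("probe-level expansion is exact in the noiseless limits", {
  sim <- generate_expression_matrix(config = synthetic_config(
    n_genes = 10, frac_null = 0, seed = 4))
  # zero probe effect and noise: all probe rows equal the gene row
  pl <- generate_probe_level(sim$expr, probes_per_gene = 3,
                             probe_effect_sd = 0, probe_noise_sd = 0)
  for (g in rownames(sim$expr$values)) {
    block <- pl$probes[pl$probe_to_gene == g, , drop = FALSE]
    expect_equal(block, matrix(sim$expr$values[g, ], 3, ncol(block),
                               byrow = TRUE, dimnames = dimnames(block)),
                 tolerance = 0)
  }
  # single probe: identity
  one <- generate_probe_level(sim$expr, probes_per_gene = 1,
                              probe_effect_sd = 0.5, probe_noise_sd = 0)
  expect_equal(unname(one$probes), unname(sim$expr$values), tolerance = 1e-12)
})

test_that("median polish of generated probes recovers the gene matrix", {
  sim <- generate_expression_matrix(config = synthetic_config(
    n_genes = 20, frac_null = 0.5, seed = 5))
  pl <- generate_probe_level(sim$expr, probes_per_gene = 11,
                             probe_effect_sd = 0.5, probe_noise_sd = 0.05,
                             seed = 6)
  back <- median_polish_summarize(pl$probes, pl$probe_to_gene)
  expect_equal(dim(back), dim(sim$expr$values))
  # per-cell summarization error stays within a few multiples of the
  # probe noise sd
  expect_lt(max(abs(back - sim$expr$values)), 3 * 0.05)
  expect_lt(mean(abs(back - sim$expr$values)), 0.05)
})

test_that("synthetic CT tables respect the CT scale", {
  sim <- generate_expression_matrix(config = synthetic_config(
    n_genes = 4, frac_null = 1, noise_sd = 0, seed = 7))
  ct0 <- generate_qpcr_ct(sim$expr, ct_noise_sd = 0)
  # constant gene, no noise: identical CT everywhere
  expect_equal(diff(range(ct0$ct["g1", ])), 0, tolerance = 0)
  # one extra log2 unit of expression = one cycle lower CT
  expr2 <- sim$expr
  expr2$values["g2", ] <- expr2$values["g1", ] + 1
  ct2 <- generate_qpcr_ct(expr2, ct_noise_sd = 0)
  expect_equal(unname(ct2$ct["g2", ] - ct2$ct["g1", ]),
               rep(-1, ncol(ct2$ct)), tolerance = 1e-12)
  expect_error(
    generate_qpcr_ct(toy_expression(matrix(1, 1, 6,
                                           dimnames = list("RPL7", NULL)),
                                    rep(c("D12", "D15"), each = 3))),
    "overlap")
})
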