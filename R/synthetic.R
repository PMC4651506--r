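#' Study design for a staged expression experiment
#'
#' Describes the sampling layout: ordered gestational stages, the number of
#' biological replicates per stage, and the baseline (calibrator) stage all
#' later stages are compared against. The default mirrors a six-stage porcine
#' gestation series (days 12, 15, 30, 60, 90 and 114) with three animals per
#' stage, i.e. 18 arrays in total.
#'
#' @param stage_labels Ordered character vector of stage identifiers (>= 2).
#' @param replicates_per_stage Positive integer >= 2.
#' @param baseline_stage One of `stage_labels`; defaults to the first.
#' @return A list of class `study_design`.
#' @export
study_design <- function(stage_labels = c("D12", "D15", "D30", "D60", "D90", "D114"),
                         replicates_per_stage = 3L,
                         baseline_stage = stage_labels[[1L]]) {
  stage_labels <- as.character(stage_labels)
  if (length(stage_labels) < 2L || anyDuplicated(stage_labels)) {
    stop("need >= 2 distinct stage labels")
  }
  replicates_per_stage <- as.integer(replicates_per_stage)
  if (is.na(replicates_per_stage) || replicates_per_stage < 2L) {
    stop("replicates_per_stage must be an integer >= 2")
  }
  if (!baseline_stage %in% stage_labels) {
    stop("baseline_stage must be one of stage_labels")
  }
  structure(
    list(stage_labels = stage_labels,
         replicates_per_stage = replicates_per_stage,
         baseline_stage = baseline_stage),
    class = "study_design"
  )
}

#' Temporal archetype profiles
#'
#' Eight canonical gestational expression patterns, standardized to mean 0
#' and standard deviation 1 across stages: a mid-gestation peak, a monotone
#' decline, a post-mid-gestation drop, a gradual rise ending in a terminal
#' spike, a sharp early drop from a high baseline, and the sign-complements
#' of the first three. These shapes echo the cluster patterns typically seen
#' in endometrial time courses and are deliberately well separated in
#' standardized-profile space so that cluster-number selection has a
#' recoverable answer.
#'
#' @param n_stages Number of stages the curves are evaluated at (>= 4).
#' @param n_archetypes How many of the 8 curves to return (1..8).
#' @return Matrix `n_archetypes x n_stages`; rows have mean 0 and sd 1.
#' @export
archetype_profiles <- function(n_stages = 6L, n_archetypes = 8L) {
  n_stages <- as.integer(n_stages)
  n_archetypes <- as.integer(n_archetypes)
  if (n_stages < 4L) stop("need >= 4 stages for distinguishable archetypes")
  if (n_archetypes < 1L || n_archetypes > 8L) {
    stop("n_archetypes must be between 1 and 8")
  }
  t <- seq(0, 1, length.out = n_stages)
  base <- rbind(
    mid_peak    = sin(pi * t),
    decline     = 1 - t,
    early_high  = as.numeric(t <= 0.5),
    late_spike  = 1.5 * t^6,
    sharp_drop  = (1 - t)^6
  )
  shapes <- rbind(base,
                  mid_valley = -base["mid_peak", ],
                  rise       = -base["decline", ],
                  late_high  = -base["early_high", ])
  shapes <- shapes[seq_len(n_archetypes), , drop = FALSE]
  t(apply(shapes, 1L, function(x) (x - mean(x)) / stats::sd(x)))
}

#' Configuration of the synthetic expression generator
#'
#' Controls how many genes are generated and how the planted structure is
#' allocated among them. Genes fall into three disjoint groups:
#' temporal-archetype genes (differential, following one of the
#' [archetype_profiles()] curves), co-expression module genes (driven by a
#' shared latent stage profile, orthogonal across modules), and null genes
#' (i.i.d. noise around a constant level). The first gene of every module is
#' its designated hub and receives 0.25x the idiosyncratic noise of the
#' other members, which makes its expected intramodular connectivity
#' maximal without altering the module correlation structure.
#'
#' @param n_genes Total number of genes.
#' @param frac_null Fraction of genes that are pure-noise nulls, in `[0, 1]`.
#' @param n_archetypes Number of temporal archetypes used (default 8).
#' @param module_sizes Integer vector of planted module sizes (possibly
#'   empty). `sum(module_sizes)` must not exceed `n_genes * (1 - frac_null)`;
#'   remaining non-null genes become archetype genes.
#' @param within_module_correlation Target expected pairwise |r| between
#'   module members, strictly between 0 and 1.
#' @param loading_spread Half-width of the uniform spread of per-gene
#'   latent correlations around `sqrt(within_module_correlation)`. Real
#'   co-expression modules show a gradient of connectivity rather than a
#'   single correlation level; drawing each member's latent correlation
#'   `c_i ~ U(sqrt(rho) - spread, sqrt(rho) + spread)` keeps the expected
#'   pairwise correlation `E[c_i c_j] = rho` while producing the
#'   heavy-tailed connectivity distribution the scale-free soft-threshold
#'   criterion expects. Must satisfy `sqrt(rho) + spread < 1`; set 0 for
#'   homogeneous modules.
#' @param effect_size Log2-scale amplitude of the planted stage curves.
#' @param noise_sd Log2-scale residual standard deviation for archetype and
#'   null genes.
#' @param base_mean,base_sd Mean/sd of the per-gene constant baseline level
#'   (log2 scale).
#' @param seed Integer seed governing all randomness of the generator.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_genes = 2000L,
                             frac_null = 0.5,
                             n_archetypes = 8L,
                             module_sizes = integer(0),
                             within_module_correlation = 0.8,
                             loading_spread = 0.1,
                             effect_size = 1,
                             noise_sd = 0.25,
                             base_mean = 8,
                             base_sd = 1.5,
                             seed = 1L) {
  n_genes <- as.integer(n_genes)
  module_sizes <- as.integer(module_sizes)
  if (n_genes < 1L) stop("n_genes must be positive")
  if (frac_null < 0 || frac_null > 1) stop("frac_null must be in [0, 1]")
  if (length(module_sizes) && any(module_sizes < 1L)) {
    stop("module_sizes must be positive")
  }
  if (sum(module_sizes) > round(n_genes * (1 - frac_null))) {
    stop("module sizes exceed the available non-null genes")
  }
  if (within_module_correlation <= 0 || within_module_correlation >= 1) {
    stop("within_module_correlation must be strictly between 0 and 1")
  }
  if (loading_spread < 0 ||
      sqrt(within_module_correlation) + loading_spread >= 1 ||
      sqrt(within_module_correlation) - loading_spread <= 0) {
    stop("loading_spread must keep sqrt(within_module_correlation) +/- ",
         "spread inside (0, 1)")
  }
  if (noise_sd < 0 || effect_size < 0) stop("noise_sd and effect_size must be >= 0")
  structure(
    list(n_genes = n_genes, frac_null = frac_null,
         n_archetypes = as.integer(n_archetypes),
         module_sizes = module_sizes,
         within_module_correlation = within_module_correlation,
         loading_spread = loading_spread,
         effect_size = effect_size, noise_sd = noise_sd,
         base_mean = base_mean, base_sd = base_sd, seed = as.integer(seed)),
    class = "synthetic_config"
  )
}

#' Default archetype-only configuration
#'
#' The condition set used to exercise the temporal clustering stage: every
#' gene is a differentially expressed gene following one of the 8 default
#' archetype curves (no planted co-expression modules, no nulls).
#'
#' @param n_genes Number of profiles (default 2000).
#' @param noise_sd Residual sd (default 0.25).
#' @param seed Integer seed.
#' @param ... Passed on to [synthetic_config()].
#' @return A `synthetic_config`.
#' @export
synthetic_archetype_config <- function(n_genes = 2000L, noise_sd = 0.25,
                                       seed = 1L, ...) {
  synthetic_config(n_genes = n_genes, frac_null = 0,
                   module_sizes = integer(0), noise_sd = noise_sd,
                   seed = seed, ...)
}

#' Default module-only configuration
#'
#' The condition set used to exercise the co-expression network stage: half
#' the genes are uncorrelated nulls, the other half are split into 5 planted
#' modules of unequal sizes (proportions 0.15/0.30/0.20/0.10/0.25 of the
#' structured pool, echoing the five unequal module sizes seen in real
#' endometrial data), each with a designated hub gene.
#'
#' @param n_genes Total number of genes (default 1000).
#' @param frac_null Fraction of null genes (default 0.5).
#' @param within_module_correlation Target member correlation (default 0.8).
#' @param seed Integer seed.
#' @param ... Passed on to [synthetic_config()].
#' @return A `synthetic_config`.
#' @export
synthetic_module_config <- function(n_genes = 1000L, frac_null = 0.5,
                                    within_module_correlation = 0.8,
                                    seed = 1L, ...) {
  pool <- round(n_genes * (1 - frac_null))
  prop <- c(0.15, 0.30, 0.20, 0.10, 0.25)
  sizes <- floor(prop * pool)
  sizes[1L] <- sizes[1L] + (pool - sum(sizes))
  synthetic_config(n_genes = n_genes, frac_null = frac_null,
                   module_sizes = sizes,
                   within_module_correlation = within_module_correlation,
                   seed = seed, ...)
}

#' Generate a synthetic staged expression matrix with planted truth
#'
#' Produces a log2-scale genes x samples matrix following the study design,
#' plus the ground truth needed to score downstream recovery: the archetype
#' of each gene, its module membership, designated hubs, and per-(gene,
#' stage) true differential-expression flags relative to the baseline stage.
#'
#' Archetype genes follow `base + effect_size * archetype(stage)` plus
#' `N(0, noise_sd^2)` noise. Module genes follow
#' `base + effect_size * latent_m(stage)` plus idiosyncratic noise whose
#' variance is calibrated so the expected pairwise correlation between two
#' ordinary members equals `within_module_correlation`; latent stage
#' profiles are orthogonal polynomial contrasts, so cross-module
#' correlations vanish in expectation. The designated hub of each module
#' receives 0.25x the noise sd of the least-noisy ordinary member, so its
#' expected intramodular connectivity is strictly maximal. Null genes are
#' i.i.d. `N(base, noise_sd^2)`.
#'
#' @param design A [study_design()].
#' @param config A [synthetic_config()].
#' @return A list with elements `expr` (an [expression_set()]) and `truth`
#'   (list with `genes`: data.frame of gene_id/archetype/module/is_hub,
#'   `deg_flags`: logical genes x later-stages matrix, and
#'   `latent_profiles`: the module latent stage curves).
#' @export
generate_expression_matrix <- function(design = study_design(),
                                       config = synthetic_config()) {
  stopifnot(inherits(design, "study_design"),
            inherits(config, "synthetic_config"))
  set.seed(config$seed)
  S <- length(design$stage_labels)
  R <- design$replicates_per_stage
  n <- config$n_genes
  n_modules <- length(config$module_sizes)
  if (n_modules > S - 1L) {
    stop("at most ", S - 1L, " mutually orthogonal modules are possible ",
         "with ", S, " stages")
  }

  n_null <- round(config$frac_null * n)
  n_mod <- sum(config$module_sizes)
  n_arch <- n - n_null - n_mod
  if (n_arch < 0L) stop("module sizes exceed the available non-null genes")

  gene_ids <- sprintf("g%0*d", nchar(n), seq_len(n))
  sample_ids <- paste0(rep(design$stage_labels, each = R), "_r", seq_len(R))
  stage_of_sample <- rep(design$stage_labels, each = R)

  archetype <- rep("null", n)
  module <- rep("background", n)
  is_hub <- logical(n)

  # planted per-gene stage-mean curves (log2 scale, relative to base level)
  curve <- matrix(0, nrow = n, ncol = S)

  if (n_arch > 0L) {
    A <- archetype_profiles(S, config$n_archetypes)
    which_arch <- rep_len(seq_len(config$n_archetypes), n_arch)
    curve[seq_len(n_arch), ] <- config$effect_size * A[which_arch, , drop = FALSE]
    archetype[seq_len(n_arch)] <- paste0("A", which_arch)
  }

  latent <- NULL
  noise_sd_gene <- rep(config$noise_sd, n)
  if (n_modules > 0L) {
    P <- stats::poly(seq_len(S), degree = n_modules)
    latent <- t(unclass(P)) * sqrt(S - 1)   # rows: mean 0, sd 1 across stages
    rownames(latent) <- paste0("M", seq_len(n_modules))
    rho <- config$within_module_correlation
    # a gene with latent correlation c has noise sd = effect*sqrt(svar)*
    # sqrt(1-c^2)/c, where svar = (S-1)/S is the population variance of the
    # latent signal across samples; two members then correlate c_i*c_j in
    # expectation, so drawing c ~ U(sqrt(rho) +/- spread) keeps the expected
    # pairwise correlation at rho while spreading connectivity
    svar <- (S - 1) / S
    sd_for <- function(c) config$effect_size * sqrt(svar) * sqrt(1 - c^2) / c
    # hub: 0.25x the noise sd of the least-noisy ordinary member, so its
    # expected intramodular connectivity strictly dominates every member
    sd_hub <- 0.25 * sd_for(sqrt(rho) + config$loading_spread)
    c_hub <- 1 / sqrt(1 + sd_hub^2 / (config$effect_size^2 * svar))
    at <- n_arch
    for (m in seq_len(n_modules)) {
      idx <- at + seq_len(config$module_sizes[m])
      curve[idx, ] <- matrix(config$effect_size * latent[m, ], length(idx), S,
                             byrow = TRUE)
      module[idx] <- paste0("M", m)
      archetype[idx] <- paste0("latent:M", m)
      cc <- stats::runif(length(idx), sqrt(rho) - config$loading_spread,
                         sqrt(rho) + config$loading_spread)
      cc[1L] <- c_hub
      noise_sd_gene[idx] <- sd_for(cc)
      is_hub[idx[1L]] <- TRUE
      at <- at + config$module_sizes[m]
    }
  }

  base <- stats::rnorm(n, config$base_mean, config$base_sd)
  stage_idx <- rep(seq_len(S), each = R)
  means <- base + curve  # n x S planted stage means
  values <- means[, stage_idx, drop = FALSE] +
    matrix(stats::rnorm(n * S * R, 0, rep(noise_sd_gene, S * R)), n, S * R)
  dimnames(values) <- list(gene_ids, sample_ids)

  later <- setdiff(design$stage_labels, design$baseline_stage)
  b <- match(design$baseline_stage, design$stage_labels)
  deg_flags <- abs(means[, match(later, design$stage_labels), drop = FALSE] -
                     means[, b]) > 1e-12
  dimnames(deg_flags) <- list(gene_ids, later)

  expr <- expression_set(values, stats::setNames(stage_of_sample, sample_ids),
                         baseline = design$baseline_stage)
  truth <- list(
    genes = data.frame(gene_id = gene_ids, archetype = archetype,
                       module = module, is_hub = is_hub,
                       stringsAsFactors = FALSE),
    deg_flags = deg_flags,
    latent_profiles = latent
  )
  list(expr = expr, truth = truth)
}

#' Expand an expression matrix to probe level
#'
#' Emulates the probe structure of an oligonucleotide array: each gene is
#' expanded to `probes_per_gene` rows equal to the gene value plus a fixed
#' per-probe affinity offset (drawn once per probe, centered within each
#' gene) plus measurement noise. The output is the natural input fixture for
#' [median_polish_summarize()].
#'
#' @param expr An [expression_set()].
#' @param probes_per_gene Integer >= 1 (>= 2 to be a meaningful fixture;
#'   1 returns the input values unchanged).
#' @param probe_effect_sd Sd of the fixed per-probe offsets.
#' @param probe_noise_sd Sd of per-observation measurement noise.
#' @param seed Integer seed.
#' @return A list with `probes` (probes x samples matrix, rownames
#'   `<gene>::p<j>`) and `probe_to_gene` (named character vector).
#' @export
generate_probe_level <- function(expr, probes_per_gene = 11L,
                                 probe_effect_sd = 0.5,
                                 probe_noise_sd = 0.1, seed = 1L) {
  stopifnot(inherits(expr, "expr_set"))
  p <- as.integer(probes_per_gene)
  if (p < 1L) stop("probes_per_gene must be >= 1")
  if (probe_effect_sd < 0 || probe_noise_sd < 0) stop("sds must be >= 0")
  set.seed(as.integer(seed))
  n <- nrow(expr$values)
  ns <- ncol(expr$values)
  offsets <- matrix(stats::rnorm(n * p, 0, probe_effect_sd), n, p)
  # centered to median 0 within each gene: median polish identifies probe
  # effects up to their median, so this keeps the gene level recoverable
  offsets <- offsets - apply(offsets, 1L, stats::median)
  probes <- expr$values[rep(seq_len(n), each = p), , drop = FALSE] +
    as.vector(t(offsets)) +
    matrix(stats::rnorm(n * p * ns, 0, probe_noise_sd), n * p, ns)
  probe_ids <- paste0(rep(rownames(expr$values), each = p), "::p",
                      formatC(seq_len(p), width = 2, flag = "0"))
  rownames(probes) <- probe_ids
  probe_to_gene <- stats::setNames(rep(rownames(expr$values), each = p),
                                   probe_ids)
  list(probes = probes, probe_to_gene = probe_to_gene)
}

#' Generate a synthetic qPCR CT table
#'
#' Converts log2 expression of a set of target genes into cycle-threshold
#' values (`CT = ct_offset - expression + noise`; one extra log2 unit of
#' expression means one cycle earlier threshold) and appends two reference
#' (endogenous control) genes whose expression is constant in expectation
#' across stages.
#'
#' @param expr_subset An [expression_set()] restricted to the target genes.
#' @param reference_genes Character vector (typically 2) of reference gene
#'   names; must not overlap the target genes.
#' @param ct_noise_sd Sd of CT measurement noise (cycles).
#' @param seed Integer seed.
#' @param ct_offset CT of a gene at log2 expression 0 (default 35).
#' @param reference_level Constant log2 expression of the references
#'   (default 10).
#' @return A list of class `qpcr_ct` with `ct` ((targets + references) x
#'   samples matrix), `stages`, `baseline` and `reference_genes`.
#' @export
generate_qpcr_ct <- function(expr_subset, reference_genes = c("RPL7", "UBB"),
                             ct_noise_sd = 0.1, seed = 1L,
                             ct_offset = 35, reference_level = 10) {
  stopifnot(inherits(expr_subset, "expr_set"))
  if (any(reference_genes %in% rownames(expr_subset$values))) {
    stop("reference genes must not overlap the target genes")
  }
  set.seed(as.integer(seed))
  ns <- ncol(expr_subset$values)
  level <- rbind(expr_subset$values,
                 matrix(reference_level, length(reference_genes), ns,
                        dimnames = list(reference_genes,
                                        colnames(expr_subset$values))))
  ct <- ct_offset - level +
    matrix(stats::rnorm(length(level), 0, ct_noise_sd), nrow(level), ns)
  structure(
    list(ct = ct, stages = expr_subset$stages,
         baseline = expr_subset$baseline, reference_genes = reference_genes),
    class = "qpcr_ct"
  )
}
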