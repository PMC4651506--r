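#' Write an expression matrix as tab-delimited text
#'
#' First column `gene_id`, header row of sample ids. The matching sample
#' sheet (columns `sample`, `stage`) is written by [write_sample_sheet()].
#'
#' @param expr An [expression_set()] or a genes x samples matrix.
#' @param path Output file path.
#' @export
write_expression <- function(expr, path) {
  v <- if (inherits(expr, "expr_set")) expr$values else expr
  df <- data.frame(gene_id = rownames(v), v, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_expression
#' @param stages Named character vector (sample -> stage).
#' @export
write_sample_sheet <- function(stages, path) {
  utils::write.table(
    data.frame(sample = names(stages), stage = unname(stages)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a tab-delimited expression matrix
#'
#' Expects a header row of sample ids and a first column of gene ids.
#' Ragged rows, non-numeric cells and duplicate gene ids raise descriptive
#' errors with line numbers. If a sample sheet is supplied the result is
#' returned as an [expression_set()] with validated stage assignments.
#'
#' @param path Path to the matrix TSV.
#' @param sample_sheet Optional path to a two-column TSV (`sample`,
#'   `stage`) or a named stage vector.
#' @param baseline Optional baseline stage (requires `sample_sheet`).
#' @return An `expr_set` when stages are available, otherwise a numeric
#'   matrix.
#' @export
read_expression <- function(path, sample_sheet = NULL, baseline = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  nf <- utils::count.fields(path, sep = "\t", quote = "")
  if (length(unique(nf)) > 1L) {
    bad <- which(nf != nf[1L])[1L]
    stop("ragged row in ", path, " at line ", bad,
         " (", nf[bad], " fields, expected ", nf[1L], ")")
  }
  df <- utils::read.delim(path, check.names = FALSE, colClasses = "character")
  if (ncol(df) < 2L) stop("expected a gene id column plus >= 1 sample column")
  ids <- df[[1L]]
  if (anyDuplicated(ids)) {
    dup <- ids[duplicated(ids)][1L]
    stop("duplicate gene id '", dup, "' at line ",
         which(ids == dup)[2L] + 1L)
  }
  m <- as.matrix(df[, -1L, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(m), dim(m)))
  if (anyNA(num)) {
    idx <- which(is.na(num), arr.ind = TRUE)[1L, ]
    stop("non-numeric value '", m[idx[1L], idx[2L]], "' at line ",
         idx[1L] + 1L, ", sample '", colnames(df)[-1L][idx[2L]], "'")
  }
  dimnames(num) <- list(ids, colnames(df)[-1L])
  if (is.null(sample_sheet)) return(num)
  stages <- if (is.character(sample_sheet) && length(sample_sheet) == 1L &&
                file.exists(sample_sheet)) {
    ss <- utils::read.delim(sample_sheet, colClasses = "character")
    if (!all(c("sample", "stage") %in% colnames(ss))) {
      stop("sample sheet must have columns 'sample' and 'stage'")
    }
    stats::setNames(ss$stage, ss$sample)
  } else sample_sheet
  unknown <- setdiff(colnames(num), names(stages))
  if (length(unknown)) {
    stop("samples missing from the sample sheet: ",
         paste(unknown, collapse = ", "))
  }
  expression_set(num, stages[colnames(num)], baseline)
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Pipeline configuration
#'
#' Bundles every tunable of an end-to-end run. Either a synthetic
#' configuration (`synthetic`) or input paths (`expression`,
#' `sample_sheet`) must be given.
#'
#' @param synthetic Optional [synthetic_config()] to generate the input.
#' @param expression,sample_sheet Optional input paths (TSV) used when no
#'   synthetic config is given.
#' @param baseline_stage Baseline stage label (default "D12").
#' @param alpha DEG / edge FDR threshold (default 0.05).
#' @param clustering List with `c` and `m` (numbers or `"auto"`).
#' @param network List with `beta` (number or `"auto"`), `cut_height`,
#'   `min_module_size`, `edge_threshold`, `dialect`.
#' @param validation `NULL` to skip the qPCR stage, or a list with
#'   `reference_genes`, `ct_noise_sd`, `scale`, `n_targets`.
#' @param seed Integer master seed; every stochastic stage derives its
#'   seed from it.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(synthetic = synthetic_config(),
                            expression = NULL, sample_sheet = NULL,
                            baseline_stage = "D12", alpha = 0.05,
                            clustering = list(c = "auto", m = "auto"),
                            network = list(beta = "auto", cut_height = 0.94,
                                           min_module_size = 30L,
                                           edge_threshold = 0.02,
                                           dialect = "squared"),
                            validation = NULL,
                            seed = 1L) {
  if (is.null(synthetic)) {
    for (p in c(expression, sample_sheet)) {
      if (!is.null(p) && !file.exists(p)) stop("no such file: ", p)
    }
    if (is.null(expression) || is.null(sample_sheet)) {
      stop("either `synthetic` or both `expression` and `sample_sheet` ",
           "must be supplied")
    }
  }
  if (alpha < 0 || alpha > 1) stop("alpha must be in [0, 1]")
  structure(
    list(synthetic = synthetic, expression = expression,
         sample_sheet = sample_sheet, baseline_stage = baseline_stage,
         alpha = alpha, clustering = clustering, network = network,
         validation = validation, seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Run the full pipeline
#'
#' Executes expression input (or synthetic generation) -> differential
#' expression -> DEG partition -> temporal soft clustering -> weighted
#' co-expression network with hub table -> optional 2^-ddCT validation,
#' writing every intermediate table, a JSON run manifest and a log to
#' `out_dir`. Identical config and seed give identical outputs.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a list with the in-memory results of every stage and
#'   the output directory.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "log.txt")
  log_con <- file(log_path, open = "wt")
  on.exit(close(log_con), add = TRUE)
  say <- function(...) {
    msg <- paste0(...)
    writeLines(msg, log_con)
    message(msg)
  }
  stage <- "input"
  result <- list(out_dir = out_dir)
  tryCatch({
    # ---- input -----------------------------------------------------------
    if (!is.null(config$synthetic)) {
      say("generating synthetic expression data (seed ",
          config$synthetic$seed, ")")
      sim <- generate_expression_matrix(config = config$synthetic)
      expr <- sim$expr
      result$truth <- sim$truth
      .write_tsv(sim$truth$genes, file.path(out_dir, "truth.tsv"))
    } else {
      say("reading expression matrix from ", config$expression)
      expr <- read_expression(config$expression, config$sample_sheet,
                              config$baseline_stage)
    }
    write_expression(expr, file.path(out_dir, "expression.tsv"))
    write_sample_sheet(expr$stages, file.path(out_dir, "sample_sheet.tsv"))
    result$expr <- expr

    # ---- differential expression ----------------------------------------
    stage <- "differential_expression"
    say("calling DEGs vs baseline ", expr$baseline,
        " (alpha = ", config$alpha, ")")
    degs <- call_degs(expr, alpha = config$alpha)
    .write_tsv(degs, file.path(out_dir, "deg_table.tsv"))
    part <- partition_degs(degs)
    .write_tsv(
      data.frame(set = c(names(part$stage_specific), "shared"),
                 n = c(vapply(part$stage_specific, length, integer(1)),
                       length(part$shared))),
      file.path(out_dir, "deg_partition.tsv"))
    say("  ", part$total_unique, " unique DEGs")
    result$degs <- degs
    result$partition <- part

    # ---- temporal soft clustering ---------------------------------------
    stage <- "soft_clustering"
    deg_genes <- unique(degs$gene_id)
    if (length(deg_genes) >= 10L) {
      prof <- standardize_profiles(expr, deg_genes)
      cc <- config$clustering$c
      mm <- config$clustering$m
      if (identical(cc, "auto") || identical(mm, "auto")) {
        say("selecting clustering parameters (c, m)")
        c_hi <- min(15L, nrow(prof) - 1L)
        sel <- select_parameters(prof, c_range = 2:c_hi,
                                 seed = config$seed + 101L)
        if (identical(cc, "auto")) cc <- sel$c
        if (identical(mm, "auto")) mm <- sel$m
        result$parameter_selection <- sel
      }
      say("fuzzy c-means with c = ", cc, ", m = ", mm)
      fit <- fcm_cluster(prof, cc, mm, seed = config$seed + 202L, nstart = 3L)
      .write_tsv(
        data.frame(gene_id = rownames(fit$membership),
                   cluster = fit$cluster,
                   round(fit$membership, 6), check.names = FALSE),
        file.path(out_dir, "cluster_membership.tsv"))
      result$clustering <- fit
    } else {
      say("fewer than 10 DEGs; clustering stage skipped")
    }

    # ---- co-expression network ------------------------------------------
    stage <- "coexpression_network"
    say("building weighted co-expression network")
    net <- build_network(expr, beta = config$network$beta,
                         cut_height = config$network$cut_height,
                         min_module_size = config$network$min_module_size,
                         edge_threshold = config$network$edge_threshold,
                         dialect = config$network$dialect)
    say("  beta = ", net$beta, "; ", net$modules$n_modules, " module(s); ",
        sum(net$hubs$is_hub), " hub(s)")
    .write_tsv(data.frame(gene_id = names(net$modules$modules),
                          module = unname(net$modules$modules)),
               file.path(out_dir, "modules.tsv"))
    .write_tsv(net$hubs, file.path(out_dir, "hub_table.tsv"))
    result$network <- net

    # ---- qPCR validation -------------------------------------------------
    stage <- "qpcr_validation"
    if (!is.null(config$validation)) {
      val <- config$validation
      n_targets <- if (is.null(val$n_targets)) 10L else val$n_targets
      hub_genes <- net$hubs$gene_id[order(-pmax(net$hubs$scaled_k_positive,
                                                net$hubs$scaled_k_negative))]
      hub_genes <- hub_genes[net$hubs$module[match(hub_genes, net$hubs$gene_id)] !=
                               "background"]
      targets <- utils::head(hub_genes, n_targets)
      say("qPCR validation of ", length(targets), " genes")
      ct <- generate_qpcr_ct(
        subset_expression(expr, genes = targets),
        reference_genes = val$reference_genes %||% c("RPL7", "UBB"),
        ct_noise_sd = val$ct_noise_sd %||% 0.1,
        seed = config$seed + 303L)
      rel <- relative_expression(ct)
      .write_tsv(
        data.frame(gene_id = rownames(rel$relative_expression),
                   round(rel$relative_expression, 6), check.names = FALSE),
        file.path(out_dir, "relative_expression.tsv"))
      edges <- correlation_network(rel, alpha = config$alpha,
                                   scale = val$scale %||% "log2")
      .write_tsv(edges, file.path(out_dir, "qpcr_edges.tsv"))
      result$qpcr <- list(ct = ct, relative = rel, edges = edges)
    } else {
      say("no CT input configured; validation stage skipped")
    }

    # ---- manifest --------------------------------------------------------
    stage <- "manifest"
    manifest <- list(
      package = "gestnet",
      version = as.character(utils::packageVersion("gestnet")),
      r_version = R.version.string,
      seed = config$seed,
      alpha = config$alpha,
      baseline = expr$baseline,
      network = list(beta = net$beta,
                     cut_height = config$network$cut_height,
                     min_module_size = config$network$min_module_size),
      n_genes = nrow(expr$values), n_samples = ncol(expr$values)
    )
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    say("run complete: ", out_dir)
  }, error = function(e) {
    say("ERROR in stage '", stage, "': ", conditionMessage(e))
    stop("pipeline failed in stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(result)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
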