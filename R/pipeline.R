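#' Validate a pipeline configuration
#'
#' A configuration is a named list (or YAML file) with:
#' \describe{
#'   \item{paths}{`expression` (TSV), `design` (CSV), `probe_map` (CSV),
#'     `catalog` (pathway JSON), `out_dir`; optional `new_expression` for
#'     the projection stage.}
#'   \item{sampler}{fields of [sampler_config] plus `n_chains`.}
#'   \item{n_perm}{permutations for the gene-set stages.}
#'   \item{seed}{integer master seed; every random operation derives its
#'     seed from it (never from the clock).}
#'   \item{stages}{logical toggles: `preprocess`, `factorize`, `genesets`,
#'     `project`, `baseline`.}
#' }
#'
#' @param config Named list or path to a YAML file.
#' @return The validated config list.
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop_invalid("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (is.null(config$paths$out_dir))
    stop_invalid("config$paths$out_dir is required")
  for (p in c("expression", "design", "probe_map", "catalog")) {
    path <- config$paths[[p]]
    if (is.null(path)) stop_invalid("config$paths$", p, " is required")
    if (!file.exists(path))
      stop_invalid("config$paths$", p, " does not exist: ", path)
  }
  if (is.null(config$seed))
    stop_invalid("config$seed is required (no wall-clock seeding)")
  defaults <- list(preprocess = TRUE, factorize = TRUE, genesets = TRUE,
                   project = TRUE, baseline = TRUE)
  config$stages <- utils::modifyList(defaults,
                                     as.list(config$stages %||% list()))
  config$n_perm <- config$n_perm %||% 1000
  config$sampler <- as.list(config$sampler %||% list())
  config$sampler$n_chains <- config$sampler$n_chains %||% 3
  config
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stage_log <- function(manifest, stage, t0) {
  message(sprintf("[pathgaps] stage %-10s %.2fs", stage,
                  as.numeric(Sys.time()) - t0))
  manifest
}

add_artifact <- function(manifest, stage, name, path) {
  manifest$artifacts[[name]] <- list(
    stage = stage, path = path,
    md5 = unname(tools::md5sum(path)))
  manifest
}

#' Run the pipeline end to end
#'
#' Executes the enabled stages in order — preprocessing (batch correction,
#' probe collapse, catalog restriction, uncertainty), multi-chain
#' factorization with pattern matching and averaging, gene-set statistics,
#' projection of the averaged signatures, and the linear-model baseline —
#' writing every intermediate artifact under `out_dir` together with a
#' manifest of paths, md5 checksums and seeds.
#'
#' @param config See [validate_config].
#' @return The manifest list, invisibly. On stage failure the partial
#'   manifest written so far is kept on disk.
#' @export
run_pipeline <- function(config) {
  config <- validate_config(config)
  out <- config$paths$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(config = config, artifacts = list())
  manifest_path <- file.path(out, "manifest.json")
  save_manifest <- function() jsonlite::write_json(
    manifest, manifest_path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
    force = TRUE, null = "null")
  on.exit(save_manifest())

  design <- read_design(config$paths$design)
  catalog <- read_catalog(config$paths$catalog, "pathway_json")
  expr <- read_expression(config$paths$expression, "tsv")
  pm <- read.delim(config$paths$probe_map, sep = ",",
                   stringsAsFactors = FALSE)
  probe_map <- stats::setNames(pm$gene_id, pm$probe_id)

  if (config$stages$preprocess) {
    t0 <- as.numeric(Sys.time())
    if (length(unique(design$batch)) > 1)
      expr <- correct_batch(expr, design)
    expr <- collapse_probes(expr, probe_map, design)
    expr <- restrict_to_catalog(expr, catalog)
    expr <- compute_uncertainty(expr, frac = config$frac %||% 0.1)
    path <- file.path(out, "preprocessed.tsv")
    write_expression(expr, path, "tsv")
    manifest <- add_artifact(manifest, "preprocess", "preprocessed", path)
    manifest <- stage_log(manifest, "preprocess", t0)
  } else {
    expr <- compute_uncertainty(expr, frac = config$frac %||% 0.1)
  }

  avg <- NULL
  matched <- NULL
  if (config$stages$factorize) {
    t0 <- as.numeric(Sys.time())
    s <- config$sampler
    chains <- lapply(seq_len(s$n_chains), function(cc) {
      cfg <- sampler_config(
        n_patterns = s$n_patterns %||% 3,
        n_burn = s$n_burn %||% 2500, n_sample = s$n_sample %||% 2500,
        thin = s$thin %||% 5, seed = config$seed + cc,
        max_atoms = s$max_atoms %||% 1e5, alpha = s$alpha %||% 0.01,
        lambda_scale = s$lambda_scale %||% 1)
      run_sampler(expr, cfg)
    })
    matched <- match_patterns(chains)
    avg <- average_results(matched, D = expr)
    path <- file.path(out, "factorization.json")
    jsonlite::write_json(
      list(A_mean = avg$A_mean, A_sd = avg$A_sd,
           P_mean = avg$P_mean, P_sd = avg$P_sd,
           chi2_final = avg$chi2_final,
           gene_ids = rownames(avg$A_mean),
           sample_ids = colnames(avg$P_mean),
           matched_correlations = matched$correlations,
           seeds = config$seed + seq_len(s$n_chains)),
      path, auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
    manifest <- add_artifact(manifest, "factorize", "factorization", path)
    manifest <- stage_log(manifest, "factorize", t0)
  }

  if (config$stages$genesets) {
    if (is.null(matched)) stop_invalid("genesets stage needs factorize")
    t0 <- as.numeric(Sys.time())
    per_chain <- lapply(seq_along(matched$aligned), function(i)
      score_catalog(matched$aligned[[i]], catalog,
                    n_perm = config$n_perm, seed = config$seed + 100 * i))
    summ <- summarize_chains(per_chain)
    path <- file.path(out, "geneset_stats.tsv")
    write.table(summ, path, sep = "\t", quote = FALSE, row.names = FALSE)
    manifest <- add_artifact(manifest, "genesets", "geneset_stats", path)
    manifest <- stage_log(manifest, "genesets", t0)
  }

  if (config$stages$project) {
    if (is.null(avg)) stop_invalid("project stage needs factorize")
    t0 <- as.numeric(Sys.time())
    target <- if (!is.null(config$paths$new_expression))
      read_expression(config$paths$new_expression, "tsv") else expr
    proj <- project(target, avg$A_mean)
    path <- file.path(out, "projection.tsv")
    write.table(
      data.frame(signature = rownames(proj$P_hat), proj$P_hat,
                 check.names = FALSE),
      path, sep = "\t", quote = FALSE, row.names = FALSE)
    manifest <- add_artifact(manifest, "project", "projection", path)
    manifest <- stage_log(manifest, "project", t0)
  }

  if (config$stages$baseline) {
    t0 <- as.numeric(Sys.time())
    design_ord <- design[match(sample_ids(expr), design$sample_id), ]
    terms <- c("condition", "media")
    keep <- terms[vapply(terms,
                         function(t) length(unique(design_ord[[t]])) > 1,
                         logical(1))]
    f <- stats::as.formula(paste("~", paste(c("1", keep), collapse = " + ")))
    X <- model.matrix(f, design_ord)
    fit <- fit_linear_model(expr, X)
    rows <- list()
    for (pw in names(catalog$pathways)) {
      set <- intersect(pathway_set(catalog, pw), rownames(fit$moderated_t))
      for (j in seq_len(ncol(fit$moderated_t))) {
        tvec <- fit$moderated_t[, j]
        names(tvec) <- rownames(fit$moderated_t)
        p_up <- gene_set_rank_test(tvec, set, "up")
        p_down <- gene_set_rank_test(tvec, set, "down")
        perm <- cogaps_style_stat_lm(fit, set, j,
                                     n_perm = config$n_perm,
                                     seed = config$seed + 17 * j)
        rows[[length(rows) + 1L]] <- data.frame(
          pathway = pw, coefficient = colnames(fit$moderated_t)[j],
          p_up = p_up, p_down = p_down,
          p_tilde_lm = rescale_lm(p_down, p_up),
          p_tilde_perm = perm$p_tilde, stringsAsFactors = FALSE)
      }
    }
    lm_stats <- do.call(rbind, rows)
    wide <- matrix(lm_stats$p_tilde_lm,
                   nrow = length(unique(lm_stats$pathway)), byrow = TRUE)
    lm_stats$p_tilde_lm_rescaled <-
      as.vector(t(heatmap_rescale(wide)))
    path <- file.path(out, "lm_stats.tsv")
    write.table(lm_stats, path, sep = "\t", quote = FALSE,
                row.names = FALSE)
    manifest <- add_artifact(manifest, "baseline", "lm_stats", path)
    manifest <- stage_log(manifest, "baseline", t0)
  }

  save_manifest()
  invisible(manifest)
}

#' Generate a synthetic dataset and run the whole pipeline on it
#'
#' Builds a small forced-expression-style dataset (3 patterns, planted
#' target sets, 2 batches, 2 probes per gene), writes it under
#' `out_dir/data`, and runs every stage with reduced sampler settings. The
#' run is deterministic given `seed`.
#'
#' @param out_dir Output directory.
#' @param seed Integer master seed.
#' @return The pipeline manifest, invisibly.
#' @export
pipeline_demo <- function(out_dir, seed = 1) {
  data_dir <- file.path(out_dir, "data")
  truth <- generate_truth(n_genes = 80, n_samples = 18, n_patterns = 3,
                          sparsity = 0.5, seed = seed)
  planted <- plant_genesets(truth, sets_per_pattern = 2, set_size = 8,
                            effect = 4, seed = seed + 1)
  expr <- simulate_expression(planted$truth, noise_frac = 0.1,
                              seed = seed + 2)
  ds <- synthetic_dataset(expr, planted$truth,
                          stats::setNames(row_ids(expr), row_ids(expr)),
                          planted$catalog)
  ds <- add_batch_and_probes(ds, n_batches = 2, batch_magnitude = 0.5,
                             probes_per_gene = 2, seed = seed + 3)
  paths <- write_dataset(ds, data_dir)

  run_pipeline(list(
    paths = list(expression = unname(paths[["expression_tsv"]]),
                 design = unname(paths[["design"]]),
                 probe_map = unname(paths[["probe_map"]]),
                 catalog = unname(paths[["catalog_json"]]),
                 out_dir = out_dir),
    sampler = list(n_patterns = 3, n_burn = 400, n_sample = 400,
                   thin = 4, n_chains = 2),
    n_perm = 200,
    seed = seed))
}
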