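#' Generate ground-truth factor matrices and a sample design
#'
#' Simulation truth for the factorization model `D ~ N(AP, Sigma)`: a sparse
#' non-negative amplitude matrix `A_true` (genes x patterns) and a pattern
#' matrix `P_true` (patterns x samples) whose rows mirror a forced-expression
#' cell-line design: one background row that is near-constant across all
#' samples, and remaining rows elevated on disjoint contiguous sample blocks
#' (one block per experimental condition). The samples are split into
#' `n_patterns` contiguous groups; the first group is a vector-control
#' condition carried by the background row alone, so the background row is
#' not expressible as a sum of the elevated rows and the truth is
#' identifiable. All rows carry entrywise multiplicative
#' Uniform(0.85, 1.15) jitter emulating within-condition replicate
#' variability, so no row is exactly constant.
#'
#' `A_true` entries are Exponential(mean 1) draws zeroed with probability
#' `sparsity`; each column is guaranteed at least 3 non-zero entries so no
#' pattern is degenerate.
#'
#' @param n_genes,n_samples,n_patterns Dimensions; `n_patterns` must not
#'   exceed `min(n_genes, n_samples)`.
#' @param sparsity Expected fraction of exact zeros per column of `A_true`,
#'   in `[0, 1]`.
#' @param seed Integer seed; output is deterministic given the seed.
#' @return An object of class `gaps_truth` with fields `A_true`, `P_true`,
#'   `design` (data.frame: `sample_id`, `condition`, `media`, `batch`),
#'   `active_sets` (planted set names per pattern, empty until
#'   [plant_genesets]) and `seed`.
#' @export
generate_truth <- function(n_genes, n_samples, n_patterns, sparsity, seed) {
  n_genes <- check_count(n_genes, "n_genes")
  n_samples <- check_count(n_samples, "n_samples")
  n_patterns <- check_count(n_patterns, "n_patterns")
  sparsity <- check_fraction(sparsity, "sparsity")
  if (n_patterns > min(n_genes, n_samples))
    stop_invalid("n_patterns exceeds min(n_genes, n_samples)")

  genes <- sprintf("g%04d", seq_len(n_genes))
  samples <- sprintf("s%03d", seq_len(n_samples))

  with_seed(seed, {
    A <- matrix(rexp(n_genes * n_patterns, rate = 1), n_genes, n_patterns,
                dimnames = list(genes, NULL))
    zero <- matrix(runif(n_genes * n_patterns) < sparsity,
                   n_genes, n_patterns)
    A[zero] <- 0
    for (k in seq_len(n_patterns)) {       # minimum support: >= 3 non-zeros
      nz <- which(A[, k] > 0)
      need <- 3L - length(nz)
      if (need > 0) {
        pick <- sample(setdiff(seq_len(n_genes), nz), need)
        A[pick, k] <- rexp(need, rate = 1)
      }
    }

    P <- matrix(0.05, n_patterns, n_samples,
                dimnames = list(NULL, samples))
    P[1L, ] <- 1
    cond <- rep("vector", n_samples)
    cond_names <- c("EGFR", "p65", "HRAS",
                    sprintf("cond%d", seq_len(max(0, n_patterns - 4)) + 3L))
    if (n_patterns > 1) {
      # group 1 is the vector control (background only); groups 2..p carry
      # one elevated pattern each
      blocks <- split(seq_len(n_samples),
                      cut(seq_len(n_samples), n_patterns, labels = FALSE))
      for (k in 2:n_patterns) {
        P[k, blocks[[k]]] <- 1
        cond[blocks[[k]]] <- cond_names[k - 1L]
      }
    }
    P <- P * matrix(runif(length(P), 0.85, 1.15), nrow(P), ncol(P))

    media <- rep("none", n_samples)
    for (cc in unique(cond)) {
      idx <- which(cond == cc)
      media[idx[seq_len(ceiling(length(idx) / 2))]] <- "serum"
    }

    structure(list(
      A_true = A,
      P_true = P,
      design = data.frame(sample_id = samples, condition = cond,
                          media = media, batch = "b1",
                          stringsAsFactors = FALSE),
      active_sets = list(),
      seed = seed), class = "gaps_truth")
  })
}

#' @export
print.gaps_truth <- function(x, ...) {
  cat(sprintf("gaps_truth: %d genes x %d patterns x %d samples, seed %d\n",
              nrow(x$A_true), ncol(x$A_true), ncol(x$P_true), x$seed))
  invisible(x)
}

#' Simulate expression data under the multiplicative noise model
#'
#' Draws `D = A_true P_true + eps` with `eps` per-entry normal with standard
#' deviation `noise_frac * (A_true P_true)`, truncated at zero (expression is
#' non-negative). When `noise_frac > 0` the uncertainty matrix is attached as
#' `noise_frac * D` with a positive floor (see [compute_uncertainty]).
#'
#' @param truth A [generate_truth] object.
#' @param noise_frac Non-negative noise fraction (the canonical microarray
#'   error model uses 0.1).
#' @param seed Integer seed.
#' @return An [expression_matrix], genes x samples.
#' @export
simulate_expression <- function(truth, noise_frac, seed) {
  stopifnot(inherits(truth, "gaps_truth"))
  if (!is.numeric(noise_frac) || length(noise_frac) != 1L || noise_frac < 0)
    stop_invalid("`noise_frac` must be a single non-negative value")
  mu <- truth$A_true %*% truth$P_true
  with_seed(seed, {
    D <- mu + rnorm(length(mu), mean = 0, sd = noise_frac * mu)
    D[D < 0] <- 0
    dimnames(D) <- dimnames(mu)
    expr <- expression_matrix(D)
    if (noise_frac > 0) expr <- compute_uncertainty(expr, frac = noise_frac)
    expr
  })
}

#' Plant active gene sets into ground-truth amplitudes
#'
#' For each pattern, `sets_per_pattern` disjoint gene sets of `set_size`
#' genes (disjoint across patterns too) have their `A_true` entries in that
#' pattern's column multiplied by `1 + effect`. Because an active target
#' set means targets that are expressed in the pattern, members are drawn
#' from the genes with non-zero amplitude in the designated column wherever
#' possible; if the column has too few active genes, the remaining members
#' are activated with fresh Exponential(mean 1) amplitudes before scaling.
#' The sets are recorded as TF-level sets grouped under one pathway per
#' pattern (pathway `PW<k>`, TFs `TF<k>_<s>`), emulating a
#' transcription-factor target catalog with known pattern-specific
#' activity.
#'
#' @param truth A [generate_truth] object.
#' @param sets_per_pattern,set_size Counts;
#'   `sets_per_pattern * set_size * n_patterns` must not exceed the gene
#'   count.
#' @param effect Non-negative amplitude multiplier minus one; `effect = 0`
#'   leaves `A_true` unchanged.
#' @param seed Integer seed.
#' @return List with elements `truth` (updated, `active_sets` filled) and
#'   `catalog` (a [gene_set_catalog]).
#' @export
plant_genesets <- function(truth, sets_per_pattern, set_size, effect, seed) {
  stopifnot(inherits(truth, "gaps_truth"))
  sets_per_pattern <- check_count(sets_per_pattern, "sets_per_pattern")
  set_size <- check_count(set_size, "set_size")
  if (!is.numeric(effect) || length(effect) != 1L || effect < 0)
    stop_invalid("`effect` must be a single non-negative value")
  p <- ncol(truth$A_true)
  n_genes <- nrow(truth$A_true)
  total <- sets_per_pattern * set_size * p
  if (total > n_genes)
    stop_invalid("not enough genes to plant ", total, " set members among ",
                 n_genes, " genes")
  genes <- rownames(truth$A_true)
  with_seed(seed, {
    pathways <- list()
    tf_targets <- list()
    taken <- character(0)
    for (k in seq_len(p)) {
      pw <- sprintf("PW%d", k)
      tfs <- character(sets_per_pattern)
      need <- sets_per_pattern * set_size
      active <- setdiff(genes[truth$A_true[, k] > 0], taken)
      pool <- if (length(active) >= need) sample(active, need)
        else c(sample(active), sample(setdiff(genes, c(taken, active)),
                                      need - length(active)))
      for (s in seq_len(sets_per_pattern)) {
        tf <- sprintf("TF%d_%d", k, s)
        members <- pool[(s - 1L) * set_size + seq_len(set_size)]
        if (effect > 0) {
          inactive <- members[truth$A_true[members, k] == 0]
          if (length(inactive))
            truth$A_true[inactive, k] <- rexp(length(inactive), rate = 1)
          truth$A_true[members, k] <-
            truth$A_true[members, k] * (1 + effect)
        }
        tf_targets[[tf]] <- members
        tfs[s] <- tf
      }
      taken <- c(taken, pool)
      pathways[[pw]] <- tfs
      truth$active_sets[[as.character(k)]] <- tfs
    }
    list(truth = truth, catalog = gene_set_catalog(pathways, tf_targets))
  })
}

#' Bundle an expression matrix with its simulation provenance
#'
#' @param expression An [expression_matrix] (rows are probes).
#' @param truth The [generate_truth] object it was simulated from.
#' @param probe_map Named character vector probe id -> gene id covering every
#'   expression row.
#' @param catalog A [gene_set_catalog].
#' @return An object of class `synthetic_dataset`.
#' @export
synthetic_dataset <- function(expression, truth, probe_map, catalog) {
  stopifnot(inherits(expression, "expression_matrix"),
            inherits(truth, "gaps_truth"),
            inherits(catalog, "gene_set_catalog"))
  if (!setequal(names(probe_map), row_ids(expression)) ||
      length(probe_map) != nrow(expression$values))
    stop_invalid("`probe_map` must cover every expression row exactly once")
  structure(list(expression = expression, truth = truth,
                 probe_map = probe_map, catalog = catalog),
            class = "synthetic_dataset")
}

#' Add batch effects and probe multiplicity to a synthetic dataset
#'
#' Samples are assigned round-robin to `n_batches` processing batches; every
#' non-reference batch receives an additive per-gene offset drawn
#' Normal(0, `batch_magnitude`), shared by all its samples (a "processing
#' date" effect removable by a linear model). Each gene is then duplicated
#' into `probes_per_gene` probe rows (`<gene>_p1`, `<gene>_p2`, ...); the
#' non-primary probes receive extra independent noise so the primary probe
#' carries the strongest condition signal in expectation. Values are clipped
#' at zero; any attached uncertainty is dropped (it is recomputed after
#' preprocessing).
#'
#' @param dataset A [synthetic_dataset].
#' @param n_batches Number of batches (`>= 1`).
#' @param batch_magnitude Standard deviation of the per-gene batch offsets.
#' @param probes_per_gene Probe rows per gene (`>= 1`).
#' @param seed Integer seed.
#' @return The modified [synthetic_dataset]; the truth's design gains batch
#'   labels and `probe_map` maps the new probe rows onto genes.
#' @export
add_batch_and_probes <- function(dataset, n_batches, batch_magnitude,
                                 probes_per_gene, seed) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  n_batches <- check_count(n_batches, "n_batches")
  probes_per_gene <- check_count(probes_per_gene, "probes_per_gene")
  if (!is.numeric(batch_magnitude) || batch_magnitude < 0)
    stop_invalid("`batch_magnitude` must be non-negative")

  vals <- dataset$expression$values
  n_genes <- nrow(vals)
  n_samples <- ncol(vals)
  genes <- dataset$probe_map[rownames(vals)]

  with_seed(seed, {
    batch <- sprintf("b%d", ((seq_len(n_samples) - 1L) %% n_batches) + 1L)
    if (n_batches > 1) {
      for (b in unique(batch)[-1L]) {
        offset <- rnorm(n_genes, 0, batch_magnitude)
        vals[, batch == b] <- vals[, batch == b] + offset
      }
      vals[vals < 0] <- 0
    }

    out <- matrix(0, n_genes * probes_per_gene, n_samples)
    probe_ids <- character(n_genes * probes_per_gene)
    probe_map <- character(n_genes * probes_per_gene)
    r <- 0L
    for (i in seq_len(n_genes)) {
      noise_sd <- 0.5 * (mean(vals[i, ]) + 0.1)
      for (q in seq_len(probes_per_gene)) {
        r <- r + 1L
        row <- vals[i, ]
        if (q > 1) {
          row <- row + rnorm(n_samples, 0, noise_sd)
          row[row < 0] <- 0
        }
        out[r, ] <- row
        probe_ids[r] <- sprintf("%s_p%d", rownames(vals)[i], q)
        probe_map[r] <- genes[[i]]
      }
    }
    rownames(out) <- probe_ids
    colnames(out) <- colnames(vals)
    names(probe_map) <- probe_ids

    truth <- dataset$truth
    truth$design$batch <- batch
    synthetic_dataset(expression_matrix(out), truth, probe_map,
                      dataset$catalog)
  })
}

#' Write a synthetic dataset's artifacts to a directory
#'
#' Writes the expression matrix (TSV and GCT 1.2), the sample-annotation CSV
#' (`sample_id`, `condition`, `media`, `batch`), the catalog (pathway JSON
#' and GMT), the probe map (CSV), and the ground truth (JSON) for test
#' harnesses.
#'
#' @param dataset A [synthetic_dataset].
#' @param dir Output directory (created if missing).
#' @return Named character vector of the paths written, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    expression_tsv = file.path(dir, "expression.tsv"),
    expression_gct = file.path(dir, "expression.gct"),
    design = file.path(dir, "design.csv"),
    catalog_json = file.path(dir, "catalog.json"),
    catalog_gmt = file.path(dir, "catalog.gmt"),
    probe_map = file.path(dir, "probe_map.csv"),
    truth = file.path(dir, "truth.json"))
  write_expression(dataset$expression, paths[["expression_tsv"]], "tsv")
  write_expression(dataset$expression, paths[["expression_gct"]], "gct")
  write_design(dataset$truth$design, paths[["design"]])
  write_catalog(dataset$catalog, paths[["catalog_json"]], "pathway_json")
  write_catalog(dataset$catalog, paths[["catalog_gmt"]], "gmt")
  write.table(data.frame(probe_id = names(dataset$probe_map),
                         gene_id = unname(dataset$probe_map)),
              paths[["probe_map"]], sep = ",", quote = FALSE,
              row.names = FALSE)
  jsonlite::write_json(
    list(A_true = dataset$truth$A_true, P_true = dataset$truth$P_true,
         active_sets = dataset$truth$active_sets,
         seed = dataset$truth$seed),
    paths[["truth"]], auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  invisible(paths)
}
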