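#' Read / write a sample-annotation table
#'
#' CSV columns: `sample_id`, `condition`, `media`, `batch`.
#'
#' @param path File path.
#' @return A data.frame with the four annotation columns.
#' @export
read_design <- function(path) {
  if (!file.exists(path)) stop_invalid("file not found: ", path)
  df <- read.delim(path, sep = ",", stringsAsFactors = FALSE)
  need <- c("sample_id", "condition", "media", "batch")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop_invalid("design file lacks column(s): ",
                 paste(missing, collapse = ", "))
  df[need]
}

#' @rdname read_design
#' @param design The annotation data.frame.
#' @export
write_design <- function(design, path) {
  write.table(design, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

check_design <- function(expr, design) {
  ids <- sample_ids(expr)
  if (anyDuplicated(design$sample_id))
    stop_invalid("duplicated sample_id in design")
  if (!setequal(design$sample_id, ids))
    stop_invalid("design must cover exactly the samples of the expression ",
                 "matrix")
  design[match(ids, design$sample_id), , drop = FALSE]
}

# Model matrix for value ~ intercept + condition + media + batch with
# treatment coding; single-level factors are dropped.
batch_model_matrix <- function(design) {
  terms <- c("condition", "media", "batch")
  keep <- terms[vapply(terms, function(t) length(unique(design[[t]])) > 1,
                       logical(1))]
  f <- if (length(keep))
    stats::as.formula(paste("~", paste(keep, collapse = " + ")))
  else ~1
  X <- model.matrix(f, data = design)
  if (qr(X)$rank < ncol(X)) {
    stop_invalid("design is rank deficient: factors ",
                 paste(keep, collapse = " + "),
                 " are confounded (batch cannot be separated)")
  }
  X
}

#' Remove an additive batch effect by per-gene linear modelling
#'
#' Per row, an ordinary least-squares fit of
#' `value ~ intercept + condition + media + batch` (treatment coding, first
#' level as reference); the fitted batch coefficients are subtracted from
#' the samples of the non-reference batches, leaving the condition and media
#' structure untouched. Corrected values are clipped at zero to preserve the
#' non-negativity required by the factorization model.
#'
#' @param expr An [expression_matrix].
#' @param design Annotation data.frame (`sample_id`, `condition`, `media`,
#'   `batch`) covering all samples; at least 2 batches.
#' @return A corrected [expression_matrix] (uncertainty dropped; recompute
#'   after correction).
#' @export
correct_batch <- function(expr, design) {
  design <- check_design(expr, design)
  if (length(unique(design$batch)) < 2)
    stop_invalid("only one batch present; nothing to correct")
  X <- batch_model_matrix(design)
  batch_cols <- grep("^batch", colnames(X))
  fit <- stats::lm.fit(X, t(expr$values))
  beta_batch <- fit$coefficients[batch_cols, , drop = FALSE]
  corrected <- expr$values - t(X[, batch_cols, drop = FALSE] %*% beta_batch)
  corrected[corrected < 0] <- 0
  expression_matrix(corrected)
}

#' Collapse probe rows to one row per gene by strongest moderated signal
#'
#' For every gene with multiple probes, retains the probe minimizing the
#' moderated F-test p-value for the condition factor (empirical-Bayes
#' moderated statistics over the model `~ condition`). Ties break to the
#' lexicographically smaller probe id.
#'
#' @param expr An [expression_matrix] whose rows are probes.
#' @param probe_map Named character vector probe id -> gene id covering all
#'   rows of `expr`.
#' @param design Annotation data.frame covering all samples.
#' @return An [expression_matrix] with one row per gene (gene ids as row
#'   ids), in first-appearance order of the genes.
#' @export
collapse_probes <- function(expr, probe_map, design) {
  design <- check_design(expr, design)
  probes <- row_ids(expr)
  missing <- setdiff(probes, names(probe_map))
  if (length(missing))
    stop_invalid("probe(s) absent from probe_map: ",
                 paste(head(missing, 3), collapse = ", "))
  genes <- probe_map[probes]

  if (length(unique(design$condition)) < 2)
    stop_invalid("collapse_probes needs >= 2 condition levels")
  X <- model.matrix(~condition, data = design)
  fit <- limma::eBayes(limma::lmFit(expr$values, X))
  tab <- limma::topTable(fit, coef = 2:ncol(X), number = Inf,
                         sort.by = "none")
  pvals <- tab$P.Value
  names(pvals) <- probes

  keep <- vapply(split(probes, factor(genes, levels = unique(genes))),
                 function(pr) {
                   pr <- pr[order(pvals[pr], pr)]   # ties: lexicographic id
                   pr[1L]
                 }, character(1))
  out <- expr$values[keep, , drop = FALSE]
  rownames(out) <- names(keep)
  expression_matrix(out)
}

#' Restrict expression rows to catalog-annotated genes
#'
#' @param expr An [expression_matrix] whose rows are gene ids.
#' @param catalog A [gene_set_catalog]; rows are kept when the gene appears
#'   in any TF target list, original order preserved.
#' @return The restricted [expression_matrix].
#' @export
restrict_to_catalog <- function(expr, catalog) {
  universe <- catalog_gene_universe(catalog)
  keep <- row_ids(expr) %in% universe
  if (!any(keep))
    stop_invalid("no expression rows are annotated in the catalog; ",
                 "pipeline cannot proceed")
  vals <- expr$values[keep, , drop = FALSE]
  unc <- if (!is.null(expr$uncertainty))
    expr$uncertainty[keep, , drop = FALSE] else NULL
  expression_matrix(vals, unc)
}

#' Attach the multiplicative uncertainty model
#'
#' Sets the element-wise standard deviation to `max(frac * value, floor)`
#' where `floor = frac * (1st percentile of strictly positive values)`, so
#' the uncertainty is strictly positive everywhere (required by the
#' chi-squared likelihood, which divides by it).
#'
#' @param expr An [expression_matrix].
#' @param frac Positive fraction; 0.1 is the canonical microarray error
#'   model.
#' @return `expr` with `uncertainty` filled in.
#' @export
compute_uncertainty <- function(expr, frac = 0.1) {
  if (!is.numeric(frac) || length(frac) != 1L || frac <= 0)
    stop_invalid("`frac` must be a single positive value")
  pos <- expr$values[expr$values > 0]
  if (!length(pos))
    stop_invalid("all expression values are zero; no positive floor exists")
  floor_val <- frac * quantile(pos, 0.01, names = FALSE)
  unc <- pmax(frac * expr$values, floor_val)
  expression_matrix(expr$values, unc)
}
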