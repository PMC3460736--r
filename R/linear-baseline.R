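#' Per-gene linear model with empirical-Bayes moderated t
#'
#' The comparison arm: ordinary least-squares fits per gene against a
#' sample design matrix, optional contrast transform, and empirical-Bayes
#' moderation of the per-gene variances toward a prior estimated from the
#' distribution of residual variances (limma's moderated-t construction).
#' The moderated t for coefficient `c` of gene `g` is
#' `coef / (stdev_unscaled * s_post)` with
#' `s_post^2 = (d0 s0^2 + df sigma_g^2) / (d0 + df)`.
#'
#' @param expr An [expression_matrix] (typically batch-corrected,
#'   gene-collapsed).
#' @param design_matrix Samples x conditions numeric design matrix (full
#'   rank).
#' @param contrasts Optional conditions x k contrast matrix; when supplied,
#'   coefficients and moderated t are reported for the contrasts.
#' @param d0_override Optional override of the prior degrees of freedom;
#'   `Inf` gives the full-shrinkage limit where every posterior variance
#'   equals `s0_sq`.
#' @return A `linear_fit`: `coefficients`, `stdev_unscaled`, `sigma`,
#'   `df_residual`, `d0` (prior df), `s0_sq` (prior variance),
#'   `moderated_t`, `df_total`.
#' @export
fit_linear_model <- function(expr, design_matrix, contrasts = NULL,
                             d0_override = NULL) {
  stopifnot(inherits(expr, "expression_matrix"))
  X <- as.matrix(design_matrix)
  if (nrow(X) != ncol(expr$values))
    stop_invalid("design matrix rows must equal sample count")
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    dep <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop_invalid("design matrix is rank deficient; dependent column(s): ",
                 paste(dep, collapse = ", "))
  }
  if (nrow(X) - ncol(X) < 1)
    stop_invalid("no residual degrees of freedom")

  fit <- limma::lmFit(expr$values, X)
  if (!is.null(contrasts))
    fit <- limma::contrasts.fit(fit, as.matrix(contrasts))
  efit <- limma::eBayes(fit)

  d0 <- unname(efit$df.prior[1])
  s0_sq <- unname(efit$s2.prior[1])
  sigma <- fit$sigma
  df <- fit$df.residual
  tmat <- efit$t
  if (!is.null(d0_override)) {
    d0 <- d0_override
    if (is.infinite(d0)) {
      s_post2 <- rep(s0_sq, length(sigma))
    } else {
      s_post2 <- (d0 * s0_sq + df * sigma^2) / (d0 + df)
    }
    tmat <- fit$coefficients / (fit$stdev.unscaled * sqrt(s_post2))
  }

  structure(list(coefficients = fit$coefficients,
                 stdev_unscaled = fit$stdev.unscaled,
                 sigma = sigma, df_residual = df,
                 d0 = d0, s0_sq = s0_sq,
                 moderated_t = tmat,
                 df_total = d0 + df), class = "linear_fit")
}

#' @export
print.linear_fit <- function(x, ...) {
  cat(sprintf(
    "linear_fit: %d genes x %d coefficients; d0 = %.3g, s0^2 = %.3g\n",
    nrow(x$coefficients), ncol(x$coefficients), x$d0, x$s0_sq))
  invisible(x)
}

#' Rank-based gene-set test on per-gene statistics
#'
#' Wilcoxon rank-sum comparison of the set members' statistics against the
#' non-members, one-sided in the requested direction, using the normal
#' approximation with midranks and tie correction (limma's rank-sum gene
#' set test, as called by `geneSetTest(ranks.only = TRUE)`).
#'
#' @param stats Named numeric vector of per-gene statistics (e.g. moderated
#'   t for one contrast).
#' @param gene_set Character vector of gene ids; must be a non-empty strict
#'   subset of the universe.
#' @param alternative `"up"` (members larger) or `"down"`.
#' @return One-sided p-value.
#' @export
gene_set_rank_test <- function(stats, gene_set,
                               alternative = c("up", "down")) {
  alternative <- match.arg(alternative)
  if (!length(gene_set)) stop_invalid("empty gene set")
  idx <- which(names(stats) %in% gene_set)
  if (!length(idx)) stop_invalid("gene set absent from the universe")
  if (length(idx) >= length(stats))
    stop_invalid("gene set must be a strict subset of the universe")
  if (length(unique(stats)) == 1L) return(0.5)  # exchangeable degenerate
  pv <- limma::rankSumTestWithCorrelation(idx, stats, correlation = 0,
                                          df = Inf)
  unname(if (alternative == "up") pv["greater"] else pv["less"])
}

#' Signed log rescaling of a down/up p-value pair
#'
#' `log10(p_down)` when `p_down < p_up`, else `-log10(p_up)`: large
#' negative values mean repression, large positive values activation.
#'
#' @param p_down,p_up P-values in `(0, 1]` from the down- and up-regulation
#'   alternatives.
#' @return Signed log10 statistic.
#' @export
rescale_lm <- function(p_down, p_up) {
  if (any(c(p_down, p_up) <= 0) || any(c(p_down, p_up) > 1))
    stop_invalid("p-values must lie in (0, 1]")
  ifelse(p_down < p_up, log10(p_down), -log10(p_up))
}

#' Rescale per-set statistics to [-1, 1] per signature column
#'
#' Affine map per column sending the maximum to `+1` and the minimum to
#' `-1` (heatmap display convention). Constant columns map to zero and are
#' flagged via the `"constant_columns"` attribute.
#'
#' @param values Numeric matrix (sets x signatures) or vector.
#' @return Rescaled matrix of the same shape.
#' @export
heatmap_rescale <- function(values) {
  v <- as.matrix(values)
  flagged <- integer(0)
  out <- v
  for (j in seq_len(ncol(v))) {
    lo <- min(v[, j])
    hi <- max(v[, j])
    if (hi == lo) {
      out[, j] <- 0
      flagged <- c(flagged, j)
    } else {
      out[, j] <- 2 * (v[, j] - lo) / (hi - lo) - 1
    }
  }
  if (length(flagged)) attr(out, "constant_columns") <- flagged
  out
}

#' Permutation gene-set statistic on moderated t
#'
#' The factorization-style gene-set statistic computed on a linear model:
#' the posterior signal-to-noise ratio is replaced by the empirical-Bayes
#' moderated t-statistic of each gene for one contrast, with the same
#' random-set permutation null and `[-1, 1]` transform.
#'
#' @param fit A [fit_linear_model] result.
#' @param gene_set Character vector of gene ids.
#' @param contrast Contrast (column) index or name.
#' @param n_perm,seed Permutation settings.
#' @param normalization Passed through (`"mean"` or `"sqrt"`).
#' @return A one-row data.frame matching [score_catalog]'s columns.
#' @export
cogaps_style_stat_lm <- function(fit, gene_set, contrast, n_perm = 1000,
                                 seed = 1,
                                 normalization = c("mean", "sqrt")) {
  normalization <- match.arg(normalization)
  stopifnot(inherits(fit, "linear_fit"))
  tvec <- fit$moderated_t[, contrast]
  names(tvec) <- rownames(fit$moderated_t)
  if (!length(gene_set)) stop_invalid("empty gene set")
  missing <- setdiff(gene_set, names(tvec))
  if (length(missing))
    stop_invalid("gene set members absent from fit: ",
                 paste(head(missing, 5), collapse = ", "))
  observed <- zscore_from_ratio(tvec[gene_set], normalization)
  pct <- percentile_from_null(tvec, observed, length(gene_set), n_perm,
                              seed, exhaustive = FALSE, normalization)
  data.frame(level = "lm", set_name = NA_character_,
             pattern = as.character(contrast), R = length(gene_set),
             Z = observed, percentile = pct,
             p_tilde = transform_percentile(pct), n_perm = n_perm,
             seed = seed, stringsAsFactors = FALSE)
}

#' Hierarchical clustering of factorization and linear-model signatures
#'
#' Agglomerative clustering (average linkage) on one minus the Pearson
#' correlation between all signature columns: the amplitude columns of each
#' chain plus the linear-model contrast coefficients. Chains whose
#' signatures for the same pattern merge together before merging with other
#' patterns indicate reproducible factorization signatures.
#'
#' @param A_chains List of amplitude matrices (genes x patterns) with
#'   shared gene rownames; list names label the chains.
#' @param lm_coefficients Genes x conditions coefficient matrix from
#'   [fit_linear_model].
#' @return List with `hclust` (the merge structure) and `cophenetic` (the
#'   cophenetic distance matrix).
#' @export
compare_signatures <- function(A_chains, lm_coefficients) {
  if (is.null(names(A_chains)))
    names(A_chains) <- sprintf("chain%d", seq_along(A_chains))
  genes <- rownames(A_chains[[1]])
  cols <- list()
  for (nm in names(A_chains)) {
    A <- A_chains[[nm]][genes, , drop = FALSE]
    colnames(A) <- paste(nm, colnames(A), sep = ".")
    cols[[length(cols) + 1L]] <- A
  }
  lm <- as.matrix(lm_coefficients)[genes, , drop = FALSE]
  colnames(lm) <- paste("lm", colnames(lm), sep = ".")
  cols[[length(cols) + 1L]] <- lm
  M <- do.call(cbind, cols)
  if (ncol(M) < 2) stop_invalid("need at least 2 signature columns")
  d <- as.dist(1 - cor(M))
  hc <- hclust(d, method = "average")
  list(hclust = hc, cophenetic = cophenetic(hc))
}
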