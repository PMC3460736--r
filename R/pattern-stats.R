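#' Pattern-level gene-set Z score
#'
#' Mean (or root-R-scaled) posterior signal-to-noise of a gene set's
#' amplitudes in one pattern:
#' `Z = (1/R) * sum_{g in set} A_mean[g, pattern] / A_sd[g, pattern]`
#' with `R` the set size. Genes whose posterior standard deviation is zero
#' (never touched by an atom) have it replaced by the smallest positive
#' standard deviation in the column; the replacement is flagged via a
#' warning attribute on the result.
#'
#' @param A_mean,A_sd Amplitude posterior mean and standard deviation
#'   matrices (genes x patterns, gene ids as rownames).
#' @param gene_set Character vector of gene ids (non-empty; all present).
#' @param pattern Pattern (column) index.
#' @param normalization `"mean"` for the `1/R` convention (default) or
#'   `"sqrt"` for `1/sqrt(R)`. The permutation null uses same-size sets, so
#'   the choice rescales `Z` without changing percentiles.
#' @return The Z score (scalar).
#' @export
zscore <- function(A_mean, A_sd, gene_set, pattern,
                   normalization = c("mean", "sqrt")) {
  normalization <- match.arg(normalization)
  if (!length(gene_set)) stop_invalid("empty gene set")
  missing <- setdiff(gene_set, rownames(A_mean))
  if (length(missing))
    stop_invalid("gene set members absent from amplitude matrix: ",
                 paste(head(missing, 5), collapse = ", "))
  ratio <- amplitude_ratio(A_mean, A_sd, pattern)
  zscore_from_ratio(ratio[gene_set], normalization)
}

# per-gene signal-to-noise column with the zero-sd replacement rule
amplitude_ratio <- function(A_mean, A_sd, pattern) {
  m <- A_mean[, pattern]
  s <- A_sd[, pattern]
  if (any(s == 0)) {
    pos <- s[s > 0]
    if (!length(pos))
      stop_invalid("all posterior sds are zero in pattern ", pattern)
    s[s == 0] <- min(pos)
  }
  r <- m / s
  names(r) <- rownames(A_mean)
  r
}

zscore_from_ratio <- function(ratios, normalization = "mean") {
  R <- length(ratios)
  denom <- if (normalization == "mean") R else sqrt(R)
  sum(ratios) / denom
}

#' Permutation percentile of a gene-set Z score
#'
#' Compares the observed Z score with a null distribution of Z scores from
#' random gene sets of the same size `R`, drawn uniformly without
#' replacement from the analyzed gene universe. Returns the mid-p add-one
#' percentile
#' `(0.5 + #(null Z < obs) + 0.5 #(null Z == obs)) / (1 + n_perm)`
#' (the observed set counts as half a draw), which lies strictly inside
#' `(0, 1)`, centres an exchangeable null at 1/2, and reduces to the usual
#' permutation estimator up to `0.5/(1+n_perm)` when ties are absent. With `exhaustive = TRUE` (universe small enough) all
#' `choose(n, R)` subsets are enumerated instead of sampled.
#'
#' @inheritParams zscore
#' @param n_perm Number of random sets (ignored when `exhaustive`).
#' @param seed Integer seed for the random sets.
#' @param exhaustive Enumerate every subset instead of sampling.
#' @return Percentile in `(0, 1]`.
#' @export
permutation_percentile <- function(A_mean, A_sd, gene_set, pattern,
                                   n_perm = 1000, seed = 1,
                                   exhaustive = FALSE,
                                   normalization = c("mean", "sqrt")) {
  normalization <- match.arg(normalization)
  ratio <- amplitude_ratio(A_mean, A_sd, pattern)
  observed <- zscore(A_mean, A_sd, gene_set, pattern, normalization)
  percentile_from_null(ratio, observed, length(gene_set), n_perm, seed,
                       exhaustive, normalization)
}

percentile_from_null <- function(ratio, observed, R, n_perm, seed,
                                 exhaustive = FALSE,
                                 normalization = "mean") {
  n <- length(ratio)
  if (R >= n)
    stop_invalid("set size must be smaller than the gene universe (",
                 R, " >= ", n, ")")
  if (exhaustive) {
    sets <- utils::combn(n, R)
    null_z <- apply(sets, 2,
                    function(ix) zscore_from_ratio(ratio[ix], normalization))
    n_perm <- ncol(sets)
  } else {
    n_perm <- check_count(n_perm, "n_perm")
    null_z <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
      zscore_from_ratio(ratio[sample.int(n, R)], normalization)
    }, numeric(1)))
  }
  (0.5 + sum(null_z < observed) + 0.5 * sum(null_z == observed)) /
    (1 + n_perm)
}

#' Map a percentile to the signed [-1, 1] scale
#'
#' `p_tilde = 2 * percentile - 1`: values near `+1` indicate
#' over-representation (activation) of the gene set in the pattern, values
#' near `-1` under-representation (repression).
#'
#' @param percentile Value(s) in `[0, 1]`.
#' @return `2 * percentile - 1`.
#' @export
transform_percentile <- function(percentile) {
  if (!is.numeric(percentile) || any(is.na(percentile)) ||
      any(percentile < 0) || any(percentile > 1))
    stop_invalid("`percentile` must lie in [0, 1]")
  2 * percentile - 1
}

#' Score a gene-set catalog against a factorization
#'
#' Computes the permutation gene-set statistic for every TF-level target
#' set and every pathway-level union set, in every pattern. The permutation
#' universe is the full set of analyzed genes (the amplitude matrix rows).
#' Catalog genes absent from the matrix are dropped from each set; the
#' effective set size is reported.
#'
#' @param result A `gaps_fit`.
#' @param catalog A [gene_set_catalog].
#' @param n_perm Permutations per set/pattern.
#' @param seed Integer master seed. Each (set, pattern) uses a seed derived
#'   from the master seed, the pattern and the set's membership, so two
#'   sets with identical members (e.g. a pathway consisting of a single TF)
#'   receive identical permutation results.
#' @param normalization Passed to [zscore].
#' @return A data.frame with one row per (set, pattern): `level` (`tf` or
#'   `pathway`), `set_name`, `pattern`, `R` (effective set size), `Z`,
#'   `percentile`, `p_tilde`, `n_perm`, `seed`.
#' @export
score_catalog <- function(result, catalog, n_perm = 1000, seed = 1,
                          normalization = c("mean", "sqrt")) {
  normalization <- match.arg(normalization)
  A_mean <- result$A_mean
  A_sd <- result$A_sd
  genes <- rownames(A_mean)
  p <- ncol(A_mean)

  sets <- c(
    lapply(catalog$tf_targets, function(g) list(level = "tf", genes = g)),
    stats::setNames(
      lapply(names(catalog$pathways), function(pw)
        list(level = "pathway", genes = pathway_set(catalog, pw))),
      names(catalog$pathways)))

  rows <- list()
  counter <- 0L
  for (set_name in names(sets)) {
    members <- intersect(sets[[set_name]]$genes, genes)
    if (!length(members))
      stop_invalid("gene set '", set_name,
                   "' has no members in the analyzed universe")
    for (k in seq_len(p)) {
      counter <- counter + 1L
      ratio <- amplitude_ratio(A_mean, A_sd, k)
      observed <- zscore_from_ratio(ratio[members], normalization)
      # membership-derived seed: identical member sets get identical nulls
      set_seed <- (seed + k +
                     sum(match(sort(members), genes)) * 131L) %% 2147483647L
      pct <- percentile_from_null(ratio, observed, length(members),
                                  n_perm, set_seed,
                                  exhaustive = FALSE, normalization)
      rows[[counter]] <- data.frame(
        level = sets[[set_name]]$level, set_name = set_name, pattern = k,
        R = length(members), Z = observed, percentile = pct,
        p_tilde = transform_percentile(pct), n_perm = n_perm,
        seed = set_seed, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Summarize gene-set statistics across chains
#'
#' Element-wise mean, minimum and maximum of `p_tilde` per (set, pattern)
#' across per-chain [score_catalog] results (chains must be aligned with
#' [match_patterns] first so pattern indices correspond).
#'
#' @param per_chain List of [score_catalog] data.frames with identical
#'   (set, pattern) rows.
#' @return A data.frame: `level`, `set_name`, `pattern`, `mean_p_tilde`,
#'   `min_p_tilde`, `max_p_tilde`.
#' @export
summarize_chains <- function(per_chain) {
  stopifnot(length(per_chain) >= 1)
  key <- function(df) paste(df$set_name, df$pattern)
  k0 <- key(per_chain[[1]])
  for (df in per_chain[-1])
    if (!identical(key(df), k0))
      stop_invalid("chains have mismatched set/pattern lists")
  mat <- vapply(per_chain, `[[`, numeric(length(k0)), "p_tilde")
  mat <- matrix(mat, nrow = length(k0))
  data.frame(level = per_chain[[1]]$level,
             set_name = per_chain[[1]]$set_name,
             pattern = per_chain[[1]]$pattern,
             mean_p_tilde = rowMeans(mat),
             min_p_tilde = apply(mat, 1, min),
             max_p_tilde = apply(mat, 1, max),
             stringsAsFactors = FALSE)
}
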