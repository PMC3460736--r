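#' Project amplitude signatures onto new expression data
#'
#' Estimates pattern weights for new samples with the amplitude matrix held
#' fixed: per sample, the ordinary least-squares solution minimizing
#' `||d - A x||^2` over the genes shared between the signature and the new
#' data. The solve is unconstrained, so negative weights can occur; they are
#' reported and flagged, not clipped.
#'
#' @param new_expr An [expression_matrix] for the new cohort.
#' @param A_fixed Amplitude matrix (genes x patterns, gene ids as rownames,
#'   pattern names as colnames), e.g. the averaged posterior mean from
#'   [average_results].
#' @param signature_subset Optional pattern indices or names restricting
#'   which signatures are projected.
#' @return A `projection_result`: `P_hat` (patterns x new samples),
#'   `signature_names`, `sample_ids`, `n_genes_used`, `n_genes_dropped`
#'   (signature genes absent from the new data) and
#'   `has_negative_weights`.
#' @export
project <- function(new_expr, A_fixed, signature_subset = NULL) {
  stopifnot(inherits(new_expr, "expression_matrix"))
  if (is.null(rownames(A_fixed)))
    stop_invalid("`A_fixed` must carry gene rownames")
  if (is.null(colnames(A_fixed)))
    colnames(A_fixed) <- sprintf("pattern%d", seq_len(ncol(A_fixed)))
  if (!is.null(signature_subset))
    A_fixed <- A_fixed[, signature_subset, drop = FALSE]

  shared <- intersect(rownames(A_fixed), row_ids(new_expr))
  dropped <- nrow(A_fixed) - length(shared)
  if (length(shared) < 5 * ncol(A_fixed))
    stop_invalid("only ", length(shared), " genes shared between signature ",
                 "and new data; need at least 5 per signature")
  A <- A_fixed[shared, , drop = FALSE]
  qrA <- qr(A)
  if (qrA$rank < ncol(A))
    stop_invalid("`A_fixed` is rank deficient over the shared genes")
  d <- new_expr$values[shared, , drop = FALSE]
  P_hat <- qr.coef(qrA, d)
  rownames(P_hat) <- colnames(A)

  structure(list(P_hat = P_hat,
                 signature_names = colnames(A),
                 sample_ids = sample_ids(new_expr),
                 n_genes_used = length(shared),
                 n_genes_dropped = dropped,
                 has_negative_weights = any(P_hat < 0)),
            class = "projection_result")
}

#' @export
print.projection_result <- function(x, ...) {
  cat(sprintf("projection_result: %d signatures x %d samples (%d genes%s)\n",
              nrow(x$P_hat), ncol(x$P_hat), x$n_genes_used,
              if (x$has_negative_weights) "; negative weights present"
              else ""))
  invisible(x)
}

#' Compare projected pattern weights between sample groups
#'
#' Welch (unequal-variance) two-sample t-test on one pattern's projected
#' weights between two sample groups, with selectable sidedness.
#'
#' @param proj A [project] result.
#' @param groups Named character vector or factor mapping sample id ->
#'   group label (must cover the projected samples; exactly two groups are
#'   compared).
#' @param pattern Pattern index or name.
#' @param sided `"two"`, `"greater"` (group A > group B) or `"less"`.
#'   Groups are taken in the order of `levels(factor(groups))` unless
#'   `group_order` is given.
#' @param group_order Optional length-2 character vector fixing which group
#'   is "A" and which is "B".
#' @return List with `t`, `p_value`, `groups`, `sided`, and the group
#'   means.
#' @export
compare_groups <- function(proj, groups, pattern,
                           sided = c("two", "greater", "less"),
                           group_order = NULL) {
  sided <- match.arg(sided)
  stopifnot(inherits(proj, "projection_result"))
  g <- groups[proj$sample_ids]
  if (any(is.na(g)))
    stop_invalid("`groups` must label every projected sample")
  labs <- if (is.null(group_order)) levels(factor(g)) else group_order
  if (length(labs) != 2)
    stop_invalid("exactly two groups are required (got ",
                 length(labs), ")")
  xa <- proj$P_hat[pattern, g == labs[1]]
  xb <- proj$P_hat[pattern, g == labs[2]]
  if (length(xa) < 2 || length(xb) < 2)
    stop_invalid("each group needs at least 2 samples")
  alt <- switch(sided, two = "two.sided", greater = "greater",
                less = "less")
  if (sd(xa) == 0 && sd(xb) == 0 && mean(xa) == mean(xb)) {
    # degenerate: both groups constant and equal
    return(list(t = 0, p_value = if (sided == "two") 1 else 0.5,
                groups = labs, sided = sided,
                mean_A = mean(xa), mean_B = mean(xb)))
  }
  ht <- t.test(xa, xb, alternative = alt, var.equal = FALSE)
  list(t = unname(ht$statistic), p_value = ht$p.value,
       groups = labs, sided = sided,
       mean_A = mean(xa), mean_B = mean(xb))
}
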