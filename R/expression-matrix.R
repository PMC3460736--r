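#' Expression matrix container
#'
#' A genes-(or probes-)by-samples matrix of non-negative expression values
#' with unique row and sample identifiers and, optionally, an element-wise
#' uncertainty (standard-deviation) matrix used by the factorization
#' likelihood.
#'
#' @param values Numeric matrix (rows x samples) with unique, non-empty
#'   `rownames` and `colnames`; all entries must be finite and `>= 0`.
#' @param uncertainty Optional numeric matrix of the same shape, strictly
#'   positive everywhere.
#' @return An object of class `expression_matrix`: a list with elements
#'   `values` and `uncertainty` (possibly `NULL`).
#' @export
expression_matrix <- function(values, uncertainty = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop_invalid("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop_invalid("`values` must carry row and column names")
  if (anyDuplicated(rownames(values)))
    stop_invalid("duplicate row identifier: ",
                 rownames(values)[duplicated(rownames(values))][1L])
  if (anyDuplicated(colnames(values)))
    stop_invalid("duplicate sample identifier: ",
                 colnames(values)[duplicated(colnames(values))][1L])
  if (any(!is.finite(values)))
    stop_invalid("`values` contains non-finite entries")
  if (any(values < 0))
    stop_invalid("expression values must be non-negative")
  if (!is.null(uncertainty)) {
    if (!is.matrix(uncertainty) || !all(dim(uncertainty) == dim(values)))
      stop_invalid("`uncertainty` must match the shape of `values`")
    if (any(!is.finite(uncertainty)) || any(uncertainty <= 0))
      stop_invalid("`uncertainty` must be strictly positive everywhere")
    dimnames(uncertainty) <- dimnames(values)
  }
  structure(list(values = values, uncertainty = uncertainty),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d rows x %d samples (%s uncertainty)\n",
              nrow(x$values), ncol(x$values),
              if (is.null(x$uncertainty)) "no" else "with"))
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

row_ids <- function(x) rownames(x$values)
sample_ids <- function(x) colnames(x$values)
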