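#' @keywords internal
"_PACKAGE"

#' @useDynLib pathgaps, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm rexp runif sd cor quantile model.matrix
#'   as.dist hclust cophenetic t.test pt wilcox.test ks.test median
#' @importFrom utils write.table read.delim head
NULL

# Run `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

stop_invalid <- function(...) stop(..., call. = FALSE)

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
      x != as.integer(x))
    stop_invalid(sprintf("`%s` must be a single integer >= %d", name, min))
  as.integer(x)
}

check_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop_invalid(sprintf("`%s` must be a single value in [0, 1]", name))
  as.numeric(x)
}

# Pearson correlation that tolerates zero-variance vectors (returns 0 and
# would be flagged by callers); used by pattern matching only.
safe_cor <- function(x, y) {
  if (sd(x) == 0 || sd(y) == 0) return(0)
  cor(x, y)
}
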