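#' Sampler configuration
#'
#' Settings for the atomic-prior Gibbs sampler. An iteration is a sweep of
#' single-atom Metropolis-Hastings steps (one per current atom, plus two);
#' each step picks a domain (amplitude or pattern, probability 1/2 each),
#' then birth/death versus move/exchange with probability 1/2.
#'
#' @param n_patterns Number of patterns `p`.
#' @param n_burn,n_sample Burn-in and sampling iterations.
#' @param thin Record every `thin`-th sampling iteration.
#' @param seed Integer master seed; chain `c` of a multi-chain run uses
#'   `seed + c`.
#' @param max_atoms Cap on atoms per domain.
#' @param alpha Expected atoms per matrix element (Poisson intensity of the
#'   atomic prior); controls sparsity.
#' @param lambda_scale Multiplier on the atom-mass prior scale. The base
#'   scale is the typical entry magnitude `sqrt(mean(D)/p)`, so proposed
#'   atom masses are commensurate with matrix entries.
#' @return A `sampler_config` list.
#' @export
sampler_config <- function(n_patterns, n_burn = 2500, n_sample = 2500,
                           thin = 5, seed = 1, max_atoms = 1e5,
                           alpha = 0.01, lambda_scale = 1) {
  n_patterns <- check_count(n_patterns, "n_patterns")
  n_burn <- check_count(n_burn, "n_burn")
  n_sample <- check_count(n_sample, "n_sample")
  thin <- check_count(thin, "thin")
  max_atoms <- check_count(max_atoms, "max_atoms")
  if (max_atoms < n_patterns)
    stop_invalid("`max_atoms` must be at least `n_patterns`")
  if (!is.numeric(alpha) || alpha <= 0)
    stop_invalid("`alpha` must be positive")
  if (!is.numeric(lambda_scale) || lambda_scale <= 0)
    stop_invalid("`lambda_scale` must be positive")
  structure(list(n_patterns = n_patterns, n_burn = n_burn,
                 n_sample = n_sample, thin = thin, seed = as.integer(seed),
                 max_atoms = max_atoms, alpha = alpha,
                 lambda_scale = lambda_scale), class = "sampler_config")
}

#' Chi-squared fit of a factorization
#'
#' `sum(((D - AP) / Sigma)^2)` over all matrix elements, the Gaussian
#' goodness-of-fit of amplitude and pattern matrices to the data under the
#' element-wise uncertainty `Sigma`.
#'
#' @param D An [expression_matrix] with `uncertainty` present.
#' @param A Amplitude matrix (genes x patterns).
#' @param P Pattern matrix (patterns x samples).
#' @return Non-negative scalar.
#' @export
chi2 <- function(D, A, P) {
  if (is.null(D$uncertainty))
    stop_invalid("`D` has no uncertainty matrix; run compute_uncertainty()")
  if (nrow(A) != nrow(D$values) || ncol(P) != ncol(D$values) ||
      ncol(A) != nrow(P))
    stop_invalid("shapes of D, A, P do not conform")
  sum(((D$values - A %*% P) / D$uncertainty)^2)
}

#' Deterministic rough non-negative factorization used as chain start
#'
#' Non-negative double SVD (NNDSVD) initialization refined by a fixed
#' number of Frobenius multiplicative updates, followed by a background
#' consolidation step (see [consolidate_background]). Entirely
#' deterministic in the data, so every chain starts from the same rough
#' fit and the MCMC seeds control only the stochastic refinement around
#' it.
#'
#' @param D Non-negative numeric matrix.
#' @param p Number of factors.
#' @param n_iter Multiplicative-update iterations.
#' @return List with `W` (rows x p) and `H` (p x columns), both
#'   non-negative.
#' @keywords internal
nmf_init <- function(D, p, n_iter = 500) {
  sv <- svd(D, nu = p, nv = p)
  W <- matrix(0, nrow(D), p)
  H <- matrix(0, p, ncol(D))
  W[, 1] <- sqrt(sv$d[1]) * abs(sv$u[, 1])
  H[1, ] <- sqrt(sv$d[1]) * abs(sv$v[, 1])
  if (p > 1) {
    for (k in 2:p) {
      u <- sv$u[, k]
      v <- sv$v[, k]
      up <- pmax(u, 0); un <- pmax(-u, 0)
      vp <- pmax(v, 0); vn <- pmax(-v, 0)
      if (sum(up) * sum(vp) >= sum(un) * sum(vn)) {
        W[, k] <- sqrt(sv$d[k]) * up
        H[k, ] <- sqrt(sv$d[k]) * vp
      } else {
        W[, k] <- sqrt(sv$d[k]) * un
        H[k, ] <- sqrt(sv$d[k]) * vn
      }
    }
  }
  eps <- 1e-6 * max(D)
  W[W < eps] <- eps
  H[H < eps] <- eps
  for (it in seq_len(n_iter)) {
    H <- H * (crossprod(W, D)) / (crossprod(W, W %*% H) + 1e-12)
    W <- W * (D %*% t(H)) / (W %*% tcrossprod(H) + 1e-12)
  }
  consolidate_background(W, H)
}

#' Consolidate a global background pattern into a single factor
#'
#' Non-negative factorizations of data with a global background are only
#' identifiable up to recombinations that split the background across
#' factors whose supports cover the samples (the sparsity prior of the
#' sampler prefers the consolidated representation, but rough least-squares
#' fits are indifferent and often land split). This rotation-to-sparsity
#' step finds the non-negative combination of pattern rows closest to a
#' flat profile; when that combination is genuinely flat (coefficient of
#' variation below 0.2), it replaces the row it draws on most, and the
#' amplitude matrix is transformed by the inverse (small negatives
#' clipped). When the factorization already has a dedicated background row
#' or the data have none, the transform is the identity.
#'
#' @param W,H Non-negative factor matrices (rows x p and p x columns).
#' @return List with the transformed `W` and `H`.
#' @keywords internal
consolidate_background <- function(W, H) {
  p <- nrow(H)
  if (p < 2) return(list(W = W, H = H))
  cvec <- tryCatch(pracma::lsqnonneg(t(H), rep(1, ncol(H)))$x,
                   error = function(e) NULL)
  if (is.null(cvec)) return(list(W = W, H = H))
  flat <- as.vector(cvec %*% H)
  if (mean(flat) <= 0 || sd(flat) / mean(flat) > 0.2)
    return(list(W = W, H = H))
  j <- which.max(cvec * rowSums(H))
  if (cvec[j] < 1e-8) return(list(W = W, H = H))
  Tm <- diag(p)
  Tm[j, ] <- cvec
  Hn <- Tm %*% H
  Wn <- W %*% solve(Tm)
  Wn[Wn < 0] <- 0
  list(W = Wn, H = Hn)
}

#' Run the atomic-prior Gibbs sampler
#'
#' Factors a non-negative expression matrix `D` with element-wise
#' uncertainty `Sigma` into non-negative amplitude (`A`, genes x patterns)
#' and pattern (`P`, patterns x samples) matrices under the model
#' `D ~ N(AP, Sigma)`. Each factor matrix is represented by an atomic
#' domain: a point process of atoms with exponentially distributed masses
#' mapped onto matrix cells, giving a sparse non-negative prior. The Markov
#' chain proposes atom births, deaths, moves and mass exchanges, accepted by
#' Metropolis-Hastings with the Gaussian likelihood via incremental
#' delta-chi-squared updates; birth masses come from an equal mixture of
#' the exponential prior and the conditional truncated-normal for the
#' proposed cell. The chain starts from a deterministic rough non-negative
#' fit ([nmf_init]), so chains with different seeds sample around the same
#' dominant posterior mode rather than re-solving the combinatorial mode
#' search from empty domains. Posterior means and standard deviations are
#' taken over the recorded post-burn-in states.
#'
#' @param D An [expression_matrix] with strictly positive uncertainty.
#' @param config A [sampler_config].
#' @return A `gaps_fit` object: `A_mean`, `A_sd`, `P_mean`, `P_sd`,
#'   `chi2_trace`, `chi2_final` (recomputed on the posterior means),
#'   `config`, atom counts and a `warnings` character vector (e.g. an empty
#'   domain at the end of burn-in).
#' @export
run_sampler <- function(D, config) {
  stopifnot(inherits(D, "expression_matrix"),
            inherits(config, "sampler_config"))
  if (is.null(D$uncertainty))
    stop_invalid("`D` has no uncertainty matrix; run compute_uncertainty()")
  if (any(!is.finite(D$values)))
    stop_invalid("non-finite values in D")
  if (config$n_patterns > min(dim(D$values)))
    stop_invalid("n_patterns exceeds matrix dimensions")

  init <- nmf_init(D$values, config$n_patterns)
  raw <- .gaps_sampler(D$values, D$uncertainty, config$n_patterns,
                       config$n_burn, config$n_sample, config$thin,
                       config$alpha, config$lambda_scale,
                       as.integer(config$max_atoms),
                       as.double(config$seed %% 2^31),
                       init$W, init$H)
  pat <- sprintf("pattern%d", seq_len(config$n_patterns))
  dimnames(raw$A_mean) <- dimnames(raw$A_sd) <-
    list(row_ids(D), pat)
  dimnames(raw$P_mean) <- dimnames(raw$P_sd) <-
    list(pat, sample_ids(D))

  warnings <- character(0)
  if (isTRUE(raw$empty_after_burn))
    warnings <- c(warnings,
                  "a domain held no atoms at the end of burn-in")
  res <- structure(list(
    A_mean = raw$A_mean, A_sd = raw$A_sd,
    P_mean = raw$P_mean, P_sd = raw$P_sd,
    chi2_trace = raw$chi2_trace,
    chi2_final = NA_real_,
    n_atoms = c(A = raw$n_atoms_A, P = raw$n_atoms_P),
    config = config, warnings = warnings), class = "gaps_fit")
  res$chi2_final <- chi2(D, res$A_mean, res$P_mean)
  res
}

#' @export
print.gaps_fit <- function(x, ...) {
  cat(sprintf(
    "gaps_fit: %d genes x %d patterns x %d samples; chi2 = %.4g\n",
    nrow(x$A_mean), ncol(x$A_mean), ncol(x$P_mean), x$chi2_final))
  if (length(x$warnings)) cat("warnings:", x$warnings, "\n")
  invisible(x)
}

# all permutations of 1..n (n small)
all_perms <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (i in seq_len(n)) {
    for (q in all_perms(n - 1L)) {
      out[[length(out) + 1L]] <- c(i, ifelse(q >= i, q + 1L, q))
    }
  }
  out
}

# exact assignment maximizing the total of `score` (p x p matrix, rows =
# reference patterns, cols = candidate patterns); enumeration for p <= 9,
# greedy beyond
best_assignment <- function(score) {
  p <- nrow(score)
  if (p <= 9L) {
    best <- NULL
    best_val <- -Inf
    for (perm in all_perms(p)) {
      v <- sum(score[cbind(seq_len(p), perm)])
      if (v > best_val) {
        best_val <- v
        best <- perm
      }
    }
    best
  } else {
    perm <- integer(p)
    taken <- rep(FALSE, p)
    for (i in order(apply(score, 1, max), decreasing = TRUE)) {
      j <- order(score[i, ], decreasing = TRUE)
      j <- j[!taken[j]][1L]
      perm[i] <- j
      taken[j] <- TRUE
    }
    perm
  }
}

permute_fit <- function(res, perm) {
  res$A_mean <- res$A_mean[, perm, drop = FALSE]
  res$A_sd <- res$A_sd[, perm, drop = FALSE]
  res$P_mean <- res$P_mean[perm, , drop = FALSE]
  res$P_sd <- res$P_sd[perm, , drop = FALSE]
  pat <- sprintf("pattern%d", seq_len(ncol(res$A_mean)))
  colnames(res$A_mean) <- colnames(res$A_sd) <- pat
  rownames(res$P_mean) <- rownames(res$P_sd) <- pat
  res
}

#' Match patterns across independent sampler chains
#'
#' Aligns the patterns of every result to the first by the assignment
#' maximizing total Pearson correlation between `P_mean` rows (exact
#' bipartite assignment, enumerated). Useful before averaging chains or
#' assessing cross-chain reproducibility.
#'
#' @param results List of `gaps_fit` objects with identical dimensions.
#' @return List with `aligned` (results, patterns reordered),
#'   `permutations` (list of integer vectors; `perm[k]` is the source
#'   pattern of aligned pattern `k`) and `correlations` (matrix, chains x
#'   patterns, matched Pearson correlations against the first chain; the
#'   first row is 1 by construction).
#' @export
match_patterns <- function(results) {
  stopifnot(length(results) >= 1)
  dims <- lapply(results, function(r) c(dim(r$A_mean), ncol(r$P_mean)))
  if (!all(vapply(dims, identical, logical(1), dims[[1]])))
    stop_invalid("results have mismatched dimensions")
  p <- ncol(results[[1]]$A_mean)
  ref <- results[[1]]$P_mean
  aligned <- vector("list", length(results))
  perms <- vector("list", length(results))
  cors <- matrix(NA_real_, length(results), p)
  for (i in seq_along(results)) {
    score <- matrix(0, p, p)
    for (a in seq_len(p))
      for (b in seq_len(p))
        score[a, b] <- safe_cor(ref[a, ], results[[i]]$P_mean[b, ])
    perm <- if (i == 1L) seq_len(p) else best_assignment(score)
    aligned[[i]] <- permute_fit(results[[i]], perm)
    perms[[i]] <- perm
    cors[i, ] <- score[cbind(seq_len(p), perm)]
  }
  structure(list(aligned = aligned, permutations = perms,
                 correlations = cors), class = "gaps_match")
}

#' Average aligned sampler chains
#'
#' Element-wise mean of `A_mean` and `P_mean` across chains;
#' `A_sd`/`P_sd` combined as the root-mean-square of the per-chain standard
#' deviations (between-chain variance is not added; this convention is
#' recorded in the result). The chi-squared fit is recomputed on the
#' averaged factors when the data are supplied.
#'
#' @param match A `gaps_match` from [match_patterns] (alignment metadata is
#'   required).
#' @param D Optional [expression_matrix]; when given, `chi2_final` is
#'   recomputed on the averaged factors.
#' @return A `gaps_fit` with the averaged matrices.
#' @export
average_results <- function(match, D = NULL) {
  if (!inherits(match, "gaps_match"))
    stop_invalid("`match` must come from match_patterns() ",
                 "(alignment metadata absent)")
  aligned <- match$aligned
  n <- length(aligned)
  out <- aligned[[1]]
  out$A_mean <- Reduce(`+`, lapply(aligned, `[[`, "A_mean")) / n
  out$P_mean <- Reduce(`+`, lapply(aligned, `[[`, "P_mean")) / n
  out$A_sd <- sqrt(Reduce(`+`, lapply(aligned,
                                      function(r) r$A_sd^2)) / n)
  out$P_sd <- sqrt(Reduce(`+`, lapply(aligned,
                                      function(r) r$P_sd^2)) / n)
  out$chi2_trace <- NULL
  out$n_atoms <- NULL
  out$sd_convention <- "rms of per-chain sds (between-chain variance ignored)"
  out$chi2_final <- if (!is.null(D)) chi2(D, out$A_mean, out$P_mean)
    else NA_real_
  out
}

#' Normalize patterns for reporting
#'
#' Scales each row of `P_mean` to sum to one, multiplying the inverse scale
#' into the corresponding column of `A_mean` so the reconstruction `AP` is
#' unchanged; standard deviations are rescaled by the same factors. All-zero
#' pattern rows are left unscaled and flagged.
#'
#' @param result A `gaps_fit`.
#' @return The rescaled `gaps_fit`; flagged rows (if any) are listed in
#'   `result$flags$zero_rows`.
#' @export
normalize_for_report <- function(result) {
  p <- nrow(result$P_mean)
  zero_rows <- integer(0)
  for (k in seq_len(p)) {
    s <- sum(result$P_mean[k, ])
    if (s == 0) {
      zero_rows <- c(zero_rows, k)
      next
    }
    result$P_mean[k, ] <- result$P_mean[k, ] / s
    result$P_sd[k, ] <- result$P_sd[k, ] / s
    result$A_mean[, k] <- result$A_mean[, k] * s
    result$A_sd[, k] <- result$A_sd[, k] * s
  }
  if (length(zero_rows)) result$flags$zero_rows <- zero_rows
  result
}

#' Select the number of patterns by the chi-squared plateau
#'
#' For each candidate `p`, runs `n_chains` independent chains (seeds
#' `config$seed + chain`), takes the median chi-squared of the posterior
#' means and the cross-chain reproducibility (minimum matched pattern
#' correlation from [match_patterns]). Returns the smallest `p` whose
#' relative chi-squared improvement to `p + 1` falls below `rel_tol` while
#' reproducibility at `p` is at least 0.8; if no candidate qualifies,
#' returns the candidate with minimal median chi-squared with attribute
#' `converged = FALSE`.
#'
#' @param D An [expression_matrix] with uncertainty.
#' @param candidate_range Integer vector of candidate pattern counts
#'   (within `[1, min(dim(D))]`).
#' @param base_config A [sampler_config]; its `n_patterns` is overridden by
#'   each candidate.
#' @param n_chains Chains per candidate (`>= 2`).
#' @param rel_tol Relative chi-squared improvement defining the plateau
#'   (default 0.01).
#' @return The selected count, with attributes `table` (per-candidate
#'   median chi-squared and reproducibility) and `converged`.
#' @export
select_n_patterns <- function(D, candidate_range, base_config,
                              n_chains = 3, rel_tol = 0.01) {
  candidate_range <- sort(unique(as.integer(candidate_range)))
  if (!length(candidate_range))
    stop_invalid("empty candidate range")
  if (min(candidate_range) < 1 || max(candidate_range) > min(dim(D$values)))
    stop_invalid("candidate range outside [1, min(dim(D))]")
  n_chains <- check_count(n_chains, "n_chains", min = 2L)

  med_chi2 <- repro <- rep(NA_real_, length(candidate_range))
  for (i in seq_along(candidate_range)) {
    p <- candidate_range[i]
    chains <- lapply(seq_len(n_chains), function(cc) {
      cfg <- base_config
      cfg$n_patterns <- p
      cfg$seed <- base_config$seed + cc
      run_sampler(D, cfg)
    })
    med_chi2[i] <- median(vapply(chains, `[[`, numeric(1), "chi2_final"))
    m <- match_patterns(chains)
    repro[i] <- min(m$correlations[-1L, , drop = FALSE])
    if (length(chains) == 1L || nrow(m$correlations) == 1L) repro[i] <- 1
  }

  tab <- data.frame(p = candidate_range, median_chi2 = med_chi2,
                    reproducibility = repro)
  selected <- NA_integer_
  for (i in seq_along(candidate_range)) {
    if (i == length(candidate_range)) break
    improvement <- (med_chi2[i] - med_chi2[i + 1]) / med_chi2[i]
    if (improvement < rel_tol && repro[i] >= 0.8) {
      selected <- candidate_range[i]
      break
    }
  }
  converged <- !is.na(selected)
  if (!converged) selected <- candidate_range[which.min(med_chi2)]
  structure(selected, table = tab, converged = converged)
}
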