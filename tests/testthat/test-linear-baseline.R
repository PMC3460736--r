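lm_fixture <- function(n_genes = 200, seed = 5) {
  set.seed(seed)
  X <- cbind(intercept = 1, grp = rep(0:1, each = 4))
  beta <- cbind(rexp(n_genes, 1 / 5), rnorm(n_genes, 0, 0.5))
  Y <- beta %*% t(X) + matrix(rnorm(n_genes * 8, 0, 0.5), n_genes)
  Y <- Y - min(Y) + 0.1
  dimnames(Y) <- list(sprintf("g%04d", seq_len(n_genes)),
                      sprintf("s%d", 1:8))
  list(expr = expression_matrix(Y), X = X)
}

test_that("identical per-gene variances give moderated t = ordinary t", {
  set.seed(1)
  row <- rnorm(8)
  Y <- matrix(rep(row, each = 30), 30, 8) +
    matrix(rep(rnorm(30, 0, 2), 8), 30, 8)  # shift rows, same residuals
  Y <- Y - min(Y) + 0.1
  dimnames(Y) <- list(sprintf("g%02d", 1:30), sprintf("s%d", 1:8))
  X <- cbind(1, rep(0:1, each = 4))
  fit <- fit_linear_model(expression_matrix(Y), X)
  ordinary <- fit$coefficients / (fit$stdev_unscaled * fit$sigma)
  expect_equal(fit$moderated_t, ordinary, tolerance = 1e-8)
  expect_equal(fit$d0, Inf)
})

test_that("forcing infinite prior df gives full shrinkage to s0_sq", {
  fx <- lm_fixture()
  fit <- fit_linear_model(fx$expr, fx$X, d0_override = Inf)
  manual <- fit$coefficients / (fit$stdev_unscaled * sqrt(fit$s0_sq))
  expect_equal(fit$moderated_t, manual, tolerance = 1e-10)
})

test_that("posterior variances interpolate between sigma^2 and s0_sq", {
  fx <- lm_fixture(seed = 6)
  fit <- fit_linear_model(fx$expr, fx$X)
  s_post2 <- if (is.finite(fit$d0)) {
    (fit$d0 * fit$s0_sq + fit$df_residual * fit$sigma^2) /
      (fit$d0 + fit$df_residual)
  } else rep(fit$s0_sq, length(fit$sigma))
  lo <- pmin(fit$sigma^2, fit$s0_sq) - 1e-12
  hi <- pmax(fit$sigma^2, fit$s0_sq) + 1e-12
  expect_true(all(s_post2 >= lo & s_post2 <= hi))
  # and the moderated t uses exactly that variance
  expect_equal(fit$moderated_t,
               fit$coefficients / (fit$stdev_unscaled * sqrt(s_post2)),
               tolerance = 1e-8)
})

test_that("empirical-Bayes hyperparameters are recovered from simulation", {
  set.seed(11)
  d0 <- 4
  s0 <- 0.25
  n <- 2000
  sg2 <- d0 * s0 / rchisq(n, d0)
  X <- cbind(1, rep(0:1, each = 4))
  Y <- t(sapply(sg2, function(v) rnorm(8, 5, sqrt(v))))
  Y <- pmax(Y, 0)
  dimnames(Y) <- list(sprintf("g%04d", 1:n), sprintf("s%d", 1:8))
  fit <- fit_linear_model(expression_matrix(Y), X)
  expect_lt(abs(fit$d0 - d0) / d0, 0.25)
  expect_lt(abs(fit$s0_sq - s0) / s0, 0.10)
})

test_that("rank deficiency is reported with the offending column", {
  fx <- lm_fixture()
  X <- cbind(fx$X, dup = fx$X[, 2])
  expect_error(fit_linear_model(fx$expr, X), "dup")
})

test_that("rank gene-set test matches the normal-approximation oracle", {
  set.seed(21)
  s <- rnorm(10)
  names(s) <- sprintf("g%02d", 1:10)
  top <- names(sort(s, decreasing = TRUE))[1:3]

  p_up <- gene_set_rank_test(s, top, "up")
  oracle <- wilcox.test(s[top], s[!names(s) %in% top],
                        alternative = "greater", exact = FALSE,
                        correct = TRUE)$p.value
  expect_equal(p_up, oracle, tolerance = 1e-8)

  # the exact enumeration tail for the top 3 of 10 is 1/120; the normal
  # approximation must sit near it
  expect_lt(abs(p_up - 1 / 120), 0.02)

  # up and down p-values are complementary under the approximation
  p_down <- gene_set_rank_test(s, top, "down")
  expect_equal(p_up + p_down, 1, tolerance = 0.01)

  tied <- setNames(rep(1, 10), names(s))
  expect_equal(gene_set_rank_test(tied, top, "up"), 0.5, tolerance = 1e-8)

  expect_error(gene_set_rank_test(s, names(s), "up"), "strict subset")
  expect_error(gene_set_rank_test(s, character(0), "up"), "empty")
})

test_that("rescale_lm follows the signed log10 branches", {
  expect_equal(rescale_lm(0.01, 0.99), -2)
  expect_equal(rescale_lm(0.9, 0.001), 3)
  expect_equal(rescale_lm(0.5, 0.5), -log10(0.5))  # tie: otherwise branch
  expect_error(rescale_lm(0, 0.5), "0, 1")
  # antisymmetry at distinct values
  for (pair in list(c(0.02, 0.8), c(0.3, 0.04))) {
    expect_equal(rescale_lm(pair[1], pair[2]),
                 -rescale_lm(pair[2], pair[1]))
  }
})

test_that("heatmap_rescale maps each column onto [-1, 1]", {
  expect_equal(as.vector(heatmap_rescale(c(-2, 0, 3))), c(-1, -0.2, 1))
  expect_equal(as.vector(heatmap_rescale(c(-1, 1))), c(-1, 1))
  flat <- heatmap_rescale(cbind(c(2, 2, 2), c(0, 1, 2)))
  expect_equal(unname(flat[, 1]), c(0, 0, 0))
  expect_equal(attr(flat, "constant_columns"), 1L)
  expect_equal(unname(flat[, 2]), c(-1, 0, 1))
})

test_that("the permutation statistic on moderated t mirrors the Z form", {
  fx <- lm_fixture(seed = 31)
  fit <- fit_linear_model(fx$expr, fx$X)
  tvec <- fit$moderated_t[, 2]

  single <- cogaps_style_stat_lm(fit, names(tvec)[7], 2, n_perm = 50,
                                 seed = 3)
  expect_equal(single$Z, unname(tvec[7]))

  top <- names(sort(tvec, decreasing = TRUE))[1:4]
  res <- cogaps_style_stat_lm(fit, top, 2, n_perm = 500, seed = 4)
  expect_gt(res$p_tilde, 0.99)
  expect_equal(res$p_tilde, 2 * res$percentile - 1)

  # null calibration: random sets under a no-effect simulation are uniform
  set.seed(41)
  Y0 <- matrix(abs(rnorm(300 * 8, 10, 1)), 300, 8,
               dimnames = list(sprintf("g%03d", 1:300),
                               sprintf("s%d", 1:8)))
  fit0 <- fit_linear_model(expression_matrix(Y0), fx$X)
  t0 <- fit0$moderated_t[, 2]
  pct <- vapply(1:300, function(i) {
    cogaps_style_stat_lm(fit0, sample(names(t0), 8), 2, n_perm = 200,
                         seed = 100 + i)$percentile
  }, numeric(1))
  expect_gt(suppressWarnings(ks.test(pct, "punif"))$p.value, 0.01)
})

test_that("signature clustering groups chains before the linear model", {
  st <- strong_study()
  A_chains <- lapply(st$matched$aligned, `[[`, "A_mean")
  names(A_chains) <- sprintf("chain%d", 1:3)

  set.seed(51)
  lm_coef <- matrix(rexp(nrow(A_chains[[1]]) * 2),
                    nrow(A_chains[[1]]), 2,
                    dimnames = list(rownames(A_chains[[1]]),
                                    c("c1", "c2")))
  cl <- compare_signatures(A_chains, lm_coef)
  expect_s3_class(cl$hclust, "hclust")

  # duplicate columns merge at distance ~0
  dup <- compare_signatures(list(a = A_chains[[1]], b = A_chains[[1]]),
                            lm_coef)
  cph <- as.matrix(dup$cophenetic)
  expect_lt(cph["a.pattern1", "b.pattern1"], 1e-10)

  # independent random columns sit near distance 1
  set.seed(52)
  r1 <- matrix(rexp(500), 500, 1, dimnames = list(sprintf("g%03d", 1:500), "r1"))
  r2 <- matrix(rexp(500 * 2), 500, 2,
               dimnames = list(sprintf("g%03d", 1:500), c("x1", "x2")))
  ind <- compare_signatures(list(solo = r1), r2)
  expect_lt(abs(as.matrix(ind$cophenetic)["solo.r1", "lm.x1"] - 1), 0.1)

  # per-pattern chain signatures cluster together before other patterns
  cph3 <- as.matrix(cl$cophenetic)
  for (k in 1:3) {
    same <- sprintf("chain%d.pattern%d", 1:3, k)
    within <- max(cph3[same, same])
    others <- setdiff(colnames(cph3), same)
    between <- min(cph3[same, others])
    expect_lt(within, between)
  }
})
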