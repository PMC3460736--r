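ratio_fixture <- function(n = 10, seed = 3) {
  set.seed(seed)
  A_mean <- matrix(rexp(2 * n), n, 2,
                   dimnames = list(sprintf("g%02d", seq_len(n)), NULL))
  A_sd <- matrix(runif(2 * n, 0.5, 1.5), n, 2)
  list(A_mean = A_mean, A_sd = A_sd)
}

test_that("zscore is the mean posterior signal-to-noise of the set", {
  A_mean <- matrix(c(3, 1, 0), 3, 1, dimnames = list(c("a", "b", "c"), NULL))
  A_sd <- matrix(1, 3, 1)
  expect_equal(zscore(A_mean, A_sd, c("a", "b"), 1), 2)
  expect_equal(zscore(A_mean, A_sd, "a", 1), 3)
  expect_equal(zscore(matrix(0, 3, 1, dimnames = list(c("a", "b", "c"))),
                      A_sd, c("a", "b", "c"), 1), 0)
  # sqrt convention rescales by sqrt(R)
  expect_equal(zscore(A_mean, A_sd, c("a", "b"), 1, "sqrt"), 2 * sqrt(2))
  expect_error(zscore(A_mean, A_sd, character(0), 1), "empty")
  expect_error(zscore(A_mean, A_sd, c("a", "zz"), 1), "zz")
})

test_that("zero posterior sds are replaced by the column minimum", {
  A_mean <- matrix(c(2, 4), 2, 1, dimnames = list(c("a", "b"), NULL))
  A_sd <- matrix(c(0, 2), 2, 1)
  expect_equal(zscore(A_mean, A_sd, c("a", "b"), 1), (2 / 2 + 4 / 2) / 2)
})

test_that("permutation percentile agrees with brute-force enumeration", {
  fx <- ratio_fixture()
  ratio <- fx$A_mean[, 1] / fx$A_sd[, 1]
  gene_set <- names(sort(ratio, decreasing = TRUE))[c(1, 4, 7)]

  # independent oracle: enumerate all choose(10, 3) = 120 subsets
  obs <- mean(ratio[gene_set])
  nulls <- apply(combn(10, 3), 2, function(ix) mean(ratio[ix]))
  oracle <- (0.5 + sum(nulls < obs) + 0.5 * sum(nulls == obs)) / (1 + 120)

  pct <- permutation_percentile(fx$A_mean, fx$A_sd, gene_set, 1,
                                exhaustive = TRUE)
  expect_equal(pct, oracle)

  # the top-3 set dominates every other subset
  top <- names(sort(ratio, decreasing = TRUE))[1:3]
  top_pct <- permutation_percentile(fx$A_mean, fx$A_sd, top, 1,
                                    exhaustive = TRUE)
  expect_gte(top_pct, 120 / 121)
  expect_lt(abs(top_pct - 120 / 121), 1 / 121)

  # sampled percentiles converge to the exhaustive one
  for (np in c(500, 2000)) {
    samp <- permutation_percentile(fx$A_mean, fx$A_sd, gene_set, 1,
                                   n_perm = np, seed = 11)
    expect_lt(abs(samp - oracle), 2 / sqrt(np))
  }

  expect_error(permutation_percentile(fx$A_mean, fx$A_sd,
                                      rownames(fx$A_mean), 1), "smaller")
})

test_that("an exchangeable null centres the percentile at one half", {
  A_mean <- matrix(1, 20, 1, dimnames = list(sprintf("g%02d", 1:20), NULL))
  A_sd <- matrix(1, 20, 1)
  pct <- permutation_percentile(A_mean, A_sd, c("g01", "g02", "g03"), 1,
                                n_perm = 1000, seed = 2)
  expect_lt(abs(pct - 0.5), 0.05)
})

test_that("transform_percentile maps [0, 1] onto [-1, 1]", {
  expect_equal(transform_percentile(1), 1)     # over-representation
  expect_equal(transform_percentile(0), -1)    # under-representation
  expect_equal(transform_percentile(0.5), 0)
  expect_equal(transform_percentile(c(0.25, 0.75)), c(-0.5, 0.5))
  expect_error(transform_percentile(1.2), "0, 1")
  expect_error(transform_percentile(-0.1), "0, 1")
})

test_that("Z increases when adding a gene above the current set mean", {
  fx <- ratio_fixture(n = 15, seed = 9)
  ratio <- fx$A_mean[, 1] / fx$A_sd[, 1]
  base <- names(ratio)[1:4]
  z0 <- zscore(fx$A_mean, fx$A_sd, base, 1)
  above <- names(ratio)[ratio > z0 & !names(ratio) %in% base][1]
  expect_gt(zscore(fx$A_mean, fx$A_sd, c(base, above), 1), z0)
})

test_that("statistics are invariant under consistent gene relabeling", {
  fx <- ratio_fixture()
  perm <- sample(10)
  A2 <- fx$A_mean[perm, , drop = FALSE]
  S2 <- fx$A_sd[perm, , drop = FALSE]
  gene_set <- rownames(fx$A_mean)[c(2, 5, 8)]
  expect_equal(zscore(A2, S2, gene_set, 1),
               zscore(fx$A_mean, fx$A_sd, gene_set, 1))
  expect_equal(
    permutation_percentile(A2, S2, gene_set, 1, exhaustive = TRUE),
    permutation_percentile(fx$A_mean, fx$A_sd, gene_set, 1,
                           exhaustive = TRUE))
})

test_that("score_catalog covers TF and pathway levels consistently", {
  st <- strong_study()
  stats <- score_catalog(st$avg, st$catalog, n_perm = 200, seed = 5)
  expect_equal(nrow(stats), (6 + 3) * 3)  # 6 TF sets + 3 pathways, 3 patterns
  expect_true(all(stats$p_tilde == 2 * stats$percentile - 1))
  expect_true(all(abs(stats$p_tilde) < 1))

  # a pathway holding a single TF equals that TF's result exactly
  cat1 <- gene_set_catalog(list(solo = "TF1_1"),
                           list(TF1_1 = st$catalog$tf_targets$TF1_1))
  s1 <- score_catalog(st$avg, cat1, n_perm = 200, seed = 5)
  tf <- s1[s1$level == "tf", ]
  pw <- s1[s1$level == "pathway", ]
  expect_equal(tf$Z, pw$Z)
  expect_equal(tf$percentile, pw$percentile)
  expect_equal(tf$p_tilde, pw$p_tilde)
})

test_that("summarize_chains reports mean, min and max across chains", {
  st <- strong_study()
  per_chain <- lapply(seq_along(st$matched$aligned), function(i)
    score_catalog(st$matched$aligned[[i]], st$catalog, n_perm = 200,
                  seed = 40 + i))
  summ <- summarize_chains(per_chain)
  expect_equal(nrow(summ), nrow(per_chain[[1]]))
  expect_true(all(summ$min_p_tilde <= summ$mean_p_tilde + 1e-12))
  expect_true(all(summ$mean_p_tilde <= summ$max_p_tilde + 1e-12))

  same <- summarize_chains(list(per_chain[[1]], per_chain[[1]]))
  expect_equal(same$mean_p_tilde, same$min_p_tilde)
  expect_equal(same$mean_p_tilde, same$max_p_tilde)

  toy <- per_chain[[1]][1:3, ]
  toy$p_tilde <- c(-0.5, 0, 0.5)
  mm <- summarize_chains(list(toy, toy, toy))
  expect_equal(mm$mean_p_tilde, c(-0.5, 0, 0.5))

  swapped <- per_chain[[2]][rev(seq_len(nrow(per_chain[[2]]))), ]
  expect_error(summarize_chains(list(per_chain[[1]], swapped)),
               "mismatched")

  # strong planted sets vary little across chains
  planted <- unlist(st$truth$active_sets)
  sub <- summ[summ$set_name %in% planted, ]
  strong <- sub[sub$mean_p_tilde > 0.8, ]
  expect_true(all(strong$max_p_tilde - strong$min_p_tilde < 0.2))
})
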