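batch_dataset <- function(seed = 51, n_batches = 2, magnitude = 1.5) {
  tr <- generate_truth(80, 16, 3, 0.5, seed = seed)
  pl <- plant_genesets(tr, 2, 8, 4, seed = seed + 1)
  expr <- simulate_expression(pl$truth, 0.1, seed = seed + 2)
  ds <- synthetic_dataset(expr, pl$truth,
                          setNames(rownames(expr$values),
                                   rownames(expr$values)), pl$catalog)
  add_batch_and_probes(ds, n_batches, magnitude, 1, seed = seed + 3)
}

batch_mean_diff <- function(expr, design) {
  d1 <- design$batch == "b1"
  rowMeans(expr$values[, !d1, drop = FALSE]) -
    rowMeans(expr$values[, d1, drop = FALSE])
}

test_that("correct_batch removes an additive batch offset", {
  ds <- batch_dataset()
  des <- ds$truth$design
  before <- batch_mean_diff(ds$expression, des)
  corrected <- correct_batch(ds$expression, des)
  after <- batch_mean_diff(corrected, des)
  expect_lt(sd(after), 0.35 * sd(before))
  # per-gene batch difference shrinks to ~0 against its standard error
  se <- apply(corrected$values, 1, sd) / sqrt(ncol(corrected$values) / 4)
  expect_gt(mean(abs(after) < 3 * pmax(se, 1e-8)), 0.95)
})

test_that("correct_batch is a no-op without a batch effect and idempotent", {
  # batches that are exact copies of each other: the fitted batch
  # coefficient is identically zero, so correction must not move the data
  set.seed(61)
  base <- matrix(abs(rnorm(40 * 6, 10, 2)), 40, 6)
  vals <- cbind(base, base)
  expr <- make_expr(vals)
  des <- data.frame(sample_id = sprintf("s%03d", 1:12),
                    condition = rep(rep(c("a", "b"), each = 3), 2),
                    media = "none",
                    batch = rep(c("b1", "b2"), each = 6))
  out <- correct_batch(expr, des)
  expect_lt(max(abs(out$values - expr$values)), 1e-8 * mean(expr$values))

  # away from the clipping boundary the correction is idempotent
  set.seed(62)
  vals2 <- matrix(abs(rnorm(40 * 12, 20, 2)), 40, 12)
  vals2[, 7:12] <- vals2[, 7:12] + rnorm(40, 0, 1.5)
  vals2 <- pmax(vals2, 5)
  expr2 <- make_expr(vals2)
  once <- correct_batch(expr2, des)
  expect_true(all(once$values > 0))  # no clipping occurred
  twice <- correct_batch(once, des)
  expect_lt(max(abs(twice$values - once$values)),
            1e-8 * mean(once$values))
})

test_that("correct_batch rejects degenerate designs", {
  ds <- batch_dataset(seed = 63, n_batches = 1)
  expect_error(correct_batch(ds$expression, ds$truth$design),
               "one batch")

  ds2 <- batch_dataset(seed = 64)
  des <- ds2$truth$design
  des$batch <- ifelse(des$condition == des$condition[1], "b1", "b2")
  expect_error(correct_batch(ds2$expression, des), "confounded")
})

test_that("collapse_probes keeps the strongest-signal probe per gene", {
  # two probes per gene: p1 carries the condition signal, p2 is pure noise;
  # the moderated F on the condition factor must pick p1 nearly always
  n_rep <- 100
  hits <- 0
  cond <- rep(c("a", "b", "c"), each = 4)
  design <- data.frame(sample_id = sprintf("s%03d", 1:12),
                       condition = cond, media = "none", batch = "b1")
  for (r in seq_len(n_rep)) {
    set.seed(7000 + r)
    signal <- 5 + 2 * (cond == "b") - 1.5 * (cond == "c") + rnorm(12, 0, 0.4)
    noise <- 5 + rnorm(12, 0, 0.4)
    vals <- rbind(signal, noise)
    expr <- make_expr(pmax(vals, 0), rows = c("g1_p1", "g1_p2"))
    # one extra gene so the EB fit has something to average over
    filler <- matrix(5 + rnorm(24, 0, 0.4), 2, 12)
    expr <- make_expr(pmax(rbind(vals, filler), 0),
                      rows = c("g1_p1", "g1_p2", "g2_p1", "g2_p2"))
    pm <- setNames(c("g1", "g1", "g2", "g2"), rownames(expr$values))
    out <- collapse_probes(expr, pm, design)
    if (identical(unname(out$values["g1", ]), unname(vals[1, ])))
      hits <- hits + 1
  }
  expect_gte(hits, 95)
})

test_that("collapse_probes handles single probes and ties", {
  cond <- rep(c("a", "b"), each = 3)
  design <- data.frame(sample_id = sprintf("s%03d", 1:6),
                       condition = cond, media = "none", batch = "b1")
  set.seed(99)
  v <- matrix(abs(rnorm(18, 5)), 3, 6)
  expr <- make_expr(v, rows = c("gA_p1", "gB_p1", "gB_p2"))
  pm <- setNames(c("gA", "gB", "gB"), rownames(expr$values))
  out <- collapse_probes(expr, pm, design)
  expect_equal(rownames(out$values), c("gA", "gB"))
  # single-probe gene keeps its probe verbatim
  expect_equal(unname(out$values["gA", ]), unname(v[1, ]))
  # identical probe rows tie on the moderated F; the lexicographically
  # smaller probe id is retained (deterministic across calls)
  ties <- collapse_probes(make_expr(v[c(1, 1, 2), ],
                                    rows = c("g_pB", "g_pA", "h_p1")),
                          setNames(c("g", "g", "h"),
                                   c("g_pB", "g_pA", "h_p1")), design)
  expect_equal(rownames(ties$values), c("g", "h"))
  ties2 <- collapse_probes(make_expr(v[c(1, 1, 2), ],
                                     rows = c("g_pB", "g_pA", "h_p1")),
                           setNames(c("g", "g", "h"),
                                    c("g_pB", "g_pA", "h_p1")), design)
  expect_identical(ties$values, ties2$values)
  expect_error(collapse_probes(expr, pm[-1], design), "probe")
})

test_that("restrict_to_catalog filters rows and preserves order", {
  cat1 <- toy_catalog()
  vals <- matrix(1:12, 6, 2)
  expr <- make_expr(vals, rows = c("FOS", "X1", "EGR1", "JUN", "X2", "MYC"))
  out <- restrict_to_catalog(expr, cat1)
  expect_equal(rownames(out$values), c("FOS", "EGR1", "JUN", "MYC"))

  all_in <- make_expr(vals[1:4, , drop = FALSE],
                      rows = c("FOS", "EGR1", "JUN", "MYC"))
  expect_equal(restrict_to_catalog(all_in, cat1)$values, all_in$values)

  none <- make_expr(vals[1:2, , drop = FALSE], rows = c("X1", "X2"))
  expect_error(restrict_to_catalog(none, cat1), "cannot proceed")
})

test_that("compute_uncertainty applies the fraction and the positive floor", {
  vals <- matrix(c(50, 0, 10, 20), 2, 2)
  expr <- make_expr(vals)
  out <- compute_uncertainty(expr, 0.1)
  expect_equal(out$uncertainty[1, 1], 5)
  floor_val <- 0.1 * quantile(vals[vals > 0], 0.01, names = FALSE)
  expect_equal(out$uncertainty[2, 1], floor_val)
  expect_true(all(out$uncertainty > 0))

  expect_error(compute_uncertainty(expr, 0), "positive")
  zero <- make_expr(matrix(0, 2, 2))
  expect_error(compute_uncertainty(zero, 0.1), "zero")
})
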