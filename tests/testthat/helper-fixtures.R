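# Shared fixture builders. Everything is generated in code; the heavier
# multi-chain study is computed once per test run and memoized.

make_expr <- function(vals, rows = NULL, cols = NULL, frac = NULL) {
  if (is.null(rows)) rows <- sprintf("g%03d", seq_len(nrow(vals)))
  if (is.null(cols)) cols <- sprintf("s%03d", seq_len(ncol(vals)))
  dimnames(vals) <- list(rows, cols)
  expr <- expression_matrix(vals)
  if (!is.null(frac)) expr <- compute_uncertainty(expr, frac)
  expr
}

toy_catalog <- function() {
  gene_set_catalog(
    pathways = list(RAS = c("ELK1", "FOS_TF"), AKT = "ELK1"),
    tf_targets = list(ELK1 = c("FOS", "EGR1"),
                      FOS_TF = c("EGR1", "JUN", "MYC")))
}

# assignment of recovered patterns to true patterns maximizing total
# correlation; returns the matched correlation per true pattern
truth_match_cor <- function(P_true, P_rec) {
  p <- nrow(P_true)
  sc <- sapply(seq_len(p), function(a)
    sapply(seq_len(p), function(b) cor(P_true[a, ], P_rec[b, ])))
  # sc[b, a] = cor(true a, rec b); columns index true patterns
  best <- -Inf
  best_cors <- NULL
  perm_rec <- function(left, acc) {
    if (!length(left)) {
      v <- sapply(seq_len(p), function(a) sc[acc[a], a])
      if (sum(v) > best) {
        best <<- sum(v)
        best_cors <<- v
      }
      return(invisible())
    }
    for (b in left) perm_rec(setdiff(left, b), c(acc, b))
  }
  perm_rec(seq_len(p), integer(0))
  best_cors
}

# one strong-signal planted study (sampler chains are the slow part), shared
# across pattern-stats / projection / factorization tests
.study_cache <- new.env(parent = emptyenv())
strong_study <- function() {
  if (!is.null(.study_cache$study)) return(.study_cache$study)
  truth <- generate_truth(150, 24, 3, 0.7, seed = 81)
  pl <- plant_genesets(truth, sets_per_pattern = 2, set_size = 10,
                       effect = 5, seed = 82)
  expr <- simulate_expression(pl$truth, 0.1, seed = 83)
  chains <- lapply(1:3, function(cc)
    run_sampler(expr, sampler_config(3, n_burn = 1500, n_sample = 1500,
                                     seed = 90 + cc)))
  matched <- match_patterns(chains)
  avg <- average_results(matched, D = expr)
  .study_cache$study <- list(truth = pl$truth, catalog = pl$catalog,
                             expr = expr, chains = chains,
                             matched = matched, avg = avg)
  .study_cache$study
}
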