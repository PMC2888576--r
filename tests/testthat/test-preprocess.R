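test_that("quantile normalization has its closed form on simple input", {
  m <- cbind(a = c(1, 2, 3), b = c(4, 5, 6))
  q <- quantile_normalize(m)
  expect_equal(unname(q[, 1]), c(2.5, 3.5, 4.5))
  expect_equal(unname(q[, 2]), c(2.5, 3.5, 4.5))
})

test_that("ties receive the mean of the reference values they span", {
  ## sorted columns: (1,2,2,5), (4,4,6,8), (1,1,1,2)
  ## reference: (2, 7/3, 3, 5)
  m <- matrix(c(1, 2, 2, 5,  4, 4, 6, 8,  1, 1, 1, 2), 4, 3)
  q <- quantile_normalize(m)
  expect_equal(q[, 3], c(rep(mean(c(2, 7 / 3, 3)), 3), 5))
  expect_equal(q[2, 1], q[3, 1])          # tie in column 1
  expect_equal(q[2, 1], mean(c(7 / 3, 3)))
  expect_equal(q[1, 2], mean(c(2, 7 / 3)))
})

test_that("normalized columns share the distribution; operation idempotent", {
  set.seed(1)
  x <- matrix(rexp(200 * 9, 1 / 1000), 200, 9)
  q <- quantile_normalize(x)
  s <- apply(q, 2, sort)
  expect_equal(max(abs(s - s[, 1])), 0)   # KS distance 0 between any two
  expect_equal(quantile_normalize(q), q)
  ## already-common distribution unchanged
  expect_equal(quantile_normalize(s), s)
})

test_that("quantile normalization agrees with the limma oracle", {
  skip_if_not_installed("limma")
  set.seed(7)
  x <- matrix(rlnorm(500 * 6, 7, 1), 500, 6)
  expect_equal(quantile_normalize(x),
               limma::normalizeQuantiles(x, ties = TRUE),
               tolerance = 1e-12)
})

test_that("non-finite signals are rejected with the offending array named", {
  m <- cbind(a = c(1, 2), b = c(NA, 4))
  expect_error(quantile_normalize(m), "b")
  expect_error(quantile_normalize(matrix(1:3)), ">= 2 arrays")
})

test_that("filter criteria are validated", {
  expect_error(filter_criteria(min_signal = -1))
  expect_error(filter_criteria(min_fold = 0.5))
  expect_error(filter_criteria(alpha = 1.5))
})

make_expr <- function(values, replicates = 3) {
  design <- design_spec(design_cells(), replicates)
  colnames(values) <- design$array_id
  if (is.null(rownames(values)))
    rownames(values) <- paste0("g", seq_len(nrow(values)))
  ate_expression(values, design)
}

test_that("constant high-signal gene passes only the signal criterion", {
  set.seed(3)
  vals <- rbind(matrix(10000, 1, 45),
                matrix(rlnorm(10 * 45, log(3000), 1), 10, 45))
  expr <- make_expr(vals)
  rep <- suppressWarnings(filter_genes(expr))
  expect_true(rep$criteria["g1", "signal"])
  expect_false(rep$criteria["g1", "fold"])
  expect_false(rep$criteria["g1", "ttest"])
  expect_lte(rep$n_pass_all,
             min(rep$n_pass_signal, rep$n_pass_fold, rep$n_pass_ttest))
  expect_equal(rep$n_input, 11)
})

test_that("planted ATE genes pass all three criteria at default settings", {
  s <- small_sim(seed = 3)
  rep <- suppressWarnings(filter_genes(quantile_normalize(s$sim$expr)))
  ate <- ate_ids(s$sim$truth)
  expect_true(all(rowSums(rep$criteria[ate, , drop = FALSE]) == 3))
  expect_true(all(ate %in% rep$passing))
})

test_that("filter is monotone in fold threshold and alpha", {
  s <- small_sim(seed = 8)
  norm <- quantile_normalize(s$sim$expr)
  folds <- c(1.2, 1.6, 2.5, 4)
  n_by_fold <- vapply(folds, function(f)
    suppressWarnings(filter_genes(norm, filter_criteria(min_fold = f)))$n_pass_all,
    integer(1))
  expect_true(all(diff(n_by_fold) <= 0))
  alphas <- c(0.05, 0.01, 0.001)
  n_by_alpha <- vapply(alphas, function(a)
    suppressWarnings(filter_genes(norm, filter_criteria(alpha = a)))$n_pass_all,
    integer(1))
  expect_true(all(diff(n_by_alpha) <= 0))
})

test_that("criterion-3 t machinery matches stats::t.test and the t-CDF oracle", {
  set.seed(11)
  for (i in 1:20) {
    a <- rnorm(3, 10, 2); b <- rnorm(3 + (i %% 3), 12, 3)
    ours_p <- ateminer:::t_from_moments(mean(a), var(a), length(a),
                                        mean(b), var(b), length(b),
                                        "pooled")
    ref <- t.test(a, b, var.equal = TRUE)
    expect_equal(ours_p$p, ref$p.value, tolerance = 1e-12)
    expect_equal(ours_p$t, unname(ref$statistic), tolerance = 1e-12)
    ours_w <- ateminer:::t_from_moments(mean(a), var(a), length(a),
                                        mean(b), var(b), length(b),
                                        "welch")
    refw <- t.test(a, b)
    expect_equal(ours_w$p, refw$p.value, tolerance = 1e-12)
    expect_equal(ours_w$df, unname(refw$parameter), tolerance = 1e-10)
    ## independent textbook oracle (numerical t-density integration)
    expect_equal(ours_p$p, t_p_integrate(ours_p$t, ours_p$df),
                 tolerance = 1e-10)
  }
})

test_that("cells with a single replicate are skipped with a warning", {
  set.seed(4)
  design <- design_spec(design_cells(), 3)
  design <- design[!(design$cell == "CONTROL_d5" & design$replicate > 1), ]
  vals <- matrix(rlnorm(5 * nrow(design), log(6000), 0.5), 5,
                 dimnames = list(paste0("g", 1:5), design$array_id))
  expr <- ate_expression(vals, design)
  expect_warning(p <- ateminer:::pairwise_cell_p(expr), "CONTROL_d5")
  involved <- unlist(strsplit(colnames(p), ".vs.", fixed = TRUE))
  expect_false("CONTROL_d5" %in% involved)
})

test_that("fdr_report flags fewer genes than the unadjusted filter", {
  s <- small_sim(seed = 5)
  norm <- quantile_normalize(s$sim$expr)
  fr <- suppressWarnings(filter_genes(norm))
  fd <- fdr_report(norm)
  expect_true(all(fd$min_p_bh >= fd$min_p))
  expect_true(all(ate_ids(s$sim$truth) %in%
                    fd$gene_id[fd$significant_bh]))
})
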