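test_that("pearson machinery matches cor.test and the t-CDF oracle", {
  set.seed(1)
  for (i in 1:15) {
    n <- sample(5:40, 1)
    x <- rnorm(n); y <- 0.4 * x + rnorm(n)
    ours <- pearson_cor(x, y)
    ref <- cor.test(x, y)
    expect_equal(ours$r, unname(ref$estimate), tolerance = 1e-12)
    expect_equal(ours$p, ref$p.value, tolerance = 1e-12)
    expect_equal(ours$p, t_p_integrate(ours$t, ours$df), tolerance = 1e-10)
  }
  ours <- pearson_cor(1:10, 1:10 * 2)
  expect_equal(ours$r, 1)
  expect_equal(ours$p, 0)
  expect_error(pearson_cor(1:10, rep(1, 10)), "zero variance")
  expect_error(pearson_cor(1:2, 1:2), "3 complete")
})

test_that("pearson p agrees with exhaustive permutation rank ordering", {
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      out <- c(out, lapply(perms(v[-i]), function(p) c(v[i], p)))
    out
  }
  set.seed(2)
  n <- 6
  x <- rnorm(n)
  datasets <- lapply(c(0.2, 0.9, 2.5), function(b) b * x + rnorm(n))
  all_p <- perms(seq_len(n))
  p_perm <- vapply(datasets, function(y) {
    r_obs <- abs(cor(x, y))
    r_all <- vapply(all_p, function(ix) abs(cor(x, y[ix])), numeric(1))
    mean(r_all >= r_obs - 1e-12)
  }, numeric(1))
  p_ours <- vapply(datasets, function(y) pearson_cor(x, y)$p, numeric(1))
  expect_equal(order(p_perm), order(p_ours))
})

test_that("printed significance thresholds reproduce", {
  expect_lte(pearson_p(0.3, 83), 0.01)
  expect_gt(pearson_p(0.25, 83), 0.01)
})

test_that("variance explained follows 100 r^2", {
  expect_equal(round(variance_explained(0.63)), 40)
  expect_equal(variance_explained(0.63), 39.69)
  expect_equal(variance_explained(1), 100)
  expect_equal(variance_explained(-0.5), 25)
  expect_error(variance_explained(1.2))
})

test_that("correlation matrix is symmetric with unit diagonal and masks", {
  set.seed(3)
  d <- data.frame(a = rnorm(50), b = rnorm(50))
  d$c <- d$a + rnorm(50, 0, 0.1)
  cm <- correlation_matrix(d, alpha = 0.01)
  expect_equal(cm$r, t(cm$r))
  expect_equal(unname(diag(cm$r)), rep(1, 3))
  expect_true(cm$significant["a", "c"])
  expect_equal(cm$r["a", "a"], 1)
  ## pairwise-complete handling
  d$b[1:10] <- NA
  cm2 <- correlation_matrix(d)
  expect_equal(cm2$n["a", "b"], 40L)
  expect_equal(cm2$n["a", "c"], 50L)
  ## all-missing pair flagged
  d$b[] <- NA
  cm3 <- correlation_matrix(d)
  expect_true(is.na(cm3$r["a", "b"]))
  expect_match(attr(cm3, "incomplete"), "a:b", all = FALSE)
})

test_that("independent variables are uncorrelated in nearly all seeds", {
  hits <- vapply(1:100, function(s) {
    set.seed(s)
    abs(cor(rnorm(1000), rnorm(1000))) < 0.1
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("planted day-112 structure shows in the correlation matrix", {
  cfg <- generator_config(seed = 13, mice_per_cell = 300,
                          n_genes_per_class = gene_counts(ATE = 4, FLAT = 2))
  phen <- generate_phenotypes(cfg, arms = "CONTROL", ages = 112)
  sim <- generate_expression(cfg, phen)
  vars <- cbind(fat_mass = phen$fm_g, t(sim$per_mouse))
  cm <- correlation_matrix(vars, alpha = 0.01)
  ate <- ate_ids(sim$truth)
  for (g in ate) expect_true(cm$significant["fat_mass", g])
  sub <- cm$significant[ate, ate]
  expect_true(all(sub | diag(length(ate))))
  flat <- sim$truth$gene_id[sim$truth$gene_class == "FLAT"]
  expect_false(any(cm$significant["fat_mass", flat]))
})

test_that("PRCF curves follow the empirical distribution", {
  expect_equal(prcf(5), data.frame(value = 5, percent = 100),
               ignore_attr = TRUE)
  p <- prcf(c(4, 1, 3, 2))
  expect_equal(p$value, 1:4)
  expect_equal(p$percent, c(25, 50, 75, 100))
  ## order invariance and monotonicity
  set.seed(4)
  x <- rlnorm(100)
  expect_equal(prcf(x), prcf(rev(sort(x))))
  expect_true(all(diff(p$value) >= 0) && all(diff(p$percent) >= 0))
  expect_equal(tail(prcf(x)$percent, 1), 100)
  expect_error(prcf(numeric(0)), "finite")
  b <- prcf(x, bin_width = 0.5)
  expect_true(all(diff(b$percent) >= 0))
  expect_equal(tail(b$percent, 1), 100)
})

test_that("under-nutrition shifts the simulated Mest-like PRCF left", {
  cfg <- generator_config(seed = 21, mice_per_cell = 300,
                          n_genes_per_class = gene_counts(ATE = 1))
  phen <- generate_phenotypes(cfg, arms = c("CONTROL", "LUN"), ages = 112)
  sim <- generate_expression(cfg, phen)
  m <- sim$per_mouse["MEST_like", ]
  ctl <- sort(m[phen$arm == "CONTROL"])
  lun <- sort(m[phen$arm == "LUN"])
  ## quantile-wise stochastic dominance: LUN curve uniformly left
  expect_true(all(lun < ctl))
})

test_that("summary-statistic t-test matches a raw-data construction", {
  mk <- function(n, m, s) {
    v <- rnorm(n)
    m + s * (v - mean(v)) / sd(v)
  }
  set.seed(5)
  for (variant in c("pooled", "welch")) {
    a <- mk(14, 10.3, 2.1); b <- mk(9, 8.0, 3.3)
    ours <- t_test_summary(mean(a), sd(a), length(a),
                           mean(b), sd(b), length(b), variant)
    ref <- t.test(a, b, var.equal = variant == "pooled")
    expect_equal(ours$t, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(ours$p, ref$p.value, tolerance = 1e-10)
  }
  ident <- t_test_summary(5, 1, 10, 5, 1, 10)
  expect_equal(ident$t, 0)
  expect_equal(ident$p, 1)
  expect_error(t_test_summary(5, 1, 1, 5, 1, 10), "n >= 2")
})

test_that("printed day-10 body-weight groups separate at p < 0.01", {
  for (variant in c("pooled", "welch"))
    expect_lt(t_test_summary(5.53, 0.71, 44, 3.79, 0.46, 26, variant)$p,
              0.01)
})

test_that("one-way ANOVA with letters behaves across regimes", {
  set.seed(6)
  ## all groups from one distribution: single shared letter
  x <- rnorm(60); g <- rep(letters[1:3], each = 20)
  a1 <- anova_cld(x, g, alpha = 0.01)
  expect_equal(length(unique(a1$groups$letters)), 1)
  ## identical groups: F = 0
  a0 <- anova_cld(rep(c(1, 2), 15), rep(c("p", "q", "r"), each = 10))
  expect_lt(a0$F, 1e-20)
  ## two groups: F = t^2, same p
  x2 <- rnorm(40); g2 <- rep(c("a", "b"), each = 20)
  a2 <- anova_cld(x2, g2)
  tt <- t_test_summary(mean(x2[1:20]), sd(x2[1:20]), 20,
                       mean(x2[21:40]), sd(x2[21:40]), 20)
  expect_equal(a2$F, tt$t^2, tolerance = 1e-10)
  expect_equal(a2$p, tt$p, tolerance = 1e-10)
  ## one clearly shifted group gets its own letter
  x3 <- c(rnorm(50), rnorm(50), rnorm(50, 3))
  g3 <- rep(c("u", "v", "w"), each = 50)
  a3 <- anova_cld(x3, g3, alpha = 0.01)
  lw <- a3$groups$letters[a3$groups$group == "w"]
  expect_false(lw %in% a3$groups$letters[a3$groups$group != "w"])
  expect_equal(a3$groups$letters[a3$groups$group == "u"],
               a3$groups$letters[a3$groups$group == "v"])
  expect_error(anova_cld(rep(1, 20), rep(c("a", "b"), 10)), "degenerate")
  expect_error(anova_cld(rnorm(3), c("a", "a", "b")), "n >= 2")
})
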