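test_that("generator configuration is validated", {
  expect_error(generator_config(mice_per_cell = 6, pool_size = 12),
               "mice_per_cell")
  bad <- table1_params()
  bad$sd[3] <- -1
  expect_error(generator_config(table1 = bad), "negative sd")
  expect_error(generator_config(couplings = list(nonsense = 0.5)),
               "unknown coupling")
  expect_error(generator_config(couplings = list(mest_fatmass_d112 = 1.2)),
               "coupling")
})

test_that("identical seed and config give bit-identical outputs", {
  a <- small_sim(seed = 11)
  b <- small_sim(seed = 11)
  expect_identical(a$phen, b$phen)
  expect_identical(a$sim$expr$values, b$sim$expr$values)
  expect_identical(a$sim$truth, b$sim$truth)
  c3a <- generate_cohort3(small_config(seed = 4), n_mice = 40, n_male = 20)
  c3b <- generate_cohort3(small_config(seed = 4), n_mice = 40, n_male = 20)
  expect_identical(c3a, c3b)
  d <- small_sim(seed = 12)
  expect_false(identical(a$sim$expr$values, d$sim$expr$values))
})

test_that("phenotype records satisfy the domain invariants", {
  phen <- suppressWarnings(
    generate_phenotypes(generator_config(seed = 5, mice_per_cell = 200)))
  expect_true(all(phen$fm_g > 0 & phen$lm_g > 0 & phen$bw_g > 0))
  expect_true(all(phen$fm_g + phen$lm_g <= phen$bw_g + 1e-9))
  expect_true(all(phen$age_days %in% c(5, 10, 21, 56, 112)))
  expect_true(all(phen$arm %in% c("CONTROL", "LUN", "LON")))
  expect_true(all(phen$leptin_ngml >= 0))
  expect_true(all(phen$leptin_ngml == 0 | phen$leptin_ngml >= 0.6))
})

test_that("zero-variance cells are degenerate and flagged", {
  t1 <- table1_params()
  t1$sd <- 0
  cfg <- generator_config(seed = 1, table1 = t1)
  expect_warning(phen <- generate_phenotypes(cfg, arms = "CONTROL",
                                             ages = 10),
                 "degenerate")
  expect_equal(unique(phen$bw_g), 5.53)
  expect_equal(unique(phen$fm_g), 0.69)
})

test_that("large-n cell means match the calibration table (3*sd/sqrt(n))", {
  n <- 3000
  phen <- suppressWarnings(
    generate_phenotypes(generator_config(seed = 42, mice_per_cell = n)))
  t1 <- table1_params()
  for (arm in c("CONTROL", "LUN", "LON")) for (age in c(5, 10, 21, 56, 112)) {
    rows <- phen$arm == arm & phen$age_days == age
    for (v in c("bw", "fm", "leptin", "insulin")) {
      par <- t1[t1$arm == arm & t1$age_days == age & t1$variable == v, ]
      got <- switch(v, bw = phen$bw_g[rows], fm = phen$fm_g[rows],
                    leptin = phen$leptin_latent[rows],
                    insulin = phen$insulin_au[rows])
      expect_lt(abs(mean(got) - par$mean), 3 * par$sd / sqrt(n) + 1e-12,
                label = sprintf("|mean - %s| for %s %s d%d",
                                par$mean, v, arm, age))
    }
  }
})

test_that("latent adiposity factor reproduces the cross-age correlation", {
  ## closed form for the construction: corr(fm_a, fm_b) = lambda_a*lambda_b,
  ## so equal loadings sqrt(0.63) give 0.63
  lam <- generator_config()$latent_loadings
  expect_equal(unname(lam[["CONTROL"]] * lam[["CONTROL"]]), 0.63)
  phen <- generate_phenotypes(
    generator_config(seed = 6, mice_per_cell = 10000),
    arms = "CONTROL", ages = c(10, 112))
  w <- merge(phen[phen$age_days == 10, c("mouse_id", "fm_g")],
             phen[phen$age_days == 112, c("mouse_id", "fm_g")],
             by = "mouse_id")
  expect_equal(cor(w$fm_g.x, w$fm_g.y), 0.63, tolerance = 0.04)
  ## LUN loading is zero: no tracking
  phl <- generate_phenotypes(
    generator_config(seed = 6, mice_per_cell = 5000),
    arms = "LUN", ages = c(10, 112))
  wl <- merge(phl[phl$age_days == 10, c("mouse_id", "fm_g")],
              phl[phl$age_days == 112, c("mouse_id", "fm_g")],
              by = "mouse_id")
  expect_lt(abs(cor(wl$fm_g.x, wl$fm_g.y)), 0.05)
})

test_that("under-nutrition leptin is mostly below the detection floor", {
  phen <- generate_phenotypes(
    generator_config(seed = 9, mice_per_cell = 600),
    arms = "LUN", ages = 10)
  frac <- mean(phen$leptin_ngml > 0)
  ## study: 5 quantifiable of 24 (~21%)
  expect_gt(frac, 0.10)
  expect_lt(frac, 0.35)
})

test_that("ATE archetype has the expansion-tracking profile shape", {
  p <- ateminer:::default_class_profiles()["ATE", ]
  expect_gt(p[["CONTROL_d10"]], p[["LUN_d10"]])
  expect_gt(p[["CONTROL_d5"]], p[["LUN_d5"]])
  for (arm in c("CONTROL", "LUN", "LON"))
    expect_gt(p[[paste0(arm, "_d112")]], p[[paste0(arm, "_d56")]])
  ## nadir at weaning through day 56
  expect_true(all(p[c("CONTROL_d21", "CONTROL_d56")] <
                    p[c("CONTROL_d5", "CONTROL_d112")]))
})

test_that("zero technical noise makes replicate arrays equal the pool mean", {
  s <- small_sim(seed = 2, noise_cv = 0)
  expr <- s$sim$expr
  for (cc in unique(expr$design$cell)) {
    cols <- which(expr$design$cell == cc)
    expect_true(all(expr$values[, cols] == expr$values[, cols[1]]))
    rows <- which(s$sim$per_mouse_info$cell == cc)
    expect_equal(unname(expr$values[, cols[1]]),
                 unname(rowMeans(s$sim$per_mouse[, rows])),
                 tolerance = 1e-12)
  }
})

test_that("per-mouse expression recovers the configured fat-mass coupling", {
  ## target: the day-112 Mest/fat-mass coupling (0.83), measured at day 10
  ## on cohorts of 119 males over seeds
  rs <- vapply(1:25, function(s) {
    cfg <- generator_config(seed = s, mice_per_cell = 119,
                            n_genes_per_class = gene_counts(ATE = 2))
    phd <- generate_phenotypes(cfg, arms = "CONTROL", ages = 10)
    sim <- generate_expression(cfg, phd)
    cor(sim$per_mouse["MEST_like", ], phd$fm_g)
  }, numeric(1))
  expect_true(all(abs(rs - 0.83) < 0.12))
  expect_lt(abs(mean(rs) - 0.83), 0.03)
})

test_that("cohort 3 respects its couplings and guards", {
  cfg <- generator_config(seed = 1,
                          n_genes_per_class = gene_counts(ATE = 2, FLAT = 2))
  c3 <- generate_cohort3(cfg, n_mice = 5000, n_male = 2500)
  ph <- c3$phenotypes
  expect_true(all(ph$litter_size %in% 6:12))
  expect_equal(cor(ph$bw_g, ph$fm_g), 0.76, tolerance = 0.03)
  expect_equal(cor(ph$fm_g, ph$adipocyte_area_au), 0.648, tolerance = 0.03)
  expect_equal(cor(ph$litter_size, ph$fm_g), -0.325, tolerance = 0.04)
  expect_equal(sum(ph$sex == "M"), 2500)
  ## decoupled litter size
  cfg0 <- generator_config(seed = 2,
                           couplings = list(littersize_fatmass = 0),
                           n_genes_per_class = gene_counts(ATE = 1))
  ph0 <- generate_cohort3(cfg0, n_mice = 5000)$phenotypes
  expect_lt(abs(cor(ph0$litter_size, ph0$fm_g)), 0.05)
  expect_warning(generate_cohort3(cfg, n_mice = 5), "not meaningful")
})

test_that("expression generation requires enough mice and valid input", {
  cfg <- small_config(seed = 1)
  phen <- generate_phenotypes(cfg)
  few <- phen[phen$mouse_id %in% unique(phen$mouse_id)[1:3] |
                phen$arm != "CONTROL", ]
  expect_error(generate_expression(cfg, few), "pool_size")
  expect_error(generate_expression(cfg, phen[, 1:4]), "generator columns")
  allzero <- gene_counts()
  expect_error(
    generate_expression(generator_config(n_genes_per_class = allzero),
                        phen),
    "no genes")
})
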