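## Synthetic-data generator: per-mouse phenotypes and pooled-array expression
## with the statistical structure the downstream pipeline assumes, so every
## stage can be tested against planted ground truth.

GENE_CLASSES <- c("ATE", "HFD_INDUCED", "LUN_INDUCED", "DEV_EARLY",
                  "MATERNAL_HFD", "FLAT")

## Class archetype profiles: multiplicative signal per design cell, rows =
## class, columns in design_cells() order (arm-major, ages 5/10/21/56/112).
## ATE: induced while fat mass expands (suckling under positive energy
## balance, adult high-fat diet), suppressed by under-nutrition, nadir at
## weaning through day 56. HFD_INDUCED: diet response only. LUN_INDUCED: up
## under under-nutrition. DEV_EARLY: developmental, nutrition-independent.
## MATERNAL_HFD: constitutively up in offspring of high-fat-fed dams.
## FLAT: null genes, no structure.
default_class_profiles <- function() {
  p <- rbind(
    ATE          = c(6.0, 5.0, 1.5, 1.0, 8.0,   1.8, 1.5, 1.2, 1.0, 5.0,
                     6.0, 5.0, 1.5, 1.0, 8.0),
    HFD_INDUCED  = c(1.0, 1.0, 1.0, 1.0, 6.0,   1.0, 1.0, 1.0, 1.0, 6.0,
                     1.0, 1.0, 1.0, 1.0, 6.0),
    LUN_INDUCED  = c(1.0, 1.0, 1.0, 1.0, 1.0,   4.0, 4.0, 3.0, 1.0, 1.0,
                     1.0, 1.0, 1.0, 1.0, 1.0),
    DEV_EARLY    = c(5.0, 5.0, 3.0, 1.0, 1.0,   5.0, 5.0, 3.0, 1.0, 1.0,
                     5.0, 5.0, 3.0, 1.0, 1.0),
    MATERNAL_HFD = c(1.0, 1.0, 1.0, 1.0, 1.0,   1.0, 1.0, 1.0, 1.0, 1.0,
                     4.0, 4.0, 4.0, 2.0, 2.0),
    FLAT         = rep(1.0, 15)
  )
  colnames(p) <- design_cells()$cell
  p
}

## Median baseline signal and per-class log-SD of the baseline spread.
## Structured classes sit in the well-detected range (their real
## counterparts passed a 5000-signal floor); FLAT genes emulate the full
## >10,000-fold dynamic range of the platform, most of them far below the
## detection floor, so the quantile map between arrays is anchored by a
## deep, stable background.
default_class_baselines <- function() {
  c(ATE = 2500, HFD_INDUCED = 2500, LUN_INDUCED = 2500, DEV_EARLY = 2500,
    MATERNAL_HFD = 2500, FLAT = 3000)
}

default_baseline_sdlog <- function() {
  c(ATE = 0.3, HFD_INDUCED = 0.3, LUN_INDUCED = 0.3, DEV_EARLY = 0.3,
    MATERNAL_HFD = 0.3, FLAT = 1.5)
}

## ---- small distributional helpers ------------------------------------------

## Moment-matched lognormal parameters for a given mean/sd (mean > 0).
lnorm_match <- function(mean, sd) {
  stopifnot(mean > 0, sd >= 0)
  if (sd == 0) return(c(meanlog = log(mean), sdlog = 0))
  s2 <- log(1 + (sd / mean)^2)
  c(meanlog = log(mean) - s2 / 2, sdlog = sqrt(s2))
}

## Underlying mean of a left-truncated-at-zero normal chosen so the
## truncated mean equals `mean` (plain truncation inflates the mean when
## mean/sd is small, which would break the calibration-fidelity invariant).
trunc0_location <- function(mean, sd) {
  stopifnot(mean > 0, sd >= 0)
  if (sd == 0 || mean / sd > 8) return(mean)
  f <- function(mu) {
    a <- mu / sd
    mu + sd * stats::dnorm(a) / stats::pnorm(a) - mean
  }
  stats::uniroot(f, lower = mean - 12 * sd, upper = mean,
                 tol = 1e-12)$root
}

## Map standard-normal disturbances u to left-truncated-at-zero normal draws
## with E[X] = mean, via the probability-integral transform; monotone in u so
## correlation structure carried by u is preserved.
trunc0_transform <- function(u, mean, sd) {
  if (sd == 0) return(rep(mean, length(u)))
  mu <- trunc0_location(mean, sd)
  p0 <- stats::pnorm(-mu / sd)
  mu + sd * stats::qnorm(p0 + stats::pnorm(u) * (1 - p0))
}

## Map standard-normal disturbances to a moment-matched lognormal.
lnorm_transform <- function(u, mean, sd) {
  par <- lnorm_match(mean, sd)
  exp(par[["meanlog"]] + par[["sdlog"]] * u)
}

## Pooled variance of an equal-weight mixture of per-cell distributions with
## the given means and sds (law of total variance; exact for the
## moment-matched lognormal cells).
mixture_var <- function(means, sds) {
  mean(sds^2) + mean(means^2) - mean(means)^2
}

## ---- configuration ---------------------------------------------------------

#' Generator configuration
#'
#' Bundles every tunable of the synthetic-data generator. Defaults are the
#' study conditions: 12 mice per (arm, age) cell pooled into one RNA pool
#' hybridized to three replicate arrays; phenotype cells calibrated from the
#' published group summary statistics ([table1_params()]); a per-mouse latent
#' adiposity factor giving cross-age fat-mass correlation
#' `prod(latent loadings)` = 0.63 for CONTROL/LON and ~0 for LUN; plasma
#' leptin lognormal per cell, coupled to fat mass, censored at a detection
#' floor chosen so only ~5/24 under-nourished day-10 pups are quantifiable;
#' inguinal leptin mRNA coupled to plasma leptin so their pooled Pearson r
#' over arms x ages 5-21 d is 0.894 in expectation.
#'
#' @param seed Integer seed; all generator randomness derives from it.
#' @param mice_per_cell Mice simulated per design cell (>= `pool_size`).
#' @param arrays_per_pool Replicate arrays per pool (default 3).
#' @param pool_size Mice pooled per cell (default 12).
#' @param n_genes_per_class Named integer vector over
#'   `ATE`, `HFD_INDUCED`, `LUN_INDUCED`, `DEV_EARLY`, `MATERNAL_HFD`,
#'   `FLAT`; zero counts allowed.
#' @param table1 Calibration table as from [table1_params()].
#' @param couplings Named list of correlation parameters:
#'   `leptin_mrna_plasma` (pooled, 0.894), `fatmass_adipocyte` (0.648),
#'   `littersize_fatmass` (signed, default -0.325), `mest_fatmass_d112`
#'   (0.83), `bodyweight_fatmass` (within-cell, 0.76), `leptin_fatmass`
#'   (latent log-scale, 0.7).
#' @param latent_loadings Per-arm loading of the persistent latent adiposity
#'   factor; cross-age fat-mass correlation between two ages is the product
#'   of their loadings (constant per arm here).
#' @param leptin_floor ELISA detection floor in ng/ml; plasma leptin below it
#'   is reported as 0.
#' @param leptin_mrna_offset Baseline mRNA signal (AU) added to the coupled
#'   term, keeping mRNA positive.
#' @param noise_cv Coefficient of variation of multiplicative technical array
#'   noise (default 0.05, low for replicate hybridizations of one pool).
#' @param biological_cv Per-mouse biological CV of true expression around the
#'   cell profile (default 0.25).
#' @param profile_jitter_sdlog Log-SD of per-gene jitter around the class
#'   profile (FLAT genes get none).
#' @param class_profiles,class_baselines Class archetype profile matrix and
#'   baseline signals; see `default_class_profiles()`.
#' @return Object of class `ate_generator_config` (a validated list; element
#'   `derived$leptin_mrna_noise_sd` holds the closed-form mRNA noise SD
#'   implied by the pooled leptin coupling).
#' @export
#' @examples
#' cfg <- generator_config(seed = 1, mice_per_cell = 12)
#' cfg$derived$leptin_mrna_noise_sd
generator_config <- function(seed = 1L,
                             mice_per_cell = 12L,
                             arrays_per_pool = 3L,
                             pool_size = 12L,
                             n_genes_per_class = c(ATE = 53L,
                                                   HFD_INDUCED = 1000L,
                                                   LUN_INDUCED = 1000L,
                                                   DEV_EARLY = 1000L,
                                                   MATERNAL_HFD = 1000L,
                                                   FLAT = 28943L),
                             table1 = table1_params(),
                             couplings = list(),
                             latent_loadings = c(CONTROL = sqrt(0.63),
                                                 LUN = 0,
                                                 LON = sqrt(0.63)),
                             leptin_floor = 0.6,
                             leptin_mrna_offset = 8,
                             noise_cv = 0.05,
                             biological_cv = 0.25,
                             profile_jitter_sdlog = 0.1,
                             class_profiles = default_class_profiles(),
                             class_baselines = default_class_baselines()) {
  defaults <- list(leptin_mrna_plasma = 0.894,
                   fatmass_adipocyte = 0.648,
                   littersize_fatmass = -0.325,
                   mest_fatmass_d112 = 0.83,
                   bodyweight_fatmass = 0.76,
                   leptin_fatmass = 0.7)
  unknown <- setdiff(names(couplings), names(defaults))
  if (length(unknown))
    stop("unknown coupling parameter(s): ", paste(unknown, collapse = ", "))
  couplings <- utils::modifyList(defaults, couplings)

  if (mice_per_cell < pool_size)
    stop("configuration error: mice_per_cell (", mice_per_cell,
         ") < pool_size (", pool_size, ")")
  if (any(table1$sd < 0))
    stop("configuration error: negative sd in calibration table")
  if (any(vapply(couplings, abs, 1) > 1))
    stop("configuration error: |coupling| > 1")
  stopifnot(arrays_per_pool >= 1, noise_cv >= 0, biological_cv >= 0,
            leptin_floor >= 0, all(latent_loadings >= 0),
            all(latent_loadings <= 1),
            all(names(latent_loadings) == ARMS))
  missing_cls <- setdiff(GENE_CLASSES, names(n_genes_per_class))
  if (length(missing_cls))
    n_genes_per_class[missing_cls] <- 0L
  n_genes_per_class <- n_genes_per_class[GENE_CLASSES]
  stopifnot(all(n_genes_per_class >= 0))
  stopifnot(identical(dim(class_profiles), c(6L, 15L)),
            all(class_profiles > 0), all(class_baselines > 0))

  ## Closed-form mRNA noise SD: pooled Pearson r between plasma leptin P and
  ## mRNA M = offset + P + e is 1/sqrt(1 + var(e)/var_pool(P)); the reference
  ## population is the 9-cell early-lactation mixture (3 arms x d5/d10/d21).
  early <- table1[table1$variable == "leptin" & table1$age_days <= 21, ]
  v <- mixture_var(early$mean, early$sd)
  r <- couplings$leptin_mrna_plasma
  tau <- if (r >= 1) 0 else sqrt(v) * sqrt(1 / r^2 - 1)

  structure(list(seed = as.integer(seed),
                 mice_per_cell = as.integer(mice_per_cell),
                 arrays_per_pool = as.integer(arrays_per_pool),
                 pool_size = as.integer(pool_size),
                 n_genes_per_class = n_genes_per_class,
                 table1 = table1,
                 couplings = couplings,
                 latent_loadings = latent_loadings,
                 leptin_floor = leptin_floor,
                 leptin_mrna_offset = leptin_mrna_offset,
                 noise_cv = noise_cv,
                 biological_cv = biological_cv,
                 profile_jitter_sdlog = profile_jitter_sdlog,
                 class_profiles = class_profiles,
                 class_baselines = class_baselines,
                 derived = list(leptin_mrna_noise_sd = tau,
                                leptin_ref_pool_var = v)),
            class = "ate_generator_config")
}

## ---- phenotypes ------------------------------------------------------------

## One arm x age block of phenotype draws given per-mouse disturbances.
phenotype_cell <- function(config, arm, age, u_fm, u2, u3, u4, u5) {
  t1 <- config$table1
  cp <- config$couplings
  fmp <- table1_lookup(t1, arm, age, "fm")
  bwp <- table1_lookup(t1, arm, age, "bw")
  lep <- table1_lookup(t1, arm, age, "leptin")
  ins <- table1_lookup(t1, arm, age, "insulin")

  fm <- trunc0_transform(u_fm, fmp$mean, fmp$sd)
  rho <- cp$bodyweight_fatmass
  u_bw <- rho * u_fm + sqrt(1 - rho^2) * u2
  bw <- trunc0_transform(u_bw, bwp$mean, bwp$sd)
  ## consistency repair: lean = weight - fat must stay positive
  bad <- fm > 0.95 * bw
  if (any(bad)) fm[bad] <- 0.95 * bw[bad]
  lm <- bw - fm

  w <- cp$leptin_fatmass
  z_lep <- w * u_fm + sqrt(1 - w^2) * u3
  lep_latent <- lnorm_transform(z_lep, lep$mean, lep$sd)
  leptin <- ifelse(lep_latent < config$leptin_floor, 0, lep_latent)
  mrna <- pmax(0, config$leptin_mrna_offset + lep_latent +
                 config$derived$leptin_mrna_noise_sd * u4)

  z_ins <- 0.5 * u_fm + sqrt(1 - 0.25) * u5
  insulin <- lnorm_transform(z_ins, ins$mean, ins$sd)

  area <- adipocyte_area_values(config, fmp$mean, u_fm,
                                stats::rnorm(length(u_fm)))

  data.frame(arm = arm, age_days = age, bw_g = bw, fm_g = fm, lm_g = lm,
             leptin_ngml = leptin, insulin_au = insulin,
             leptin_mrna_au = mrna, adipocyte_area_au = area,
             fm_z = u_fm, leptin_latent = lep_latent,
             stringsAsFactors = FALSE)
}

## Adipocyte cross-sectional area (AU): cell mean grows with the cell's mean
## fat mass; within-cell disturbance coupled to the fat-mass disturbance at
## the configured correlation, linear so the raw-scale Pearson r equals it.
adipocyte_area_values <- function(config, fm_mean, u_fm, eps) {
  rho <- abs(config$couplings$fatmass_adipocyte)
  x <- rho * u_fm + sqrt(1 - rho^2) * eps
  mu <- 800 + 250 * fm_mean
  pmax(mu * (1 + 0.3 * x), 0.05 * mu)
}

#' Simulate per-mouse adiposity phenotypes
#'
#' Draws `mice_per_cell` mice per nutrition arm, followed longitudinally
#' across the design ages. Fat mass and body weight are mean-calibrated
#' left-truncated normals per (arm, age) cell; a persistent per-mouse latent
#' adiposity factor (loading per arm) produces positive cross-age fat-mass
#' correlations for CONTROL/LON and none for LUN; lean mass is
#' body weight minus fat mass with consistency repair. Plasma leptin is a
#' fat-mass-coupled moment-matched lognormal censored at the detection
#' floor (reported as 0 when non-quantifiable); leptin mRNA is plasma
#' leptin plus calibrated noise; insulin and adipocyte area follow the same
#' disturbance machinery.
#'
#' @param config An [generator_config()] object.
#' @param arms,ages Optional subsets of arms/ages to simulate.
#' @return Data frame of class `ate_phenotypes`, one row per mouse x age,
#'   with columns `mouse_id`, `arm`, `sex`, `litter_size`, `age_days`,
#'   `bw_g`, `fm_g`, `lm_g`, `leptin_ngml`, `insulin_au`, `leptin_mrna_au`,
#'   `adipocyte_area_au`, plus latent columns `fm_z` (the mouse's
#'   standardized fat-mass disturbance) and `leptin_latent` (pre-censoring
#'   plasma leptin) used by the expression generator. Cells with zero SD are
#'   degenerate (all mice at the cell mean) and listed in the
#'   `degenerate_cells` attribute.
#' @export
#' @examples
#' phen <- generate_phenotypes(generator_config(seed = 7))
#' aggregate(fm_g ~ arm + age_days, phen, mean)
generate_phenotypes <- function(config, arms = ARMS, ages = AGES) {
  stopifnot(inherits(config, "ate_generator_config"),
            all(arms %in% ARMS), all(ages %in% AGES))
  set.seed(config$seed)
  n <- config$mice_per_cell
  out <- vector("list", length(arms) * length(ages))
  k <- 0L
  for (arm in arms) {
    z <- stats::rnorm(n)                      # persistent latent adiposity
    sex <- sample(c("M", "F"), n, replace = TRUE)
    ids <- sprintf("%s_m%04d", arm, seq_len(n))
    lam <- config$latent_loadings[[arm]]
    for (age in ages) {
      u_fm <- lam * z + sqrt(1 - lam^2) * stats::rnorm(n)
      cell <- phenotype_cell(config, arm, age, u_fm,
                             stats::rnorm(n), stats::rnorm(n),
                             stats::rnorm(n), stats::rnorm(n))
      cell <- cbind(data.frame(mouse_id = ids, stringsAsFactors = FALSE),
                    cell)
      cell$sex <- sex
      cell$litter_size <- ARM_LITTER_SIZE[[arm]]
      k <- k + 1L
      out[[k]] <- cell
    }
  }
  phen <- do.call(rbind, out)
  phen <- phen[, c("mouse_id", "arm", "sex", "litter_size", "age_days",
                   "bw_g", "fm_g", "lm_g", "leptin_ngml", "insulin_au",
                   "leptin_mrna_au", "adipocyte_area_au",
                   "fm_z", "leptin_latent")]
  rownames(phen) <- NULL
  t1 <- config$table1
  degen <- t1[t1$sd == 0 & t1$arm %in% arms & t1$age_days %in% ages, ]
  if (nrow(degen)) {
    attr(phen, "degenerate_cells") <-
      paste(degen$arm, degen$age_days, degen$variable, sep = ":")
    warning("zero-variance calibration cells are degenerate: ",
            paste(attr(phen, "degenerate_cells"), collapse = ", "),
            "; cross-age correlations involving them are undefined")
  }
  class(phen) <- c("ate_phenotypes", "data.frame")
  phen
}

## ---- gene specs and expression --------------------------------------------

## Deterministic-given-RNG-state gene specification table. The first two ATE
## genes are the marker archetypes (Mest-like, Bmp3-like) carrying the
## configured day-112 fat-mass coupling.
build_gene_specs <- function(config) {
  counts <- config$n_genes_per_class
  cls <- rep(names(counts), counts)
  n <- length(cls)
  if (n == 0L) stop("n_genes_per_class is all zero: no genes to simulate")
  ids <- sprintf("%s_%04d", cls, unlist(lapply(counts, seq_len),
                                        use.names = FALSE))
  if (counts[["ATE"]] >= 1) ids[cls == "ATE"][1] <- "MEST_like"
  if (counts[["ATE"]] >= 2) ids[cls == "ATE"][2] <- "BMP3_like"
  baseline <- config$class_baselines[cls] *
    exp(stats::rnorm(n, 0, default_baseline_sdlog()[cls]))
  coupling <- numeric(n)
  is_ate <- cls == "ATE"
  coupling[is_ate] <- stats::runif(sum(is_ate), 0.45, 0.70)
  coupling[ids %in% c("MEST_like", "BMP3_like")] <-
    config$couplings$mest_fatmass_d112
  ## Per-gene multiplicative jitter of the class profile, shared across
  ## cells where the archetype takes the same value: a gene deviates from
  ## its class's response magnitudes, but contrasts the class defines as
  ## null (e.g. CONTROL vs LUN at day 5 for a diet-response-only gene)
  ## stay exactly null, keeping the planted classes recoverable by
  ## construction. FLAT genes therefore stay exactly flat.
  ## ATE genes get half the jitter of the other classes: the expansion
  ## cluster is described as near-superimposable gene profiles, and the
  ## template-matching stage relies on that tightness.
  jitter_sd <- ifelse(cls == "ATE", 0.5, 1) * config$profile_jitter_sdlog
  profiles <- config$class_profiles[cls, , drop = FALSE]
  for (i in seq_len(n)) {
    grp <- match(profiles[i, ], unique(profiles[i, ]))
    jit <- exp(stats::rnorm(max(grp), 0, jitter_sd[i]))
    profiles[i, ] <- profiles[i, ] * jit[grp]
  }
  rownames(profiles) <- ids
  list(spec = data.frame(gene_id = ids, gene_class = cls,
                         baseline = baseline, fat_coupling = coupling,
                         stringsAsFactors = FALSE),
       profiles = profiles)
}

## Per-mouse true expression for one block of phenotype rows (single cell):
## baseline x profile x (1 + cv_bio * x), x = coupling * fm_z + noise.
true_expression_block <- function(specs, config, cell, fm_z) {
  g <- nrow(specs$spec)
  m <- length(fm_z)
  gamma <- specs$spec$fat_coupling
  eps <- matrix(stats::rnorm(g * m), g, m)
  x <- gamma %o% fm_z + sqrt(1 - gamma^2) * eps
  base <- specs$spec$baseline * specs$profiles[, cell]
  vals <- base * (1 + config$biological_cv * x)
  pmax(vals, 0.05 * base)
}

#' Simulate pooled microarray expression data
#'
#' Given a phenotype table, draws per-mouse true expression for each gene
#' (class archetype profile x per-gene jitter x a biological disturbance
#' coupled to the mouse's fat-mass z-score for ATE genes), averages
#' `pool_size` mice per (arm, age) cell into one pool, and emits
#' `arrays_per_pool` replicate arrays per pool under mean-unbiased
#' multiplicative lognormal technical noise with CV `noise_cv`. Planted ATE
#' genes satisfy the downstream Venn criteria by construction at default
#' effect sizes; FLAT genes satisfy none.
#'
#' @param config An [generator_config()] object.
#' @param phen Phenotypes from [generate_phenotypes()] covering at least
#'   `pool_size` mice in every (arm, age) cell present.
#' @return Object of class `ate_simulation`: list with `expr`
#'   (an [ate_expression()] of pooled arrays), `truth` (gene_id, gene_class,
#'   baseline, fat_coupling), `per_mouse` (genes x mouse-age matrix of true
#'   expression; columns named `mouse_id.age`), and `per_mouse_info`
#'   (the matching phenotype rows).
#' @export
#' @examples
#' cfg <- generator_config(seed = 1, n_genes_per_class =
#'   c(ATE = 5, FLAT = 5, HFD_INDUCED = 0, LUN_INDUCED = 0,
#'     DEV_EARLY = 0, MATERNAL_HFD = 0))
#' sim <- generate_expression(cfg, generate_phenotypes(cfg))
#' sim$expr
generate_expression <- function(config, phen) {
  stopifnot(inherits(config, "ate_generator_config"),
            inherits(phen, "data.frame"))
  need <- c("mouse_id", "arm", "age_days", "fm_z")
  if (!all(need %in% names(phen)))
    stop("phenotype table lacks generator columns: ",
         paste(setdiff(need, names(phen)), collapse = ", "))
  set.seed(config$seed + 1L)
  specs <- build_gene_specs(config)

  phen$cell <- cell_key(phen$arm, phen$age_days)
  cells_present <- unique(phen$cell)
  canon <- design_cells()
  canon <- canon[canon$cell %in% cells_present, ]
  short <- table(phen$cell)
  if (any(short < config$pool_size))
    stop("cells with fewer mice than pool_size: ",
         paste(names(short)[short < config$pool_size], collapse = ", "))

  g <- nrow(specs$spec)
  per_mouse <- matrix(NA_real_, g, nrow(phen),
                      dimnames = list(specs$spec$gene_id,
                                      paste0(phen$mouse_id, ".d",
                                             phen$age_days)))
  pools <- matrix(NA_real_, g, nrow(canon),
                  dimnames = list(specs$spec$gene_id, canon$cell))
  for (i in seq_len(nrow(canon))) {
    cc <- canon$cell[i]
    rows <- which(phen$cell == cc)
    vals <- true_expression_block(specs, config, cc, phen$fm_z[rows])
    per_mouse[, rows] <- vals
    members <- if (length(rows) == config$pool_size) seq_along(rows) else
      sample(length(rows), config$pool_size)
    pools[, i] <- rowMeans(vals[, members, drop = FALSE])
  }

  design <- design_spec(canon, config$arrays_per_pool)
  sdlog <- sqrt(log(1 + config$noise_cv^2))
  arrays <- matrix(NA_real_, g, nrow(design),
                   dimnames = list(specs$spec$gene_id, design$array_id))
  for (j in seq_len(nrow(design))) {
    noise <- if (sdlog == 0) 1 else
      exp(stats::rnorm(g, 0, sdlog) - sdlog^2 / 2)
    arrays[, j] <- pools[, design$cell[j]] * noise
  }

  structure(list(expr = ate_expression(arrays, design),
                 truth = specs$spec,
                 per_mouse = per_mouse,
                 per_mouse_info = phen),
            class = "ate_simulation")
}

#' @export
print.ate_simulation <- function(x, ...) {
  cat(sprintf("ate_simulation: %d genes (%s), %d arrays, %d mice x ages\n",
              nrow(x$truth),
              paste(names(table(x$truth$gene_class)),
                    table(x$truth$gene_class), sep = ":", collapse = " "),
              ncol(x$expr$values), ncol(x$per_mouse)))
  invisible(x)
}

## ---- cohort 3 --------------------------------------------------------------

#' Simulate the single-condition developmental cohort
#'
#' An independent cohort raised under control conditions only and phenotyped
#' at 10 days of age: litter sizes 6-12, fat mass weakly coupled to litter
#' size (competition; configured |r| = 0.325, sign configurable), body
#' weight coupled to fat mass (r = 0.76), adipocyte area monotone-plus-noise
#' in fat mass (r = 0.648), plus per-mouse expression of the gene panel at
#' the CONTROL day-10 cell.
#'
#' @param config An [generator_config()] object.
#' @param n_mice Total mice (default 249; of which ~119 male).
#' @param n_male Number of males; phenotypes are emitted for all mice, and
#'   downstream analyses conventionally subset males.
#' @return List with `phenotypes` (class `ate_phenotypes`) and `per_mouse`
#'   expression matrix (genes x mice) with `truth` attached as attribute.
#' @export
#' @examples
#' c3 <- generate_cohort3(generator_config(seed = 3), n_mice = 60, n_male = 30)
#' cor(c3$phenotypes$fm_g, c3$phenotypes$bw_g)
generate_cohort3 <- function(config, n_mice = 249L,
                             n_male = round(n_mice * 119 / 249)) {
  stopifnot(inherits(config, "ate_generator_config"), n_male <= n_mice)
  if (n_mice < 10)
    warning("n_mice < 10: correlation targets are not meaningful")
  set.seed(config$seed + 2L)
  cp <- config$couplings

  litter <- sample(6:12, n_mice, replace = TRUE)
  ## standardize against the discrete-uniform moments so the coupling is the
  ## population correlation, not a per-draw renormalization
  ls_z <- (litter - 9) / 2
  b <- cp$littersize_fatmass
  u_fm <- b * ls_z + sqrt(1 - b^2) * stats::rnorm(n_mice)
  cell <- phenotype_cell(config, "CONTROL", 10L, u_fm,
                         stats::rnorm(n_mice), stats::rnorm(n_mice),
                         stats::rnorm(n_mice), stats::rnorm(n_mice))
  phen <- cbind(data.frame(mouse_id = sprintf("C3_m%04d", seq_len(n_mice)),
                           stringsAsFactors = FALSE),
                cell)
  phen$sex <- rep(c("M", "F"), c(n_male, n_mice - n_male))
  phen$litter_size <- litter
  phen <- phen[, c("mouse_id", "arm", "sex", "litter_size", "age_days",
                   "bw_g", "fm_g", "lm_g", "leptin_ngml", "insulin_au",
                   "leptin_mrna_au", "adipocyte_area_au",
                   "fm_z", "leptin_latent")]
  class(phen) <- c("ate_phenotypes", "data.frame")

  specs <- build_gene_specs(config)
  vals <- true_expression_block(specs, config, "CONTROL_d10", phen$fm_z)
  dimnames(vals) <- list(specs$spec$gene_id, phen$mouse_id)
  attr(vals, "truth") <- specs$spec
  list(phenotypes = phen, per_mouse = vals)
}
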