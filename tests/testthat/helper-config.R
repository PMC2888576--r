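## Shared fixtures. Most tests run on deliberately small gene universes;
## default-scale (full platform) runs are expensive (~20 s) and cached per
## seed so acceptance and clustering tests can share them.

gene_counts <- function(ATE = 0, HFD_INDUCED = 0, LUN_INDUCED = 0,
                        DEV_EARLY = 0, MATERNAL_HFD = 0, FLAT = 0) {
  c(ATE = as.integer(ATE), HFD_INDUCED = as.integer(HFD_INDUCED),
    LUN_INDUCED = as.integer(LUN_INDUCED),
    DEV_EARLY = as.integer(DEV_EARLY),
    MATERNAL_HFD = as.integer(MATERNAL_HFD), FLAT = as.integer(FLAT))
}

## small universe for fast unit tests
small_config <- function(seed = 1,
                         n_genes_per_class = gene_counts(
                           ATE = 5, HFD_INDUCED = 5, LUN_INDUCED = 5,
                           DEV_EARLY = 5, MATERNAL_HFD = 5, FLAT = 20),
                         ...) {
  generator_config(seed = seed, n_genes_per_class = n_genes_per_class, ...)
}

## reduced universe for the noise-degradation grid: class structure intact,
## scaled down from the platform default so 100 simulations fit the budget
grid_config <- function(seed, noise_cv) {
  generator_config(seed = seed, noise_cv = noise_cv,
                   n_genes_per_class = gene_counts(ATE = 53,
                                                   HFD_INDUCED = 50,
                                                   LUN_INDUCED = 50,
                                                   DEV_EARLY = 50,
                                                   MATERNAL_HFD = 50,
                                                   FLAT = 800))
}

small_sim <- function(seed = 1, ...) {
  cfg <- small_config(seed = seed, ...)
  phen <- suppressWarnings(generate_phenotypes(cfg))
  list(cfg = cfg, phen = phen, sim = generate_expression(cfg, phen))
}

## Default-scale (platform-sized) run cache: simulate + normalize + filter
## once per seed; per-mouse matrices are dropped to bound memory.
.default_runs <- new.env(parent = emptyenv())

default_run <- function(seed) {
  key <- as.character(seed)
  if (!is.null(.default_runs[[key]])) return(.default_runs[[key]])
  cfg <- generator_config(seed = seed)
  phen <- suppressWarnings(generate_phenotypes(cfg))
  sim <- generate_expression(cfg, phen)
  sim$per_mouse <- NULL
  sim$per_mouse_info <- NULL
  norm <- quantile_normalize(sim$expr)
  frep <- filter_genes(norm)
  keep <- norm
  keep$values <- keep$values[frep$passing, , drop = FALSE]
  res <- list(cfg = cfg, truth = sim$truth, norm = norm,
              filter = frep, kept = keep)
  .default_runs[[key]] <- res
  res
}

ate_ids <- function(truth) truth$gene_id[truth$gene_class == "ATE"]

## independent textbook oracle: two-tailed t probability by numerical
## integration of the t density (never uses pt())
t_p_integrate <- function(t, df) {
  dens <- function(x) {
    gamma((df + 1) / 2) / (sqrt(df * pi) * gamma(df / 2)) *
      (1 + x^2 / df)^(-(df + 1) / 2)
  }
  2 * stats::integrate(dens, abs(t), Inf, rel.tol = 1e-12)$value
}
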