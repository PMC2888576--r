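## End-to-end driver: simulate -> normalize -> filter -> cluster/template ->
## Venn cascade -> association, with a machine-readable run manifest.

#' Pipeline configuration
#'
#' @param generator A [generator_config()] object (its seed drives every
#'   stochastic stage).
#' @param filter A [filter_criteria()] object.
#' @param clustering List with `k`, `n_restarts`, `weight_rate` (template
#'   weight on the fat-accumulation-rate component) and `min_cor`.
#' @param comparisons List of [comparison_spec()]s for the Venn cascade.
#' @param association List with `alpha` for correlation masks.
#' @return Object of class `ate_pipeline_config`.
#' @export
pipeline_config <- function(generator = generator_config(),
                            filter = filter_criteria(),
                            clustering = list(k = 50L, n_restarts = 10L,
                                              weight_rate = 0.5,
                                              min_cor = 0.5),
                            comparisons = default_comparisons(),
                            association = list(alpha = 0.01)) {
  stopifnot(inherits(generator, "ate_generator_config"),
            inherits(filter, "ate_filter_criteria"))
  structure(list(generator = generator, filter = filter,
                 clustering = clustering, comparisons = comparisons,
                 association = association),
            class = "ate_pipeline_config")
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(deparse(config), tmp)
  unname(tools::md5sum(tmp))
}

write_manifest <- function(out_dir, config, outputs) {
  manifest <- list(
    package = "ateminer",
    version = as.character(utils::packageVersion("ateminer")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$generator$seed,
    config_hash = config_hash(config),
    timestamp = format(Sys.time(), tz = "UTC"),
    outputs = outputs)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  manifest
}

stage <- function(name, expr) {
  t0 <- Sys.time()
  res <- tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE))
  message(sprintf("[%s] done in %.2fs", name,
                  as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  res
}

#' Run the full ATE discovery pipeline on synthetic data
#'
#' Generates phenotypes and pooled expression arrays, quantile-normalizes,
#' applies the three-criterion filter, clusters the standardized profiles
#' of passing genes and selects the template-matching cluster, runs the
#' Venn cascade, and computes association statistics (correlation matrix of
#' marker expression and adiposity at day 112; PRCF of Mest-like expression
#' per arm). When `out_dir` is given, writes the phenotype CSV, expression
#' TSV + design sidecar, truth labels, filter report, cluster summary,
#' Venn gene lists, correlation report and PRCF tables, plus a
#' `manifest.json` recording seed, versions and config hash.
#'
#' @param config An [pipeline_config()] object.
#' @param out_dir Optional output directory (created if missing).
#' @return Invisible list with elements `phenotypes`, `sim`, `normalized`,
#'   `filter_report`, `clusters`, `template_match`, `venn`, `associations`,
#'   and `manifest` (when writing).
#' @export
#' @examples
#' \donttest{
#' res <- run_pipeline(pipeline_config(generator_config(seed = 42)))
#' res$venn
#' }
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "ate_pipeline_config"))
  gen <- config$generator

  phen <- stage("simulate-phenotypes", generate_phenotypes(gen))
  sim <- stage("simulate-expression", generate_expression(gen, phen))
  norm <- stage("normalize", quantile_normalize(sim$expr))
  frep <- stage("filter", filter_genes(norm, config$filter))

  empty <- length(frep$passing) == 0
  clus <- tmpl_match <- venn <- NULL
  if (!empty) {
    keep <- norm
    keep$values <- keep$values[frep$passing, , drop = FALSE]
    prof <- stage("standardize", standardize_profiles(keep))
    k_eff <- min(config$clustering$k, nrow(prof) - 1L)
    clus <- stage("cluster",
                  kmeans_profiles(prof, k = k_eff, seed = gen$seed,
                                  n_restarts = config$clustering$n_restarts))
    markers <- intersect(c("MEST_like", "BMP3_like"), rownames(prof))
    tmpl <- ate_template(gen$table1,
                         marker_profiles = prof[markers, , drop = FALSE],
                         weight_rate = config$clustering$weight_rate)
    tmpl_match <- stage("template-match",
                        select_cluster_by_template(clus, tmpl,
                                                   config$clustering$min_cor))
    venn <- stage("venn", venn_ate(keep, config$comparisons))
  } else {
    venn <- venn_cascade(list(A = character(0), B = character(0),
                              C = character(0), D = character(0),
                              E = character(0)))
  }

  assoc <- stage("associate", pipeline_associations(config, phen, sim))

  out <- list(phenotypes = phen, sim = sim, normalized = norm,
              filter_report = frep, clusters = clus,
              template_match = tmpl_match, venn = venn,
              associations = assoc)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    files <- write_pipeline_outputs(out, out_dir)
    out$manifest <- write_manifest(out_dir, config, files)
  }
  invisible(out)
}

## Association analytics on the per-mouse simulated data: day-112
## marker/adiposity correlations and per-arm PRCF of the Mest-like gene.
pipeline_associations <- function(config, phen, sim) {
  info <- sim$per_mouse_info
  d112 <- info$age_days == 112
  markers <- intersect(c("MEST_like", "BMP3_like"),
                       rownames(sim$per_mouse))
  cm <- NULL
  if (sum(d112) >= 3 && length(markers)) {
    vars <- cbind(fat_mass = info$fm_g[d112],
                  body_weight = info$bw_g[d112],
                  t(sim$per_mouse[markers, d112, drop = FALSE]))
    cm <- correlation_matrix(vars, alpha = config$association$alpha)
  }
  prcfs <- NULL
  if ("MEST_like" %in% rownames(sim$per_mouse) && sum(d112) >= 1) {
    prcfs <- lapply(split(sim$per_mouse["MEST_like", d112],
                          info$arm[d112]), prcf)
  }
  list(cormat = cm, prcf_mest_d112 = prcfs)
}

write_pipeline_outputs <- function(res, out_dir) {
  p <- function(f) file.path(out_dir, f)
  write_phenotypes(res$phenotypes, p("phenotypes.csv"))
  write_expression(res$sim$expr, p("expression.tsv"))
  write_truth(res$sim$truth, p("gene_truth.tsv"))
  utils::write.csv(data.frame(
    criterion = c("input", "signal", "fold", "ttest", "all"),
    n = c(res$filter_report$n_input, res$filter_report$n_pass_signal,
          res$filter_report$n_pass_fold, res$filter_report$n_pass_ttest,
          res$filter_report$n_pass_all)),
    p("filter_report.csv"), row.names = FALSE)
  if (!is.null(res$clusters)) {
    utils::write.table(data.frame(
      gene_id = names(res$clusters$assignments),
      cluster = res$clusters$assignments,
      selected = res$clusters$assignments ==
        (res$template_match$cluster %||% -1L)),
      p("clusters.tsv"), sep = "\t", row.names = FALSE, quote = FALSE)
  }
  for (s in names(res$venn$sets)) {
    writeLines(res$venn$sets[[s]], p(sprintf("venn_%s.txt", s)))
  }
  if (!is.null(res$associations$cormat)) {
    utils::write.csv(res$associations$cormat$r, p("correlations.csv"))
  }
  if (!is.null(res$associations$prcf_mest_d112)) {
    for (arm in names(res$associations$prcf_mest_d112)) {
      utils::write.table(res$associations$prcf_mest_d112[[arm]],
                         p(sprintf("prcf_mest_d112_%s.tsv", arm)),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    }
  }
  list.files(out_dir)
}
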