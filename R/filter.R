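## Gene-selection filter: minimal signal, fold variation between groups, and
## at least one significant pairwise t-test across the design cells.

#' Filter criteria for gene selection
#'
#' The published selection rule: a gene is kept when (1) its group signal
#' reaches `min_signal` in at least `min_groups_at_signal` of the design
#' cells, (2) its expression varies at least `min_fold`-fold between some
#' two cells, and (3) at least one pairwise two-tailed t-test between cell
#' replicates is significant at `alpha`.
#'
#' @param min_signal Minimal linear signal (default 5000).
#' @param min_groups_at_signal Cells that must reach it (default 3).
#' @param min_fold Minimal max/min group-mean ratio (default 1.6).
#' @param alpha Per-comparison significance level (default 0.01).
#' @param signal_any_array If `TRUE`, criterion 1 uses the max single array
#'   in a cell instead of the replicate mean.
#' @param variant `"pooled"` (classical equal-variance, default) or
#'   `"welch"` t-test for criterion 3.
#' @param comparisons Optional 2-column matrix of cell-name pairs for
#'   criterion 3; default all pairwise comparisons.
#' @return Object of class `ate_filter_criteria`.
#' @export
filter_criteria <- function(min_signal = 5000, min_groups_at_signal = 3L,
                            min_fold = 1.6, alpha = 0.01,
                            signal_any_array = FALSE,
                            variant = c("pooled", "welch"),
                            comparisons = NULL) {
  stopifnot(min_signal > 0, min_fold >= 1, alpha > 0, alpha < 1,
            min_groups_at_signal >= 1)
  structure(list(min_signal = min_signal,
                 min_groups_at_signal = as.integer(min_groups_at_signal),
                 min_fold = min_fold, alpha = alpha,
                 signal_any_array = isTRUE(signal_any_array),
                 variant = match.arg(variant),
                 comparisons = comparisons),
            class = "ate_filter_criteria")
}

## Vectorized two-sample t-test from per-group means, variances and sizes.
## Zero-variance convention (needed in the noise-free limit): both group
## variances zero => p = 0 if the means differ, 1 if they are equal.
t_from_moments <- function(m1, v1, n1, m2, v2, n2,
                           variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  if (variant == "pooled") {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- rep_len(n1 + n2 - 2, length(se))
  } else {
    a <- v1 / n1; b <- v2 / n2
    se <- sqrt(a + b)
    df <- (a + b)^2 / (a^2 / (n1 - 1) + b^2 / (n2 - 1))
  }
  t <- (m1 - m2) / se
  p <- 2 * stats::pt(-abs(t), df)
  degen <- se == 0
  if (any(degen, na.rm = TRUE)) {
    p[degen] <- ifelse(m1[degen] == m2[degen], 1, 0)
    t[degen] <- ifelse(m1[degen] == m2[degen], 0,
                       sign(m1[degen] - m2[degen]) * Inf)
    df[degen] <- NA_real_
  }
  list(t = t, df = df, p = p)
}

## Per-cell replicate moments of an expression object.
cell_moments <- function(expr) {
  idx <- cell_columns(expr)
  g <- nrow(expr$values)
  m <- vapply(idx, function(j) rowMeans(expr$values[, j, drop = FALSE]),
              numeric(g))
  v <- vapply(idx, function(j) {
    x <- expr$values[, j, drop = FALSE]
    if (ncol(x) < 2) rep(NA_real_, g) else
      rowSums((x - rowMeans(x))^2) / (ncol(x) - 1)
  }, numeric(g))
  n <- vapply(idx, length, integer(1))
  if (g == 1L) {
    m <- matrix(m, 1, dimnames = list(NULL, names(idx)))
    v <- matrix(v, 1, dimnames = list(NULL, names(idx)))
  }
  list(mean = m, var = v, n = n)
}

## Genes x comparisons matrix of pairwise p-values between design cells.
pairwise_cell_p <- function(expr, comparisons = NULL,
                            variant = "pooled", warn_small = TRUE) {
  mom <- cell_moments(expr)
  cells <- colnames(mom$mean)
  if (is.null(comparisons)) {
    comparisons <- t(utils::combn(cells, 2))
  }
  small <- cells[mom$n < 2]
  if (length(small) && warn_small)
    warning("cells with < 2 replicate arrays skipped in t-tests: ",
            paste(small, collapse = ", "))
  keep <- !(comparisons[, 1] %in% small | comparisons[, 2] %in% small)
  comparisons <- comparisons[keep, , drop = FALSE]
  p <- matrix(NA_real_, nrow(expr$values), nrow(comparisons),
              dimnames = list(rownames(expr$values),
                              paste(comparisons[, 1], comparisons[, 2],
                                    sep = ".vs.")))
  for (i in seq_len(nrow(comparisons))) {
    a <- comparisons[i, 1]; b <- comparisons[i, 2]
    p[, i] <- t_from_moments(mom$mean[, a], mom$var[, a], mom$n[[a]],
                             mom$mean[, b], mom$var[, b], mom$n[[b]],
                             variant)$p
  }
  p
}

#' Apply the three-criterion gene-selection filter
#'
#' @param expr An [ate_expression()] object (quantile-normalized; a warning
#'   is issued if the columns do not share a distribution).
#' @param crit [filter_criteria()] object.
#' @return Object of class `ate_filter_report`: counts per criterion
#'   (`n_input`, `n_pass_signal`, `n_pass_fold`, `n_pass_ttest`,
#'   `n_pass_all`), the `passing` gene ids, and the per-gene logical matrix
#'   `criteria`.
#' @export
#' @examples
#' cfg <- generator_config(seed = 1)
#' sim <- generate_expression(cfg, generate_phenotypes(cfg))
#' filter_genes(quantile_normalize(sim$expr), filter_criteria())
filter_genes <- function(expr, crit = filter_criteria()) {
  stopifnot(inherits(expr, "ate_expression"),
            inherits(crit, "ate_filter_criteria"))
  cs <- apply(expr$values, 2, sort)
  if (max(abs(cs - rowMeans(cs))) > 1e-8 * max(abs(cs)))
    warning("arrays do not share a common distribution; ",
            "filter assumes quantile-normalized input")

  mom <- cell_moments(expr)
  if (crit$signal_any_array) {
    idx <- cell_columns(expr)
    sig <- vapply(idx, function(j)
      apply(expr$values[, j, drop = FALSE], 1, max),
      numeric(nrow(expr$values)))
  } else sig <- mom$mean
  pass1 <- rowSums(sig >= crit$min_signal) >= crit$min_groups_at_signal

  lo <- apply(mom$mean, 1, min)
  hi <- apply(mom$mean, 1, max)
  fold <- ifelse(lo > 0, hi / lo, ifelse(hi > 0, Inf, 1))
  pass2 <- fold >= crit$min_fold

  p <- pairwise_cell_p(expr, crit$comparisons, crit$variant)
  pass3 <- apply(p < crit$alpha, 1, any, na.rm = TRUE)

  criteria <- cbind(signal = pass1, fold = pass2, ttest = pass3)
  rownames(criteria) <- rownames(expr$values)
  all_pass <- pass1 & pass2 & pass3
  structure(list(n_input = nrow(expr$values),
                 n_pass_signal = sum(pass1),
                 n_pass_fold = sum(pass2),
                 n_pass_ttest = sum(pass3),
                 n_pass_all = sum(all_pass),
                 passing = rownames(expr$values)[all_pass],
                 criteria = criteria,
                 crit = crit),
            class = "ate_filter_report")
}

#' @export
print.ate_filter_report <- function(x, ...) {
  cat(sprintf(paste0("ate_filter_report: %d genes in; signal %d, fold %d, ",
                     "t-test %d; all criteria %d\n"),
              x$n_input, x$n_pass_signal, x$n_pass_fold, x$n_pass_ttest,
              x$n_pass_all))
  invisible(x)
}

#' Benjamini-Hochberg FDR report (post-hoc)
#'
#' The selection filter deliberately uses unadjusted per-comparison
#' p-values; this helper reports, for transparency, how many genes would
#' retain at least one comparison after Benjamini-Hochberg adjustment
#' across comparisons within each gene.
#'
#' @param expr An [ate_expression()] object.
#' @param alpha Adjusted significance level (default 0.05).
#' @param variant t-test variant, as in [filter_criteria()].
#' @return Data frame with per-gene minimal raw and BH-adjusted p-values and
#'   the significance call at `alpha`.
#' @export
fdr_report <- function(expr, alpha = 0.05, variant = "pooled") {
  p <- pairwise_cell_p(expr, variant = variant)
  adj <- t(apply(p, 1, stats::p.adjust, method = "BH"))
  data.frame(gene_id = rownames(p),
             min_p = apply(p, 1, min, na.rm = TRUE),
             min_p_bh = apply(adj, 1, min, na.rm = TRUE),
             significant_bh = apply(adj < alpha, 1, any, na.rm = TRUE),
             row.names = NULL, stringsAsFactors = FALSE)
}
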