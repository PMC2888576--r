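## Correlation, PRCF and summary-statistic testing linking gene expression
## to adiposity phenotypes.

#' Pearson correlation with t-distribution p-value
#'
#' Pearson r with the classical two-tailed p-value from
#' `t = r * sqrt(n - 2) / sqrt(1 - r^2)` against the t distribution with
#' `n - 2` degrees of freedom (the regression-analysis convention under
#' which r > 0.3 at n = 83 is significant at p = 0.01).
#'
#' @param x,y Paired numeric vectors; pairs with missing values are
#'   dropped.
#' @return List with `r`, `p`, `n`, `t`, `df`.
#' @export
#' @examples
#' pearson_cor(1:10, (1:10) + rnorm(10))
pearson_cor <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined: zero variance input")
  r <- stats::cor(x, y)
  p <- pearson_p(r, n)
  t <- r * sqrt(n - 2) / sqrt(max(1 - r^2, 0))
  list(r = r, p = p, n = n, t = t, df = n - 2)
}

#' Two-tailed p-value for a Pearson correlation coefficient
#'
#' @param r Correlation coefficient, `|r| <= 1`.
#' @param n Sample size, `>= 3`.
#' @return Two-tailed p-value (0 when `|r| = 1`).
#' @export
#' @examples
#' pearson_p(0.3, 83)   # <= 0.01
pearson_p <- function(r, n) {
  stopifnot(all(abs(r) <= 1), all(n >= 3))
  t <- r * sqrt(n - 2) / sqrt(pmax(1 - r^2, 0))
  ifelse(abs(r) == 1, 0, 2 * stats::pt(-abs(t), n - 2))
}

#' Percent of variance explained by a correlation
#'
#' @param r Correlation coefficient(s), `|r| <= 1`.
#' @return `100 * r^2`, unrounded (round per reporting convention; e.g.
#'   r = 0.63 gives 39.69, i.e. 40% to the nearest integer).
#' @export
variance_explained <- function(r) {
  stopifnot(all(abs(r) <= 1))
  100 * r^2
}

#' Pairwise correlation matrix with significance mask
#'
#' Pairwise-complete Pearson correlations between the columns of a table of
#' per-mouse variables, with the [pearson_p()] p-value per pair and a
#' significance mask at `alpha`.
#'
#' @param variables Data frame or matrix of numeric columns.
#' @param alpha Significance level for the mask (default 0.01).
#' @return Object of class `ate_cormat`: list of matrices `r`, `p`, `n`
#'   and logical `significant`; pairs with < 3 complete rows are `NA` and
#'   flagged in the `incomplete` attribute.
#' @export
correlation_matrix <- function(variables, alpha = 0.01) {
  m <- as.matrix(variables)
  stopifnot(is.numeric(m), ncol(m) >= 2)
  v <- colnames(m) %||% paste0("V", seq_len(ncol(m)))
  k <- ncol(m)
  r <- p <- matrix(NA_real_, k, k, dimnames = list(v, v))
  n <- matrix(0L, k, k, dimnames = list(v, v))
  incomplete <- character(0)
  for (i in seq_len(k)) for (j in i:k) {
    ok <- is.finite(m[, i]) & is.finite(m[, j])
    n[i, j] <- n[j, i] <- sum(ok)
    if (i == j) { r[i, j] <- 1; p[i, j] <- 0; next }
    if (sum(ok) < 3 || stats::sd(m[ok, i]) == 0 ||
        stats::sd(m[ok, j]) == 0) {
      incomplete <- c(incomplete, paste(v[i], v[j], sep = ":"))
      next
    }
    r[i, j] <- r[j, i] <- stats::cor(m[ok, i], m[ok, j])
    p[i, j] <- p[j, i] <- pearson_p(r[i, j], sum(ok))
  }
  structure(list(r = r, p = p, n = n, significant = p < alpha,
                 alpha = alpha, handling = "pairwise-complete"),
            incomplete = incomplete, class = "ate_cormat")
}

#' @export
print.ate_cormat <- function(x, digits = 2, ...) {
  cat("ate_cormat (", x$handling, "), alpha =", x$alpha, "\n")
  print(round(x$r, digits))
  invisible(x)
}

#' Percent relative cumulative frequency curve
#'
#' The empirical cumulative distribution expressed as a percentage:
#' values ascending, percent(i) = 100 i / n. A distribution shifted left
#' (e.g. fat mass or Mest-like expression under early under-nutrition)
#' produces a curve uniformly left of the reference.
#'
#' @param values Numeric vector, at least one finite value.
#' @param bin_width Optional fixed bin width; when given, the curve is
#'   reported at bin upper edges (plotting parity with binned frequency
#'   plots); default exact (no binning).
#' @return Object of class `ate_prcf`: data frame with columns `value` and
#'   `percent` (nondecreasing, ending at 100).
#' @export
#' @examples
#' prcf(c(3, 1, 2, 4))
prcf <- function(values, bin_width = NULL) {
  values <- values[is.finite(values)]
  if (length(values) == 0) stop("no finite values")
  x <- sort(values)
  n <- length(x)
  if (is.null(bin_width)) {
    out <- data.frame(value = x, percent = 100 * seq_len(n) / n)
  } else {
    stopifnot(bin_width > 0)
    edges <- seq(floor(min(x) / bin_width) * bin_width,
                 max(x) + bin_width, by = bin_width)
    cnt <- cumsum(tabulate(findInterval(x, edges, left.open = TRUE),
                           length(edges)))
    out <- data.frame(value = edges, percent = 100 * cnt / n)
  }
  class(out) <- c("ate_prcf", "data.frame")
  out
}

#' @export
plot.ate_prcf <- function(x, ..., xlab = "value",
                          ylab = "cumulative frequency (%)", type = "s") {
  graphics::plot(x$value, x$percent, type = type, xlab = xlab,
                 ylab = ylab, ...)
  invisible(x)
}

#' Two-sample t-test from group summary statistics
#'
#' Two-tailed t-test computed from (mean, sd, n) only, as needed to test
#' printed group summaries against each other. Both the classical
#' pooled-variance and the Welch variant are available.
#'
#' @param mean1,sd1,n1,mean2,sd2,n2 Group summaries (`n >= 2`, `sd >= 0`).
#' @param variant `"pooled"` (default) or `"welch"`.
#' @return List with `t`, `df`, `p`.
#' @export
#' @examples
#' # day-10 body weight, Control vs under-nutrition
#' t_test_summary(5.53, 0.71, 44, 3.79, 0.46, 26)$p
t_test_summary <- function(mean1, sd1, n1, mean2, sd2, n2,
                           variant = c("pooled", "welch")) {
  if (n1 < 2 || n2 < 2) stop("need n >= 2 in both groups")
  stopifnot(sd1 >= 0, sd2 >= 0)
  t_from_moments(mean1, sd1^2, n1, mean2, sd2^2, n2, match.arg(variant))
}

## Insert-and-absorb compact letter display over a pairwise significance
## matrix: every non-significant pair must share a letter, no letter set
## may contain a significantly different pair.
letter_display <- function(sig) {
  g <- nrow(sig)
  cols <- list(seq_len(g))
  for (i in seq_len(g - 1)) for (j in (i + 1):g) {
    if (!isTRUE(sig[i, j])) next
    split_cols <- list()
    for (s in cols) {
      if (all(c(i, j) %in% s))
        split_cols <- c(split_cols, list(setdiff(s, i), setdiff(s, j)))
      else split_cols <- c(split_cols, list(s))
    }
    split_cols <- Filter(length, split_cols)
    ## absorb: drop any letter set contained in another (ties keep first)
    keep <- rep(TRUE, length(split_cols))
    for (a in seq_along(split_cols)) for (b in seq_along(split_cols)) {
      if (a == b || !keep[a] || !keep[b]) next
      if (all(split_cols[[a]] %in% split_cols[[b]]) &&
          (length(split_cols[[a]]) < length(split_cols[[b]]) || a > b))
        keep[a] <- FALSE
    }
    cols <- split_cols[keep]
  }
  letters_out <- rep("", g)
  for (k in seq_along(cols))
    letters_out[cols[[k]]] <- paste0(letters_out[cols[[k]]], letters[k])
  letters_out
}

#' One-way ANOVA with post-hoc pairwise t-tests and letter grouping
#'
#' Classical one-way ANOVA followed by pairwise two-tailed t-tests; groups
#' that are not significantly different at `alpha` share a superscript
#' letter (compact letter display, insert-and-absorb construction).
#'
#' @param values Numeric response.
#' @param groups Grouping factor (>= 2 levels, each n >= 2).
#' @param alpha Significance level for the letter display (default 0.01).
#' @param variant Pairwise t-test variant (`"pooled"` default).
#' @return Object of class `ate_anova`: `F`, `df`, `p`, per-group summary
#'   with `letters`, and the pairwise `p_matrix`.
#' @export
#' @examples
#' anova_cld(c(rnorm(20), rnorm(20, 5)), rep(c("a", "b"), each = 20))
anova_cld <- function(values, groups, alpha = 0.01,
                      variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  groups <- factor(groups)
  ok <- is.finite(values) & !is.na(groups)
  values <- values[ok]; groups <- droplevels(groups[ok])
  k <- nlevels(groups)
  if (k < 2) stop("need >= 2 groups")
  ns <- tabulate(groups)
  if (any(ns < 2)) stop("every group needs n >= 2")
  means <- tapply(values, groups, mean)
  vars <- tapply(values, groups, stats::var)
  n <- length(values)
  ss_between <- sum(ns * (means - mean(values))^2)
  ss_within <- sum((ns - 1) * vars)
  if (ss_within == 0 && ss_between == 0)
    stop("degenerate input: zero variance everywhere")
  df1 <- k - 1; df2 <- n - k
  Fstat <- (ss_between / df1) / (ss_within / df2)
  p <- stats::pf(Fstat, df1, df2, lower.tail = FALSE)

  pm <- matrix(NA_real_, k, k,
               dimnames = list(levels(groups), levels(groups)))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    pm[i, j] <- pm[j, i] <-
      t_test_summary(means[i], sqrt(vars[i]), ns[i],
                     means[j], sqrt(vars[j]), ns[j], variant)$p
  }
  sig <- pm < alpha
  sig[is.na(sig)] <- FALSE
  lett <- letter_display(sig)
  structure(list(F = Fstat, df = c(df1, df2), p = p,
                 groups = data.frame(group = levels(groups), n = ns,
                                     mean = as.numeric(means),
                                     sd = sqrt(as.numeric(vars)),
                                     letters = lett,
                                     stringsAsFactors = FALSE),
                 p_matrix = pm, alpha = alpha),
            class = "ate_anova")
}

#' @export
print.ate_anova <- function(x, ...) {
  cat(sprintf("one-way ANOVA: F(%d, %d) = %.3f, p = %.3g\n",
              x$df[1], x$df[2], x$F, x$p))
  print(x$groups, row.names = FALSE)
  invisible(x)
}
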