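## K-means clustering of standardized 15-cell expression profiles and
## template-matching selection of the adiposity-tracking cluster.

#' Standardize expression profiles to cell-mean z-scores
#'
#' Collapses replicate arrays to per-cell means and z-scores each gene's
#' profile (row mean 0, SD 1) so cluster assignment is driven by profile
#' shape, not signal magnitude. Constant rows are dropped with a warning.
#'
#' @param expr An [ate_expression()] object.
#' @return Genes x cells numeric matrix with attributes `center` and
#'   `scale` (per-row mean/SD allowing exact un-standardization) and
#'   `dropped` (ids of constant rows).
#' @export
standardize_profiles <- function(expr) {
  stopifnot(inherits(expr, "ate_expression"))
  m <- cell_means(expr)
  ctr <- rowMeans(m)
  sdv <- sqrt(rowSums((m - ctr)^2) / (ncol(m) - 1))
  const <- sdv == 0
  if (any(const))
    warning(sum(const), " constant profile(s) dropped: ",
            paste(utils::head(rownames(m)[const], 5), collapse = ", "),
            if (sum(const) > 5) ", ...")
  z <- (m[!const, , drop = FALSE] - ctr[!const]) / sdv[!const]
  attr(z, "center") <- ctr[!const]
  attr(z, "scale") <- sdv[!const]
  attr(z, "dropped") <- rownames(m)[const]
  z
}

## k-means++ seeding: first centre uniform, subsequent centres with
## probability proportional to squared distance to the nearest chosen one.
kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  centers <- integer(k)
  centers[1] <- sample.int(n, 1)
  d2 <- rowSums((x - rep(x[centers[1], ], each = n))^2)
  for (i in seq_len(k - 1L)) {
    prob <- d2 / sum(d2)
    if (all(d2 == 0)) prob <- rep(1 / n, n)
    centers[i + 1L] <- sample.int(n, 1, prob = prob)
    d2 <- pmin(d2, rowSums((x - rep(x[centers[i + 1L], ],
                                    each = n))^2))
  }
  x[centers, , drop = FALSE]
}

## Squared Euclidean distances of every row of x to every centroid row.
dist2_to_centers <- function(x, centers) {
  xx <- rowSums(x^2)
  cc <- rowSums(centers^2)
  outer(xx, cc, "+") - 2 * x %*% t(centers)
}

lloyd_once <- function(x, k, max_iter, tol) {
  centers <- kmeanspp_init(x, k)
  wss_trace <- numeric(0)
  assign_old <- rep(0L, nrow(x))
  for (iter in seq_len(max_iter)) {
    d2 <- dist2_to_centers(x, centers)
    assign_new <- max.col(-d2, ties.method = "first")
    ## empty clusters are re-seeded from the point farthest from its centre
    for (j in which(tabulate(assign_new, k) == 0L)) {
      far <- which.max(d2[cbind(seq_len(nrow(x)), assign_new)])
      assign_new[far] <- j
      d2[far, ] <- Inf; d2[far, j] <- 0
    }
    wss_trace <- c(wss_trace,
                   sum(d2[cbind(seq_len(nrow(x)), assign_new)]))
    for (j in seq_len(k))
      centers[j, ] <- colMeans(x[assign_new == j, , drop = FALSE])
    if (identical(assign_new, assign_old)) break
    if (length(wss_trace) > 1 &&
        abs(diff(utils::tail(wss_trace, 2))) < tol) break
    assign_old <- assign_new
  }
  d2 <- dist2_to_centers(x, centers)
  assign_new <- max.col(-d2, ties.method = "first")
  wss <- sum(d2[cbind(seq_len(nrow(x)), assign_new)])
  list(assignments = assign_new, centers = centers,
       wss = wss, wss_trace = c(wss_trace, wss))
}

#' K-means clustering of expression profiles
#'
#' Euclidean K-means (Lloyd's algorithm with k-means++ seeding), best of
#' `n_restarts` restarts by total within-cluster sum of squares;
#' deterministic given `seed`. Empty clusters are re-seeded from the point
#' farthest from its current centroid.
#'
#' @param profiles Genes x cells matrix, typically from
#'   [standardize_profiles()].
#' @param k Number of clusters (default 50); must be positive and smaller
#'   than the number of genes.
#' @param seed Integer seed.
#' @param n_restarts Random restarts (default 10).
#' @param max_iter,tol Lloyd iteration controls.
#' @return Object of class `ate_clusters`: `assignments` (named integer),
#'   `centroids` (k x cells), `sizes`, `wss`, `wss_trace` of the winning
#'   restart, `k`, `seed`, `n_restarts`.
#' @export
#' @examples
#' set.seed(1)
#' x <- rbind(matrix(rnorm(60, 2), 10), matrix(rnorm(60, -2), 10))
#' kmeans_profiles(x, k = 2, seed = 1)$sizes
kmeans_profiles <- function(profiles, k = 50L, seed = 1L,
                            n_restarts = 10L, max_iter = 100L,
                            tol = 1e-10) {
  stopifnot(is.matrix(profiles), is.numeric(profiles))
  if (k <= 0) stop("k must be positive")
  if (k >= nrow(profiles)) stop("k must be smaller than the number of genes")
  if (is.null(rownames(profiles)))
    rownames(profiles) <- paste0("g", seq_len(nrow(profiles)))
  set.seed(seed)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    fit <- lloyd_once(profiles, k, max_iter, tol)
    if (is.null(best) || fit$wss < best$wss) best <- fit
  }
  sizes <- tabulate(best$assignments, k)
  structure(list(k = as.integer(k),
                 assignments = stats::setNames(best$assignments,
                                               rownames(profiles)),
                 centroids = best$centers,
                 sizes = sizes,
                 wss = best$wss,
                 wss_trace = best$wss_trace,
                 seed = as.integer(seed),
                 n_restarts = as.integer(n_restarts)),
            class = "ate_clusters")
}

#' @export
print.ate_clusters <- function(x, ...) {
  cat(sprintf("ate_clusters: k = %d over %d genes, sizes %d-%d, WSS %.3f\n",
              x$k, length(x$assignments), min(x$sizes), max(x$sizes),
              x$wss))
  invisible(x)
}

#' Build the adiposity-tracking profile template
#'
#' A 15-cell profile combining (a) the percent rate of fat accumulation per
#' day implied by the calibrated group fat masses (the phenotype that the
#' sought gene cluster should track) and (b) optionally the standardized
#' expression profiles of marker genes known to track fat expansion
#' (Mest-like, Bmp3-like). Each component is z-scored before weighting, so
#' the template is scale-free.
#'
#' @param table1 Calibration table from [table1_params()].
#' @param marker_profiles Optional matrix of standardized marker rows (from
#'   [standardize_profiles()]) averaged into the template.
#' @param weight_rate Weight on the fat-accumulation-rate component
#'   (default 0.5); markers carry `1 - weight_rate`.
#' @param fm_birth Assumed fat mass at birth in grams (essentially no
#'   depot), anchoring the day-5 rate.
#' @return Object of class `ate_template`: numeric 15-vector in
#'   [design_cells()] order with a `source` attribute.
#' @export
ate_template <- function(table1 = table1_params(), marker_profiles = NULL,
                         weight_rate = 0.5, fm_birth = 0.05) {
  stopifnot(weight_rate >= 0, weight_rate <= 1)
  cells <- design_cells()
  fm <- mapply(function(a, d) table1_lookup(table1, a, d, "fm")$mean,
               cells$arm, cells$age_days)
  prev_age <- c(0, AGES[-length(AGES)])[match(cells$age_days, AGES)]
  fm_prev <- ifelse(prev_age == 0, fm_birth,
                    mapply(function(a, d)
                      table1_lookup(table1, a, d, "fm")$mean,
                      cells$arm, pmax(prev_age, 5)))
  fm_prev[prev_age == 0] <- fm_birth
  rate <- 100 * (fm - fm_prev) / ((cells$age_days - prev_age) * fm_prev)
  z <- function(v) (v - mean(v)) / stats::sd(v)
  tmpl <- weight_rate * z(rate)
  src <- "fat-accumulation rate"
  if (!is.null(marker_profiles) && nrow(marker_profiles) > 0 &&
      weight_rate < 1) {
    mk <- colMeans(marker_profiles)
    tmpl <- tmpl + (1 - weight_rate) * z(mk)
    src <- paste0(src, " + ", nrow(marker_profiles), " marker profile(s)")
  }
  structure(stats::setNames(as.numeric(tmpl), cells$cell), source = src,
            class = "ate_template")
}

#' Select the cluster best matching a profile template
#'
#' Returns the cluster whose centroid has the largest Pearson correlation
#' with the template; ties go to the larger cluster, then the lower index.
#' Constant centroids (undefined correlation) are excluded. Selection is
#' invariant to affine rescaling of the template.
#'
#' @param clusters An [kmeans_profiles()] result.
#' @param template An [ate_template()] or numeric vector matching the
#'   centroid length.
#' @param min_cor Correlation floor; a best match below it is flagged with
#'   a warning (default 0.5).
#' @return List with `cluster` (index), `correlation`, `genes` (ids
#'   assigned to the selected cluster), and the per-cluster `correlations`.
#' @export
select_cluster_by_template <- function(clusters, template, min_cor = 0.5) {
  stopifnot(inherits(clusters, "ate_clusters"))
  tmpl <- as.numeric(template)
  if (length(tmpl) != ncol(clusters$centroids))
    stop("template length ", length(tmpl), " != centroid length ",
         ncol(clusters$centroids))
  if (stats::sd(tmpl) == 0) stop("template is constant")
  cors <- apply(clusters$centroids, 1, function(ctr) {
    if (stats::sd(ctr) == 0) NA_real_ else stats::cor(ctr, tmpl)
  })
  if (all(is.na(cors))) stop("all centroids constant; no correlation defined")
  best <- which(!is.na(cors) & cors == max(cors, na.rm = TRUE))
  if (length(best) > 1) {
    best <- best[order(-clusters$sizes[best], best)]
  }
  best <- best[1]
  if (cors[best] < min_cor)
    warning(sprintf("best template match is weak (r = %.3f < %.2f)",
                    cors[best], min_cor))
  list(cluster = best,
       correlation = cors[best],
       genes = names(clusters$assignments)[clusters$assignments == best],
       correlations = cors)
}
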