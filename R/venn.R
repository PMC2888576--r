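## Phenotype-driven Venn intersection cascade: directional differential sets
## per comparison (A-E) and their intersections down to the ATE gene set.

#' Differential-comparison specification
#'
#' One directional differential-expression comparison between two design
#' cells: a gene is included when the two-tailed t-test on replicate arrays
#' is significant at `alpha`, the `cell_hi`/`cell_lo` fold change reaches
#' `min_fold`, and the direction holds (`UP`: hi mean > lo mean).
#'
#' @param name Comparison label (e.g. `"A"`).
#' @param cell_hi,cell_lo Cell keys (`"ARM_dAGE"`), distinct.
#' @param direction `"UP"`, `"DOWN"` or `"BOTH"`.
#' @param min_fold Minimal fold change (default 1.6).
#' @param alpha Significance level (default 0.01).
#' @return Object of class `ate_comparison`.
#' @export
comparison_spec <- function(name, cell_hi, cell_lo,
                            direction = c("UP", "DOWN", "BOTH"),
                            min_fold = 1.6, alpha = 0.01) {
  direction <- match.arg(direction)
  stopifnot(cell_hi != cell_lo, min_fold >= 1, alpha > 0, alpha < 1)
  structure(list(name = name, cell_hi = cell_hi, cell_lo = cell_lo,
                 direction = direction, min_fold = min_fold,
                 alpha = alpha),
            class = "ate_comparison")
}

#' Default comparisons of the ATE cascade
#'
#' Adiposity differed between Control and under-nourished pups at days 5
#' (A) and 10 (B), and within every arm between day 56 (chow) and day 112
#' (8 weeks of high-fat diet; C = Control, D = LUN, E = LON). Control vs
#' over-nutrition comparisons are deliberately absent: those arms did not
#' differ in adiposity, so differences there would reflect the maternal
#' high-fat diet, not fat-mass expansion. The default direction `UP` tracks
#' genes higher with greater adiposity; `direction = "DOWN"` builds the
#' complementary cascade.
#'
#' @param min_fold,alpha Shared thresholds (defaults 1.6 and 0.01).
#' @param direction Direction of all five comparisons.
#' @return Named list of [comparison_spec()] objects `A`-`E`.
#' @export
default_comparisons <- function(min_fold = 1.6, alpha = 0.01,
                                direction = "UP") {
  list(A = comparison_spec("A", "CONTROL_d5", "LUN_d5", direction,
                           min_fold, alpha),
       B = comparison_spec("B", "CONTROL_d10", "LUN_d10", direction,
                           min_fold, alpha),
       C = comparison_spec("C", "CONTROL_d112", "CONTROL_d56", direction,
                           min_fold, alpha),
       D = comparison_spec("D", "LUN_d112", "LUN_d56", direction,
                           min_fold, alpha),
       E = comparison_spec("E", "LON_d112", "LON_d56", direction,
                           min_fold, alpha))
}

#' Directional differential gene set for one comparison
#'
#' @param expr An [ate_expression()] object.
#' @param spec A [comparison_spec()].
#' @param variant t-test variant (`"pooled"` default, `"welch"`).
#' @return Character vector of gene ids with attributes `name` and `spec`.
#'   A zero `cell_lo` mean makes the fold undefined; such genes pass the
#'   fold criterion if the `cell_hi` mean is positive (logged via message).
#' @export
differential_set <- function(expr, spec, variant = "pooled") {
  stopifnot(inherits(expr, "ate_expression"),
            inherits(spec, "ate_comparison"))
  mom <- cell_moments(expr)
  for (cc in c(spec$cell_hi, spec$cell_lo)) {
    if (!cc %in% colnames(mom$mean))
      stop("cell not present in design: ", cc)
    if (mom$n[[cc]] < 2)
      stop("cell ", cc, " has < 2 replicate arrays")
  }
  hi <- mom$mean[, spec$cell_hi]; lo <- mom$mean[, spec$cell_lo]
  tt <- t_from_moments(hi, mom$var[, spec$cell_hi], mom$n[[spec$cell_hi]],
                       lo, mom$var[, spec$cell_lo], mom$n[[spec$cell_lo]],
                       variant)
  zero_lo <- lo == 0
  if (any(zero_lo))
    message(sum(zero_lo), " gene(s) with zero ", spec$cell_lo,
            " mean in comparison ", spec$name,
            "; fold treated as passing where the high cell is positive")
  fold_hi <- ifelse(zero_lo, ifelse(hi > 0, Inf, 1), hi / lo)
  fold_pass <- pmax(fold_hi, 1 / fold_hi) >= spec$min_fold
  dir_pass <- switch(spec$direction,
                     UP = hi > lo,
                     DOWN = hi < lo,
                     BOTH = hi != lo)
  ## directional comparisons require the fold in the stated direction
  if (spec$direction == "UP") fold_pass <- fold_hi >= spec$min_fold
  if (spec$direction == "DOWN") fold_pass <- fold_hi <= 1 / spec$min_fold
  keep <- tt$p < spec$alpha & fold_pass & dir_pass
  structure(rownames(expr$values)[keep], name = spec$name, spec = spec)
}

#' Venn intersection cascade to the ATE gene set
#'
#' Intersects the five differential sets: `F = A` \eqn{\cap} `B` (genes
#' shared by the neonatal comparisons), `G = C` \eqn{\cap} `D` \eqn{\cap}
#' `E` (genes shared by the adult high-fat-diet comparisons within every
#' arm), and `ATE = F` \eqn{\cap} `G`.
#'
#' @param sets Named list of five character vectors `A`-`E` (as from
#'   [differential_set()]).
#' @return Object of class `ate_venn`: the sets `A`-`E`, `F`, `G`, `ATE`,
#'   their `cardinalities`, and a `provenance` logical matrix (genes in any
#'   set x comparisons).
#' @export
#' @examples
#' venn_cascade(list(A = "g1", B = "g1", C = "g1", D = "g1", E = "g1"))$ATE
venn_cascade <- function(sets) {
  stopifnot(is.list(sets), all(c("A", "B", "C", "D", "E") %in% names(sets)))
  sets <- lapply(sets[c("A", "B", "C", "D", "E")], as.character)
  Fset <- intersect(sets$A, sets$B)
  Gset <- Reduce(intersect, sets[c("C", "D", "E")])
  ate <- intersect(Fset, Gset)
  universe <- sort(unique(unlist(sets)))
  prov <- vapply(sets, function(s) universe %in% s,
                 logical(length(universe)))
  if (length(universe) == 1L)
    prov <- matrix(prov, 1, dimnames = list(universe, names(sets)))
  else rownames(prov) <- universe
  res <- c(sets, list(F = Fset, G = Gset, ATE = ate))
  structure(list(sets = res,
                 cardinalities = vapply(res, length, integer(1)),
                 provenance = prov,
                 ATE = ate),
            class = "ate_venn")
}

#' @export
print.ate_venn <- function(x, ...) {
  cat("ate_venn cascade:",
      paste(names(x$cardinalities), x$cardinalities, sep = "=",
            collapse = " "), "\n")
  invisible(x)
}

#' Run the five default comparisons and the cascade
#'
#' @param expr An [ate_expression()] object (typically the filtered,
#'   normalized matrix).
#' @param comparisons List of [comparison_spec()]s, default
#'   [default_comparisons()].
#' @param variant t-test variant.
#' @return An `ate_venn` object.
#' @export
venn_ate <- function(expr, comparisons = default_comparisons(),
                     variant = "pooled") {
  sets <- lapply(comparisons, function(sp)
    differential_set(expr, sp, variant))
  venn_cascade(sets)
}
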