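#' @keywords internal
"_PACKAGE"

## Factorial layout constants: three lactation-nutrition arms crossed with
## five ages. LUN = lactation under-nutrition (dam at 50% food, litter of 8),
## LON = lactation over-nutrition (litter reduced to 4, dam on 58 kcal% fat).
ARMS <- c("CONTROL", "LUN", "LON")
AGES <- c(5L, 10L, 21L, 56L, 112L)

## Litter sizes fixed by the rearing protocol for the main cohorts.
ARM_LITTER_SIZE <- c(CONTROL = 8L, LUN = 8L, LON = 4L)

#' Canonical (arm, age) design cells
#'
#' The expression experiment covers 15 cells: each nutrition arm
#' (`CONTROL`, `LUN`, `LON`) at ages 5, 10, 21, 56 and 112 days. Cell order
#' is arm-major and is the index order used for 15-long profile vectors
#' throughout the package.
#'
#' @return A data frame with columns `arm`, `age_days` and `cell`
#'   (the `"ARM_dAGE"` key), one row per design cell.
#' @export
#' @examples
#' design_cells()
design_cells <- function() {
  d <- expand.grid(age_days = AGES, arm = ARMS,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  d <- d[, c("arm", "age_days")]
  d$cell <- cell_key(d$arm, d$age_days)
  d
}

#' Build a cell key from arm and age
#'
#' @param arm Character vector of nutrition arms.
#' @param age_days Integer vector of ages in days.
#' @return Character vector of `"ARM_dAGE"` keys.
#' @export
cell_key <- function(arm, age_days) {
  arm <- match.arg(toupper(as.character(arm)), ARMS, several.ok = TRUE)
  stopifnot(all(age_days %in% AGES))
  paste0(arm, "_d", age_days)
}

#' Array-to-cell design specification
#'
#' Describes which microarray belongs to which (arm, age) cell. The default
#' mirrors the study layout: one 12-mouse RNA pool per cell hybridized to
#' three replicate arrays.
#'
#' @param cells Data frame of design cells as from [design_cells()]; may be
#'   a subset for reduced designs.
#' @param replicates_per_cell Number of replicate arrays per pool (default 3).
#' @return An object of class `ate_design`: a data frame with columns
#'   `array_id`, `arm`, `age_days`, `replicate`, `cell`.
#' @export
#' @examples
#' head(design_spec())
design_spec <- function(cells = design_cells(), replicates_per_cell = 3L) {
  stopifnot(is.data.frame(cells), nrow(cells) >= 1,
            replicates_per_cell >= 1)
  if (is.null(cells$cell)) cells$cell <- cell_key(cells$arm, cells$age_days)
  if (anyDuplicated(cells$cell))
    stop("duplicated design cells: ",
         paste(unique(cells$cell[duplicated(cells$cell)]), collapse = ", "))
  d <- cells[rep(seq_len(nrow(cells)), each = replicates_per_cell), ]
  d$replicate <- rep(seq_len(replicates_per_cell), times = nrow(cells))
  d$array_id <- paste0(d$cell, "_r", d$replicate)
  rownames(d) <- NULL
  d <- d[, c("array_id", "arm", "age_days", "replicate", "cell")]
  class(d) <- c("ate_design", "data.frame")
  d
}

validate_design <- function(design, array_ids) {
  if (anyDuplicated(design$array_id))
    stop("duplicated array ids in design: ",
         paste(unique(design$array_id[duplicated(design$array_id)]),
               collapse = ", "))
  missing <- setdiff(array_ids, design$array_id)
  if (length(missing))
    stop("arrays not mapped to any design cell: ",
         paste(missing, collapse = ", "))
  tab <- table(design$cell[design$array_id %in% array_ids])
  if (any(tab < 1)) stop("design cell without arrays")
  invisible(TRUE)
}

#' Expression matrix container
#'
#' A light container pairing a genes-by-arrays signal matrix with the design
#' annotation that maps every array to an (arm, age) cell, in the style of a
#' matrix plus a targets frame.
#'
#' @param values Numeric matrix, rows = genes (rownames required),
#'   columns = arrays (colnames required).
#' @param design An `ate_design` data frame covering every column.
#' @return An object of class `ate_expression` (list with elements `values`
#'   and `design`).
#' @export
ate_expression <- function(values, design) {
  stopifnot(is.matrix(values), is.numeric(values))
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("expression matrix needs gene rownames and array colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicated gene ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "))
  validate_design(design, colnames(values))
  design <- design[match(colnames(values), design$array_id), , drop = FALSE]
  rownames(design) <- NULL
  structure(list(values = values, design = design),
            class = "ate_expression")
}

#' @export
print.ate_expression <- function(x, ...) {
  cat(sprintf("ate_expression: %d genes x %d arrays, %d design cells\n",
              nrow(x$values), ncol(x$values),
              length(unique(x$design$cell))))
  invisible(x)
}

#' @export
dim.ate_expression <- function(x) dim(x$values)

## Per-cell replicate column indices, in design_cells() order restricted to
## the cells present. Returns a named list of integer vectors.
cell_columns <- function(expr) {
  cells <- unique(expr$design$cell)
  canon <- design_cells()$cell
  cells <- c(intersect(canon, cells), setdiff(cells, canon))
  lapply(stats::setNames(cells, cells),
         function(cc) which(expr$design$cell == cc))
}

## Matrix of per-cell mean signals (genes x cells).
cell_means <- function(expr) {
  idx <- cell_columns(expr)
  out <- vapply(idx, function(j) rowMeans(expr$values[, j, drop = FALSE]),
                numeric(nrow(expr$values)))
  if (nrow(expr$values) == 1L) out <- matrix(out, nrow = 1,
                                             dimnames = list(rownames(expr$values), names(idx)))
  out
}
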