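#' Quantile normalization across arrays
#'
#' Forces every array (column) to the same signal distribution: the
#' reference is the row-wise mean of the sorted columns, and each value is
#' replaced by the reference value at its within-column rank. Tied values
#' within a column receive the mean of the reference values their ranks
#' span. Gene order is preserved; the operation is idempotent.
#'
#' @param x Numeric matrix (genes x arrays) or an [ate_expression()] object.
#' @return Object of the same type with normalized signals.
#' @export
#' @examples
#' quantile_normalize(cbind(a = c(1, 2, 3), b = c(4, 5, 6)))
quantile_normalize <- function(x) {
  if (inherits(x, "ate_expression")) {
    x$values <- quantile_normalize(x$values)
    return(x)
  }
  stopifnot(is.matrix(x), is.numeric(x))
  if (ncol(x) < 2) stop("quantile normalization needs >= 2 arrays")
  bad <- which(!apply(x, 2, function(col) all(is.finite(col))))
  if (length(bad))
    stop("non-finite signals in array(s): ",
         paste(colnames(x)[bad] %||% bad, collapse = ", "))
  ref <- rowMeans(apply(x, 2, sort))
  n <- nrow(x)
  out <- x
  for (j in seq_len(ncol(x))) {
    o <- order(x[, j])
    xs <- x[o, j]
    ## runs of equal sorted values form tie groups; each group gets the
    ## mean of the reference values its positions span
    grp <- cumsum(c(TRUE, xs[-1L] != xs[-n]))
    gmean <- rowsum(ref, grp, reorder = FALSE) / tabulate(grp)
    out[o, j] <- gmean[grp]
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
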