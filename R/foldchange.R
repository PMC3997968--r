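#' Fixed slope-1 regression between two log2 expression vectors
#'
#' Fits `y = x + b` by least squares (the only free parameter is the
#' intercept, so `b = mean(y - x)`) and returns the residuals
#' `y - x - b`. The intercept absorbs any global library-size ratio between
#' the two samples; each residual is the miRNA's log2 fold change after that
#' correction.
#'
#' @param x,y numeric vectors of equal length: log2 expression of the same
#'   miRNAs in two samples. Names of `x` (or `y`) are carried to the
#'   residuals.
#' @param sample_a,sample_b optional sample labels stored in the result.
#' @return Object of class `"slope1_fc"`: list with `intercept` (log2 units),
#'   `residuals` (per-miRNA log2 fold changes, summing to zero), and the two
#'   sample labels.
#' @examples
#' fc <- fit_slope1(c(0, 1, 2), c(0, 1, 4))
#' fc$intercept        # 2/3
#' fc$residuals        # -2/3 -2/3 4/3
#' @export
fit_slope1 <- function(x, y, sample_a = "a", sample_b = "b") {
  if (length(x) != length(y))
    abort("x and y must have the same length (%d vs %d)", length(x), length(y))
  if (length(x) < 1L) abort("need at least one point")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    abort("non-finite values in input to fit_slope1")
  b <- mean(y - x)
  r <- y - x - b
  names(r) <- names(x) %||% names(y)
  structure(list(sample_a = sample_a, sample_b = sample_b,
                 intercept = b, residuals = r),
            class = "slope1_fc")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.slope1_fc <- function(x, ...) {
  cat(sprintf("Slope-1 fit %s vs %s: intercept %.4f log2 units, %d residuals\n",
              x$sample_b, x$sample_a, x$intercept, length(x$residuals)))
  invisible(x)
}

#' @export
residuals.slope1_fc <- function(object, ...) object$residuals

#' Percent expression variation implied by a log2 residual
#'
#' Converts log2 fold-change residuals into percent deviations:
#' `(2^|r| - 1) * 100`. A residual of 0 is 0% variation; a residual of 1
#' (a 2-fold change) is 100%.
#'
#' @param fc a `"slope1_fc"` object or a numeric vector of log2 residuals.
#' @return nonnegative numeric vector of percent variations.
#' @export
percent_variation <- function(fc) {
  r <- if (inherits(fc, "slope1_fc")) fc$residuals else fc
  if (!is.numeric(r) || any(!is.finite(r)))
    abort("residuals must be finite numbers")
  (2 ^ abs(r) - 1) * 100
}
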