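#' Age-adjusted partial Pearson correlation with Fisher-z interval
#'
#' Pearson correlation between the residuals of `x` and `y` after
#' least-squares regression of each on an intercept and the control
#' variable(s). The 95% confidence interval uses the Fisher z transform,
#' `tanh(atanh(r) +/- 1.96 / sqrt(n - g - 3))`, where `g` is the number of
#' control variables (one, age, throughout the pipeline).
#'
#' @param x,y Numeric vectors of equal length (n >= 5), all values finite.
#' @param control Numeric vector (or matrix with one column per control
#'   variable) of the same length; must have nonzero variance.
#' @return A list with elements `r`, `ci_lo`, `ci_hi`, `n` and `g`.
#' @examples
#' set.seed(1)
#' age <- rnorm(100, 55, 8)
#' x <- 0.1 * age + rnorm(100)
#' y <- 0.2 * age + rnorm(100)
#' partial_corr(x, y, age)
#' @export
partial_corr <- function(x, y, control) {
  x <- as.numeric(x); y <- as.numeric(y)
  cm <- as.matrix(control)
  n <- length(x)
  if (length(y) != n || nrow(cm) != n)
    stop("'x', 'y' and 'control' must have equal length")
  if (n < 5L) stop("need at least 5 observations")
  if (!all(is.finite(x)) || !all(is.finite(y)) || !all(is.finite(cm)))
    stop("non-finite values in input")
  if (any(apply(cm, 2L, stats::var) <= 0))
    stop("control variable has zero variance")
  g <- ncol(cm)
  qx <- qr(cbind(1, cm))
  rx <- qr.resid(qx, x)
  ry <- qr.resid(qx, y)
  ssx <- sum(rx^2); ssy <- sum(ry^2)
  # relative threshold: residuals that are pure rounding noise of an exact
  # linear dependence must be flagged, not correlated
  if (ssx <= 1e-12 * sum((x - mean(x))^2) ||
      ssy <= 1e-12 * sum((y - mean(y))^2))
    stop("undefined correlation: zero residual variance after adjustment")
  r <- sum(rx * ry) / sqrt(ssx * ssy)
  r <- min(max(r, -1), 1)
  ci <- fisher_ci(r, n, g)
  list(r = r, ci_lo = ci[1L], ci_hi = ci[2L], n = n, g = g)
}

# 95% Fisher-z interval; 1.96 fixed (two-sided 95%), df = n - g - 3.
fisher_ci <- function(r, n, g = 1L) {
  se <- 1 / sqrt(n - g - 3)
  z <- atanh(r)
  c(tanh(z - 1.96 * se), tanh(z + 1.96 * se))
}
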