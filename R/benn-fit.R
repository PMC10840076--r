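#' Fit a sex-specific height exponent for a relative-weight index
#'
#' The central fitting function: derives the anthropometric measures on a
#' single-sex cohort, scans the exponent grid computing age-adjusted
#' partial correlation curves for every measure, builds the criterion
#' report (conventional p = 2, height-independency, and each
#' fatness-dependency criterion), and selects the working exponent by the
#' height-independency criterion — the grid exponent at which the index's
#' age-adjusted correlation with height is zero.
#'
#' @param data A single-sex cohort data frame (generated by
#'   [generate_cohort()] or read by [read_cohort()]).
#' @param grid A [power_grid()] of candidate exponents; defaults to -5 to 5
#'   in steps of 0.01, which comfortably brackets plausible human
#'   allometry. Use `power_grid(-50, 50, 0.01)` for an exhaustive scan.
#' @param measures Measures to correlate against; default all eight.
#' @return An object of class `benn_fit` with components `power` (the
#'   selected exponent), `criterion_table`, `curves`, `optimum` (the height
#'   criterion optimum), `n`, `sex` and `call`. Methods: `print`,
#'   `summary`, `coef`, `predict`, `plot`.
#' @examples
#' cohort <- generate_cohort(cohort_params("F", n = 2000, seed = 1))
#' fit <- benn_fit(cohort, grid = power_grid(-2, 4, 0.05))
#' coef(fit)
#' @export
benn_fit <- function(data, grid = power_grid(-5, 5, 0.01),
                     measures = BENN_MEASURES) {
  cl <- match.call()
  grid <- as_power_grid(grid)
  data <- derive_measures(data)
  curves <- scan_powers(data, measures, grid)
  opt <- find_height_independent_power(curves)
  tab <- build_criterion_table(curves = curves)
  structure(list(power = opt$p_opt, criterion_table = tab, curves = curves,
                 optimum = opt, n = curves$n,
                 sex = as.character(unique(data$sex)), call = cl),
            class = "benn_fit")
}

#' @export
print.benn_fit <- function(x, ...) {
  cat("Height-independent relative-weight index fit\n")
  cat(sprintf("  sex: %s   n = %d   grid: %g..%g by %g\n",
              x$sex, x$n, x$curves$grid$p_min, x$curves$grid$p_max,
              x$curves$grid$step))
  cat(sprintf("  selected exponent (height-independency): %.2f\n", x$power))
  cat(sprintf("  correlation with height at optimum: %.3f\n",
              x$optimum$correlations_at_opt["height"]))
  cat(sprintf("  correlation with BF%% at optimum: %.3f\n",
              x$optimum$correlations_at_opt["bf_pct"]))
  invisible(x)
}

#' @export
summary.benn_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.benn_fit")
}

#' @export
print.summary.benn_fit <- function(x, ...) {
  print(x$fit)
  cat("\n")
  print(x$fit$criterion_table)
  invisible(x)
}

#' @export
coef.benn_fit <- function(object, ...) {
  p <- object$criterion_table$power
  names(p) <- object$criterion_table$criterion
  p
}

#' Index values under a fitted exponent
#'
#' @param object A [benn_fit()] object.
#' @param newdata Cohort data frame with `weight` (kg) and `height` (m).
#' @param power Exponent to apply; defaults to the fitted
#'   height-independent exponent.
#' @param ... Unused.
#' @return Numeric vector of index values.
#' @export
predict.benn_fit <- function(object, newdata, power = object$power, ...) {
  compute_index(newdata$weight, newdata$height, power,
                ids = newdata$id)
}

#' Plot age-adjusted correlation curves
#'
#' Draws the correlation of the index with each measure as a function of
#' the height exponent, with the zero reference line and the selected
#' exponent marked.
#'
#' @param x A [benn_fit()] object.
#' @param measures Measures to draw (default all fitted).
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.benn_fit <- function(x, measures = x$curves$measures, ...) {
  pw <- x$curves$grid$powers
  R <- sapply(measures, function(m) curve_for(x$curves, m)$r)
  graphics::matplot(pw, R, type = "l", lty = 1, col = seq_along(measures),
                    xlab = "height exponent p",
                    ylab = "age-adjusted partial correlation", ...)
  graphics::abline(h = 0, col = "grey60")
  graphics::abline(v = x$power, col = "grey30", lty = 2)
  graphics::legend("bottomright", legend = measures, lty = 1,
                   col = seq_along(measures), cex = 0.7, bty = "n")
  invisible(x)
}
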