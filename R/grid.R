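#' Exponent grid for the power scan
#'
#' Builds the ordered, uniformly spaced grid of height exponents over which
#' correlation curves are evaluated. Powers are stored exactly as integer
#' multiples of the step so that repeated arithmetic cannot drift off the
#' grid; the default grid (-50 to 50 in steps of 0.01) has 10,001 points.
#'
#' @param p_min,p_max Grid endpoints (inclusive), dimensionless exponents.
#' @param step Grid spacing; must be positive and divide `p_max - p_min`.
#' @return An object of class `power_grid`: a list with `p_min`, `p_max`,
#'   `step` and the numeric vector `powers`.
#' @examples
#' g <- power_grid(-5, 5, 0.01)
#' length(g$powers)
#' @export
power_grid <- function(p_min = -50, p_max = 50, step = 0.01) {
  stopifnot(is.numeric(p_min), is.numeric(p_max), is.numeric(step),
            length(p_min) == 1L, length(p_max) == 1L, length(step) == 1L)
  if (!is.finite(step) || step <= 0) stop("'step' must be a positive number")
  if (!is.finite(p_min) || !is.finite(p_max) || p_min >= p_max)
    stop("'p_min' must be strictly less than 'p_max'")
  i_min <- round(p_min / step)
  i_max <- round(p_max / step)
  if (abs(i_min * step - p_min) > 1e-9 || abs(i_max * step - p_max) > 1e-9)
    stop("grid endpoints must be integer multiples of 'step'")
  powers <- (i_min:i_max) * step
  structure(list(p_min = p_min, p_max = p_max, step = step, powers = powers),
            class = "power_grid")
}

#' @export
print.power_grid <- function(x, ...) {
  cat(sprintf("Exponent grid: %g to %g by %g (%d points)\n",
              x$p_min, x$p_max, x$step, length(x$powers)))
  invisible(x)
}

as_power_grid <- function(grid) {
  if (inherits(grid, "power_grid")) return(grid)
  if (is.numeric(grid) && length(grid) == 3L)
    return(power_grid(grid[1L], grid[2L], grid[3L]))
  stop("'grid' must be a power_grid or a numeric vector c(p_min, p_max, step)")
}
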