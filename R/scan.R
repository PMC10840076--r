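# Precomputed sufficient statistics for age-adjusted correlation of the
# index with each measure. Partial correlation given a single control is
# obtained from plain correlations via
#   r_xy.z = (r_xy - r_xz r_yz) / sqrt((1 - r_xz^2)(1 - r_yz^2)),
# algebraically identical to correlating OLS residuals; only correlations
# that involve the index change across the grid, so each grid point costs a
# handful of dot products.
scan_stats <- function(cohort, measures) {
  M <- as.matrix(cohort[measures])
  storage.mode(M) <- "double"
  age <- as.numeric(cohort$age)
  n <- nrow(M)
  ac <- age - mean(age)
  sa <- sqrt(sum(ac^2))
  if (sa == 0) stop("age has zero variance; cannot age-adjust")
  Mc <- sweep(M, 2L, colMeans(M), check.margin = FALSE)
  sm <- sqrt(colSums(Mc^2))
  if (any(sm == 0))
    stop("undefined correlation: zero variance in measure(s) ",
         paste(measures[sm == 0], collapse = ", "))
  r_ma <- as.vector(crossprod(Mc, ac)) / (sm * sa)
  list(n = n, measures = measures, logw = log(cohort$weight),
       logh = log(cohort$height), weight = as.numeric(cohort$weight),
       ac = ac, sa = sa, Mc = Mc, sm = sm, r_ma = r_ma)
}

# age-adjusted partial correlations of index(p) with every measure, one p
scan_at_power <- function(st, p) {
  idx <- if (p == 0) st$weight else exp(st$logw - p * st$logh)
  if (!all(is.finite(idx))) return(rep(NA_real_, length(st$measures)))
  ic <- idx - mean(idx)
  si <- sqrt(sum(ic^2))
  # a constant index (noise-free cohort at p = p_true) carries no
  # information about any measure; its correlation is defined as 0, the
  # limit of the correlation as the weight residual SD goes to 0
  if (si == 0) return(rep(0, length(st$measures)))
  r_im <- as.vector(crossprod(st$Mc, ic)) / (st$sm * si)
  r_ia <- sum(ic * st$ac) / (si * st$sa)
  r <- (r_im - r_ia * st$r_ma) / sqrt((1 - r_ia^2) * (1 - st$r_ma^2))
  pmin(pmax(r, -1), 1)
}

#' Age-adjusted partial correlation curves over an exponent grid
#'
#' For every grid exponent p and every measure, computes the age-adjusted
#' partial Pearson correlation between the index weight/height^p and the
#' measure, exactly at each grid point (no interpolation), with 95%
#' Fisher-z confidence bounds. Index values are formed in log space so the
#' scan survives |p| up to 50 without overflow; any grid point yielding
#' non-finite index values is flagged as `NA` with a warning.
#'
#' @param cohort A single-sex cohort with derived measures present (see
#'   [derive_measures()]).
#' @param measures Character vector of measure columns; defaults to height
#'   plus the seven fatness / central-adiposity measures.
#' @param grid A [power_grid()] (or `c(p_min, p_max, step)`).
#' @return An object of class `benn_curves`: list with the `grid`, the
#'   effective `n`, and `curves`, a long data frame with columns `power`,
#'   `measure`, `r`, `ci_lo`, `ci_hi`.
#' @export
scan_powers <- function(cohort, measures = BENN_MEASURES,
                        grid = power_grid()) {
  grid <- as_power_grid(grid)
  if (length(unique(as.character(cohort$sex))) > 1L)
    stop("power scan requires a single-sex cohort; split by sex first")
  miss <- setdiff(measures, names(cohort))
  if (length(miss))
    stop("derived measures missing from cohort: ",
         paste(miss, collapse = ", "), "; run derive_measures() first")
  st <- scan_stats(cohort, measures)
  pw <- grid$powers
  R <- matrix(NA_real_, nrow = length(pw), ncol = length(measures),
              dimnames = list(NULL, measures))
  for (i in seq_along(pw)) R[i, ] <- scan_at_power(st, pw[i])
  if (anyNA(R))
    warning("non-finite index values at some grid exponents; ",
            "correlations flagged as NA")
  se <- 1 / sqrt(st$n - 1 - 3)
  z <- atanh(pmin(pmax(R, -1 + 1e-16), 1 - 1e-16))
  z[which(R == 1)] <- Inf; z[which(R == -1)] <- -Inf
  curves <- data.frame(
    power = rep(pw, times = length(measures)),
    measure = rep(measures, each = length(pw)),
    r = as.vector(R),
    ci_lo = as.vector(tanh(z - 1.96 * se)),
    ci_hi = as.vector(tanh(z + 1.96 * se)),
    stringsAsFactors = FALSE)
  structure(list(grid = grid, n = st$n, measures = measures, curves = curves),
            class = "benn_curves")
}

#' @export
print.benn_curves <- function(x, ...) {
  cat(sprintf(
    "Age-adjusted correlation curves: %d measures x %d grid points (n = %d)\n",
    length(x$measures), length(x$grid$powers), x$n))
  invisible(x)
}

curve_for <- function(curves, measure) {
  stopifnot(inherits(curves, "benn_curves"))
  if (!measure %in% x_measures(curves))
    stop("no curve for measure '", measure, "'")
  curves$curves[curves$curves$measure == measure, , drop = FALSE]
}

x_measures <- function(curves) curves$measures

criterion_optimum <- function(curves, criterion, i_opt, note = NULL) {
  pw <- curves$grid$powers
  at <- vapply(curves$measures, function(m) {
    cf <- curve_for(curves, m)
    cf$r[i_opt]
  }, numeric(1L))
  structure(list(criterion = criterion, p_opt = pw[i_opt],
                 correlations_at_opt = at, n = curves$n, note = note),
            class = "criterion_optimum")
}

#' @export
print.criterion_optimum <- function(x, ...) {
  cat(sprintf("Criterion '%s': optimal power %.2f\n", x$criterion, x$p_opt))
  print(round(x$correlations_at_opt, 3))
  if (!is.null(x$note)) cat("note:", x$note, "\n")
  invisible(x)
}

#' Height-independency optimum: exponent where the height correlation is 0
#'
#' Selects the grid exponent minimizing the absolute age-adjusted partial
#' correlation between the index and height (ties broken toward the smaller
#' exponent), and records whether a sign change of the height curve
#' brackets the optimum — anthropometric-like data is expected to cross
#' zero exactly once. If the curve never changes sign a warning is issued
#' and the minimum-|r| point is still returned.
#'
#' @param curves A [scan_powers()] result containing a `height` curve.
#' @return A `criterion_optimum`: criterion name, `p_opt` (on the grid),
#'   and the correlations of the index at `p_opt` with every measure.
#' @export
find_height_independent_power <- function(curves) {
  cf <- curve_for(curves, "height")
  r <- cf$r
  if (all(is.na(r))) stop("height curve is entirely NA")
  i <- which.min(abs(r))            # first index = smallest power on ties
  sgn <- sign(r[!is.na(r) & r != 0])
  note <- NULL
  if (length(unique(sgn)) < 2L && !any(r == 0, na.rm = TRUE)) {
    warning("height correlation curve has no sign change on the grid; ",
            "returning the minimum-|r| point")
    note <- "no zero crossing bracketed on grid"
  }
  criterion_optimum(curves, "height", i, note)
}

#' Fatness-dependency optimum: exponent maximizing a measure's correlation
#'
#' Selects the grid exponent maximizing the signed age-adjusted partial
#' correlation between the index and the given fatness measure (ties toward
#' the smaller exponent). A plateau of more than 10 grid points at the
#' maximum triggers a warning.
#'
#' @param curves A [scan_powers()] result.
#' @param measure The fatness measure whose correlation is maximized.
#' @return A `criterion_optimum`.
#' @export
find_max_corr_power <- function(curves, measure) {
  cf <- curve_for(curves, measure)
  r <- cf$r
  if (all(is.na(r))) stop("curve for '", measure, "' is entirely NA")
  i <- which.max(r)
  note <- NULL
  plateau <- sum(!is.na(r) & r >= max(r, na.rm = TRUE) - 1e-12)
  if (plateau > 10L) {
    warning("correlation plateau of ", plateau,
            " grid points at the maximum for '", measure, "'")
    note <- sprintf("plateau of %d grid points at the maximum", plateau)
  }
  criterion_optimum(curves, measure, i, note)
}

#' Criterion-optimum report over all measures
#'
#' Builds the report of optimal exponents under each criterion: one row for
#' the conventional formula (p = 2.00), one for the height-independency
#' criterion, and one per fatness-dependency criterion (BF%, weight, fat
#' mass, fat-free mass, WC, WHR, WHtR) — nine rows; each row reports the
#' age-adjusted correlations of the index at that row's exponent with all
#' eight measures.
#'
#' @param cohort A single-sex cohort with derived measures.
#' @param grid A [power_grid()]; must contain p = 2 (the default does).
#' @param curves Optionally, a precomputed [scan_powers()] result (then
#'   `cohort`/`grid` are ignored).
#' @return A data frame of class `criterion_table` with columns
#'   `criterion`, `power`, and `r_<measure>` for every measure.
#' @export
build_criterion_table <- function(cohort = NULL, grid = power_grid(),
                                  curves = NULL) {
  if (is.null(curves)) curves <- scan_powers(cohort, BENN_MEASURES, grid)
  pw <- curves$grid$powers
  i2 <- which(abs(pw - 2) < 1e-9)
  if (!length(i2)) stop("the grid must contain p = 2.00 (conventional row)")
  opts <- c(list(criterion_optimum(curves, "conventional", i2[1L])),
            list(find_height_independent_power(curves)),
            lapply(intersect(BENN_FATNESS_MEASURES, curves$measures),
                   function(m) find_max_corr_power(curves, m)))
  tab <- do.call(rbind, lapply(opts, function(o) {
    row <- data.frame(criterion = o$criterion, power = o$p_opt,
                      stringsAsFactors = FALSE)
    for (m in names(o$correlations_at_opt))
      row[[paste0("r_", m)]] <- unname(o$correlations_at_opt[m])
    row
  }))
  class(tab) <- c("criterion_table", "data.frame")
  attr(tab, "n") <- curves$n
  tab
}

#' @export
print.criterion_table <- function(x, digits = 2, ...) {
  cat(sprintf("Criterion optima (n = %d):\n", attr(x, "n")))
  y <- as.data.frame(x)
  y$power <- sprintf("%.2f", y$power)
  num <- vapply(y, is.numeric, logical(1L))
  y[num] <- lapply(y[num], round, digits)
  print(y, row.names = FALSE)
  invisible(x)
}
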