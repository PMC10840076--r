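#' Relative-weight index weight / height^p
#'
#' Evaluates the Benn-type index for a vector of subjects. Computation is in
#' log space, `exp(log(weight) - p * log(height))`, so exponents up to |p| =
#' 50 do not overflow double precision; at p = 0 the index is returned as
#' weight itself.
#'
#' @param weight Body weight in kg, positive.
#' @param height Standing height in m, positive.
#' @param power Height exponent p (finite scalar). Conventional BMI uses
#'   p = 2.
#' @param ids Optional subject identifiers used in error messages.
#' @return Numeric vector of index values (kg / m^p).
#' @examples
#' compute_index(80, 2.0, 2)     # 20
#' compute_index(71.4, 1.62, 1.39)
#' @export
compute_index <- function(weight, height, power, ids = NULL) {
  stopifnot(is.numeric(power), length(power) == 1L, is.finite(power))
  weight <- as.numeric(weight); height <- as.numeric(height)
  if (length(weight) != length(height))
    stop("'weight' and 'height' must have equal length")
  bad <- !is.finite(weight) | !is.finite(height) | weight <= 0 | height <= 0
  if (any(bad)) {
    lab <- if (is.null(ids)) which(bad) else ids[bad]
    stop("non-positive or non-finite weight/height for record(s): ",
         paste(utils::head(lab, 10L), collapse = ", "))
  }
  if (power == 0) return(weight)
  exp(log(weight) - power * log(height))
}

#' Derive body-composition and central-adiposity measures
#'
#' Adds (or recomputes) the derived columns used throughout the pipeline:
#' body fat percentage `bf_pct = 100 * fat_mass / weight`, waist-to-hip
#' ratio `whr = wc / hip`, waist-to-height ratio `whtr = wc / (100 *
#' height)` (waist in cm over height in cm), and relative sitting height
#' `rsh = sitting_height / height`.
#'
#' @param cohort A cohort data frame (see [generate_cohort()] for the
#'   schema).
#' @return The cohort with columns `bf_pct`, `whr`, `whtr`, `rsh`.
#' @export
derive_measures <- function(cohort) {
  need <- c("weight", "fat_mass", "wc", "hip", "height", "sitting_height")
  miss <- setdiff(need, names(cohort))
  if (length(miss))
    stop("missing required columns: ", paste(miss, collapse = ", "))
  for (v in need) {
    bad <- !is.finite(cohort[[v]]) | cohort[[v]] <= 0
    if (any(bad)) {
      lab <- if ("id" %in% names(cohort)) cohort$id[bad] else which(bad)
      stop("non-positive '", v, "' for record(s): ",
           paste(utils::head(lab, 10L), collapse = ", "))
    }
  }
  cohort$bf_pct <- 100 * cohort$fat_mass / cohort$weight
  cohort$whr <- cohort$wc / cohort$hip
  cohort$whtr <- cohort$wc / (100 * cohort$height)
  cohort$rsh <- cohort$sitting_height / cohort$height
  cohort
}

#' Ordered category scheme for a relative-weight index
#'
#' @param thresholds Three strictly increasing cut points on the index scale
#'   (default 18.5 / 25 / 30, the standard BMI bands).
#' @param labels Four ordered category labels.
#' @return An object of class `category_scheme`.
#' @export
category_scheme <- function(thresholds = c(18.5, 25, 30),
                            labels = c("underweight", "normal",
                                       "overweight", "obese")) {
  thresholds <- as.numeric(thresholds)
  if (any(!is.finite(thresholds)) || any(diff(thresholds) <= 0))
    stop("'thresholds' must be finite and strictly increasing")
  if (length(labels) != length(thresholds) + 1L)
    stop("need one more label than thresholds")
  structure(list(thresholds = thresholds, labels = as.character(labels)),
            class = "category_scheme")
}

#' @export
print.category_scheme <- function(x, ...) {
  cat("Category scheme:\n")
  cuts <- c("-Inf", format(x$thresholds), "Inf")
  for (k in seq_along(x$labels))
    cat(sprintf("  %-12s [%s, %s)\n", x$labels[k], cuts[k], cuts[k + 1L]))
  invisible(x)
}

#' Classify index values into ordered categories
#'
#' Half-open, left-closed binning: a value falls in category k when
#' `thresholds[k-1] <= x < thresholds[k]`; the lowest bin is unbounded below
#' and the highest unbounded above, so a value exactly on a threshold goes
#' to the upper category (a BMI of 25.0 is "overweight").
#'
#' @param x Numeric index values, all finite.
#' @param scheme A [category_scheme()].
#' @return An ordered factor with the scheme's labels.
#' @export
classify_index <- function(x, scheme) {
  stopifnot(inherits(scheme, "category_scheme"))
  if (any(!is.finite(x))) stop("non-finite index values cannot be classified")
  cut(x, breaks = c(-Inf, scheme$thresholds, Inf), labels = scheme$labels,
      right = FALSE, ordered_result = TRUE)
}

#' Map category thresholds from one index formula to another
#'
#' Quantile matching on the training set: each new threshold is the
#' empirical quantile (linear interpolation, type 7) of the new index at the
#' cumulative fraction of training subjects whose old index falls below the
#' corresponding old threshold. Applying the mapped scheme to the training
#' set preserves marginal category frequencies to within 1/n.
#'
#' @param train_old_index,train_new_index Index values for the same training
#'   subjects under the old and new formulas.
#' @param old_scheme The [category_scheme()] on the old index scale.
#' @return A `category_scheme` on the new index scale.
#' @export
map_category_thresholds <- function(train_old_index, train_new_index,
                                    old_scheme) {
  stopifnot(inherits(old_scheme, "category_scheme"))
  if (length(train_old_index) != length(train_new_index))
    stop("index vectors must come from the same training subjects")
  if (any(!is.finite(train_old_index)) || any(!is.finite(train_new_index)))
    stop("non-finite index values")
  fr <- vapply(old_scheme$thresholds,
               function(t) mean(train_old_index < t), numeric(1L))
  new_t <- as.numeric(stats::quantile(train_new_index, fr, type = 7,
                                      names = FALSE))
  if (any(diff(new_t) <= 0))
    stop("degenerate new-index distribution: mapped thresholds are not ",
         "strictly increasing")
  category_scheme(new_t, old_scheme$labels)
}
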