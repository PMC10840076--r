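#' Label excessive body fat
#'
#' Applies the sex-specific screening definition of excessive body fat:
#' strictly greater than 35% for females and 25% for males. Records with a
#' missing BF% are excluded (returned as `NA`) with a message giving the
#' count.
#'
#' @param cohort Cohort with `bf_pct` and `sex`.
#' @param thresholds Named vector of per-sex thresholds (percent).
#' @return Logical vector: `TRUE` = high body fat.
#' @export
label_excess_fat <- function(cohort, thresholds = c(F = 35, M = 25)) {
  if (!all(c("bf_pct", "sex") %in% names(cohort)))
    stop("cohort must contain 'bf_pct' and 'sex'")
  thr <- thresholds[as.character(cohort$sex)]
  lab <- cohort$bf_pct > unname(thr)
  n_na <- sum(is.na(lab))
  if (n_na > 0L)
    message(n_na, " record(s) excluded for missing bf_pct")
  lab
}

#' Rank-based AUC (area under the ROC curve)
#'
#' The probability that a randomly chosen high-label score exceeds a
#' randomly chosen low-label score, ties counted one half — the
#' Mann-Whitney statistic divided by n1*n0. For a single continuous
#' predictor this equals the ROC area of a logistic regression of the label
#' on the score, because the fitted probability is a monotone transform of
#' the score; that equivalence is exercised in the test suite.
#'
#' @param scores Numeric scores (higher = more likely high).
#' @param labels Logical (or coercible) class labels; both classes must be
#'   present.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]; labels <- labels[keep]
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L)
    stop("AUC undefined: both classes must be present")
  r <- rank(scores)                     # midranks handle ties as 1/2
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Youden-optimal screening cutoff
#'
#' Maximizes sensitivity + specificity over all candidate cutoffs —
#' midpoints between consecutive distinct sorted scores plus -Inf and
#' +Inf — under the classification rule "score >= cutoff predicts high".
#' Ties are broken toward the smallest cutoff.
#'
#' @inheritParams roc_auc
#' @return A list with `cutoff`, `sensitivity` and `specificity` (both in
#'   percent), and `youden` (sensitivity + specificity, percent).
#' @export
youden_optimal_cutoff <- function(scores, labels) {
  labels <- as.logical(labels)
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]; labels <- labels[keep]
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L)
    stop("cutoff undefined: both classes must be present")
  o <- order(scores)
  s <- scores[o]; l <- labels[o]
  nn <- length(s)
  new_grp <- c(TRUE, s[-1L] != s[-nn])
  u <- s[new_grp]
  g <- cumsum(new_grp)
  # candidate k classifies "high" exactly the scores >= u[k+1]
  cum1 <- unname(cumsum(rowsum(as.numeric(l), g)[, 1L]))
  cum0 <- unname(cumsum(rowsum(as.numeric(!l), g)[, 1L]))
  cand <- c(-Inf, (u[-length(u)] + u[-1L]) / 2, Inf)
  sens <- c(1, (n1 - cum1) / n1) * 100
  spec <- c(0, cum0 / n0) * 100
  j <- sens + spec
  # ties (within rounding noise of the percent arithmetic) break toward
  # the smallest cutoff
  i <- which(j > max(j) - 1e-9)[1L]
  list(cutoff = cand[i], sensitivity = sens[i], specificity = spec[i],
       youden = j[i])
}

#' Sensitivity and specificity at a fixed cutoff
#'
#' Evaluates the rule "score >= cutoff predicts high" — used to apply a
#' training-derived cutoff to a test cohort.
#'
#' @inheritParams roc_auc
#' @param cutoff The frozen cutoff.
#' @return A list with `sensitivity` and `specificity` in percent.
#' @export
sens_spec_at_cutoff <- function(scores, labels, cutoff) {
  labels <- as.logical(labels)
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]; labels <- labels[keep]
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  pred <- scores >= cutoff
  list(sensitivity = 100 * sum(pred & labels) / n1,
       specificity = 100 * sum(!pred & !labels) / n0)
}

#' Relative-sitting-height strata
#'
#' Assigns each subject to a body-build stratum from relative sitting
#' height (sitting height / standing height): lower third below the 2.5%
#' quantile, upper third at or above the 97.5% quantile, middle third in
#' between. Quantiles are the linear-interpolation empirical definition
#' (type 7), computed per sex on the cohort being stratified.
#'
#' @param cohort Cohort with `rsh` and `sex` (run [derive_measures()]
#'   first).
#' @return Factor with levels `rsh_lower`, `rsh_middle`, `rsh_upper`.
#' @export
stratify_rsh <- function(cohort) {
  if (!"rsh" %in% names(cohort))
    stop("'rsh' missing; run derive_measures() first")
  out <- factor(rep(NA_character_, nrow(cohort)),
                levels = c("rsh_lower", "rsh_middle", "rsh_upper"))
  for (s in unique(as.character(cohort$sex))) {
    rows <- which(as.character(cohort$sex) == s)
    if (length(rows) < 40L)
      warning("fewer than 40 subjects for sex ", s,
              "; RSH strata unreliable")
    r <- cohort$rsh[rows]
    if (max(r) == min(r)) {
      warning("all RSH values equal for sex ", s,
              "; extreme strata are empty")
      out[rows] <- "rsh_middle"
      next
    }
    q <- stats::quantile(r, c(0.025, 0.975), type = 7, names = FALSE)
    out[rows] <- ifelse(r < q[1L], "rsh_lower",
                        ifelse(r < q[2L], "rsh_middle", "rsh_upper"))
  }
  out
}

#' Category reclassification between two formulas
#'
#' Fraction of subjects whose ordinal category changes between the old and
#' new classification, split by direction.
#'
#' @param old_categories,new_categories Ordered factors over the same label
#'   set, same subjects.
#' @return A list with `pct_changed`, `pct_up`, `pct_down` (percent) and
#'   `n`; `pct_changed = pct_up + pct_down`.
#' @export
reclassification <- function(old_categories, new_categories) {
  if (length(old_categories) != length(new_categories))
    stop("category vectors must have equal length")
  if (!identical(levels(old_categories), levels(new_categories)))
    stop("category label sets do not match")
  o <- as.integer(old_categories); nw <- as.integer(new_categories)
  n <- length(o)
  list(pct_changed = 100 * sum(nw != o) / n,
       pct_up = 100 * sum(nw > o) / n,
       pct_down = 100 * sum(nw < o) / n,
       n = n)
}

#' Screening accuracy table for competing index formulas
#'
#' Evaluates each formula as a screen for excessive body fat on the test
#' cohort, overall and within relative-sitting-height strata, at
#' Youden-optimal cutoffs learned on the training cohort and frozen —
#' mirroring the train/test design (no test-set leakage). Also reports the
#' category reclassification between the first ("old") and second ("new")
#' formula on the test cohort, using the old scheme's thresholds mapped to
#' the new index scale by training-set quantile matching.
#'
#' @param train,test Single-sex cohorts (training and evaluation).
#' @param powers Named numeric vector of height exponents, e.g.
#'   `c(old = 2, new = 1.39)`.
#' @param bf_thresholds Per-sex BF% thresholds for the high-fat label.
#' @param old_scheme [category_scheme()] on the first formula's scale.
#' @return A list of class `screening_table`: `screening` (data frame,
#'   formula x stratum rows with n, auc, cutoff, sensitivity, specificity),
#'   `cutoffs`, `reclassification`, and the mapped `schemes`.
#' @export
build_screening_table <- function(train, test, powers = c(old = 2),
                                  bf_thresholds = c(F = 35, M = 25),
                                  old_scheme = category_scheme()) {
  if (is.null(names(powers)) || any(names(powers) == ""))
    stop("'powers' must be a named vector of exponents")
  train <- derive_measures(train)
  test <- derive_measures(test)
  lab_train <- label_excess_fat(train, bf_thresholds)
  lab_test <- label_excess_fat(test, bf_thresholds)
  strata <- stratify_rsh(test)

  cutoffs <- numeric(0)
  rows <- list()
  for (f in names(powers)) {
    sc_train <- compute_index(train$weight, train$height, powers[[f]])
    sc_test <- compute_index(test$weight, test$height, powers[[f]])
    cut_f <- youden_optimal_cutoff(sc_train, lab_train)$cutoff
    cutoffs[f] <- cut_f
    for (st in c("all", levels(strata))) {
      in_st <- if (st == "all") rep(TRUE, nrow(test)) else strata == st
      if (!any(in_st)) {
        rows[[length(rows) + 1L]] <- data.frame(
          formula = f, power = unname(powers[[f]]), stratum = st, n = 0L,
          auc = NA_real_, cutoff = cut_f, sensitivity = NA_real_,
          specificity = NA_real_, stringsAsFactors = FALSE)
        next
      }
      ss <- sens_spec_at_cutoff(sc_test[in_st], lab_test[in_st], cut_f)
      rows[[length(rows) + 1L]] <- data.frame(
        formula = f, power = unname(powers[[f]]), stratum = st,
        n = sum(in_st),
        auc = roc_auc(sc_test[in_st], lab_test[in_st]),
        cutoff = cut_f,
        sensitivity = ss$sensitivity, specificity = ss$specificity,
        stringsAsFactors = FALSE)
    }
  }
  out <- list(screening = do.call(rbind, rows), cutoffs = cutoffs)

  if (length(powers) >= 2L) {
    f_old <- names(powers)[1L]; f_new <- names(powers)[2L]
    tr_old <- compute_index(train$weight, train$height, powers[[f_old]])
    tr_new <- compute_index(train$weight, train$height, powers[[f_new]])
    new_scheme <- map_category_thresholds(tr_old, tr_new, old_scheme)
    te_old <- compute_index(test$weight, test$height, powers[[f_old]])
    te_new <- compute_index(test$weight, test$height, powers[[f_new]])
    out$reclassification <- reclassification(
      classify_index(te_old, old_scheme),
      classify_index(te_new, new_scheme))
    out$schemes <- stats::setNames(list(old_scheme, new_scheme),
                                   c(f_old, f_new))
  }
  class(out) <- "screening_table"
  out
}

#' @export
print.screening_table <- function(x, ...) {
  cat("Screening accuracy (cutoffs learned on training data):\n")
  y <- x$screening
  for (v in c("auc")) y[[v]] <- round(y[[v]], 3)
  for (v in c("cutoff", "sensitivity", "specificity"))
    y[[v]] <- round(y[[v]], 1)
  print(y, row.names = FALSE)
  if (!is.null(x$reclassification)) {
    r <- x$reclassification
    cat(sprintf(
      "Reclassification: %.1f%% changed (%.1f%% up, %.1f%% down), n = %d\n",
      r$pct_changed, r$pct_up, r$pct_down, r$n))
  }
  invisible(x)
}
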