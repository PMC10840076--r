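MEASURES_ALL <- c("height", "bf_pct", "weight", "fat_mass",
                  "fat_free_mass", "wc", "whr", "whtr")
MEASURES_FATNESS <- setdiff(MEASURES_ALL, "height")

# small seeded cohorts used across tests
tiny_cohort <- function(n = 400, sex = "F", seed = 1, ...) {
  generate_cohort(cohort_params(sex, n = n, seed = seed, ...))
}

# mixed-sex cohort by concatenation (ids stay unique via the sex prefix)
mixed_cohort <- function(n_f = 200, n_m = 200, seed = 1) {
  rbind(tiny_cohort(n_f, "F", seed), tiny_cohort(n_m, "M", seed + 1))
}

# residual-regression partial correlation: the independent two-stage OLS
# oracle used against the package's recursion-based scan
oracle_partial_corr <- function(x, y, control) {
  rx <- stats::residuals(stats::lm(x ~ control))
  ry <- stats::residuals(stats::lm(y ~ control))
  stats::cor(rx, ry)
}

# O(n^2) pair-counting AUC oracle
oracle_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  hi <- scores[labels]; lo <- scores[!labels]
  tot <- 0
  for (h in hi) tot <- tot + sum(h > lo) + 0.5 * sum(h == lo)
  tot / (length(hi) * length(lo))
}

# exhaustive Youden-cutoff oracle over all midpoint candidates
oracle_youden <- function(scores, labels) {
  labels <- as.logical(labels)
  u <- sort(unique(scores))
  cand <- c(-Inf, (u[-length(u)] + u[-1]) / 2, Inf)
  best <- NULL
  for (ct in cand) {
    pred <- scores >= ct
    sens <- 100 * sum(pred & labels) / sum(labels)
    spec <- 100 * sum(!pred & !labels) / sum(!labels)
    if (is.null(best) || sens + spec > best$youden + 1e-12)
      best <- list(cutoff = ct, sensitivity = sens, specificity = spec,
                   youden = sens + spec)
  }
  best
}
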