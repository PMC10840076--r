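test_that("excess-fat labels follow the strict sex-specific rule", {
  co <- data.frame(
    sex = factor(c("F", "F", "F", "M", "M", "M", "F", "M")),
    bf_pct = c(35.0, 35.01, 40, 25.0, 25.3, 24.9, 10, 60))
  lab <- label_excess_fat(co)
  expect_identical(lab, c(FALSE, TRUE, TRUE, FALSE, TRUE, FALSE,
                          FALSE, TRUE))
  co$bf_pct[1] <- NA
  expect_message(lab2 <- label_excess_fat(co), "1 record")
  expect_true(is.na(lab2[1]))
})

test_that("AUC is the tie-aware pair-counting probability", {
  expect_equal(roc_auc(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1)), 1.0)
  expect_equal(roc_auc(rep(5, 10), rep(c(0, 1), 5)), 0.5)
  s <- c(3, 1, 4, 1, 5, 9)
  l <- c(0, 0, 1, 0, 1, 1)
  expect_equal(roc_auc(s, l), oracle_auc(s, l))
  set.seed(8)
  for (rep in 1:20) {
    s <- sample(1:15, 40, replace = TRUE)      # many ties
    l <- rbinom(40, 1, 0.4)
    if (sum(l) %in% c(0, 40)) next
    expect_equal(roc_auc(s, l), oracle_auc(s, l), tolerance = 1e-12)
  }
  expect_error(roc_auc(1:5, rep(1, 5)), "both classes")
})

test_that("AUC equals the ROC area of a single-predictor logistic model", {
  skip_if_not_installed("pROC")
  set.seed(21)
  for (rep in 1:5) {
    s <- rnorm(300)
    l <- rbinom(300, 1, plogis(1.5 * s))
    if (sum(l) %in% c(0, 300)) next
    fit <- glm(l ~ s, family = binomial)
    roc <- pROC::roc(l, fitted(fit), quiet = TRUE, direction = "<")
    expect_equal(roc_auc(s, l), as.numeric(pROC::auc(roc)),
                 tolerance = 1e-6)
  }
})

test_that("Youden cutoff maximizes sensitivity plus specificity", {
  # perfect separation: cutoff in the gap, sens = spec = 100
  out <- youden_optimal_cutoff(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1))
  expect_equal(out$cutoff, 6.5)
  expect_equal(out$sensitivity, 100)
  expect_equal(out$specificity, 100)
  # 10-point toy vs exhaustive scan
  s <- c(1, 2, 2, 3, 4, 5, 5, 6, 7, 8)
  l <- c(0, 0, 1, 0, 1, 0, 1, 1, 1, 1)
  got <- youden_optimal_cutoff(s, l)
  ref <- oracle_youden(s, l)
  expect_equal(got[c("cutoff", "sensitivity", "specificity")],
               ref[c("cutoff", "sensitivity", "specificity")])
  expect_error(youden_optimal_cutoff(1:5, rep(0, 5)), "both classes")
})

test_that("random instances agree with the exhaustive cutoff oracle", {
  set.seed(33)
  for (rep in 1:60) {
    n <- sample(8:40, 1)
    s <- round(rnorm(n, 25, 4), sample(0:2, 1))
    l <- rbinom(n, 1, plogis((s - 25) / 2))
    if (sum(l) %in% c(0, n)) next
    got <- youden_optimal_cutoff(s, l)
    ref <- oracle_youden(s, l)
    expect_equal(got$youden, ref$youden, tolerance = 1e-9)
    expect_equal(got$cutoff, ref$cutoff)
  }
})

test_that("raising the cutoff trades sensitivity for specificity", {
  set.seed(12)
  s <- rnorm(200, 25, 4)
  l <- rbinom(200, 1, plogis((s - 25) / 2))
  u <- sort(unique(s))
  path <- sapply(c(-Inf, (u[-length(u)] + u[-1]) / 2, Inf), function(ct) {
    ss <- sens_spec_at_cutoff(s, l, ct)
    c(ss$sensitivity, ss$specificity)
  })
  expect_true(all(diff(path[1, ]) <= 0))
  expect_true(all(diff(path[2, ]) >= 0))
})

test_that("RSH strata split at the 2.5% and 97.5% quantiles per sex", {
  co <- data.frame(sex = factor(rep("F", 1000)),
                   rsh = seq(0.45, 0.60, length.out = 1000))
  st <- stratify_rsh(co)
  expect_lte(abs(sum(st == "rsh_lower") - 25), 1)
  expect_lte(abs(sum(st == "rsh_upper") - 25), 1)
  expect_equal(sum(table(st)), 1000)
  # degenerate: everyone identical -> all middle, with a warning
  co2 <- data.frame(sex = factor(rep("F", 100)), rsh = rep(0.52, 100))
  expect_warning(st2 <- stratify_rsh(co2), "equal")
  expect_true(all(st2 == "rsh_middle"))
  expect_warning(stratify_rsh(data.frame(sex = factor(rep("F", 10)),
                                         rsh = runif(10, 0.4, 0.6))),
                 "fewer than 40")
})

test_that("reclassification counts ordinal moves by direction", {
  sch <- category_scheme()
  x <- classify_index(c(17, 20, 26, 31, 24), sch)
  expect_equal(reclassification(x, x),
               list(pct_changed = 0, pct_up = 0, pct_down = 0, n = 5))
  old <- classify_index(c(17, 20, 20, 26, 26, 31, 24, 24, 28, 33), sch)
  new <- classify_index(c(17, 26, 20, 31, 26, 29, 24, 24, 28, 33), sch)
  out <- reclassification(old, new)
  expect_equal(out$pct_changed, 30)
  expect_equal(out$pct_up, 20)
  expect_equal(out$pct_down, 10)
  expect_equal(out$pct_up + out$pct_down, out$pct_changed)
  bad <- factor(rep("a", 10))
  expect_error(reclassification(old, bad), "label sets")
})

test_that("screening table evaluates frozen training cutoffs on test data", {
  co <- tiny_cohort(4000, seed = 41)
  sp <- split_train_test(co, 0.25, seed = 2)
  tab <- build_screening_table(sp$train, sp$test,
                               powers = c(old = 2, new = 1.4))
  expect_identical(nrow(tab$screening), 8L)   # 2 formulas x (all + 3 strata)
  expect_setequal(unique(tab$screening$stratum),
                  c("all", "rsh_lower", "rsh_middle", "rsh_upper"))
  # strata partition the test cohort
  ns <- tab$screening[tab$screening$formula == "old", "n"]
  expect_equal(sum(ns[-1]), ns[1])
  # AUC sensible when the index tracks fatness
  expect_true(all(tab$screening$auc[tab$screening$n > 30] > 0.5))
  expect_true(all(tab$screening$auc <= 1, na.rm = TRUE))
  # identical formulas give identical rows
  tab2 <- build_screening_table(sp$train, sp$test,
                                powers = c(old = 2, new = 2))
  rows <- tab2$screening
  old_rows <- rows[rows$formula == "old", -1]
  new_rows <- rows[rows$formula == "new", -1]
  rownames(old_rows) <- rownames(new_rows) <- NULL
  expect_equal(old_rows, new_rows)
  expect_equal(tab2$reclassification$pct_changed, 0)
  # reclassification consistency on the non-trivial pair
  r <- tab$reclassification
  expect_equal(r$pct_up + r$pct_down, r$pct_changed, tolerance = 0.01)
  expect_equal(r$n, nrow(sp$test))
})
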