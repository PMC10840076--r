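test_that("fifths are assigned at interpolated quintiles, ties go low", {
  expect_identical(assign_fifths(1:10), rep(1:5, each = 2L))
  x <- rlnorm(100, 3, 0.2)
  expect_identical(assign_fifths(x), assign_fifths(7.5 * x))
  # tied data: values equal to a cutpoint fall in the lower fifth
  y <- c(1, 1, 2, 2, 3, 3, 4, 4, 5, 5)
  q <- quantile(y, c(.2, .4, .6, .8), type = 7, names = FALSE)
  hand <- 1L + (y > q[1]) + (y > q[2]) + (y > q[3]) + (y > q[4])
  expect_identical(assign_fifths(y), hand)
  expect_error(assign_fifths(rep(1, 50)), "ties")
  expect_error(assign_fifths(1:3), "at least 5")
})

test_that("three-subject partial likelihood matches the hand product", {
  time <- c(1, 2, 3); event <- c(1L, 1L, 1L)
  X <- matrix(c(1, 0, 2), ncol = 1)
  b <- 0.5
  e <- exp(b * X[, 1])
  hand <- log(e[1] / sum(e)) + log(e[2] / sum(e[2:3])) + log(e[3] / e[3])
  got <- cox_partial_loglik(b, time, event, X)
  expect_equal(got$loglik, hand, tolerance = 1e-12)
})

test_that("analytic score matches central finite differences", {
  set.seed(4)
  n <- 60
  X <- cbind(rnorm(n), rbinom(n, 1, 0.5), runif(n))
  t_ev <- rexp(n, 0.1 * exp(0.3 * X[, 1] - 0.2 * X[, 2]))
  time <- round(pmin(t_ev, 8), 1) + 0.05
  event <- as.integer(t_ev <= 8)
  beta <- c(0.25, -0.15, 0.1)
  for (ties in c("efron", "breslow")) {
    g <- cox_partial_loglik(beta, time, event, X, ties = ties)$gradient
    h <- 1e-6
    fd <- sapply(seq_along(beta), function(i) {
      e <- numeric(3); e[i] <- h
      (cox_partial_loglik(beta + e, time, event, X, ties = ties)$loglik -
         cox_partial_loglik(beta - e, time, event, X, ties = ties)$loglik) /
        (2 * h)
    })
    expect_equal(g, fd, tolerance = 1e-6)
  }
})

test_that("Efron and Breslow coincide when no event times tie", {
  set.seed(5)
  n <- 80
  X <- cbind(a = rnorm(n), b = runif(n))
  t_ev <- rexp(n, 0.08 * exp(0.4 * X[, 1]))
  time <- pmin(t_ev, 10)                      # continuous: no ties
  event <- as.integer(t_ev <= 10)
  beta <- c(0.3, -0.2)
  ef <- cox_partial_loglik(beta, time, event, X, ties = "efron")
  br <- cox_partial_loglik(beta, time, event, X, ties = "breslow")
  expect_equal(ef$loglik, br$loglik, tolerance = 1e-12)
  expect_equal(ef$gradient, br$gradient, tolerance = 1e-12)
})

test_that("the fit agrees with an independent Cox implementation", {
  skip_if_not_installed("survival")
  set.seed(6)
  n <- 1500
  X <- cbind(x1 = rnorm(n), x2 = rbinom(n, 1, 0.4))
  t_ev <- rexp(n, 0.05 * exp(0.4 * X[, 1] - 0.3 * X[, 2]))
  time <- round(pmin(t_ev, 10), 1)            # induces ties
  time[time == 0] <- 0.05
  event <- as.integer(t_ev <= 10)
  fit <- fit_cox(time, event, X)
  ref <- survival::coxph(survival::Surv(time, event) ~ X, ties = "efron")
  expect_equal(unname(coef(fit)), unname(coef(ref)), tolerance = 1e-7)
  expect_equal(unname(fit$se), unname(sqrt(diag(vcov(ref)))),
               tolerance = 1e-7)
  expect_equal(fit$loglik, ref$loglik[2], tolerance = 1e-9)
  expect_equal(fit$aic, -2 * fit$loglik + 2 * length(coef(fit)))
})

test_that("a null model recovers hazard ratios near one", {
  set.seed(7)
  n <- 4000
  X <- cbind(x1 = rnorm(n), x2 = runif(n))
  t_ev <- rexp(n, 0.03)                       # no covariate effect
  time <- pmin(t_ev, 12); event <- as.integer(t_ev <= 12)
  fit <- fit_cox(time, event, X)
  expect_true(all(abs(coef(fit) / fit$se) < 4))
  expect_true(all(fit$hr$hr_lo < 1 & fit$hr$hr_hi > 1))
  expect_true(all(fit$hr$hr > 0))
  expect_true(all(fit$hr$hr_lo <= fit$hr$hr & fit$hr$hr <= fit$hr$hr_hi))
})

test_that("degenerate designs are rejected with diagnostics", {
  time <- c(1, 2, 3, 4, 5, 6)
  event <- c(1L, 0L, 0L, 0L, 0L, 0L)
  expect_error(fit_cox(time, event, matrix(1, 6, 1)), "constant")
  # the single event carries the only x = 1: monotone likelihood
  X <- matrix(c(1, 0, 0, 0, 0, 0), ncol = 1)
  expect_error(suppressWarnings(fit_cox(time, event, X)), "separation|converge")
  expect_error(fit_cox(c(-1, time[-1]), event, matrix(rnorm(6), 6, 1)),
               "positive")
})

test_that("formula comparison reports per-fifth HRs and delta AIC", {
  p <- cohort_params("F", n = 6000, seed = 51)
  co <- generate_mortality(generate_cohort(p), p)
  cmp <- suppressWarnings(suppressMessages(
    compare_formulas_survival(co, powers = c(old = 2, new = 1.4),
                              covariates = c("age", "townsend"))))
  expect_identical(nrow(cmp$hr_fifths), 10L)
  expect_equal(cmp$hr_fifths$hr[cmp$hr_fifths$fifth == 1], c(1, 1))
  expect_true(all(cmp$hr_fifths$hr > 0))
  expect_equal(cmp$delta_aic, unname(cmp$aic[2] - cmp$aic[1]))
  for (f in cmp$fits)
    expect_equal(f$aic, -2 * f$loglik + 2 * length(coef(f)))
  # identical formulas give delta AIC of exactly zero
  cmp0 <- suppressWarnings(suppressMessages(
    compare_formulas_survival(co, powers = c(old = 2, new = 2),
                              covariates = c("age", "townsend"))))
  expect_equal(cmp0$delta_aic, 0)
})
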