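#' Assign index fifths
#'
#' Cuts values into five equal-frequency ordinal groups at the empirical
#' 20/40/60/80 percentiles (linear-interpolation, type 7). A value exactly
#' equal to a cutpoint goes to the lower fifth. Rejects distributions whose
#' ties leave a fifth empty.
#'
#' @param x Numeric values, n >= 5.
#' @return Integer vector in 1..5.
#' @export
assign_fifths <- function(x) {
  if (length(x) < 5L) stop("need at least 5 values for fifths")
  if (any(!is.finite(x))) stop("non-finite values")
  q <- stats::quantile(x, c(0.2, 0.4, 0.6, 0.8), type = 7, names = FALSE)
  f <- 1L + (x > q[1L]) + (x > q[2L]) + (x > q[3L]) + (x > q[4L])
  if (length(unique(f)) < 5L)
    stop("heavy ties: at least one fifth is empty")
  f
}

# Efron (or Breslow) log partial likelihood with analytic gradient and
# observed information. Subjects sorted by time; the risk set at an event
# time t comprises everyone with time >= t.
cox_pl_core <- function(beta, time, event, X, ties = "efron") {
  n <- length(time)
  p <- ncol(X)
  ord <- order(time)
  time <- time[ord]; event <- event[ord]
  X <- X[ord, , drop = FALSE]
  eta <- drop(X %*% beta)
  eta <- eta - max(eta)                       # guard exp overflow
  w <- exp(eta)
  wX <- X * w
  pairs_i <- rep(seq_len(p), times = p)
  pairs_j <- rep(seq_len(p), each = p)
  wXX <- X[, pairs_i, drop = FALSE] * X[, pairs_j, drop = FALSE] * w

  revcum <- function(M) {
    M <- apply(M[n:1, , drop = FALSE], 2L, cumsum)
    M[n:1, , drop = FALSE]
  }
  S0 <- rev(cumsum(rev(w)))
  S1 <- revcum(wX)
  S2 <- revcum(wXX)

  starts <- which(c(TRUE, time[-1L] != time[-n]))
  grp <- cumsum(c(TRUE, time[-1L] != time[-n]))

  ll <- 0
  grad <- numeric(p)
  info <- matrix(0, p, p)
  ev_idx <- which(event == 1L)
  ev_by_grp <- split(ev_idx, grp[ev_idx])
  for (gname in names(ev_by_grp)) {
    gi <- as.integer(gname)
    rows <- ev_by_grp[[gname]]
    d <- length(rows)
    st <- starts[gi]
    s0 <- S0[st]; s1 <- S1[st, ]; s2 <- matrix(S2[st, ], p, p)
    if (ties == "efron" && d > 1L) {
      s0d <- sum(w[rows])
      s1d <- colSums(wX[rows, , drop = FALSE])
      s2d <- matrix(colSums(wXX[rows, , drop = FALSE]), p, p)
    } else {
      s0d <- 0; s1d <- numeric(p); s2d <- matrix(0, p, p)
    }
    ll <- ll + sum(eta[rows])
    grad <- grad + colSums(X[rows, , drop = FALSE])
    fr <- if (ties == "efron") (seq_len(d) - 1) / d else rep(0, d)
    for (l in seq_len(d)) {
      den <- s0 - fr[l] * s0d
      num1 <- s1 - fr[l] * s1d
      mu <- num1 / den
      ll <- ll - log(den)
      grad <- grad - mu
      info <- info + (s2 - fr[l] * s2d) / den - tcrossprod(mu)
    }
  }
  list(loglik = ll, gradient = grad, information = info)
}

#' Cox log partial likelihood and score vector
#'
#' Evaluates the Efron- (default) or Breslow-tie-corrected Cox log partial
#' likelihood, its gradient (score vector) and observed information at a
#' given coefficient vector. Exposed so the analytic score can be checked
#' against finite differences.
#'
#' @param beta Coefficient vector (length = ncol(X)).
#' @param time Follow-up times (> 0).
#' @param event Event indicator (0/1).
#' @param X Numeric design matrix.
#' @param ties `"efron"` or `"breslow"`; with no tied event times the two
#'   coincide.
#' @return A list with `loglik`, `gradient` and `information`.
#' @export
cox_partial_loglik <- function(beta, time, event, X,
                               ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  X <- as.matrix(X)
  stopifnot(length(beta) == ncol(X), length(time) == nrow(X),
            length(event) == nrow(X))
  cox_pl_core(as.numeric(beta), as.numeric(time), as.integer(event),
              X, ties)
}

#' Fit a Cox proportional-hazards model
#'
#' Maximizes the Efron-tie-corrected log partial likelihood by Newton
#' iteration with step-halving, to a gradient max-norm below `tol` scaled
#' by `max(1, |loglik|)` (the score components grow with the number of
#' subjects, so the tolerance is relative to the likelihood's magnitude).
#' Standard errors come from the inverse observed information; hazard
#' ratios are `exp(coef)` with Wald 95% confidence intervals
#' `exp(coef +/- 1.96 se)`.
#'
#' @inheritParams cox_partial_loglik
#' @param X Numeric design matrix with column names; no constant columns.
#' @param tol Convergence tolerance on the gradient max-norm.
#' @param max_iter Maximum Newton iterations (non-convergence is an error).
#' @return An object of class `benn_cox`: `coefficients`, `se`, `vcov`,
#'   `hr` (HR with CI per coefficient), `loglik`, `aic` (`-2 loglik + 2 *
#'   #coefficients`), `n`, `events`, `iterations`.
#' @export
fit_cox <- function(time, event, X, ties = c("efron", "breslow"),
                    tol = 1e-8, max_iter = 50L) {
  ties <- match.arg(ties)
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (is.null(colnames(X)))
    colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (any(!is.finite(X))) stop("non-finite values in design matrix")
  if (any(time <= 0)) stop("follow-up times must be positive")
  if (!all(event %in% c(0L, 1L))) stop("'event' must be 0/1")
  const <- apply(X, 2L, function(v) max(v) == min(v))
  if (any(const))
    stop("constant column(s) in design matrix: ",
         paste(colnames(X)[const], collapse = ", "))
  n <- nrow(X); p <- ncol(X); nev <- sum(event)
  if (nev == 0L) stop("no events in the data")
  if (nev < 10L * p)
    warning("fewer than 10 events per coefficient (", nev, " events, ",
            p, " coefficients); estimates may be unstable")

  beta <- numeric(p)
  cur <- cox_pl_core(beta, time, event, X, ties)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    if (iter > max_iter)
      stop("Cox fit did not converge in ", max_iter,
           " iterations (gradient max-norm ",
           format(max(abs(cur$gradient))), ")")
    step <- solve(cur$information, cur$gradient)
    # expected quadratic gain g'H^-1 g / 2; once it falls below the
    # double-precision resolution of the log likelihood, one last Newton
    # step squares the remaining coefficient error and we stop
    final <- sum(cur$gradient * step) / 2 <
      1e-10 * max(1, abs(cur$loglik))
    lambda <- 1
    repeat {
      cand <- beta + lambda * step
      nxt <- cox_pl_core(cand, time, event, X, ties)
      if (is.finite(nxt$loglik) &&
          nxt$loglik >= cur$loglik - 1e-9 * max(1, abs(cur$loglik))) break
      lambda <- lambda / 2
      if (lambda < 1e-10)
        stop("Cox fit: step-halving failed to improve the likelihood")
    }
    beta <- cand; cur <- nxt
    if (any(abs(beta) > 20))
      stop("separation detected: |coefficient| > 20")
    # gradient norm scaled by |loglik|: absolute 1e-8 is unattainable in
    # double precision once the likelihood involves thousands of subjects
    if (final || max(abs(cur$gradient)) < tol * max(1, abs(cur$loglik)))
      break
  }
  vc <- solve(cur$information)
  se <- sqrt(diag(vc))
  names(beta) <- names(se) <- colnames(X)
  hr <- data.frame(term = colnames(X), coef = beta, se = se,
                   hr = exp(beta),
                   hr_lo = exp(beta - 1.96 * se),
                   hr_hi = exp(beta + 1.96 * se),
                   row.names = NULL, stringsAsFactors = FALSE)
  structure(list(coefficients = beta, se = se, vcov = vc, hr = hr,
                 loglik = cur$loglik, aic = -2 * cur$loglik + 2 * p,
                 n = n, events = nev, iterations = iter, ties = ties),
            class = "benn_cox")
}

#' @export
print.benn_cox <- function(x, ...) {
  cat(sprintf("Cox proportional-hazards fit (%s ties): n = %d, events = %d\n",
              x$ties, x$n, x$events))
  cat(sprintf("  log partial likelihood = %.3f, AIC = %.1f\n",
              x$loglik, x$aic))
  y <- x$hr
  y[-1L] <- lapply(y[-1L], round, 4)
  print(y, row.names = FALSE)
  invisible(x)
}

#' @export
coef.benn_cox <- function(object, ...) object$coefficients

# expand the adjustment covariates into a numeric design matrix; categorical
# covariates are dummy-coded against their first level ("unknown" stays a
# level of its own). Factor levels containing no events would send their
# dummy coefficient to -Inf (monotone likelihood), so they are collapsed
# into the reference level with a message.
covariate_design <- function(cohort, covariates, event = NULL) {
  miss <- setdiff(covariates, names(cohort))
  if (length(miss))
    stop("missing covariate column(s): ", paste(miss, collapse = ", "))
  if (!length(covariates)) return(NULL)
  df <- cohort[covariates]
  for (v in names(df)) if (is.character(df[[v]])) df[[v]] <- factor(df[[v]])
  for (v in names(df)) {
    if (!is.factor(df[[v]])) next
    df[[v]] <- droplevels(df[[v]])
    if (!is.null(event) && nlevels(df[[v]]) > 1L) {
      ev_by <- tapply(event, df[[v]], sum)
      dead <- names(ev_by)[is.na(ev_by) | ev_by == 0]
      dead <- setdiff(dead, levels(df[[v]])[1L])
      if (length(dead)) {
        message("collapsing zero-event level(s) of '", v, "' into '",
                levels(df[[v]])[1L], "': ", paste(dead, collapse = ", "))
        lv <- levels(df[[v]])
        lv_map <- ifelse(lv %in% dead, lv[1L], lv)
        df[[v]] <- factor(lv_map[as.integer(df[[v]])],
                          levels = unique(lv_map))
      }
    }
  }
  mm <- stats::model.matrix(~ ., data = df)
  mm[, -1L, drop = FALSE]               # drop intercept
}

#' Compare index formulas as mortality predictors
#'
#' For each height exponent, categorizes the index into fifths (lowest
#' fifth as reference), fits a Cox model of all-cause mortality on the
#' fifth indicators plus the adjustment covariates, and reports per-fifth
#' hazard ratios with 95% CIs, the log partial likelihood and the AIC;
#' the AIC difference is second formula minus first.
#'
#' @param cohort A single-sex cohort with survival outcomes filled.
#' @param powers Named vector of height exponents, e.g.
#'   `c(old = 2, new = 1.39)`.
#' @param covariates Adjustment covariates (columns of `cohort`); default
#'   age, Townsend deprivation, education, smoking, alcohol and ethnicity.
#' @return A list of class `survival_comparison`: `fits` (one `benn_cox`
#'   per formula), `hr_fifths` (long data frame of per-fifth HRs; fifth 1
#'   is the reference with HR 1), `aic`, `delta_aic`.
#' @export
compare_formulas_survival <- function(cohort, powers = c(old = 2),
                                      covariates = c("age", "townsend",
                                                     "education", "smoking",
                                                     "alcohol", "ethnicity")) {
  if (is.null(names(powers)) || any(names(powers) == ""))
    stop("'powers' must be a named vector of exponents")
  if (anyNA(cohort$follow_time) || anyNA(cohort$event))
    stop("survival outcomes missing; run generate_mortality() or supply ",
         "follow_time/event")
  Z <- covariate_design(cohort, covariates, event = cohort$event)
  fits <- list()
  hr_rows <- list()
  for (f in names(powers)) {
    idx <- compute_index(cohort$weight, cohort$height, powers[[f]])
    fifth <- assign_fifths(idx)
    Ff <- stats::model.matrix(~ factor(fifth, levels = 1:5))[, -1L,
                                                             drop = FALSE]
    colnames(Ff) <- paste0("fifth", 2:5)
    X <- if (is.null(Z)) Ff else cbind(Ff, Z)
    fit <- fit_cox(cohort$follow_time, cohort$event, X)
    fits[[f]] <- fit
    hr_rows[[f]] <- data.frame(
      formula = f, fifth = 1:5,
      hr = c(1, fit$hr$hr[1:4]),
      hr_lo = c(NA, fit$hr$hr_lo[1:4]),
      hr_hi = c(NA, fit$hr$hr_hi[1:4]),
      stringsAsFactors = FALSE)
  }
  aic <- vapply(fits, function(f) f$aic, numeric(1L))
  delta <- if (length(aic) >= 2L) unname(aic[2L] - aic[1L]) else NA_real_
  structure(list(fits = fits, hr_fifths = do.call(rbind, hr_rows),
                 aic = aic, delta_aic = delta),
            class = "survival_comparison")
}

#' @export
print.survival_comparison <- function(x, ...) {
  cat("Cox comparison of index formulas (fifths, lowest = reference):\n")
  y <- x$hr_fifths
  y[c("hr", "hr_lo", "hr_hi")] <- lapply(y[c("hr", "hr_lo", "hr_hi")],
                                         round, 3)
  print(y, row.names = FALSE)
  cat("AIC:", paste(sprintf("%s = %.1f", names(x$aic), x$aic),
                    collapse = ", "), "\n")
  if (!is.na(x$delta_aic))
    cat(sprintf("delta AIC (second - first) = %.2f\n", x$delta_aic))
  invisible(x)
}
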