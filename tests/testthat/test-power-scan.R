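test_that("the default exponent grid has 10,001 uniformly spaced points", {
  g <- power_grid()
  expect_length(g$powers, 10001L)
  expect_equal(g$powers[1], -50)
  expect_equal(g$powers[10001], 50)
  expect_equal(unique(round(diff(g$powers), 12)), 0.01)
  expect_error(power_grid(0, 1, -0.1), "positive")
  expect_error(power_grid(3, 1, 0.1), "strictly less")
  expect_error(power_grid(0, 1, 0.3), "integer multiples")
})

test_that("the scan refuses mixed-sex cohorts and missing measures", {
  co <- mixed_cohort(50, 50, seed = 1)
  expect_error(scan_powers(derive_measures(co), grid = power_grid(0, 1, 0.5)),
               "single-sex")
  expect_error(scan_powers(tiny_cohort(50), grid = power_grid(0, 1, 0.5)),
               "derive_measures")
})

test_that("at p = 0 the index is weight and its weight-correlation is 1", {
  co <- derive_measures(tiny_cohort(400, seed = 2))
  cv <- scan_powers(co, grid = power_grid(-1, 1, 0.5))
  wr <- cv$curves[cv$curves$measure == "weight" & cv$curves$power == 0, ]
  expect_equal(wr$r, 1, tolerance = 1e-12)
  expect_equal(wr$ci_hi, 1)
})

test_that("curve values agree with direct partial correlations at p = 2", {
  co <- derive_measures(tiny_cohort(400, seed = 3))
  cv <- scan_powers(co, grid = power_grid(1, 3, 0.5))
  idx <- compute_index(co$weight, co$height, 2)
  for (m in cv$measures) {
    direct <- partial_corr(idx, co[[m]], co$age)
    row <- cv$curves[cv$curves$measure == m & cv$curves$power == 2, ]
    expect_equal(row$r, direct$r, tolerance = 1e-10)
    expect_equal(row$ci_lo, direct$ci_lo, tolerance = 1e-10)
    expect_equal(row$ci_hi, direct$ci_hi, tolerance = 1e-10)
  }
})

test_that("curves are invariant to a positive rescaling of the index", {
  co <- derive_measures(tiny_cohort(400, seed = 4))
  co2 <- co
  co2$weight <- co$weight * 7.3      # rescales index(p) by 7.3 at every p
  g <- power_grid(-2, 3, 0.25)
  c1 <- scan_powers(co, setdiff(MEASURES_ALL, "weight"), g)
  c2 <- scan_powers(co2, setdiff(MEASURES_ALL, "weight"), g)
  expect_equal(c1$curves$r, c2$curves$r, tolerance = 1e-12)
})

test_that("noise-free allometric cohorts recover p_true exactly", {
  for (pt in c(1.5, 2)) {
    p <- cohort_params("F", n = 800, seed = 6, weight_log_sd = 0,
                       age_weight_slope = 0, p_true = pt)
    co <- derive_measures(generate_cohort(p))
    cv <- scan_powers(co, grid = power_grid(-3, 4, 0.01))
    opt <- find_height_independent_power(cv)
    expect_equal(opt$p_opt, pt)
  }
})

test_that("the height curve falls strictly through its zero crossing", {
  co <- derive_measures(tiny_cohort(20000, seed = 7))
  cv <- scan_powers(co, measures = "height", grid = power_grid(0.5, 2.5, 0.01))
  opt <- find_height_independent_power(cv)
  r <- cv$curves$r
  pw <- cv$curves$power
  win <- which(abs(pw - opt$p_opt) <= 0.3)
  expect_true(all(diff(r[win]) < 0))
})

test_that("height-independency estimates track the ground truth", {
  p <- cohort_params("F", n = 20000, seed = 8, p_true = 1.5)
  co <- derive_measures(generate_cohort(p))
  cv <- scan_powers(co, measures = "height", grid = power_grid(1, 2, 0.01))
  opt <- find_height_independent_power(cv)
  expect_lt(abs(opt$p_opt - 1.5), 0.1)
})

test_that("fatness-criterion maxima match an exhaustive independent scan", {
  co <- derive_measures(tiny_cohort(500, seed = 9))
  g <- power_grid(-2, 3, 0.25)
  cv <- scan_powers(co, grid = g)
  for (m in c("bf_pct", "fat_mass", "whtr")) {
    opt <- find_max_corr_power(cv, m)
    # brute force through the residual-regression path
    rs <- sapply(g$powers, function(p)
      oracle_partial_corr(compute_index(co$weight, co$height, p),
                          co[[m]], co$age))
    expect_equal(opt$p_opt, g$powers[which.max(rs)])
  }
  expect_error(find_max_corr_power(cv, "nope"), "no curve")
})

test_that("criterion table has the report structure and argmax property", {
  co <- derive_measures(tiny_cohort(2000, seed = 10))
  tab <- build_criterion_table(co, grid = power_grid(-3, 4, 0.05))
  expect_identical(nrow(tab), 9L)
  rcols <- paste0("r_", MEASURES_ALL)
  expect_true(all(rcols %in% names(tab)))
  expect_identical(tab$criterion[1:2], c("conventional", "height"))
  expect_equal(tab$power[1], 2.00)
  # conventional row equals direct computation
  idx <- compute_index(co$weight, co$height, 2)
  expect_equal(tab$r_bf_pct[1], partial_corr(idx, co$bf_pct, co$age)$r,
               tolerance = 1e-10)
  # each fatness criterion's own correlation is the grid maximum
  for (m in MEASURES_FATNESS) {
    own <- tab[tab$criterion == m, paste0("r_", m)]
    expect_true(all(own >= tab[[paste0("r_", m)]] - 1e-12))
  }
})
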