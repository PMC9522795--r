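# Model families, selection and bootstrap validation.

test_that("adjusted R-squared follows the penalized formula", {
  expect_equal(adjusted_r2(0.5, 12, 1), 0.45)
  expect_equal(adjusted_r2(1.0, 50, 7), 1.0)
  expect_equal(adjusted_r2(0.0, 10, 2), 1 - 9 / 7)
  expect_error(adjusted_r2(0.5, 4, 3), "n > p")
  # strictly decreasing in p at fixed r2 < 1
  vals <- sapply(1:6, function(p) adjusted_r2(0.7, 30, p))
  expect_true(all(diff(vals) < 0))
})

test_that("OLS wrapper reproduces exact and null fits", {
  set.seed(11)
  X <- cbind(x1 = runif(200), x2 = runif(200))
  y <- 5 + 2 * X[, 1] - 3 * X[, 2]
  f <- fit_linear(y, X)
  expect_lt(max(abs(f$residuals)), 1e-10)
  expect_equal(f$fit_stats$r2, 1)
  expect_equal(unname(f$coefficients), c(5, 2, -3), tolerance = 1e-10)

  ynull <- rnorm(5000)
  Xn <- cbind(x1 = runif(5000))
  expect_lt(abs(fit_linear(ynull, Xn)$fit_stats$adj_r2), 0.01)

  expect_error(fit_linear(y, cbind(a = X[, 1], b = 2 * X[, 1])),
               "collinear columns: b")
})

test_that("mlr recovery: simulated coefficients land within 3 SE", {
  set.seed(21)
  n <- 1e4
  X <- cbind(x1 = rnorm(n), x2 = rnorm(n))
  y <- 5 + 2 * X[, 1] - 3 * X[, 2] + rnorm(n)
  f <- fit_linear(y, X)
  se <- (f$conf_int[, 2] - f$conf_int[, 1]) / (2 * qt(0.975, n - 3))
  expect_true(all(abs(f$coefficients - c(5, 2, -3)) < 3 * se))
})

test_that("sex-specific fitting recovers exact linear truth and checks inputs", {
  both <- rbind(make_linear_cohort(100, 1, "male"),
                make_linear_cohort(100, 2, "female", intercept = 35))
  mm <- lung_age_fit(both, "male", "mlr")
  mf <- lung_age_fit(both, "female", "mlr")
  expect_equal(unname(mm$intercept), 20, tolerance = 1e-7)
  expect_equal(unname(mf$intercept), 35, tolerance = 1e-7)
  expect_equal(unname(mm$linear_terms["fev1"]), -6, tolerance = 1e-8)
  expect_equal(unname(mm$linear_terms["fef75"]), -4, tolerance = 1e-8)
  expect_equal(mm$fit_stats$n, 100L)

  expect_error(lung_age_fit(both[both$sex == "male", ], "female"), "no records")
  d <- make_linear_cohort(80, 3)
  d$height <- 170
  expect_error(lung_age_fit(d, "male", "mlr"), "collinear")
  expect_error(lung_age_fit(both, "male", predictors = "fvc2"),
               "unknown linear predictors")
})

test_that("piecewise fit recovers a noiseless two-segment FEV1 effect", {
  set.seed(5)
  fev1 <- runif(400, 1, 5)
  age <- ifelse(fev1 <= 3, 10 + 2 * fev1, 10 + 2 * 3 - 5 * (fev1 - 3))
  d <- make_linear_cohort(400, 5)
  d$fev1 <- fev1; d$age <- age
  grid <- seq(1.5, 4.5, by = 0.05)
  m <- lung_age_fit(d, "male", "piecewise", predictors = character(0),
                    breakpoint_grid = grid)
  expect_equal(m$breakpoint_spec$breakpoint, 3.0, tolerance = 1e-9)
  expect_equal(m$breakpoint_spec$slope_left, 2, tolerance = 1e-6)
  expect_equal(m$breakpoint_spec$slope_right, -5, tolerance = 1e-6)
  # grid search equals brute force over the same grid
  rss_brute <- sapply(grid, function(b) {
    sum(lm.fit(cbind(1, fev1, pmax(fev1 - b, 0)), age)$residuals^2)
  })
  expect_equal(m$breakpoint_spec$breakpoint, grid[which.min(rss_brute)])
  # continuity at the breakpoint
  eps <- 1e-7
  nd <- d[1:2, ]; nd$fev1 <- c(3 - eps, 3 + eps)
  pr <- predict_quiet(m, nd)
  expect_lt(abs(diff(pr)), 1e-5)
  expect_error(lung_age_fit(d, "male", "piecewise", breakpoint_grid = c(0.2, 3)),
               "outside the observed FEV1 range")
})

test_that("piecewise slopes agree on single-slope truth", {
  d <- make_linear_cohort(300, 9)
  m <- lung_age_fit(d, "male", "piecewise")
  expect_equal(m$breakpoint_spec$slope_left, m$breakpoint_spec$slope_right,
               tolerance = 1e-5)
})

test_that("spline fit nests the linear fit (R2 monotonicity)", {
  h <- generate_healthy("healthy_modelling", 800, 31)
  ms <- lung_age_fit(h, "male", "spline")
  mm <- lung_age_fit(h, "male", "mlr")
  expect_gte(ms$fit_stats$r2, mm$fit_stats$r2)
  expect_identical(ms$predictors, c("height", "fef50", "fef75"))
  expect_identical(ncol(natural_spline_basis(1, ms$spline_spec$knots)), 4L)
})

test_that("selection picks the maximum adjusted R2 with deterministic ties", {
  h <- generate_healthy("healthy_modelling", 600, 32)
  sel <- lung_age_select(h, subsets = list(c("height", "fef50", "fef75"),
                                           "height"),
                         methods = c("mlr", "spline"), sexes = "male")
  expect_s3_class(sel, "lung_age_selection")
  expect_rows(sel$ranking, 4)
  best_adj <- max(sel$ranking$adj_r2, na.rm = TRUE)
  expect_equal(sel$best$male$fit_stats$adj_r2, best_adj)
  # failures are logged, not fatal
  h2 <- h; h2$fvc <- 1
  sel2 <- lung_age_select(h2, subsets = list("fvc", "height"),
                          methods = "mlr", sexes = "male")
  expect_true(any(!is.na(sel2$ranking$error)))
  expect_identical(sel2$best$male$predictors, "height")
})

test_that("bootstrap on noiseless data reproduces the primary fit; seeded runs repeat", {
  d <- make_linear_cohort(120, 8)
  m <- lung_age_fit(d, "male", "mlr")
  bt <- bootstrap_validate(m, d, B = 25, seed = 3)
  expect_identical(bt$skipped, 0L)
  expect_equal(bt$coefficient_summaries[, "sd"],
               setNames(rep(0, 5), names(m$coefficients)), tolerance = 1e-7)
  expect_equal(bt$coefficient_summaries[, "mean"], m$coefficients,
               tolerance = 1e-7)
  bt2 <- bootstrap_validate(m, d, B = 25, seed = 3)
  expect_identical(bt$replicates, bt2$replicates)
})

test_that("bootstrap means track the primary coefficients on noisy data", {
  d <- make_linear_cohort(400, 13, noise_sd = 8)
  m <- lung_age_fit(d, "male", "mlr")
  bt <- bootstrap_validate(m, d, B = 500, seed = 4)
  cs <- bt$coefficient_summaries
  expect_true(all(abs(cs[, "mean"] - m$coefficients) <= 2 * cs[, "sd"]))
})

test_that("coefficient recovery stays inside the 95% interval ~95% of the time", {
  true <- c(intercept = 20, fev1 = -6, height = 0.3, fef50 = 2, fef75 = -4)
  hits <- matrix(0L, 100, 5)
  for (r in 1:100) {
    d <- make_linear_cohort(400, 1000 + r, noise_sd = 8)
    m <- lung_age_fit(d, "male", "mlr")
    ci <- m$conf_int[c("(Intercept)", "fev1", "height", "fef50", "fef75"), ]
    hits[r, ] <- as.integer(true >= ci[, 1] & true <= ci[, 2])
  }
  expect_true(all(colSums(hits) >= 90))
})
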