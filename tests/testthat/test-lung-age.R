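# Lung-age prediction, delta computation, and the published equation.

test_that("published linear part evaluates by hand arithmetic (zero spline)", {
  ks <- list(boundary = c(1.5, 5.5), interior = c(2.5, 3.5, 4.5))
  m <- published_lung_age_model("male", spline_coefficients = rep(0, 4),
                                knots = ks)
  rec <- data.frame(id = "x", sex = "male", age = 50, height = 170,
                    fev1 = 3.81, fef50 = 4.83, fef75 = 1.91)
  expect_equal(unname(predict(m, rec)),
               2.25 + 0.49 * 170 + 3.47 * 4.83 - 8.92 * 1.91,
               tolerance = 1e-12)
  expect_equal(unname(predict(m, rec)), 85.27, tolerance = 1e-3)
})

test_that("published model loads the printed coefficients and guards the spline part", {
  ks <- list(boundary = c(1.5, 5.5), interior = c(3.0))
  f <- published_lung_age_model("female", spline_coefficients = c(1, 2),
                                knots = ks)
  expect_equal(unname(f$intercept), 28.49)
  expect_equal(unname(f$linear_terms["fef75"]), -12.52)
  expect_equal(unname(f$linear_terms["height"]), 0.36)
  m <- published_lung_age_model("male", spline_coefficients = c(1, 2), knots = ks)
  expect_equal(unname(m$intercept), 2.25)
  expect_equal(unname(m$linear_terms["fef50"]), 3.47)

  expect_error(published_lung_age_model("male"),
               "published spline coefficients required")
  expect_error(published_lung_age_model("male", spline_coefficients = c(1, 2, 3),
                                        knots = ks),
               "does not match the knot-implied basis dimension")
})

test_that("prediction on noiseless training data returns the true ages", {
  d <- make_linear_cohort(150, 17)
  m <- lung_age_fit(d, "male", "mlr")
  expect_equal(unname(predict(m, d)), d$age, tolerance = 1e-8)
})

test_that("prediction errors name missing predictors and mismatched sex", {
  d <- make_linear_cohort(60, 19)
  m <- lung_age_fit(d, "male", "spline")
  expect_error(predict(m, d[, setdiff(names(d), "fef75")]),
               "missing predictor column.*fef75")
  d2 <- d; d2$sex <- "female"
  expect_error(predict(m, d2), "sex mismatch")
  # out-of-range predictors warn but still predict
  d3 <- d[1, ]; d3$fev1 <- 0.4
  expect_warning(predict(m, d3), "outside the model's training range")
})

test_that("delta lung age is the exact difference and antisymmetric", {
  expect_identical(delta_lung_age(60, 50), 10)
  expect_identical(delta_lung_age(47.3, 47.3), 0)
  expect_identical(delta_lung_age(40, 50), -10)
  expect_error(delta_lung_age(NA, 50), "finite")
})

test_that("delta MSE is the mean of squared deltas", {
  expect_equal(delta_mse(c(3, -4)), 12.5)
  expect_identical(delta_mse(rep(0, 10)), 0)
  expect_error(delta_mse(numeric(0)), "non-empty")
  # zero on a model's own noiseless training data
  d <- make_linear_cohort(90, 23)
  m <- lung_age_fit(d, "male", "mlr")
  expect_lt(delta_mse(predict(m, d) - d$age), 1e-14)
})

test_that("increasing FEF75 under a negative coefficient lowers lung age", {
  d <- make_linear_cohort(200, 29)   # b_fef75 = -4 in the truth
  m <- lung_age_fit(d, "male", "mlr")
  expect_lt(unname(m$linear_terms["fef75"]), 0)
  r1 <- d[1, ]; r2 <- r1; r2$fef75 <- r1$fef75 + 0.5
  expect_lt(predict_quiet(m, r2), predict_quiet(m, r1))
})

test_that("delta_results ties the pipeline together consistently", {
  h <- generate_healthy("healthy_modelling", 500, 41)
  m <- lung_age_fit(h, "male", "spline")
  hm <- h[h$sex == "male", ]
  u <- uln_model(12.243, -0.323, 7.037)
  res <- delta_results(m, hm, uln = u)
  expect_rows(res, nrow(hm))
  expect_equal(res$delta, res$lung_age - hm$age)
  expect_equal(res$uln_at_age, uln_at_age(u, hm$age))
  expect_true(all(res$classification %in%
                    c("consistent", "older_within_uln", "above_uln")))
})
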