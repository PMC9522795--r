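# Upper limits of normal, classification, staging and exceedance tables.

test_that("published ULN formula arithmetic at ages 50, 18 and 80", {
  u <- uln_model(12.243, -0.323, 7.037)
  expect_equal(uln_at_age(u, 50), 12.243 - 0.323 * 50 + 1.645 * 7.037)
  expect_equal(uln_at_age(u, 50), 7.669, tolerance = 5e-4)
  expect_equal(uln_at_age(u, 18), 18.005, tolerance = 5e-4)
  expect_equal(uln_at_age(u, 80), -2.021, tolerance = 5e-4)
  # the MLR variant is representable too
  um <- uln_model(14.690, -0.392, 7.387)
  expect_equal(uln_at_age(um, 50), 14.690 - 0.392 * 50 + 1.645 * 7.387)
})

test_that("ULN is affine in age and the lower limit mirrors it", {
  u <- uln_model(10, -0.4, 5, z = 1.645)
  a1 <- runif(20, 18, 80); a2 <- runif(20, 18, 80)
  expect_equal(uln_at_age(u, a1) - uln_at_age(u, a2), -0.4 * (a1 - a2))
  expect_equal(uln_at_age(u, 40, limit = "lower"),
               10 - 0.4 * 40 - 1.645 * 5)
})

test_that("fitting the delta-on-age regression recovers degenerate cases", {
  ages <- seq(20, 70, length.out = 40)
  # deltas exactly on a line: RSE 0, ULN equals the line
  u <- uln_fit(5 - 0.2 * ages, ages)
  expect_equal(u$rse, 0, tolerance = 1e-10)
  expect_equal(uln_at_age(u, 44), 5 - 0.2 * 44, tolerance = 1e-8)
  # constant deltas: slope 0
  u2 <- uln_fit(rep(3, 40), ages)
  expect_equal(u2$age_slope, 0, tolerance = 1e-12)
  expect_equal(uln_at_age(u2, 60), 3, tolerance = 1e-8)
  expect_error(uln_fit(rnorm(40), rep(50, 40)), "constant")
  expect_error(uln_fit(1:5, 1:5), "at least 10")
})

test_that("ULN parameter recovery at the printed generating values", {
  d <- generate_delta_null(12.243, -0.323, 7.037, n = 1e5, seed = 77)
  fit <- lm(delta ~ age, data = d)
  se <- coef(summary(fit))[, "Std. Error"]
  u <- uln_fit(d$delta, d$age)
  expect_lt(abs(u$intercept - 12.243), 3 * se[1])
  expect_lt(abs(u$age_slope + 0.323), 3 * se[2])
  expect_lt(abs(u$rse - 7.037), 3 * 7.037 / sqrt(2 * nrow(d)))
})

test_that("constant ULN is the interpolated percentile and is monotone", {
  expect_equal(derive_constant_uln(1:100), 95.05)
  expect_equal(derive_constant_uln(rep(4.2, 30)), 4.2)
  expect_error(derive_constant_uln(numeric(0)), "non-empty")
  expect_error(derive_constant_uln(1:10, 1.2), "between 0 and 1")
  # adding a value above the current limit never lowers it
  set.seed(9)
  x <- rnorm(500)
  q0 <- derive_constant_uln(x)
  expect_gte(derive_constant_uln(c(x, q0 + 1)), q0)
})

test_that("classification partitions deltas with the boundary inside the ULN", {
  u <- uln_model(12.243, -0.323, 7.037)
  # stage-IV COPD mean delta at its mean age exceeds the printed ULN
  expect_identical(as.character(classify_delta(65.43, 63.79, u)), "above_uln")
  expect_identical(as.character(classify_delta(0, 40, u)), "consistent")
  lim <- uln_at_age(u, 55)
  expect_identical(as.character(classify_delta(lim, 55, u)), "older_within_uln")
  # constant mode needs the constant
  expect_error(classify_delta(5, 50, u, mode = "constant"), "constant_uln")
  u$constant_uln <- 12.5
  expect_identical(as.character(classify_delta(13, 50, u, mode = "constant")),
                   "above_uln")
  expect_identical(as.character(classify_delta(12.5, 50, u, mode = "constant")),
                   "older_within_uln")
  # every (delta, age) maps to exactly one label
  set.seed(2)
  cls <- classify_delta(rnorm(200, 0, 20), runif(200, 18, 80), u)
  expect_false(anyNA(cls))
})

test_that("airflow stages use half-open bands on percent predicted", {
  expect_identical(as.character(gold_stage(87.84)), "I")
  expect_identical(as.character(gold_stage(c(80, 79.99))), c("I", "II"))
  expect_identical(as.character(gold_stage(c(50, 49.99))), c("II", "III"))
  expect_identical(as.character(gold_stage(c(30, 29.9))), c("III", "IV"))
  expect_error(gold_stage(0), "positive")
  expect_error(gold_stage(-5), "positive")
  # partition: one stage per value
  expect_false(anyNA(gold_stage(runif(500, 5, 150))))
})

test_that("exceedance tables count cohorts against each ULN variant", {
  u <- uln_model(12.243, -0.323, 7.037)
  uc <- uln_model(12.243, -0.323, 7.037, constant_uln = 12.5)
  severe <- data.frame(cohort = "severe", delta = 60,
                       age = runif(50, 60, 70))
  tab <- exceedance_table(severe,
                          list(age_dep = list(uln = u, mode = "age_dependent"),
                               const = list(uln = uc, mode = "constant")))
  expect_equal(tab$pct[tab$variant == "age_dep"], 100.0)
  expect_equal(tab$n[1], 50L)
  # healthy draws from the derivation law leave about 5% above
  d <- generate_delta_null(12.243, -0.323, 7.037, n = 3000, seed = 5)
  htab <- exceedance_table(data.frame(cohort = "healthy", delta = d$delta,
                                      age = d$age),
                           list(age_dep = list(uln = u, mode = "age_dependent")))
  expect_gte(htab$pct, 3.5)
  expect_lte(htab$pct, 6.5)
  # an empty cohort (declared factor level without rows) warns and yields
  # a zero-count row
  severe2 <- severe
  severe2$cohort <- factor(severe2$cohort, levels = c("severe", "mild"))
  expect_warning(
    tab2 <- exceedance_table(severe2,
                             list(age_dep = list(uln = u, mode = "age_dependent"))),
    "empty cohort")
  expect_identical(tab2$n[tab2$cohort == "mild"], 0L)
  expect_true(is.na(tab2$pct[tab2$cohort == "mild"]))
})
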