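# Shared fixtures: all synthetic, built in code at test time.

# Records whose age is an exact linear function of the predictors
# (OLS oracle: any fitter must reproduce the coefficients exactly).
make_linear_cohort <- function(n = 120, seed = 42, sex = "male",
                               intercept = 20, b_fev1 = -6, b_height = 0.3,
                               b_fef50 = 2, b_fef75 = -4, noise_sd = 0) {
  set.seed(seed)
  fev1 <- runif(n, 1.5, 5.5)
  height <- runif(n, 150, 190)
  fef50 <- runif(n, 1, 7)
  fef75 <- runif(n, 0.3, 3)
  age <- intercept + b_fev1 * fev1 + b_height * height +
    b_fef50 * fef50 + b_fef75 * fef75 + rnorm(n, 0, noise_sd)
  fvc <- fev1 / runif(n, 0.7, 0.9)
  data.frame(id = sprintf("lin_%04d", seq_len(n)), sex = sex, age = age,
             height = height, weight = runif(n, 50, 90),
             fev1 = fev1, fvc = fvc, fev1_fvc = fev1 / fvc,
             fev1_pct_pred = runif(n, 85, 115),
             mmef = runif(n, 1, 6), fef50 = fef50, fef75 = fef75,
             nl_fev1 = TRUE, nl_fvc = TRUE, nl_ratio = TRUE,
             nl_mmef = TRUE, smoker = FALSE,
             stringsAsFactors = FALSE)
}

# predict() warns when patient records fall outside the healthy training
# range; that is expected behaviour in many tests.
predict_quiet <- function(...) suppressWarnings(predict(...))

expect_rows <- function(df, n) testthat::expect_identical(nrow(df), as.integer(n))
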