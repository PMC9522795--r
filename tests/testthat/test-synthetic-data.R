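# Calibration and structural invariants of the synthetic cohort generator.

test_that("built-in profiles exist for every emulated group and stage", {
  ps <- builtin_profiles()
  expect_true(all(c("healthy_modelling", "healthy_validation",
                    paste0("copd_stage_", c("I", "II", "III", "IV")),
                    paste0("asthma_stage_", c("I", "II", "III", "IV"))) %in%
                    names(ps)))
  expect_error(builtin_profiles("copd_stage_V"), "available")
  # headline calibration constants
  expect_equal(ps$healthy_modelling$targets$fev1, c(3.81, 0.63))
  expect_equal(ps$copd_stage_IV$targets$fev1_pct_pred, c(24.26, 3.89))
  # stage bands agree with the staging rule
  for (nm in grep("stage", names(ps), value = TRUE)) {
    p <- ps[[nm]]
    mid <- mean(c(p$band[1], min(p$band[2], 120)))
    expect_identical(as.character(gold_stage(mid)), p$stage)
  }
})

test_that("cohort means converge to the printed calibration targets", {
  n <- 1e4
  ps <- builtin_profiles()
  for (nm in names(ps)) {
    p <- ps[[nm]]
    d <- if (p$kind == "healthy") generate_healthy(p, n, seed = 101)
         else generate_patients(p$disease, p$stage, n, seed = 101)
    for (q in p$calibrated) {
      tg <- p$targets[[q]]
      expect_lt(abs(mean(d[[q]]) - tg[1]), 3 * tg[2] / sqrt(n),
                label = sprintf("|mean(%s) - %.3g| for %s", q, tg[1], nm))
    }
  }
})

test_that("records satisfy their structural invariants", {
  for (gen in list(generate_healthy("healthy_modelling", 2000, 3),
                   generate_patients("copd", "IV", 2000, 3),
                   generate_patients("asthma", "IV", 2000, 3))) {
    expect_true(all(gen$fev1 > 0 & gen$fev1 <= gen$fvc))
    expect_true(all(abs(gen$fev1 / gen$fvc - gen$fev1_fvc) < 1e-12))
    expect_true(all(gen$fev1_fvc <= 1))
    expect_true(all(gen$age >= 18 & gen$age <= 80))
    expect_true(all(gen$fef50 > gen$fef75))
    expect_true(all(gen$mmef > 0 & gen$fef50 > 0 & gen$fef75 > 0))
    expect_true(all(gen$height > 120 & gen$height < 210))
    expect_false(anyDuplicated(gen$id) > 0)
  }
})

test_that("identical seeds give identical cohorts; generation preserves RNG state", {
  a <- generate_healthy("healthy_modelling", 300, 99)
  set.seed(123); before <- runif(1)
  b <- generate_healthy("healthy_modelling", 300, 99)
  set.seed(123); after <- runif(1)
  expect_identical(a, b)
  expect_identical(before, after)
  c1 <- generate_patients("asthma", "II", 100, 7)
  c2 <- generate_patients("asthma", "II", 100, 7)
  expect_identical(c1, c2)
})

test_that("patient percent predicted stays in band with the printed stage mean", {
  d <- generate_patients("copd", "IV", 1000, 55)
  expect_true(all(d$fev1_pct_pred < 30))
  expect_lt(abs(mean(d$fev1_pct_pred) - 24.26), 2 * 3.89 / sqrt(1000))
  means <- sapply(c("I", "II", "III", "IV"), function(st)
    mean(generate_patients("copd", st, 400, 56)$fev1_pct_pred))
  expect_true(all(diff(means) < 0))
})

test_that("delta-null generator reproduces its generating law", {
  d0 <- generate_delta_null(5, -0.1, 0, n = 50, seed = 1)
  expect_equal(d0$delta, 5 - 0.1 * d0$age, tolerance = 1e-12)
  d1 <- generate_delta_null(5, -0.1, 2, n = 50, seed = 8)
  d2 <- generate_delta_null(5, -0.1, 2, n = 50, seed = 8)
  expect_identical(d1, d2)
  expect_error(generate_delta_null(n = 5, seed = 1), "n must be >= 10")
})

test_that("staged patient cohorts show strictly increasing mean delta lung age", {
  h <- generate_healthy("healthy_modelling", 2931, 201)
  models <- list(male = lung_age_fit(h, "male", "spline"),
                 female = lung_age_fit(h, "female", "spline"))
  mean_delta <- sapply(c("I", "II", "III", "IV"), function(st) {
    d <- generate_patients("copd", st, 300, 202)
    la <- rep(NA_real_, nrow(d))
    for (s in c("male", "female")) {
      idx <- d$sex == s
      la[idx] <- predict_quiet(models[[s]], d[idx, ])
    }
    mean(la - d$age)
  })
  expect_true(all(diff(mean_delta) > 0))
})
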