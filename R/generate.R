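# Seeded synthetic cohort generation from calibrated profiles.

resolve_profile <- function(profile) {
  if (inherits(profile, "generator_profile")) return(profile)
  if (is.character(profile) && length(profile) == 1L)
    return(builtin_profiles(profile)[[1]])
  stop("`profile` must be a profile name or a generator_profile object")
}

# Core sampler shared by the healthy and patient generators.  All
# marginals are quantile transforms of exactly standard-normal latents
# (Gaussian copula), so calibrated cohort means are exact in expectation;
# see the methods vignette for the construction.
generate_cohort <- function(profile, n, seed) {
  p <- resolve_profile(profile)
  if (n < 1L) stop("n must be >= 1")
  with_preserved_seed(seed, {
    male <- stats::runif(n) < p$p_male
    age <- tn_quantile(stats::runif(n), p$age$mu, p$age$sigma, p$age$lo, p$age$hi)
    hz <- stats::rnorm(n)
    height <- ifelse(male, p$height$mu_male, p$height$mu_female) +
      p$height$sigma_within * hz

    # youth score: gaussianized quadratic age severity (peak in the 20s)
    sq <- sqrt((age - GENERATOR_STRUCTURE$age_peak)^2)
    FA <- tn_cdf(GENERATOR_STRUCTURE$age_peak + sq, p$age$mu, p$age$sigma,
                 p$age$lo, p$age$hi) -
          tn_cdf(GENERATOR_STRUCTURE$age_peak - sq, p$age$mu, p$age$sigma,
                 p$age$lo, p$age$hi)
    A <- stats::qnorm(pmin(pmax(1 - FA, 1e-12), 1 - 1e-12))
    w <- p$latent
    L <- w[["wa"]] * A + w[["wh"]] * hz + w[["we"]] * stats::rnorm(n)
    mix <- function(rho) rho * L + sqrt(1 - rho^2) * stats::rnorm(n)

    t <- p$targets
    z_v <- mix(p$rho[["fvc"]])
    eta_v <- (z_v - p$rho[["fvc"]] * L) / sqrt(1 - p$rho[["fvc"]]^2)
    cc <- p$fv_corr$corr
    b <- (cc - p$rho[["fev1"]] * p$rho[["fvc"]]) / sqrt(1 - p$rho[["fvc"]]^2)
    ce <- sqrt(max(1 - p$rho[["fev1"]]^2 - b^2, 0))
    z_f <- p$rho[["fev1"]] * L + b * eta_v + ce * stats::rnorm(n)
    fvc <- pmax(t$fvc[1] + t$fvc[2] * z_v, 0.3)
    fev1 <- pmax(t$fev1[1] + t$fev1[2] * z_f, 0.05)
    fev1 <- pmin(fev1, 0.99 * fvc)

    gshape <- function(m, s) (m / s)^2
    qgam <- function(z, m, s) {
      k <- gshape(m, s)
      stats::qgamma(pmin(pmax(stats::pnorm(z), 1e-12), 1 - 1e-12),
                    shape = k, rate = k / m)
    }
    fef50 <- qgam(mix(p$rho[["fef50"]]), t$fef50[1], t$fef50[2])
    mmef <- qgam(mix(p$rho[["mmef"]]), t$mmef[1], t$mmef[2])
    r75 <- tn_quantile(stats::pnorm(stats::rnorm(n)), p$fef_ratio$mu,
                       p$fef_ratio$sigma, p$fef_ratio$lo, p$fef_ratio$hi)
    fef75 <- fef50 * r75

    pct <- if (p$kind == "patient") {
      tn_quantile(stats::pnorm(mix(p$rho[["pct"]])), p$pct_tn$mu,
                  p$pct_tn$sigma, p$pct_tn$lo, p$pct_tn$hi)
    } else {
      t$fev1_pct_pred[1] + t$fev1_pct_pred[2] * mix(p$rho[["pct"]])
    }

    bmi <- tn_quantile(stats::pnorm(stats::rnorm(n)), p$bmi$mu, p$bmi$sigma,
                       p$bmi$lo, p$bmi$hi)
    weight <- bmi * (height / 100)^2

    healthy <- p$kind == "healthy"
    out <- data.frame(
      id = sprintf("%s_%05d", p$label, seq_len(n)),
      sex = ifelse(male, "male", "female"),
      age = age, height = height, weight = weight,
      fev1 = fev1, fvc = fvc, fev1_fvc = fev1 / fvc,
      fev1_pct_pred = pct,
      mmef = mmef, fef50 = fef50, fef75 = fef75,
      nl_fev1 = healthy, nl_fvc = healthy, nl_ratio = healthy,
      nl_mmef = healthy, smoker = FALSE,
      stringsAsFactors = FALSE
    )
    attr(out, "profile") <- p$label
    attr(out, "seed") <- seed
    out
  })
}

#' Generate a synthetic healthy spirometry cohort
#'
#' Draws records from a healthy generator profile: truncated-normal age
#' on the profile's age window, sex-specific normal heights, and
#' spirometric indices tied to a latent lung-function level that declines
#' nonlinearly with age (quadratic severity peaking in the mid-20s).
#' Cohort means of the calibrated quantities converge to the profile
#' targets as n grows; identical seeds give identical cohorts.
#'
#' @param profile Profile name (e.g. `"healthy_modelling"`,
#'   `"healthy_validation"`) or a `generator_profile`.
#' @param n Number of records.
#' @param seed Integer seed.
#' @return Data frame of spirometry records with normal-limit flags set
#'   TRUE and `smoker` FALSE.
#' @export
generate_healthy <- function(profile = "healthy_modelling", n, seed) {
  p <- resolve_profile(profile)
  if (p$kind != "healthy")
    stop("profile '", p$label, "' is a patient profile; use generate_patients()")
  generate_cohort(p, n, seed)
}

#' Generate a synthetic staged patient cohort
#'
#' Draws COPD or asthma records whose FEV1 percent predicted is confined
#' to the requested airflow-limitation stage band (truncated normal at
#' the profile's stage mean/SD) and whose flows are depressed relative to
#' healthy cohorts per the stage profile.
#'
#' @param disease `"copd"` or `"asthma"`.
#' @param stage `"I"`, `"II"`, `"III"` or `"IV"`.
#' @param n Number of records.
#' @param seed Integer seed.
#' @param profile Optional `generator_profile` overriding the built-in
#'   `<disease>_stage_<stage>` profile.
#' @return Data frame of spirometry records (normal-limit flags FALSE).
#' @export
generate_patients <- function(disease = c("copd", "asthma"),
                              stage = c("I", "II", "III", "IV"),
                              n, seed, profile = NULL) {
  disease <- match.arg(disease)
  stage <- match.arg(stage)
  p <- if (is.null(profile)) {
    builtin_profiles(paste0(disease, "_stage_", stage))[[1]]
  } else resolve_profile(profile)
  if (p$kind != "patient")
    stop("profile '", p$label, "' is not a patient profile")
  generate_cohort(p, n, seed)
}

#' Simulate delta lung ages from a known delta-on-age law
#'
#' Generating truth for ULN parameter-recovery studies: ages are drawn
#' from a truncated-normal distribution and deltas as
#' `intercept + slope * age + N(0, rse^2)`.
#'
#' @param intercept,slope,rse Coefficients and residual SD of the
#'   generating rule (years, years/year, years).
#' @param age_distribution Either a profile name (its age distribution is
#'   used) or a list with `mean`, `sd`, `lo`, `hi`.
#' @param n Number of subjects (>= 10).
#' @param seed Integer seed.
#' @return Data frame with columns `age` and `delta`.
#' @export
generate_delta_null <- function(intercept = 12.243, slope = -0.323,
                                rse = 7.037,
                                age_distribution = "healthy_modelling",
                                n, seed) {
  if (n < 10L) stop("n must be >= 10")
  ad <- if (is.character(age_distribution)) {
    resolve_profile(age_distribution)$age
  } else {
    s <- tn_solve_robust(age_distribution$mean, age_distribution$sd,
                         age_distribution$lo, age_distribution$hi)
    list(mu = s$mu, sigma = s$sigma, lo = age_distribution$lo,
         hi = age_distribution$hi)
  }
  with_preserved_seed(seed, {
    age <- tn_quantile(stats::runif(n), ad$mu, ad$sigma, ad$lo, ad$hi)
    delta <- intercept + slope * age + stats::rnorm(n, 0, rse)
    data.frame(age = age, delta = delta)
  })
}
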