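# Normal limits of delta lung age, classification and airflow staging.

#' Derive the age-dependent upper limit of normal of delta lung age
#'
#' Regresses delta lung age on chronological age in healthy subjects
#' (sexes pooled) and defines ULN(age) = fitted(age) + z * RSE with a
#' one-sided 95% multiplier z = 1.645 by default.  The symmetric lower
#' limit fitted(age) - z * RSE is available from the same object but is
#' not applied by default, the clinical interest being in older lung ages.
#'
#' @param deltas Delta lung ages (years) of healthy subjects.
#' @param ages Matching chronological ages (years).
#' @param z One-sided normal multiplier (default 1.645).
#' @return An object of class `uln_model` with fields `intercept`,
#'   `age_slope`, `rse`, `z`, `n` and (optionally, via
#'   [derive_constant_uln()]) `constant_uln`.
#' @examples
#' u <- uln_fit(c(5, 2, -1, 0, 3, -2, 1, 4, -3, 2),
#'              c(20, 30, 40, 50, 60, 70, 35, 45, 55, 65))
#' uln_at_age(u, 50)
#' @export
uln_fit <- function(deltas, ages, z = 1.645) {
  if (length(deltas) != length(ages)) stop("deltas and ages must be paired")
  if (length(deltas) < 10L) stop("need at least 10 paired observations")
  if (z <= 0) stop("z must be positive")
  if (stats::sd(ages) == 0) stop("ages are constant; cannot regress delta on age")
  fit <- stats::lm(deltas ~ ages)
  out <- list(
    intercept = unname(stats::coef(fit)[1]),
    age_slope = unname(stats::coef(fit)[2]),
    rse = summary(fit)$sigma,
    z = z,
    n = length(deltas),
    constant_uln = NULL,
    source_label = "fitted"
  )
  class(out) <- "uln_model"
  out
}

#' Construct a ULN model from published coefficients
#'
#' @param intercept,age_slope,rse Regression coefficients and residual
#'   standard error of the delta-on-age model (years, years/year, years).
#' @param z One-sided normal multiplier.
#' @param constant_uln Optional constant (percentile-based) ULN in years.
#' @param source_label Free-text provenance label.
#' @return An object of class `uln_model`.
#' @examples
#' # the published spline-method rule: ULN(age) = 12.243 - 0.323*age + 1.645*7.037
#' u <- uln_model(12.243, -0.323, 7.037)
#' uln_at_age(u, 50)
#' @export
uln_model <- function(intercept, age_slope, rse, z = 1.645,
                      constant_uln = NULL, source_label = "supplied") {
  if (rse < 0) stop("rse must be >= 0")
  if (z <= 0) stop("z must be positive")
  out <- list(intercept = intercept, age_slope = age_slope, rse = rse,
              z = z, n = NA_integer_, constant_uln = constant_uln,
              source_label = source_label)
  class(out) <- "uln_model"
  out
}

#' @export
print.uln_model <- function(x, ...) {
  cat("ULN of delta lung age: ", fmt_num(x$intercept, 5), " ",
      ifelse(x$age_slope < 0, "- ", "+ "), fmt_num(abs(x$age_slope), 5),
      " * age + ", fmt_num(x$z, 4), " * ", fmt_num(x$rse, 5),
      " (", x$source_label, ")\n", sep = "")
  if (!is.null(x$constant_uln))
    cat("  constant ULN: ", fmt_num(x$constant_uln, 4), " years\n", sep = "")
  invisible(x)
}

#' Evaluate the age-dependent ULN at given ages
#'
#' @param uln A `uln_model`.
#' @param age Ages in years (vectorized).
#' @param limit `"upper"` (default) or `"lower"`; the lower limit uses
#'   `fit - z * rse` and is provided for completeness.
#' @return ULN (or LLN) in years; negative values are legal output and
#'   are reported as-is (the published rule crosses zero near age 74).
#' @export
uln_at_age <- function(uln, age, limit = c("upper", "lower")) {
  limit <- match.arg(limit)
  stopifnot(inherits(uln, "uln_model"))
  if (any(!is.finite(age))) stop("age must be finite")
  s <- if (limit == "upper") 1 else -1
  uln$intercept + uln$age_slope * age + s * uln$z * uln$rse
}

#' Constant (percentile) upper limit of normal
#'
#' The requested percentile of healthy-subject delta lung ages, by linear
#' interpolation between order statistics (the default 95th percentile
#' mirrors the one-sided 95% convention of the age-dependent rule).
#'
#' @param deltas Delta lung ages (years) of healthy subjects.
#' @param percentile Probability strictly between 0 and 1 (default 0.95).
#' @return The percentile, in years.
#' @export
derive_constant_uln <- function(deltas, percentile = 0.95) {
  if (length(deltas) == 0L) stop("`deltas` must be non-empty")
  if (percentile <= 0 || percentile >= 1)
    stop("percentile must be strictly between 0 and 1")
  unname(stats::quantile(deltas, percentile, type = 7))
}

#' Classify a delta lung age against the ULN
#'
#' Three-way rule: `consistent` when delta <= 0 (lung age at or below the
#' chronological age), `older_within_uln` when 0 < delta <= ULN (the lung
#' age, not the chronological age, should then be quoted so the subject is
#' aware of the lower-than-average function), and `above_uln` when
#' delta > ULN.  A delta exactly equal to the ULN is classified as within.
#'
#' @param delta Delta lung ages (years), vectorized.
#' @param age Chronological ages (years), used by the age-dependent rule.
#' @param uln A `uln_model`; for `mode = "constant"` it must carry a
#'   `constant_uln` value.
#' @param mode `"age_dependent"` or `"constant"`.
#' @return Factor with levels `consistent`, `older_within_uln`,
#'   `above_uln`.
#' @export
classify_delta <- function(delta, age, uln,
                           mode = c("age_dependent", "constant")) {
  mode <- match.arg(mode)
  stopifnot(inherits(uln, "uln_model"))
  lim <- if (mode == "age_dependent") {
    uln_at_age(uln, age)
  } else {
    if (is.null(uln$constant_uln))
      stop("constant-mode classification needs `constant_uln` ",
           "(see derive_constant_uln)")
    rep(uln$constant_uln, length(delta))
  }
  lab <- ifelse(delta <= 0, "consistent",
                ifelse(delta <= lim, "older_within_uln", "above_uln"))
  factor(lab, levels = c("consistent", "older_within_uln", "above_uln"))
}

#' GOLD-style airflow-limitation stage
#'
#' Stages on FEV1 percent predicted with half-open bands: stage I
#' `[80, Inf)`, II `[50, 80)`, III `[30, 50)`, IV `(0, 30)`.  The stage-IV
#' band is below 30% predicted, the GOLD convention.
#'
#' @param fev1_pct_pred FEV1 as a percentage of the predicted value
#'   (strictly positive), vectorized.
#' @return Factor with levels `I`, `II`, `III`, `IV`.
#' @export
gold_stage <- function(fev1_pct_pred) {
  if (any(!is.finite(fev1_pct_pred)) || any(fev1_pct_pred <= 0))
    stop("FEV1 percent predicted must be finite and positive")
  lab <- cut(fev1_pct_pred, breaks = c(0, 30, 50, 80, Inf),
             labels = c("IV", "III", "II", "I"), right = FALSE)
  factor(as.character(lab), levels = c("I", "II", "III", "IV"))
}

#' Exceedance summary over ULN variants
#'
#' For labelled cohorts of (delta, age) pairs and a list of ULN variants,
#' counts the subjects whose delta lung age exceeds each variant's limit
#' and reports percentages to one decimal.
#'
#' @param cohorts Data frame with columns `cohort`, `delta`, `age`.
#' @param uln_variants Named list; each element is a list with elements
#'   `uln` (a `uln_model`) and `mode` (`"age_dependent"` or `"constant"`).
#' @return Data frame with columns `cohort`, `variant`, `n_over`, `n`,
#'   `pct`.
#' @export
exceedance_table <- function(cohorts, uln_variants) {
  check_record_columns(cohorts, c("cohort", "delta", "age"))
  if (is.null(names(uln_variants)) || any(names(uln_variants) == ""))
    stop("`uln_variants` must be a named list")
  labels <- if (is.factor(cohorts$cohort)) levels(cohorts$cohort)
            else unique(cohorts$cohort)
  rows <- list()
  for (lab in labels) {
    g <- cohorts[cohorts$cohort == lab, , drop = FALSE]
    if (nrow(g) == 0L) warning("empty cohort: ", lab)
    for (vn in names(uln_variants)) {
      v <- uln_variants[[vn]]
      if (nrow(g)) {
        cls <- classify_delta(g$delta, g$age, v$uln, mode = v$mode)
        over <- sum(cls == "above_uln")
        pct <- round(100 * over / nrow(g), 1)
      } else {
        over <- 0L; pct <- NA_real_
      }
      rows[[paste(lab, vn)]] <- data.frame(
        cohort = lab, variant = vn, n_over = over, n = nrow(g), pct = pct,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(cohort = character(0), variant = character(0),
                      n_over = integer(0), n = integer(0), pct = numeric(0)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
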