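# Delta lung age and the published backward-age equation.

#' Difference between lung age and chronological age
#'
#' A 50-year-old with a lung age of 60 has a delta lung age of +10 years;
#' positive values indicate lung function below the healthy average for
#' that age.
#'
#' @param lung_age Estimated lung age (years).
#' @param age Chronological age (years).
#' @return `lung_age - age` (years), vectorized.
#' @export
delta_lung_age <- function(lung_age, age) {
  if (any(!is.finite(lung_age)) || any(!is.finite(age)))
    stop("lung_age and age must be finite")
  lung_age - age
}

#' Mean squared delta lung age
#'
#' The external-validation error measure: the mean of squared differences
#' between lung age and chronological age over a cohort.
#'
#' @param deltas Numeric vector of delta lung ages (years).
#' @return Mean of squared deltas (years squared).
#' @export
delta_mse <- function(deltas) {
  if (length(deltas) == 0L) stop("`deltas` must be non-empty")
  mean(deltas^2)
}

# Published linear coefficients of the final sex-specific equations
# (spline method; the spline part is distributed separately and must be
# supplied by the user).
PUBLISHED_COEF <- list(
  male   = c(intercept = 2.25,  height = 0.49, fef50 = 3.47,  fef75 = -8.92),
  female = c(intercept = 28.49, height = 0.36, fef50 = 4.45,  fef75 = -12.52)
)
PUBLISHED_STATS <- list(
  male   = list(adj_r2 = 0.660, rse = 8.693),
  female = list(adj_r2 = 0.689, rse = 8.544)
)

#' Load the published lung-age equation
#'
#' Builds a `lung_age_model` carrying the published sex-specific linear
#' coefficients (height, FEF50, FEF75 and intercept) together with a
#' user-supplied natural-spline FEV1 part.  The spline coefficients and
#' knots are distributed as supplementary material to the source
#' publication and are not bundled here; without them the model refuses
#' to predict rather than silently dropping the FEV1 term.
#'
#' @param sex `"male"` or `"female"`.
#' @param spline_coefficients Numeric vector of natural-spline
#'   coefficients for the FEV1 term; its length must equal
#'   `length(knots$interior) + 1`.
#' @param knots An `ns_knots` object (or list with `boundary` and
#'   `interior`) describing the published spline knots.
#' @return A `lung_age_model` with `source = "published"`.
#' @export
published_lung_age_model <- function(sex, spline_coefficients = NULL,
                                     knots = NULL) {
  sex <- match.arg(sex, c("male", "female"))
  if (is.null(spline_coefficients) || is.null(knots))
    stop("published spline coefficients required: supply both `knots` and ",
         "`spline_coefficients` (supplementary spline specification); ",
         "refusing to predict from the linear part alone")
  if (!inherits(knots, "ns_knots")) {
    knots <- structure(list(boundary = as.numeric(knots$boundary),
                            interior = as.numeric(knots$interior)),
                       class = "ns_knots")
  }
  validate_ns_knots(knots)
  k <- length(knots$interior) + 1L
  if (length(spline_coefficients) != k)
    stop("spline coefficient count (", length(spline_coefficients),
         ") does not match the knot-implied basis dimension (", k, ")")
  pub <- PUBLISHED_COEF[[sex]]
  spl <- as.numeric(spline_coefficients)
  names(spl) <- paste0("ns", seq_len(k))
  coefficients <- c("(Intercept)" = unname(pub["intercept"]),
                    spl,
                    height = unname(pub["height"]),
                    fef50 = unname(pub["fef50"]),
                    fef75 = unname(pub["fef75"]))
  out <- list(
    sex = sex,
    method = "spline",
    intercept = unname(pub["intercept"]),
    linear_terms = pub[c("height", "fef50", "fef75")],
    predictors = c("height", "fef50", "fef75"),
    spline_spec = list(knots = knots, coefficients = spl),
    breakpoint_spec = NULL,
    fit_stats = NULL,
    reference_stats = PUBLISHED_STATS[[sex]],
    conf_int = NULL,
    coefficients = coefficients,
    training_ranges = NULL,
    source = "published"
  )
  class(out) <- "lung_age_model"
  out
}

#' Per-subject lung age, delta and optional classification
#'
#' Applies a lung-age model to records of the matching sex, computes the
#' delta lung age, and (when a ULN model is supplied) the upper limit of
#' normal at each age and the three-way classification label.
#'
#' @param model A `lung_age_model`.
#' @param records Spirometry records (must include `id` and `age`).
#' @param uln Optional `uln_model` for classification.
#' @param mode `"age_dependent"` or `"constant"` ULN rule.
#' @param model_id Label recorded in the output.
#' @return Data frame with columns `id`, `lung_age`, `delta`,
#'   `uln_at_age`, `classification`, `model_id`.
#' @export
delta_results <- function(model, records, uln = NULL,
                          mode = c("age_dependent", "constant"),
                          model_id = paste0(model$method, "_", model$sex)) {
  mode <- match.arg(mode)
  check_record_columns(records, c("id", "age"))
  la <- predict(model, records)
  delta <- delta_lung_age(la, records$age)
  out <- data.frame(id = records$id, lung_age = la, delta = delta,
                    uln_at_age = NA_real_, classification = NA_character_,
                    model_id = model_id, stringsAsFactors = FALSE)
  if (!is.null(uln)) {
    out$uln_at_age <- uln_at_age(uln, records$age)
    out$classification <- as.character(
      classify_delta(delta, records$age, uln, mode = mode))
  }
  out
}
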