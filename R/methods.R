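# S3 methods for lung_age_model objects.

#' @export
print.lung_age_model <- function(x, ...) {
  cat("Lung-age model (", x$method, ", ", x$sex, ")\n", sep = "")
  if (x$source == "published")
    cat("  published backward-age equation (user-supplied spline part)\n")
  cat("  intercept: ", fmt_num(x$intercept, 4), "\n", sep = "")
  if (length(x$linear_terms)) {
    cat("  linear terms:\n")
    for (nm in names(x$linear_terms))
      cat("    ", nm, ": ", fmt_num(x$linear_terms[[nm]], 4), "\n", sep = "")
  }
  if (!is.null(x$spline_spec)) {
    cat("  FEV1 spline: ", length(x$spline_spec$knots$interior),
        " interior knot(s), boundary [",
        fmt_num(x$spline_spec$knots$boundary[1], 4), ", ",
        fmt_num(x$spline_spec$knots$boundary[2], 4), "] L\n", sep = "")
  }
  if (!is.null(x$breakpoint_spec)) {
    cat("  FEV1 breakpoint: ", fmt_num(x$breakpoint_spec$breakpoint, 4),
        " L (slopes ", fmt_num(x$breakpoint_spec$slope_left, 4), " / ",
        fmt_num(x$breakpoint_spec$slope_right, 4), " y per L)\n", sep = "")
  }
  if (!is.null(x$fit_stats))
    cat("  fit: n = ", x$fit_stats$n, ", adj R2 = ",
        fmt_num(x$fit_stats$adj_r2, 4), ", RSE = ",
        fmt_num(x$fit_stats$rse, 4), " y\n", sep = "")
  invisible(x)
}

#' @export
summary.lung_age_model <- function(object, ...) {
  print(object)
  if (!is.null(object$conf_int)) {
    cat("\nCoefficients (95% CI):\n")
    ci <- object$conf_int
    for (nm in names(object$coefficients))
      cat(sprintf("  %-12s %9.4g  (%.4g, %.4g)\n", nm,
                  object$coefficients[[nm]], ci[nm, 1], ci[nm, 2]))
  }
  invisible(object)
}

#' @export
coef.lung_age_model <- function(object, ...) object$coefficients

#' @export
residuals.lung_age_model <- function(object, ...) {
  if (is.null(object$fit_residuals))
    stop("residuals are only available for freshly fitted models")
  object$fit_residuals
}

#' Predict lung age for spirometry records
#'
#' Evaluates the backward-age equation: intercept + linear terms + the
#' FEV1 term (linear, piecewise or spline).  Predictions are never clamped
#' to the modelling age range; a warning is issued when a record's
#' predictors fall outside the model's training ranges (severe patients
#' routinely do, and the natural spline then extrapolates linearly).
#'
#' @param object A `lung_age_model`.
#' @param newdata Data frame of spirometry records.  If a `sex` column is
#'   present it must match the model's sex.
#' @param ... Unused.
#' @return Numeric vector of lung ages (years).
#' @export
predict.lung_age_model <- function(object, newdata, ...) {
  if (object$source == "published" && is.null(object$spline_spec$coefficients))
    stop("published spline coefficients required before prediction")
  if ("sex" %in% names(newdata)) {
    other <- unique(newdata$sex[newdata$sex != object$sex])
    if (length(other))
      stop("sex mismatch: model is for ", object$sex,
           " records, got ", paste(other, collapse = ", "))
  }
  X <- model_design(object, newdata)
  cf <- object$coefficients
  needed <- setdiff(names(cf), "(Intercept)")
  if (!all(needed %in% colnames(X)))
    stop("internal error: design/coefficient mismatch")
  if (!is.null(object$training_ranges)) {
    tr <- object$training_ranges
    vars <- intersect(rownames(tr), c("fev1", object$predictors))
    out_of_range <- vapply(vars, function(v) {
      any(newdata[[v]] < tr[v, "min"] | newdata[[v]] > tr[v, "max"])
    }, logical(1))
    if (any(out_of_range))
      warning("predictor(s) outside the model's training range: ",
              paste(vars[out_of_range], collapse = ", "),
              " (prediction extrapolates)")
  }
  drop(object$intercept + X[, needed, drop = FALSE] %*% cf[needed])
}
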