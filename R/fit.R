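# Backward age regression: the lung-age model families.
#
# Lung age is estimated by regressing the chronological age of healthy
# never-smokers on spirometric indices and height, separately by sex.
# Three families encode the FEV1 effect: a linear term (mlr), a single
# continuous breakpoint (piecewise), or a natural cubic spline (spline).

# Linear predictors a record table can contribute besides the FEV1 term.
LINEAR_PREDICTORS <- c("height", "fvc", "fev1_fvc", "mmef", "fef50", "fef75")

#' Adjusted coefficient of determination
#'
#' @param r2 Unadjusted R-squared.
#' @param n Sample size.
#' @param p Number of predictors (excluding the intercept).
#' @return `1 - (1 - r2) * (n - 1) / (n - p - 1)`.
#' @export
adjusted_r2 <- function(r2, n, p) {
  if (any(n <= p + 1)) stop("adjusted R-squared requires n > p + 1")
  1 - (1 - r2) * (n - 1) / (n - p - 1)
}

#' Ordinary least squares with fit statistics
#'
#' Thin wrapper around [stats::lm()] returning the coefficient vector,
#' t-based 95% confidence intervals, and the fit statistics used for model
#' selection (R-squared, adjusted R-squared, residual standard error, mean
#' squared error).
#'
#' @param y Numeric response (ages, years).
#' @param X Numeric design matrix without an intercept column.
#' @return A list with `coefficients`, `conf_int`, `fit_stats`, `fitted`,
#'   `residuals`.
#' @export
fit_linear <- function(y, X) {
  X <- as.matrix(X)
  n <- length(y)
  p <- ncol(X)
  if (n <= p + 1) stop("need n > p + 1 observations to fit ", p, " predictors")
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(p))
  qrX <- qr(cbind(`(Intercept)` = 1, X))
  if (qrX$rank < p + 1) {
    keep <- qrX$pivot[seq_len(qrX$rank)]
    dropped <- setdiff(seq_len(p + 1), keep) - 1L
    stop("design matrix is rank deficient; collinear columns: ",
         paste(colnames(X)[dropped], collapse = ", "))
  }
  df <- data.frame(.age = y, X, check.names = FALSE)
  fit <- stats::lm(.age ~ ., data = df)
  sm <- summary(fit)
  r2 <- sm$r.squared
  res <- stats::residuals(fit)
  stats_out <- list(
    r2 = r2,
    adj_r2 = adjusted_r2(r2, n, p),
    rse = sm$sigma,
    mse = mean(res^2),
    n = n,
    p = p
  )
  list(coefficients = stats::coef(fit),
       conf_int = stats::confint(fit, level = 0.95),
       fit_stats = stats_out,
       fitted = stats::fitted(fit),
       residuals = res)
}

check_predictors <- function(predictors) {
  bad <- setdiff(predictors, LINEAR_PREDICTORS)
  if (length(bad))
    stop("unknown linear predictors: ", paste(bad, collapse = ", "),
         " (allowed: ", paste(LINEAR_PREDICTORS, collapse = ", "),
         "; the FEV1 term is always included and shaped by `method`)")
  invisible(predictors)
}

check_record_columns <- function(data, cols) {
  miss <- setdiff(cols, names(data))
  if (length(miss))
    stop("missing predictor column(s): ", paste(miss, collapse = ", "))
  invisible(data)
}

subset_sex <- function(data, sex) {
  sex <- match.arg(sex, c("male", "female"))
  if (!"sex" %in% names(data)) stop("records need a `sex` column")
  out <- data[data$sex == sex, , drop = FALSE]
  if (nrow(out) == 0L) stop("no records for sex = '", sex, "'")
  out
}

#' Fit a sex-specific lung-age model
#'
#' Regresses chronological age on an FEV1 term plus linear covariates,
#' for one sex.  The FEV1 effect is encoded according to `method`:
#' \describe{
#'   \item{`"mlr"`}{a single linear FEV1 coefficient;}
#'   \item{`"piecewise"`}{a continuous single-breakpoint FEV1 effect, the
#'     breakpoint chosen by minimum residual sum of squares over a grid of
#'     FEV1 quantiles (5th--95th percentile, step 1 percentile, by
#'     default);}
#'   \item{`"spline"`}{a natural cubic spline in FEV1 (default 3 interior
#'     knots at the quartiles of the fitting sample, boundary knots at the
#'     5th/95th percentiles; see [ns_knots()]).}
#' }
#'
#' @param data Data frame of spirometry records (see [read_spirometry()]
#'   or [generate_healthy()]); must contain `age`, `sex`, `fev1` and the
#'   requested predictors.
#' @param sex `"male"` or `"female"`; the data are restricted to this sex.
#' @param method One of `"mlr"`, `"piecewise"`, `"spline"`.
#' @param predictors Character vector of linear covariates drawn from
#'   `height`, `fvc`, `fev1_fvc`, `mmef`, `fef50`, `fef75`.
#' @param knots Optional `ns_knots` object overriding data-driven knot
#'   placement (spline method only).
#' @param n_interior,boundary_quantiles Knot configuration passed to
#'   [ns_knots()] when `knots` is not supplied.
#' @param breakpoint_grid Optional numeric vector of candidate FEV1
#'   breakpoints (piecewise method only); defaults to the 5th--95th
#'   percentile grid of the fitting sample.
#' @return An object of class `lung_age_model`.
#' @examples
#' h <- generate_healthy("healthy_modelling", n = 400, seed = 1)
#' m <- lung_age_fit(h, sex = "male", method = "spline")
#' predict(m, h[h$sex == "male", ][1:5, ])
#' @export
lung_age_fit <- function(data, sex, method = c("spline", "mlr", "piecewise"),
                         predictors = c("height", "fef50", "fef75"),
                         knots = NULL, n_interior = 3L,
                         boundary_quantiles = c(0.05, 0.95),
                         breakpoint_grid = NULL) {
  method <- match.arg(method)
  check_predictors(predictors)
  d <- subset_sex(data, sex)
  check_record_columns(d, c("age", "fev1", predictors))
  y <- d$age
  fev1 <- d$fev1
  Xlin <- as.matrix(d[, predictors, drop = FALSE])

  spline_spec <- NULL
  breakpoint_spec <- NULL
  if (method == "mlr") {
    X <- cbind(fev1 = fev1, Xlin)
    fit <- fit_linear(y, X)
  } else if (method == "spline") {
    if (is.null(knots))
      knots <- ns_knots(fev1, n_interior = n_interior,
                        boundary_quantiles = boundary_quantiles)
    B <- natural_spline_basis(fev1, knots)
    X <- cbind(B, Xlin)
    fit <- fit_linear(y, X)
    spline_spec <- list(knots = knots,
                        coefficients = fit$coefficients[colnames(B)])
  } else {
    if (is.null(breakpoint_grid))
      breakpoint_grid <- unname(stats::quantile(fev1, seq(0.05, 0.95, by = 0.01),
                                                type = 7))
    rng <- range(fev1)
    if (any(breakpoint_grid < rng[1]) || any(breakpoint_grid > rng[2]))
      stop("breakpoint grid extends outside the observed FEV1 range [",
           fmt_num(rng[1], 4), ", ", fmt_num(rng[2], 4), "]")
    grid <- unique(breakpoint_grid)
    rss <- vapply(grid, function(b) {
      Xb <- cbind(1, fev1, pmax(fev1 - b, 0), Xlin)
      f <- stats::lm.fit(Xb, y)
      sum(f$residuals^2)
    }, numeric(1))
    bp <- grid[which.min(rss)]
    X <- cbind(fev1 = fev1, fev1_hinge = pmax(fev1 - bp, 0), Xlin)
    fit <- fit_linear(y, X)
    left <- unname(fit$coefficients["fev1"])
    breakpoint_spec <- list(breakpoint = bp,
                            slope_left = left,
                            slope_right = left + unname(fit$coefficients["fev1_hinge"]),
                            grid = grid,
                            rss = rss)
  }

  linear_terms <- fit$coefficients[intersect(names(fit$coefficients),
                                             c("fev1", predictors))]
  ranges <- rbind(fev1 = range(fev1))
  if (ncol(Xlin) > 0L) ranges <- rbind(ranges, t(apply(Xlin, 2, range)))
  colnames(ranges) <- c("min", "max")
  out <- list(
    sex = match.arg(sex, c("male", "female")),
    method = method,
    intercept = unname(fit$coefficients["(Intercept)"]),
    linear_terms = linear_terms,
    predictors = predictors,
    spline_spec = spline_spec,
    breakpoint_spec = breakpoint_spec,
    fit_stats = fit$fit_stats,
    conf_int = fit$conf_int,
    coefficients = fit$coefficients,
    fit_fitted = unname(fit$fitted),
    fit_residuals = unname(fit$residuals),
    training_ranges = ranges,
    source = "fitted"
  )
  class(out) <- "lung_age_model"
  out
}

# Rebuild the design matrix a fitted model expects, for new records.
model_design <- function(object, data) {
  check_record_columns(data, c("fev1", object$predictors))
  fev1 <- data$fev1
  Xlin <- as.matrix(data[, object$predictors, drop = FALSE])
  if (object$method == "mlr") {
    cbind(fev1 = fev1, Xlin)
  } else if (object$method == "spline") {
    B <- natural_spline_basis(fev1, object$spline_spec$knots)
    cbind(B, Xlin)
  } else {
    bp <- object$breakpoint_spec$breakpoint
    cbind(fev1 = fev1, fev1_hinge = pmax(fev1 - bp, 0), Xlin)
  }
}
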