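# Candidate-model enumeration and selection by adjusted R-squared.

#' Default candidate predictor subsets
#'
#' All subsets of the linear covariates `height`, `fvc`, `fev1_fvc`,
#' `mmef`, `fef50`, `fef75` of size at most `max_extra`; the FEV1 term is
#' always added by the fitting method, so the default cap of 4 keeps every
#' candidate at 5 terms or fewer.
#'
#' @param max_extra Maximum number of linear covariates per candidate.
#' @return List of character vectors (the empty subset included).
#' @export
candidate_subsets <- function(max_extra = 4L) {
  vars <- LINEAR_PREDICTORS
  out <- list(character(0))
  for (k in seq_len(min(max_extra, length(vars))))
    out <- c(out, utils::combn(vars, k, simplify = FALSE))
  out
}

#' Enumerate candidate lung-age models and select the best per sex
#'
#' Fits every combination of candidate predictor subset, method and sex,
#' ranks the fits by adjusted R-squared, and returns the best model per
#' sex.  Candidates that fail to fit (for example rank-deficient designs)
#' are skipped and logged rather than aborting the enumeration, unless
#' every candidate fails.  Exact ties are broken towards fewer parameters,
#' then by the fixed method order mlr, piecewise, spline.
#'
#' @param data Spirometry records for both sexes.
#' @param subsets List of character vectors of linear covariates; default
#'   [candidate_subsets()].
#' @param methods Subset of `c("mlr", "piecewise", "spline")`.
#' @param sexes Sexes to model (default both).
#' @param ... Passed to [lung_age_fit()] (knot and grid configuration).
#' @return An object of class `lung_age_selection`: list with `best`
#'   (named list of `lung_age_model` per sex) and `ranking` (data frame
#'   with one row per attempted candidate).
#' @export
lung_age_select <- function(data, subsets = candidate_subsets(),
                            methods = c("mlr", "piecewise", "spline"),
                            sexes = c("male", "female"), ...) {
  methods <- match.arg(methods, several.ok = TRUE)
  if (length(subsets) < 1L) stop("need at least one candidate subset")
  method_order <- c(mlr = 1L, piecewise = 2L, spline = 3L)
  rows <- list()
  models <- list()
  for (sex in sexes) {
    for (si in seq_along(subsets)) {
      for (method in methods) {
        key <- paste(sex, si, method, sep = ".")
        res <- tryCatch(
          lung_age_fit(data, sex = sex, method = method,
                       predictors = subsets[[si]], ...),
          error = function(e) e)
        if (inherits(res, "error")) {
          rows[[key]] <- data.frame(
            sex = sex, method = method,
            predictors = paste(subsets[[si]], collapse = "+"),
            p = NA_integer_, r2 = NA_real_, adj_r2 = NA_real_,
            rse = NA_real_, mse = NA_real_,
            error = conditionMessage(res), stringsAsFactors = FALSE)
        } else {
          fs <- res$fit_stats
          rows[[key]] <- data.frame(
            sex = sex, method = method,
            predictors = paste(subsets[[si]], collapse = "+"),
            p = fs$p, r2 = fs$r2, adj_r2 = fs$adj_r2,
            rse = fs$rse, mse = fs$mse,
            error = NA_character_, stringsAsFactors = FALSE)
          models[[key]] <- res
        }
      }
    }
  }
  ranking <- do.call(rbind, rows)
  rownames(ranking) <- NULL
  if (all(is.na(ranking$adj_r2)))
    stop("every candidate model failed to fit; first error: ",
         ranking$error[1])
  best <- list()
  for (sex in sexes) {
    keys <- names(rows)[vapply(rows, function(r) r$sex == sex && is.na(r$error),
                               logical(1))]
    if (!length(keys)) stop("every candidate failed for sex = ", sex)
    tab <- do.call(rbind, rows[keys])
    ord <- order(-tab$adj_r2, tab$p, method_order[tab$method])
    best[[sex]] <- models[[keys[ord[1]]]]
  }
  out <- list(best = best, ranking = ranking)
  class(out) <- "lung_age_selection"
  out
}

#' @export
print.lung_age_selection <- function(x, ...) {
  cat("Lung-age model selection:", nrow(x$ranking), "candidates\n")
  for (sex in names(x$best)) {
    m <- x$best[[sex]]
    cat(sprintf("  best %-6s %-9s {%s}  adj R2 = %.4f\n", sex, m$method,
                paste(c("fev1", m$predictors), collapse = ","),
                m$fit_stats$adj_r2))
  }
  invisible(x)
}

#' Bootstrap validation of a fitted lung-age model
#'
#' Refits the model recipe on `B` subject-level resamples drawn with
#' replacement and summarizes the coefficients and fit statistics across
#' replicates.  Spline knots are held fixed at the primary model's knots
#' so replicate coefficients are comparable; the piecewise breakpoint is
#' re-searched on the primary grid.  Replicates whose resample yields a
#' rank-deficient design are skipped and counted.
#'
#' @param model A fitted `lung_age_model`.
#' @param data The records the model was fitted on (both sexes allowed;
#'   the model's sex stratum is used).
#' @param B Number of bootstrap replicates.
#' @param seed Integer seed; the report is fully reproducible from it.
#' @return An object of class `lung_age_boot`: list with `B`, `skipped`,
#'   `seed`, `coefficient_summaries` (per-coefficient mean, sd and 2.5/97.5
#'   percentiles), `adj_r2_summary`, `mse_summary`, and the replicate
#'   draws in `replicates`.
#' @export
bootstrap_validate <- function(model, data, B = 1000L, seed = 1L) {
  stopifnot(inherits(model, "lung_age_model"))
  if (B < 1L) stop("B must be >= 1")
  d <- subset_sex(data, model$sex)
  n <- nrow(d)
  cf_names <- names(model$coefficients)
  draws <- matrix(NA_real_, B, length(cf_names),
                  dimnames = list(NULL, cf_names))
  adj <- mse <- rep(NA_real_, B)
  skipped <- 0L
  with_preserved_seed(seed, {
    for (b in seq_len(B)) {
      idx <- sample.int(n, n, replace = TRUE)
      res <- tryCatch(
        lung_age_fit(d[idx, , drop = FALSE], sex = model$sex,
                     method = model$method, predictors = model$predictors,
                     knots = model$spline_spec$knots,
                     breakpoint_grid = model$breakpoint_spec$grid),
        error = function(e) NULL)
      if (is.null(res)) { skipped <- skipped + 1L; next }
      draws[b, names(res$coefficients)] <- res$coefficients
      adj[b] <- res$fit_stats$adj_r2
      mse[b] <- res$fit_stats$mse
    }
  })
  ok <- !is.na(adj)
  summarize <- function(v) c(mean = mean(v[ok]), sd = stats::sd(v[ok]),
                             q2.5 = unname(stats::quantile(v[ok], 0.025, type = 7)),
                             q97.5 = unname(stats::quantile(v[ok], 0.975, type = 7)))
  out <- list(
    B = B, skipped = skipped, seed = seed,
    coefficient_summaries = t(apply(draws, 2, summarize)),
    adj_r2_summary = summarize(adj),
    mse_summary = summarize(mse),
    replicates = list(coefficients = draws[ok, , drop = FALSE],
                      adj_r2 = adj[ok], mse = mse[ok])
  )
  class(out) <- "lung_age_boot"
  out
}

#' @export
print.lung_age_boot <- function(x, ...) {
  cat("Bootstrap validation: B =", x$B,
      if (x$skipped) paste0("(", x$skipped, " replicate(s) skipped)"), "\n")
  cat("  adj R2: mean", fmt_num(x$adj_r2_summary["mean"], 4),
      " MSE: mean", fmt_num(x$mse_summary["mean"], 4), "\n")
  print(round(x$coefficient_summaries, 4))
  invisible(x)
}
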