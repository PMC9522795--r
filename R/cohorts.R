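# Healthy-subject inclusion filtering and propensity score matching.

#' Inclusion configuration for healthy subjects
#'
#' The healthy-cohort entry rules: age 18--80 years, body mass index at
#' most 30 kg/m2, never-smoker, and the four spirometric indices (FEV1,
#' FVC, FEV1/FVC, MMEF) within normal limits.  The normal-limit judgement
#' depends on external reference equations and is consumed as precomputed
#' boolean flag columns (`nl_fev1`, `nl_fvc`, `nl_ratio`, `nl_mmef`),
#' never computed here.
#'
#' @param age_range Length-2 inclusive age window (years).
#' @param bmi_max Maximum body mass index (kg/m2).
#' @param require_normal_flags Require the four `nl_*` flag columns TRUE.
#' @param require_nonsmoker Require the `smoker` column FALSE.
#' @return A list of class `inclusion_config`.
#' @export
inclusion_config <- function(age_range = c(18, 80), bmi_max = 30,
                             require_normal_flags = TRUE,
                             require_nonsmoker = TRUE) {
  if (age_range[1] >= age_range[2]) stop("age_range must be increasing")
  if (bmi_max <= 0) stop("bmi_max must be positive")
  structure(list(age_range = age_range, bmi_max = bmi_max,
                 require_normal_flags = require_normal_flags,
                 require_nonsmoker = require_nonsmoker),
            class = "inclusion_config")
}

#' Apply the healthy-subject inclusion filter
#'
#' Checks each record against the active rules in a fixed order (age,
#' BMI, smoking, normal-limit flags) and logs the first failed rule per
#' excluded record.  Filtering is idempotent: the included subset passes
#' the same filter unchanged.
#'
#' @param records Spirometry records.
#' @param config An [inclusion_config()].
#' @return List of class `inclusion_result` with `included` (record
#'   subset) and `exclusions` (data frame `id`, `reason`).
#' @export
healthy_inclusion_filter <- function(records, config = inclusion_config()) {
  stopifnot(inherits(config, "inclusion_config"))
  need <- c("id", "age")
  if (is.finite(config$bmi_max)) need <- c(need, "weight", "height")
  if (config$require_nonsmoker) need <- c(need, "smoker")
  flag_cols <- c("nl_fev1", "nl_fvc", "nl_ratio", "nl_mmef")
  if (config$require_normal_flags) need <- c(need, flag_cols)
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("active inclusion rules need missing field(s): ",
         paste(miss, collapse = ", "))
  reason <- rep(NA_character_, nrow(records))
  mark <- function(bad, why) ifelse(is.na(reason) & bad, why, reason)
  reason <- mark(records$age < config$age_range[1],
                 paste0("age<", config$age_range[1]))
  reason <- mark(records$age > config$age_range[2],
                 paste0("age>", config$age_range[2]))
  if (is.finite(config$bmi_max)) {
    bmi <- records$weight / (records$height / 100)^2
    reason <- mark(bmi > config$bmi_max, paste0("bmi>", config$bmi_max))
  }
  if (config$require_nonsmoker)
    reason <- mark(as.logical(records$smoker), "smoker")
  if (config$require_normal_flags) {
    for (fc in flag_cols)
      reason <- mark(!as.logical(records[[fc]]), paste0("outside normal limits: ", fc))
  }
  keep <- is.na(reason)
  out <- list(included = records[keep, , drop = FALSE],
              exclusions = data.frame(id = records$id[!keep],
                                      reason = reason[!keep],
                                      stringsAsFactors = FALSE))
  class(out) <- "inclusion_result"
  out
}

#' @export
print.inclusion_result <- function(x, ...) {
  cat("Inclusion filter:", nrow(x$included), "included,",
      nrow(x$exclusions), "excluded\n")
  if (nrow(x$exclusions)) print(table(x$exclusions$reason))
  invisible(x)
}

#' Standardized mean difference
#'
#' Balance diagnostic for matching: for continuous covariates the mean
#' difference over the pooled (average-variance) standard deviation; for
#' binary covariates the difference in proportions over the pooled
#' binomial standard deviation.
#'
#' @param a,b Numeric (or logical/binary) vectors for the two groups.
#' @param type `"continuous"` or `"binary"`.
#' @return The SMD; a signed infinity (with a warning) when the pooled SD
#'   is zero but the means differ, 0 when both groups are constant and
#'   equal.
#' @export
standardized_mean_difference <- function(a, b,
                                         type = c("continuous", "binary")) {
  type <- match.arg(type)
  if (!length(a) || !length(b)) stop("both groups must be non-empty")
  a <- as.numeric(a); b <- as.numeric(b)
  if (type == "binary") {
    pa <- mean(a); pb <- mean(b)
    s <- sqrt((pa * (1 - pa) + pb * (1 - pb)) / 2)
    num <- pa - pb
  } else {
    s <- sqrt((stats::var(a) + stats::var(b)) / 2)
    if (is.na(s)) s <- 0   # length-1 groups
    num <- mean(a) - mean(b)
  }
  if (s == 0) {
    if (num == 0) return(0)
    warning("zero pooled SD with unequal means; returning signed infinity")
    return(sign(num) * Inf)
  }
  num / s
}

#' Propensity score matching of patients to healthy controls
#'
#' Fits a logistic propensity model of case membership on the covariates,
#' then matches each case to up to `ratio` unused controls by greedy
#' nearest-neighbour search on the logit of the propensity score, without
#' replacement, in a seeded random case order, within a caliper of
#' `caliper` standard deviations of the logit.
#'
#' @param cases,controls Spirometry record data frames (must contain `id`
#'   and the covariates).
#' @param covariates Covariate columns for the propensity model; `sex` is
#'   treated as binary.
#' @param ratio Maximum controls matched per case.
#' @param caliper Caliper width in SD units of the logit propensity score;
#'   `Inf` disables it.
#' @param seed Integer seed controlling the case order.
#' @return An object of class `psm_match`: `pairs` (data frame `case_id`,
#'   `control_id`, `distance`), `scores`, `balance` (pre/post SMD per
#'   covariate), `caliper`, `seed`, counts.
#' @export
propensity_match <- function(cases, controls,
                             covariates = c("age", "height", "sex"),
                             ratio = 1L, caliper = 0.2, seed = 1L) {
  if (!nrow(cases) || !nrow(controls))
    stop("both cases and controls must be non-empty")
  check_record_columns(cases, c("id", covariates))
  check_record_columns(controls, c("id", covariates))
  build <- function(d) {
    out <- d[, covariates, drop = FALSE]
    if ("sex" %in% covariates) out$sex <- as.numeric(out$sex == "male")
    out
  }
  df <- rbind(cbind(.case = 1, build(cases)), cbind(.case = 0, build(controls)))
  separated <- FALSE
  fit <- withCallingHandlers(
    stats::glm(.case ~ ., family = stats::binomial(), data = df),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        separated <<- TRUE
      invokeRestart("muffleWarning")
    })
  if (separated || !fit$converged)
    stop("propensity model shows complete (or quasi-complete) separation; ",
         "consider caliper-free exact matching on the covariates instead")
  logit <- stats::predict(fit, type = "link")
  nc <- nrow(cases)
  logit_case <- logit[seq_len(nc)]
  logit_ctrl <- logit[-seq_len(nc)]
  cal_abs <- if (is.finite(caliper)) caliper * stats::sd(logit) else Inf
  used <- rep(FALSE, length(logit_ctrl))
  pairs <- list()
  with_preserved_seed(seed, {
    for (i in sample.int(nc)) {
      for (r in seq_len(ratio)) {
        d <- abs(logit_ctrl - logit_case[i])
        d[used] <- Inf
        j <- which.min(d)
        if (!is.finite(d[j]) || d[j] > cal_abs) break
        used[j] <- TRUE
        pairs[[length(pairs) + 1L]] <- data.frame(
          case_id = cases$id[i], control_id = controls$id[j],
          distance = d[j], stringsAsFactors = FALSE)
      }
    }
  })
  pairs <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(case_id = character(0), control_id = character(0),
               distance = numeric(0))
  m_cases <- cases[match(unique(pairs$case_id), cases$id), , drop = FALSE]
  m_ctrls <- controls[match(pairs$control_id, controls$id), , drop = FALSE]
  bal <- do.call(rbind, lapply(covariates, function(v) {
    typ <- if (v == "sex") "binary" else "continuous"
    val <- function(d) if (v == "sex") d$sex == "male" else d[[v]]
    post <- if (nrow(pairs)) standardized_mean_difference(val(m_cases), val(m_ctrls), typ)
            else NA_real_
    data.frame(covariate = v,
               smd_pre = standardized_mean_difference(val(cases), val(controls), typ),
               smd_post = post, stringsAsFactors = FALSE)
  }))
  out <- list(pairs = pairs,
              scores = data.frame(id = c(cases$id, controls$id),
                                  group = rep(c("case", "control"),
                                              c(nc, length(logit_ctrl))),
                                  logit = unname(logit)),
              balance = bal,
              caliper = caliper, caliper_abs = cal_abs, seed = seed,
              n_cases = nc, n_controls = length(logit_ctrl),
              n_matched_cases = length(unique(pairs$case_id)))
  class(out) <- "psm_match"
  out
}

#' @export
print.psm_match <- function(x, ...) {
  cat("Propensity score matching:", x$n_matched_cases, "of", x$n_cases,
      "cases matched (", nrow(x$pairs), "pairs, caliper", x$caliper,
      "SD )\n")
  print(transform(x$balance, smd_pre = round(smd_pre, 3),
                  smd_post = round(smd_post, 3)), row.names = FALSE)
  invisible(x)
}
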