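# Reading/writing record tables and structured-text model files.
#
# Tabular artifacts are comma-separated text with a header and an
# optional leading "#" provenance comment (tool version and generating
# command).  Models and ULN parameters are serialized as JSON at full
# precision so a write -> read -> write cycle is byte-identical.

MANDATORY_COLUMNS <- c("id", "sex", "age", "height", "fev1", "fvc",
                       "fev1_fvc", "mmef", "fef50", "fef75")
NUMERIC_COLUMNS <- c("age", "height", "weight", "fev1", "fvc", "fev1_fvc",
                     "fev1_pct_pred", "mmef", "fef50", "fef75")
MODEL_FORMAT <- "lungage-model/1"

pkg_version <- function() {
  as.character(utils::packageVersion("lungage"))
}

provenance_line <- function(command = NULL) {
  paste0("# lungage ", pkg_version(),
         if (!is.null(command)) paste0(" | ", command))
}

#' Read a spirometry record table
#'
#' Reads comma-separated records with a header, validates the column
#' schema and types, applies unit sanity checks (heights plausibly cm,
#' volumes plausibly L), and collects malformed rows into an error
#' report attached as the `"errors"` attribute (malformed rows are
#' dropped with a warning).  Sex must be the literal strings `"male"` /
#' `"female"`; numeric encodings are rejected.
#'
#' @param path Path to a CSV file.
#' @return Data frame of records; attributes `source` and `errors`.
#' @export
read_spirometry <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  if (nrow(d) == 0L) stop("no records in ", path)
  miss <- setdiff(MANDATORY_COLUMNS, names(d))
  if (length(miss))
    stop("missing column: ", paste(miss, collapse = ", "))
  if (is.numeric(d$sex))
    stop("`sex` must be the strings \"male\"/\"female\", not a numeric code")
  errors <- character(0)
  bad <- rep(FALSE, nrow(d))
  for (cc in intersect(NUMERIC_COLUMNS, names(d))) {
    v <- suppressWarnings(as.numeric(d[[cc]]))
    nb <- !is.na(d[[cc]]) & is.na(v)
    nb <- nb | (cc %in% MANDATORY_COLUMNS & is.na(d[[cc]]))
    if (any(nb))
      errors <- c(errors, paste0("row ", which(nb), ": malformed ", cc,
                                 " value '", d[[cc]][nb], "'"))
    bad <- bad | nb
    d[[cc]] <- v
  }
  sex_bad <- !d$sex %in% c("male", "female")
  if (any(sex_bad))
    errors <- c(errors, paste0("row ", which(sex_bad), ": invalid sex '",
                               d$sex[sex_bad], "'"))
  bad <- bad | sex_bad
  if (any(bad)) {
    warning(sum(bad), " malformed row(s) dropped; see attr(x, 'errors')")
    d <- d[!bad, , drop = FALSE]
    if (nrow(d) == 0L) stop("no well-formed records in ", path)
  }
  if (anyDuplicated(d$id)) stop("duplicate record ids in ", path)
  med_h <- stats::median(d$height, na.rm = TRUE)
  if (is.finite(med_h) && (med_h < 100 || med_h > 220))
    warning("median height ", fmt_num(med_h, 4),
            " is implausible for cm; check units")
  if (any(d$fev1 > 10, na.rm = TRUE) || any(d$fvc > 12, na.rm = TRUE))
    warning("volumes above 10-12 L; check units (expected litres)")
  attr(d, "source") <- path
  attr(d, "errors") <- errors
  d
}

#' Write a spirometry record table
#'
#' @param records Data frame of records.
#' @param path Output CSV path.
#' @param command Optional command string embedded in the provenance
#'   comment line.
#' @export
write_spirometry <- function(records, path, command = NULL) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(provenance_line(command), con)
  utils::write.csv(records, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a generic results table (CSV with provenance comment)
#'
#' @inheritParams write_spirometry
#' @param table Data frame to write.
#' @export
write_result_table <- function(table, path, command = NULL) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(provenance_line(command), con)
  utils::write.csv(table, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

model_to_list <- function(m) {
  list(
    sex = m$sex, method = m$method, source = m$source,
    intercept = m$intercept,
    linear_terms = as.list(m$linear_terms),
    predictors = as.list(m$predictors),
    coefficients = as.list(m$coefficients),
    spline_spec = if (!is.null(m$spline_spec)) list(
      boundary = m$spline_spec$knots$boundary,
      interior = m$spline_spec$knots$interior,
      coefficients = as.list(m$spline_spec$coefficients)),
    breakpoint_spec = if (!is.null(m$breakpoint_spec)) list(
      breakpoint = m$breakpoint_spec$breakpoint,
      slope_left = m$breakpoint_spec$slope_left,
      slope_right = m$breakpoint_spec$slope_right,
      grid = m$breakpoint_spec$grid),
    fit_stats = m$fit_stats,
    conf_int = if (!is.null(m$conf_int)) list(
      terms = rownames(m$conf_int),
      low = unname(m$conf_int[, 1]), high = unname(m$conf_int[, 2])),
    training_ranges = if (!is.null(m$training_ranges)) list(
      vars = rownames(m$training_ranges),
      min = unname(m$training_ranges[, "min"]),
      max = unname(m$training_ranges[, "max"]))
  )
}

model_from_list <- function(l) {
  num <- function(x) if (is.null(x)) NULL else unlist(x)
  m <- list(
    sex = l$sex, method = l$method,
    intercept = l$intercept,
    linear_terms = num(l$linear_terms),
    predictors = as.character(unlist(l$predictors)),
    spline_spec = if (!is.null(l$spline_spec)) list(
      knots = structure(list(boundary = num(l$spline_spec$boundary),
                             interior = as.numeric(num(l$spline_spec$interior))),
                        class = "ns_knots"),
      coefficients = num(l$spline_spec$coefficients)),
    breakpoint_spec = if (!is.null(l$breakpoint_spec)) list(
      breakpoint = l$breakpoint_spec$breakpoint,
      slope_left = l$breakpoint_spec$slope_left,
      slope_right = l$breakpoint_spec$slope_right,
      grid = num(l$breakpoint_spec$grid)),
    fit_stats = l$fit_stats,
    conf_int = if (!is.null(l$conf_int)) {
      ci <- cbind(num(l$conf_int$low), num(l$conf_int$high))
      dimnames(ci) <- list(unlist(l$conf_int$terms), c("2.5 %", "97.5 %"))
      ci
    },
    coefficients = num(l$coefficients),
    training_ranges = if (!is.null(l$training_ranges)) {
      tr <- cbind(min = num(l$training_ranges$min),
                  max = num(l$training_ranges$max))
      rownames(tr) <- unlist(l$training_ranges$vars)
      tr
    },
    source = l$source
  )
  class(m) <- "lung_age_model"
  m
}

uln_to_list <- function(u) {
  list(intercept = u$intercept, age_slope = u$age_slope, rse = u$rse,
       z = u$z, n = u$n, constant_uln = u$constant_uln,
       source_label = u$source_label)
}

uln_from_list <- function(l) {
  u <- list(intercept = l$intercept, age_slope = l$age_slope, rse = l$rse,
            z = l$z, n = if (is.null(l$n)) NA_integer_ else l$n,
            constant_uln = l$constant_uln,
            source_label = l$source_label)
  class(u) <- "uln_model"
  u
}

#' Write lung-age (and optional ULN) models to a structured-text file
#'
#' JSON at full numeric precision; the file records the format version,
#' the package version and the generating command, and round-trips
#' losslessly through [read_lung_age_model()].
#'
#' @param models A `lung_age_model` or a named list of them (e.g. one per
#'   sex).
#' @param path Output path.
#' @param uln Optional `uln_model` (or named list of them) stored
#'   alongside.
#' @param command Optional provenance command string.
#' @export
write_lung_age_model <- function(models, path, uln = NULL, command = NULL) {
  if (inherits(models, "lung_age_model")) models <- list(model = models)
  stopifnot(all(vapply(models, inherits, logical(1), "lung_age_model")))
  if (inherits(uln, "uln_model")) uln <- list(uln = uln)
  payload <- list(
    format = MODEL_FORMAT,
    tool = list(package = "lungage", version = pkg_version(),
                command = command),
    models = lapply(models, model_to_list),
    uln = if (!is.null(uln)) lapply(uln, uln_to_list)
  )
  # digits = I(17): significant digits, enough to round-trip doubles
  # bit-exactly
  json <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = I(17),
                           null = "null", pretty = TRUE)
  writeLines(json, path, useBytes = TRUE)
  invisible(path)
}

#' Read a lung-age model file
#'
#' @param path Path written by [write_lung_age_model()].
#' @return List with `models` (named list of `lung_age_model`), `uln`
#'   (named list of `uln_model` or NULL) and `tool` provenance.
#' @export
read_lung_age_model <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  l <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                error = function(e) stop("cannot parse model file ", path,
                                         ": ", conditionMessage(e)))
  if (is.null(l$format) || !identical(l$format, MODEL_FORMAT))
    stop("model file format '", if (is.null(l$format)) "<missing>" else l$format,
         "' does not match supported '", MODEL_FORMAT, "'")
  list(models = lapply(l$models, model_from_list),
       uln = if (!is.null(l$uln)) lapply(l$uln, uln_from_list),
       tool = l$tool)
}
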