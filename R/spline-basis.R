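# Natural cubic spline basis for the FEV1 term of the lung-age models.
#
# The basis is built from cubic B-splines with the second-derivative
# ("natural") constraints at the boundary knots projected out, and is
# evaluated by linear extrapolation beyond the boundary knots.  A
# truncated-power construction of the same function space is provided as an
# independent oracle for testing.

#' Place knots for the FEV1 spline
#'
#' Interior knots are placed at equally spaced quantiles of `values`
#' (linear-interpolation quantiles), boundary knots at the requested
#' quantile pair.  Passing `boundary_quantiles = c(0, 1)` uses the sample
#' minimum and maximum.
#'
#' @param values Numeric vector of FEV1 values (L) from the fitting sample.
#' @param n_interior Number of interior knots (>= 0).
#' @param boundary_quantiles Length-2 probabilities in `[0, 1]` for the
#'   boundary knots.
#' @return An object of class `ns_knots`: a list with elements `boundary`
#'   (length 2) and `interior` (length `n_interior`), strictly increasing.
#' @examples
#' ns_knots(1:100, n_interior = 3, boundary_quantiles = c(0, 1))
#' @export
ns_knots <- function(values, n_interior = 3L, boundary_quantiles = c(0.05, 0.95)) {
  values <- as.numeric(values)
  if (length(values) == 0L || anyNA(values) || any(!is.finite(values)))
    stop("`values` must be non-empty, finite and free of NA")
  n_interior <- as.integer(n_interior)
  if (n_interior < 0L) stop("`n_interior` must be >= 0")
  bq <- as.numeric(boundary_quantiles)
  if (length(bq) != 2L || any(bq < 0) || any(bq > 1) || bq[1] >= bq[2])
    stop("`boundary_quantiles` must be two increasing probabilities in [0, 1]")
  n_distinct <- length(unique(values))
  needed <- n_interior + 2L
  if (n_distinct < needed)
    stop(sprintf("need at least %d distinct values to place %d knots, have %d (deficit %d)",
                 needed, needed, n_distinct, needed - n_distinct))
  boundary <- unname(stats::quantile(values, bq, type = 7))
  interior <- if (n_interior > 0L) {
    probs <- seq_len(n_interior) / (n_interior + 1)
    unname(stats::quantile(values, probs, type = 7))
  } else numeric(0)
  ks <- list(boundary = boundary, interior = interior)
  class(ks) <- "ns_knots"
  validate_ns_knots(ks)
  ks
}

validate_ns_knots <- function(ks) {
  all_k <- c(ks$boundary[1], ks$interior, ks$boundary[2])
  if (any(!is.finite(all_k)))
    stop("knots must be finite")
  if (any(diff(all_k) <= 0))
    stop("knots are not strictly increasing (indistinct knots); ",
         "supply fewer interior knots or more spread-out values")
  invisible(ks)
}

#' @export
print.ns_knots <- function(x, ...) {
  cat("Natural-spline knot set (FEV1, L)\n")
  cat("  boundary:", format(x$boundary, digits = 4), "\n")
  cat("  interior:", if (length(x$interior)) format(x$interior, digits = 4) else "(none)", "\n")
  invisible(x)
}

# Cox-de Boor evaluation of all B-splines of order `ord` on the extended
# knot vector `tk`, optionally differentiated `deriv` times.  Returns a
# length(x) x (length(tk) - ord) matrix.  Repeated knots give zero-width
# intervals whose terms are defined as zero.
bspline_matrix <- function(x, tk, ord = 4L, deriv = 0L) {
  nb <- length(tk) - ord
  if (nb < 1L) stop("knot vector too short for requested order")
  if (deriv > 0L) {
    lower <- bspline_matrix(x, tk, ord - 1L, deriv - 1L) # nb + 1 columns
    res <- matrix(0, length(x), nb)
    for (j in seq_len(nb)) {
      d1 <- tk[j + ord - 1L] - tk[j]
      d2 <- tk[j + ord] - tk[j + 1L]
      if (d1 > 0) res[, j] <- res[, j] + (ord - 1L) * lower[, j] / d1
      if (d2 > 0) res[, j] <- res[, j] - (ord - 1L) * lower[, j + 1L] / d2
    }
    return(res)
  }
  # order 1: indicator functions, right-closed on the final interval
  n1 <- length(tk) - 1L
  B <- matrix(0, length(x), n1)
  last <- max(which(diff(tk) > 0))
  for (j in seq_len(n1)) {
    if (tk[j + 1L] > tk[j]) {
      hit <- x >= tk[j] & x < tk[j + 1L]
      if (j == last) hit <- hit | x == tk[j + 1L]
      B[hit, j] <- 1
    }
  }
  if (ord == 1L) return(B)
  for (k in 2:ord) {
    ncol_k <- length(tk) - k
    Bk <- matrix(0, length(x), ncol_k)
    for (j in seq_len(ncol_k)) {
      d1 <- tk[j + k - 1L] - tk[j]
      d2 <- tk[j + k] - tk[j + 1L]
      if (d1 > 0) Bk[, j] <- Bk[, j] + (x - tk[j]) / d1 * B[, j]
      if (d2 > 0) Bk[, j] <- Bk[, j] + (tk[j + k] - x) / d2 * B[, j + 1L]
    }
    B <- Bk
  }
  B
}

# Full cubic B-spline basis (with intercept direction still present) on the
# knot set, evaluated with linear extrapolation beyond the boundary knots.
full_cubic_basis <- function(x, ks) {
  bl <- ks$boundary[1]; bh <- ks$boundary[2]
  tk <- c(rep(bl, 4L), ks$interior, rep(bh, 4L))
  n_full <- length(tk) - 4L
  B <- matrix(0, length(x), n_full)
  inside <- x >= bl & x <= bh
  if (any(inside)) B[inside, ] <- bspline_matrix(x[inside], tk, 4L, 0L)
  for (side in c("low", "high")) {
    b <- if (side == "low") bl else bh
    out <- if (side == "low") x < bl else x > bh
    if (!any(out)) next
    v0 <- bspline_matrix(b, tk, 4L, 0L)
    v1 <- bspline_matrix(b, tk, 4L, 1L)
    B[out, ] <- rep(v0, each = sum(out)) + outer(x[out] - b, drop(v1))
  }
  B
}

#' Natural cubic spline design matrix
#'
#' Evaluates a basis for the space of cubic splines with the given interior
#' knots that are constrained to be linear beyond the boundary knots
#' (a natural cubic spline), without an intercept column.  Values outside
#' the boundary knots are extrapolated linearly, which is the defining
#' boundary behaviour of the natural spline; FEV1 values of patients with
#' severe airflow limitation routinely lie below the healthy-range boundary
#' knot and are deliberately not clamped.
#'
#' @param x Numeric vector of FEV1 values (L); finite, any range.
#' @param knots An `ns_knots` object (see [ns_knots()]).
#' @return A numeric matrix with `length(x)` rows and
#'   `length(knots$interior) + 1` columns.
#' @seealso [truncated_power_basis()] for an independent construction of
#'   the same function space.
#' @export
natural_spline_basis <- function(x, knots) {
  validate_ns_knots(knots)
  x <- as.numeric(x)
  if (anyNA(x) || any(!is.finite(x))) stop("`x` must be finite and free of NA")
  bl <- knots$boundary[1]; bh <- knots$boundary[2]
  tk <- c(rep(bl, 4L), knots$interior, rep(bh, 4L))
  B <- full_cubic_basis(x, knots)
  const <- rbind(bspline_matrix(bl, tk, 4L, 2L),
                 bspline_matrix(bh, tk, 4L, 2L))
  # remove the intercept direction, then project out the two second-
  # derivative constraints at the boundaries (as in the classical natural
  # spline construction)
  B <- B[, -1L, drop = FALSE]
  const <- const[, -1L, drop = FALSE]
  qrc <- qr(t(const))
  out <- t(qr.qty(qrc, t(B)))[, -(1:2), drop = FALSE]
  colnames(out) <- paste0("ns", seq_len(ncol(out)))
  out
}

#' Truncated-power natural spline basis (test oracle)
#'
#' Spans the same function space as [natural_spline_basis()] using
#' truncated power functions with the natural (linear-tail) constraints
#' imposed algebraically.  Numerically less stable than the B-spline
#' construction; intended as an independent oracle in tests, not for
#' fitting.
#'
#' @inheritParams natural_spline_basis
#' @return A numeric matrix with `length(x)` rows and
#'   `length(knots$interior) + 1` columns (first column is `x` itself).
#' @export
truncated_power_basis <- function(x, knots) {
  validate_ns_knots(knots)
  x <- as.numeric(x)
  if (anyNA(x) || any(!is.finite(x))) stop("`x` must be finite and free of NA")
  xi <- c(knots$boundary[1], knots$interior, knots$boundary[2])
  K <- length(xi)
  d <- function(j) {
    (pmax(x - xi[j], 0)^3 - pmax(x - xi[K], 0)^3) / (xi[K] - xi[j])
  }
  out <- matrix(x, length(x), 1L)
  if (K > 2L) {
    dlast <- d(K - 1L)
    for (j in seq_len(K - 2L)) out <- cbind(out, d(j) - dlast)
  }
  colnames(out) <- paste0("tp", seq_len(ncol(out)))
  out
}
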