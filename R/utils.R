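# Small numerical utilities shared across the package.

# Run code with a local, restored RNG state so that seeded package
# functions do not disturb the caller's random stream.
with_preserved_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Truncated-normal helpers (closed-form moments and quantile function).
tn_moments <- function(mu, sigma, lo, hi) {
  a <- (lo - mu) / sigma
  b <- (hi - mu) / sigma
  Z <- stats::pnorm(b) - stats::pnorm(a)
  if (Z <= 0) return(list(mean = NA_real_, sd = NA_real_))
  pa <- stats::dnorm(a); pb <- stats::dnorm(b)
  m <- mu + sigma * (pa - pb) / Z
  aa <- if (is.finite(a)) a * pa else 0
  bb <- if (is.finite(b)) b * pb else 0
  v <- sigma^2 * (1 + (aa - bb) / Z - ((pa - pb) / Z)^2)
  list(mean = m, sd = sqrt(max(v, 0)))
}

tn_quantile <- function(u, mu, sigma, lo, hi) {
  a <- stats::pnorm((lo - mu) / sigma)
  b <- stats::pnorm((hi - mu) / sigma)
  u <- pmin(pmax(a + u * (b - a), 1e-12), 1 - 1e-12)
  mu + sigma * stats::qnorm(u)
}

tn_cdf <- function(x, mu, sigma, lo, hi) {
  a <- stats::pnorm((lo - mu) / sigma)
  b <- stats::pnorm((hi - mu) / sigma)
  p <- (stats::pnorm((pmin(pmax(x, lo), hi) - mu) / sigma) - a) / (b - a)
  pmin(pmax(p, 0), 1)
}

# Solve truncated-normal parameters so the truncated distribution has the
# requested mean and SD on [lo, hi].  The search is confined to a box in
# which the closed-form moment expressions are numerically stable; a
# printed SD wider than the band supports (the uniform limit) is matched
# as closely as the family allows, with the mean prioritized.
tn_solve <- function(target_mean, target_sd, lo, hi, sigma_start = target_sd) {
  mean_w <- 100  # the mean target dominates; SD is best-effort
  obj <- function(par) {
    m <- tn_moments(par[1], exp(par[2]), lo, hi)
    if (!is.finite(m$mean) || !is.finite(m$sd)) return(1e8)
    mean_w * ((m$mean - target_mean) / target_sd)^2 +
      ((m$sd - target_sd) / target_sd)^2
  }
  lo_f <- if (is.finite(lo)) lo else target_mean - 8 * target_sd
  hi_f <- if (is.finite(hi)) hi else target_mean + 8 * target_sd
  fit <- stats::optim(c(target_mean, log(sigma_start)), obj,
                      method = "L-BFGS-B",
                      lower = c(lo_f - 10 * target_sd, log(target_sd / 50)),
                      upper = c(hi_f + 10 * target_sd, log(target_sd * 40)),
                      control = list(maxit = 500, factr = 1e4))
  list(mu = fit$par[1], sigma = exp(fit$par[2]), value = fit$value)
}

# Gauss-Hermite nodes/weights for the standard normal weight function
# (Golub-Welsch on the probabilists' Hermite recurrence; weights sum to 1).
gauss_hermite_norm <- function(n) {
  J <- diag(0, n)
  off <- sqrt(seq_len(n - 1))
  J[cbind(seq_len(n - 1), seq_len(n - 1) + 1)] <- off
  J[cbind(seq_len(n - 1) + 1, seq_len(n - 1))] <- off
  e <- eigen(J, symmetric = TRUE)
  list(nodes = e$values, weights = e$vectors[1, ]^2)
}

fmt_num <- function(x, digits) formatC(x, digits = digits, format = "fg")
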