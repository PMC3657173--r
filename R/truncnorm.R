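# Truncated-normal utilities for per-subject percent-positive draws.
# Published group statistics (mean, SD, range) describe the observed,
# range-bounded data, so the generator solves for the latent normal
# location whose *truncated* mean equals the printed group mean.

#' Mean of a truncated normal distribution
#'
#' @param mu,sd Location and scale of the latent normal (`sd` > 0).
#' @param low,high Truncation bounds.
#' @return The expectation of the normal truncated to \[low, high\].
#' @export
truncnorm_mean <- function(mu, sd, low, high) {
  stopifnot(sd > 0, low < high)
  a <- (low - mu) / sd
  b <- (high - mu) / sd
  z <- stats::pnorm(b) - stats::pnorm(a)
  if (z <= 0) stop("truncation interval has no mass", call. = FALSE)
  mu + sd * (stats::dnorm(a) - stats::dnorm(b)) / z
}

# Latent location mu* with E[TruncNorm(mu*, sd, low, high)] == target_mean.
# The truncated mean is strictly increasing in mu with range (low, high).
calibrate_truncnorm <- function(target_mean, sd, low, high) {
  if (low > high) stop("empty truncation range", call. = FALSE)
  if (sd == 0) {
    if (target_mean < low || target_mean > high) {
      stop("degenerate distribution: mean outside range", call. = FALSE)
    }
    return(target_mean)
  }
  if (target_mean <= low || target_mean >= high) {
    stop("with sd > 0 the truncated mean must lie strictly inside the range",
         call. = FALSE)
  }
  # +/- 6 SD brackets every attainable interior mean while keeping both
  # normal tails representable in double precision
  f <- function(mu) truncnorm_mean(mu, sd, low, high) - target_mean
  stats::uniroot(f, lower = low - 6 * sd, upper = high + 6 * sd,
                 tol = 1e-10)$root
}

# Inverse-CDF sampler; one uniform per draw so draws are reproducible
# and order-stable under a fixed RNG state.
rtruncnorm <- function(n, mu, sd, low, high) {
  if (sd == 0) return(rep(mu, n))
  pa <- stats::pnorm(low, mu, sd)
  pb <- stats::pnorm(high, mu, sd)
  if (pb <= pa) stop("truncation interval has no mass", call. = FALSE)
  u <- stats::runif(n)
  stats::qnorm(pa + u * (pb - pa), mu, sd)
}

#' Draw per-subject true positive fractions for one group
#'
#' Samples subject-level true antigen-positive fractions from the group's
#' mean-calibrated truncated normal (parameters in percent, result as
#' proportions in \[0, 1\]).
#'
#' @param config A [cohort_config()].
#' @param condition Group label (`"control"`, `"BM"`, `"UCMD"`).
#' @param permeabilised Logical staining status.
#' @param n Number of subjects to draw.
#' @param seed Integer seed.
#' @return Numeric vector of `n` fractions inside the group range / 100.
#' @export
draw_group_fractions <- function(config, condition, permeabilised, n,
                                 seed = config$base_seed) {
  row <- cohort_group_row(config, condition, permeabilised)
  mu <- calibrate_truncnorm(row$mean_pct, row$sd_pct, row$low_pct, row$high_pct)
  with_seed(seed, rtruncnorm(n, mu, row$sd_pct, row$low_pct, row$high_pct)) / 100
}
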