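# Likelihood machinery for fraction-vs-time trajectories.
#
# Measurement model: at each sampling time the cytometer classifies n events
# of which x fall in the fluorescent gate, so the natural likelihood is
# binomial in (x, n) with success probability given by the mean model
# (logistic or exponential fraction dynamics). When only fractions and event
# totals are available, a Gaussian approximation with per-point variance
# p(1-p)/n is used instead. f0 is fixed to the measured t = 0 fraction
# (smoothed (x+0.5)/(n+1) when x = 0, so the logistic model, which divides
# by f0, stays evaluable) and the t = 0 point is excluded from the
# likelihood sum; both candidate models are treated identically, so AICc
# comparisons are like for like.

# Normalise a trajectory table to (t, x, n, fraction) with the t = 0 row
# split out. Accepts recombined/total (simulator output), x/n, or
# fraction (+ n or total).
prep_trajectory <- function(trajectory) {
  d <- as_tibble(trajectory)
  if (!"time_h" %in% names(d)) abort("trajectory needs a `time_h` column.")
  if ("recombined" %in% names(d) && !"x" %in% names(d)) d$x <- d$recombined
  if ("total" %in% names(d) && !"n" %in% names(d)) d$n <- d$total
  has_counts <- all(c("x", "n") %in% names(d))
  if (!has_counts && !all(c("fraction", "n") %in% names(d))) {
    abort("trajectory needs counts (`x`/`n` or `recombined`/`total`) or `fraction` plus `n`.")
  }
  if (!has_counts) d$x <- d$fraction * d$n
  d$fraction <- d$x / d$n
  d <- d[order(d$time_h), ]
  if (d$time_h[1] != 0) abort("trajectory must include a t = 0 measurement (f0 is fixed from it).")
  x0 <- d$x[1]; n0 <- d$n[1]
  f0 <- if (x0 == 0 || x0 == n0) (x0 + 0.5) / (n0 + 1) else x0 / n0
  rest <- d[-1, , drop = FALSE]
  list(
    t = rest$time_h, x = rest$x, n = rest$n, fraction = rest$fraction,
    f0 = f0, f0_smoothed = (x0 == 0 || x0 == n0),
    has_counts = has_counts, n_obs = nrow(rest),
    fmax_lower = max(d$fraction)
  )
}

# Log-likelihood (binomial kernel, or Gaussian fallback) of predicted
# fractions p at the prepared points. Predictions outside (0, 1) with
# discordant counts give -Inf.
loglik_points <- function(p, prep) {
  if (any(!is.finite(p))) return(-Inf)
  if (prep$has_counts) {
    ll <- numeric(length(p))
    hard0 <- p <= 0
    hard1 <- p >= 1
    bad <- (hard0 & prep$x > 0) | (hard1 & prep$x < prep$n) | p < 0 | p > 1
    if (any(bad)) return(-Inf)
    ok <- !hard0 & !hard1
    ll[ok] <- prep$x[ok] * log(p[ok]) + (prep$n[ok] - prep$x[ok]) * log1p(-p[ok])
    sum(ll)
  } else {
    ph <- pmin(pmax(prep$fraction, 0.5 / prep$n), 1 - 0.5 / prep$n)
    v <- ph * (1 - ph) / prep$n
    sum(stats::dnorm(prep$fraction, mean = p, sd = sqrt(v), log = TRUE))
  }
}

#' Log-likelihood of a fraction trajectory under a switching model
#'
#' Binomial log-likelihood kernel
#' \eqn{\sum_i x_i \ln p_i + (n_i - x_i)\ln(1 - p_i)} on gated counts
#' (the constant binomial coefficient is omitted), or a Gaussian
#' approximation on fractions with per-point variance \eqn{\hat p(1-\hat p)/n}
#' when only fractions are available. The t = 0 point fixes `f0` and is not
#' part of the sum. Predicted fractions of exactly 0 or 1 that contradict the
#' counts yield `-Inf`.
#'
#' @param trajectory Tibble with `time_h` and counts (`recombined`/`total` or
#'   `x`/`n`) or `fraction` plus `n`; must include a t = 0 row.
#' @param model `"logistic"` or `"exponential"`.
#' @param k Switching rate, per hour.
#' @param fmax Saturation fraction (logistic model only).
#' @param f0 Override for the initial fraction; default: measured at t = 0.
#' @return The log-likelihood (a single number; `-Inf` if the parameters are
#'   inconsistent with the data).
#' @export
switching_loglik <- function(trajectory, model = c("logistic", "exponential"),
                             k, fmax = NULL, f0 = NULL) {
  model <- match.arg(model)
  prep <- prep_trajectory(trajectory)
  f0 <- f0 %||% prep$f0
  p <- if (model == "logistic") {
    if (is.null(fmax)) abort("`fmax` is required for the logistic model.")
    logistic_fraction(prep$t, f0, fmax, k)
  } else {
    f0 * exp(k * prep$t)
  }
  loglik_points(p, prep)
}

#' Corrected Akaike information criterion
#'
#' \deqn{AICc = -2\,\ell_{max} + 2p + \frac{2p(p+1)}{n - p - 1}.}
#' Lower is better; the correction term penalises parameters more strongly at
#' small sample sizes and requires `n_obs > n_params + 1`.
#'
#' @param max_loglik Maximised log-likelihood.
#' @param n_params Number of fitted parameters.
#' @param n_obs Number of observations entering the likelihood.
#' @return The AICc value.
#' @examples
#' aicc(-10, 2, 8) # 26.4
#' @export
aicc <- function(max_loglik, n_params, n_obs) {
  if (n_obs <= n_params + 1) {
    abort(sprintf("AICc undefined: n_obs (%d) must exceed n_params + 1 (%d).",
                  n_obs, n_params + 1))
  }
  -2 * max_loglik + 2 * n_params + 2 * n_params * (n_params + 1) / (n_obs - n_params - 1)
}
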