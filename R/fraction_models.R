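#' Logistic mean dynamics of the recombined-cell fraction
#'
#' Closed-form solution of the logistic growth of the fraction `f` of
#' recombined (fluorescent) cells,
#' \deqn{f(t) = \frac{f_{max}}{1 + (f_{max}/f_0 - 1)\, e^{-k t}},}
#' which solves \eqn{df/dt = k f (1 - f/f_{max})}. `f0` is the fraction at
#' time 0, `fmax` the saturation fraction, and `k` the per-hour recombination
#' rate. The curve is non-decreasing in `t` and bounded above by `fmax`.
#'
#' @param t Time in hours (vectorised), `t >= 0`.
#' @param f0 Initial fraction, in `(0, 1]`; must not exceed `fmax`. The model
#'   divides by `f0`, so an exactly zero initial fraction is a domain error
#'   (smooth zero counts first, see [estimate_fraction()]).
#' @param fmax Saturation fraction in `(0, 1]`.
#' @param k Recombination rate, per hour, `>= 0`.
#' @return Fractions in `[f0, fmax]`, same length as `t`.
#' @examples
#' logistic_fraction(6, f0 = 0.001, fmax = 0.9, k = 0.5)
#' @seealso [exponential_fraction()] for the small-`f` limit.
#' @export
logistic_fraction <- function(t, f0, fmax, k) {
  assert_scalar_number(f0, "f0")
  assert_scalar_number(fmax, "fmax")
  assert_scalar_number(k, "k", min = 0)
  if (f0 <= 0) abort("`f0` must be > 0: the logistic fraction divides by `f0`.")
  if (f0 > fmax) abort("`f0` must not exceed `fmax`.")
  if (fmax > 1) abort("`fmax` must be <= 1.")
  if (any(t < 0)) abort("`t` must be >= 0.")
  fmax / (1 + (fmax / f0 - 1) * exp(-k * t))
}

#' Exponential early-time approximation of the recombined fraction
#'
#' Leading term of the logistic dynamics in the small parameter `f/fmax`:
#' \eqn{f(t) = f_0 e^{k t}}. Has one fewer parameter than the logistic
#' model, which matters when `f` stays far below saturation and `fmax` is
#' not identifiable.
#'
#' Values above 1 are possible for a pure exponential; they are returned
#' (so optimisers can see the misfit) but with a warning, since a fraction
#' cannot exceed 1.
#'
#' @param t Time in hours (vectorised).
#' @param f0 Initial fraction, `> 0`.
#' @param k Recombination rate, per hour, `>= 0`.
#' @return `f0 * exp(k * t)`.
#' @examples
#' exponential_fraction(10, f0 = 0.001, k = 0.2)
#' @export
exponential_fraction <- function(t, f0, k) {
  assert_scalar_number(f0, "f0")
  assert_scalar_number(k, "k", min = 0)
  if (f0 <= 0) abort("`f0` must be > 0.")
  out <- f0 * exp(k * t)
  if (any(out > 1)) {
    warn("exponential_fraction() exceeds 1 at some times; a fraction cannot exceed 1.")
  }
  out
}
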