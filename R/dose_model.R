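#' Hill-type dose model for the switching rate
#'
#' Ground-truth generator mapping inducer concentration to a per-hour
#' switching rate,
#' \deqn{k(c) = k_{leak} + k_{max} \frac{c^n}{c^n + K_{half}^n}.}
#' This functional form exists only to generate synthetic dose--response
#' data with a known monotone truth; the inference side estimates one rate
#' per concentration and never assumes a parametric dose curve.
#'
#' @param k_max Saturating induced rate, per hour (> 0).
#' @param K_half Half-saturation concentration, molar (> 0).
#' @param hill_n Hill coefficient (> 0).
#' @param k_leak Basal (leakage) rate at zero inducer, per hour (>= 0).
#' @return An object of class `dose_model`.
#' @examples
#' dm <- dose_model(k_max = 0.6, K_half = 5e-6, hill_n = 1.5, k_leak = 1e-4)
#' dose_response_rates(dm, c(0, 5e-6, 1e-4))
#' @export
dose_model <- function(k_max = 0.6, K_half = 5e-6, hill_n = 1.5, k_leak = 0) {
  assert_scalar_number(k_max, "k_max", min = 0)
  assert_scalar_number(K_half, "K_half")
  assert_scalar_number(hill_n, "hill_n")
  assert_scalar_number(k_leak, "k_leak", min = 0)
  if (K_half <= 0 || hill_n <= 0) abort("`K_half` and `hill_n` must be > 0.")
  structure(
    list(k_max = k_max, K_half = K_half, hill_n = hill_n, k_leak = k_leak),
    class = "dose_model"
  )
}

#' Evaluate a dose model on a concentration ladder
#'
#' @param model A [dose_model()].
#' @param concentrations Inducer concentrations, molar, `>= 0`.
#' @return A tibble with columns `concentration` and `k` (per hour);
#'   `k` is non-decreasing in concentration and `k(0) = k_leak`.
#' @export
dose_response_rates <- function(model, concentrations) {
  if (!inherits(model, "dose_model")) abort("`model` must be a dose_model().")
  if (any(concentrations < 0)) abort("`concentrations` must be >= 0.")
  cn <- concentrations^model$hill_n
  tibble(
    concentration = concentrations,
    k = model$k_leak + model$k_max * ifelse(
      is.infinite(cn), 1, cn / (cn + model$K_half^model$hill_n)
    )
  )
}
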