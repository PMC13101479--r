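# Shared fixture builders and independent oracles, built in code at test time.

# Binomial cytometry sampling of a deterministic logistic population:
# 7-point trajectory table with counts, the measurement model the fitters
# assume.
sampled_trajectory <- function(k, fmax, f0 = 0.01, t_grid = seq(0, 16, length.out = 7),
                               n_events = 2e4, seed = 1) {
  withr::with_seed(seed, {
    p <- logistic_fraction(t_grid, f0, fmax, k)
    tibble::tibble(
      time_h = t_grid,
      x = rbinom(length(t_grid), n_events, p),
      n = n_events
    )
  })
}

# Noiseless fraction trajectory (Gaussian-likelihood path).
exact_exp_trajectory <- function(k, f0, t_grid, n = 1e4) {
  tibble::tibble(time_h = t_grid, fraction = f0 * exp(k * t_grid), n = n)
}

# Minimal hand-built gate (threshold geometry known exactly).
manual_gate <- function(fsc_low, fl1_low, q = 0.999) {
  structure(
    list(fsc_low = fsc_low, fl1_low = fl1_low, q = q, fsc_quantile = 0.01,
         control_id = "manual", n_control = 1000L),
    class = "lox_gate"
  )
}

# Deterministic two-type competition recursion: per-generation frequency of
# the disfavoured (recombined) type under selection coefficient s.
competition_recursion <- function(f0, s, n_generations) {
  f <- numeric(n_generations + 1)
  f[1] <- f0
  for (g in seq_len(n_generations)) f[g + 1] <- f[g] * (1 - s) / (1 - s * f[g])
  f
}
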