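#' Summarise selected fits across technical replicates
#'
#' Pointwise mean of the best-fit fraction curves, their min--max envelope,
#' and the minimum / mean / maximum estimated rates across replicates, as
#' used to report per-condition rate estimates and plot replicate bands.
#'
#' @param fits A list of `switch_fit` objects (the selected fit of each
#'   technical replicate).
#' @param t_grid Times (hours) on which to evaluate the curves.
#' @return An object of class `switch_ensemble`: list with `curves` (tibble
#'   `time_h`, `mean`, `min`, `max`), `rates` (tibble `replicate`, `model`,
#'   `k`), and `k_min`, `k_mean`, `k_max`.
#' @examples
#' t1 <- simulate_switching(1e4, 0.01, 0.3, 0:8, fmax = 0.9, seed = 1)
#' t2 <- simulate_switching(1e4, 0.01, 0.3, 0:8, fmax = 0.9, seed = 2)
#' ensemble_summary(list(fit_exponential(t1), fit_exponential(t2)), 0:8)
#' @export
ensemble_summary <- function(fits, t_grid) {
  if (inherits(fits, "switch_fit")) fits <- list(fits)
  if (length(fits) < 1) abort("at least one fit is required.")
  if (!all(vapply(fits, inherits, logical(1), "switch_fit"))) {
    abort("`fits` must be switch_fit objects.")
  }
  curves <- vapply(fits, function(f) predict(f, t_grid), numeric(length(t_grid)))
  curves <- matrix(curves, nrow = length(t_grid))
  ks <- vapply(fits, function(f) f$k, numeric(1))
  structure(
    list(
      curves = tibble(
        time_h = t_grid,
        mean = rowMeans(curves),
        min = apply(curves, 1, min),
        max = apply(curves, 1, max)
      ),
      rates = tibble(
        replicate = seq_along(fits),
        model = vapply(fits, function(f) f$model, character(1)),
        k = ks
      ),
      k_min = min(ks), k_mean = mean(ks), k_max = max(ks),
      n_replicates = length(fits)
    ),
    class = "switch_ensemble"
  )
}

#' @export
print.switch_ensemble <- function(x, ...) {
  cat(sprintf("<switch_ensemble: %d replicate(s)>\n", x$n_replicates))
  cat(sprintf("  k (per hour): min %.4g, mean %.4g, max %.4g\n",
              x$k_min, x$k_mean, x$k_max))
  invisible(x)
}

#' @export
tidy.switch_ensemble <- function(x, ...) x$rates

#' @export
glance.switch_ensemble <- function(x, ...) {
  tibble(k_min = x$k_min, k_mean = x$k_mean, k_max = x$k_max,
         n_replicates = x$n_replicates)
}

#' Fit every replicate of a dose--response experiment and summarise rates
#'
#' Groups a trajectory table by concentration and replicate, runs the full
#' per-replicate fit-and-select procedure ([fit_switching_rate()]), and
#' returns the per-concentration rate summary (min / mean / max across
#' technical replicates) — the tabular form of a pointwise dose--response
#' curve.
#'
#' @param trajectories Tibble with columns `treatment` (inducer
#'   concentration, molar), `replicate`, `time_h`, and counts
#'   (`recombined`/`total` or `x`/`n`).
#' @param seed Optional global seed; each replicate fit gets a derived
#'   sub-seed.
#' @param ... Passed to [fit_switching_rate()].
#' @return A tibble `concentration`, `k_min`, `k_mean`, `k_max`,
#'   `n_replicates`, with the selected fits in attribute `"fits"`.
#' @export
fit_dose_response <- function(trajectories, seed = NULL, ...) {
  d <- as_tibble(trajectories)
  if (!all(c("treatment", "replicate", "time_h") %in% names(d))) {
    abort("`trajectories` needs columns treatment, replicate, time_h.")
  }
  groups <- d |> dplyr::distinct(.data$treatment, .data$replicate)
  fits <- purrr::pmap(groups, function(treatment, replicate) {
    tr <- d[d$treatment == treatment & d$replicate == replicate, ]
    sub_seed <- if (is.null(seed)) NULL else {
      derive_seed(seed, which(groups$treatment == treatment &
                                groups$replicate == replicate)[1])
    }
    fit_switching_rate(tr, concentration = treatment, seed = sub_seed, ...)
  })
  groups$k <- vapply(fits, function(f) f$k, numeric(1))
  out <- groups |>
    dplyr::group_by(concentration = .data$treatment) |>
    dplyr::summarise(
      k_min = min(.data$k), k_mean = mean(.data$k), k_max = max(.data$k),
      n_replicates = dplyr::n(), .groups = "drop"
    ) |>
    dplyr::arrange(.data$concentration)
  attr(out, "fits") <- fits
  out
}
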