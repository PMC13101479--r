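#' Two-sided Welch's t-test on two groups of readouts
#'
#' Unequal-variance t statistic with Welch--Satterthwaite degrees of freedom
#' (delegated to [stats::t.test()]), returned as a tidy one-row tibble. Used
#' to compare biosensor readouts (gated fractions or median fluorescence)
#' between successive inducer concentrations within a biological replicate.
#'
#' @param a,b Numeric readout vectors, each with at least 2 values.
#' @return A one-row tibble: `t`, `df`, `p`.
#' @examples
#' welch_test(c(0.10, 0.12, 0.11), c(0.20, 0.22, 0.21))
#' @export
welch_test <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) {
    abort("each group needs at least 2 values for a Welch t-test.")
  }
  if (var(a) == 0 && var(b) == 0) {
    # degenerate: no within-group variance; identical means -> no evidence
    if (mean(a) == mean(b)) return(tibble(t = 0, df = length(a) + length(b) - 2, p = 1))
    abort("zero variance in both groups with different means: t statistic undefined.")
  }
  ht <- t.test(a, b, var.equal = FALSE, alternative = "two.sided")
  tibble(t = unname(ht$statistic), df = unname(ht$parameter), p = ht$p.value)
}

#' Combine independent p-values with Fisher's method
#'
#' \eqn{X = -2 \sum_i \ln p_i} follows a chi-square distribution with `2 m`
#' degrees of freedom under the null when the `m` p-values are independent
#' and uniform; the combined p is the upper tail. Exact zeros are floored at
#' `1e-300` with an explicit warning (never silently), since `ln 0` diverges.
#'
#' @param p_values p-values in `(0, 1]`; at least one.
#' @return A one-row tibble: `chi2`, `df`, `p`.
#' @examples
#' fisher_combine(c(0.5, 0.5, 0.5))
#' @export
fisher_combine <- function(p_values) {
  if (length(p_values) < 1) abort("at least one p-value is required.")
  if (any(!is.finite(p_values)) || any(p_values < 0) || any(p_values > 1)) {
    abort("p-values must lie in [0, 1].")
  }
  if (any(p_values == 0)) {
    warn("p-value(s) of exactly 0 floored at 1e-300 before taking logs.")
    p_values <- pmax(p_values, 1e-300)
  }
  chi2 <- -2 * sum(log(p_values))
  df <- 2 * length(p_values)
  tibble(chi2 = chi2, df = df, p = pchisq(chi2, df, lower.tail = FALSE))
}

#' Detection ladder: Welch tests per step, Fisher-combined across experiments
#'
#' For each adjacent pair of inducer concentrations, a two-sided Welch t-test
#' compares the technical-replicate readouts within each biological replicate
#' (experiment); the per-experiment p-values for the same step are then
#' combined across experiments with Fisher's method. The lowest detected
#' concentration is the smallest concentration whose step-up-from-previous
#' combined p falls below `alpha`.
#'
#' No correction is applied across ladder steps by default (combination
#' happens across experiments per step only); an optional Holm adjustment
#' across steps is available via `holm = TRUE`.
#'
#' @param readouts Tibble with columns `experiment`, `concentration`,
#'   and `value` (one row per technical replicate); >= 2 technical replicates
#'   per concentration per experiment.
#' @param alpha Detection threshold on the combined p (default 0.05).
#' @param exclude Optional experiment ids to leave out (e.g. a replicate run
#'   under a different protocol duration).
#' @param holm Apply a Holm adjustment across ladder steps (default `FALSE`).
#' @return A list with `steps` (tibble: `c_low`, `c_high`, per-experiment
#'   p-values nested in `p_by_experiment`, `chi2`, `df`, `p_combined`) and
#'   `lowest_detected` (concentration, or `NA` if no step is significant).
#' @examples
#' ro <- tidyr::expand_grid(experiment = 1:3, concentration = c(0, 15e-9), rep = 1:3)
#' ro$value <- stats::rnorm(nrow(ro), mean = ifelse(ro$concentration > 0, 0.2, 0.1), sd = 0.01)
#' detection_ladder(ro)
#' @export
detection_ladder <- function(readouts, alpha = 0.05, exclude = NULL, holm = FALSE) {
  d <- as_tibble(readouts)
  need <- c("experiment", "concentration", "value")
  if (!all(need %in% names(d))) {
    abort(sprintf("`readouts` needs columns %s.", paste(need, collapse = ", ")))
  }
  if (!is.null(exclude)) d <- d[!d$experiment %in% exclude, ]
  concs <- sort(unique(d$concentration))
  if (length(concs) < 2) abort("at least two concentrations are required.")
  experiments <- sort(unique(d$experiment))

  # every experiment must cover every concentration
  cover <- tidyr::expand_grid(experiment = experiments, concentration = concs)
  have <- dplyr::distinct(d, .data$experiment, .data$concentration)
  gaps <- dplyr::anti_join(cover, have, by = c("experiment", "concentration"))
  if (nrow(gaps) > 0) {
    abort(paste0(
      "missing concentration levels: ",
      paste(sprintf("experiment %s @ %g", gaps$experiment, gaps$concentration),
            collapse = "; ")
    ))
  }

  steps <- purrr::map(seq_len(length(concs) - 1), function(i) {
    c_lo <- concs[i]; c_hi <- concs[i + 1]
    p_exp <- vapply(experiments, function(e) {
      a <- d$value[d$experiment == e & d$concentration == c_lo]
      b <- d$value[d$experiment == e & d$concentration == c_hi]
      welch_test(a, b)$p
    }, numeric(1))
    comb <- fisher_combine(p_exp)
    tibble(
      c_low = c_lo, c_high = c_hi,
      p_by_experiment = list(setNames(p_exp, experiments)),
      chi2 = comb$chi2, df = comb$df, p_combined = comb$p
    )
  }) |> dplyr::bind_rows()

  if (holm) steps$p_combined <- stats::p.adjust(steps$p_combined, method = "holm")
  hit <- which(steps$p_combined < alpha)
  list(
    steps = steps,
    lowest_detected = if (length(hit)) steps$c_high[min(hit)] else NA_real_,
    alpha = alpha
  )
}

#' Type-I calibration of the detection ladder on null data
#'
#' Simulates the full Welch + Fisher detection step under the null (all
#' concentrations share one readout distribution) and reports how often the
#' combined p falls below `alpha` — the realised false-detection rate of one
#' ladder step.
#'
#' @param n_sims Number of null simulations.
#' @param n_experiments Biological replicates per simulation.
#' @param n_replicates Technical replicates per group.
#' @param alpha Detection threshold.
#' @param sd Readout noise sd of the shared null distribution.
#' @param seed Optional integer seed.
#' @return A list: `rate` (realised type-I error), `n_sims`, and the vector
#'   of combined p-values `p`.
#' @export
calibrate_detection <- function(n_sims = 2000, n_experiments = 3, n_replicates = 3,
                                alpha = 0.05, sd = 1, seed = NULL) {
  with_seed_(seed, {
    p <- vapply(seq_len(n_sims), function(i) {
      p_exp <- vapply(seq_len(n_experiments), function(e) {
        welch_test(rnorm(n_replicates, 0, sd), rnorm(n_replicates, 0, sd))$p
      }, numeric(1))
      fisher_combine(p_exp)$p
    }, numeric(1))
    list(rate = mean(p < alpha), n_sims = n_sims, p = p)
  })
}

#' Leakage: recombined fraction added in the absence of inducer
#'
#' Per experiment, the added recombined fraction is the zero-inducer endpoint
#' estimate minus the paired pre-exposure baseline estimate; the summary is
#' the median across experiments. Negative values (sampling noise) are kept
#' as-is.
#'
#' @param baseline,endpoint Tibbles (or vectors) of paired fraction
#'   estimates: either numeric vectors of `p_hat`, or [estimate_fraction()]
#'   rows bound together, matched by position.
#' @return A list: `per_experiment` tibble (`experiment`, `added_fraction`)
#'   and `median_added_fraction`.
#' @examples
#' leakage_summary(c(0.001, 0.0012, 0.0009), c(0.0015, 0.0023, 0.0029))
#' @export
leakage_summary <- function(baseline, endpoint) {
  p0 <- if (is.data.frame(baseline)) baseline$p_hat else baseline
  p1 <- if (is.data.frame(endpoint)) endpoint$p_hat else endpoint
  if (length(p0) != length(p1)) abort("baseline and endpoint must be paired (same length).")
  added <- p1 - p0
  list(
    per_experiment = tibble(experiment = seq_along(added), added_fraction = added),
    median_added_fraction = median(added)
  )
}

#' Generations per serial-passage cycle
#'
#' A culture diluted `dilution_factor`-fold that regrows from density
#' `rho_prev / dilution_factor` to density `rho` has doubled
#' \eqn{\log_2(\rho_i \cdot D / \rho_{i-1})} times. With regrowth to the same
#' density (carrying capacity) this is exactly `log2(D)` per cycle, e.g.
#' `log2(1e4)` is about 13.3 generations for a 10,000-fold dilution.
#'
#' When only the dilution factor is known (`rho` omitted), regrowth to the
#' previous density is assumed (dilution-only mode).
#'
#' @param dilution_factor Fold-dilution per cycle (> 0), scalar or per-cycle
#'   vector.
#' @param rho Post-growth cell density of each cycle (> 0); optional.
#' @param rho_prev Density before dilution of each cycle; defaults to the
#'   previous element of `rho` (with `rho_prev[1]` the pre-passaging
#'   density).
#' @param n_cycles Number of cycles for dilution-only mode (used when `rho`
#'   is omitted).
#' @return A tibble: `cycle`, `generations`, `cumulative_generations`.
#' @examples
#' generations(1e4, rho = c(1e9, 1e9, 1e9, 1e9), rho_prev = c(1e9, 1e9, 1e9, 1e9))
#' generations(1e4, n_cycles = 4) # dilution-only mode
#' @export
generations <- function(dilution_factor, rho = NULL, rho_prev = NULL, n_cycles = NULL) {
  if (any(dilution_factor <= 0)) abort("`dilution_factor` must be > 0.")
  if (is.null(rho)) {
    if (is.null(n_cycles)) abort("give `rho` or `n_cycles`.")
    rho <- rep(1, n_cycles)
    rho_prev <- rep(1, n_cycles)
  }
  if (is.null(rho_prev)) rho_prev <- c(rho[1], head(rho, -1))
  if (length(rho_prev) != length(rho)) abort("`rho` and `rho_prev` must have equal length.")
  if (any(rho <= 0) || any(rho_prev <= 0)) abort("densities must be > 0.")
  g <- log2(rho * rep_len(dilution_factor, length(rho)) / rho_prev)
  tibble(
    cycle = seq_along(g),
    generations = g,
    cumulative_generations = cumsum(g)
  )
}

#' Track reporter stability across passages
#'
#' Relative change of the fluorescent-cell fraction at each passage versus
#' the post-exposure reference point (the fraction measured right after the
#' transient inducer exposure). A decline of 0.6 means the fraction dropped
#' by 60% relative to the reference. Monotonicity is not assumed.
#'
#' @param track Tibble with columns `phase` (labels such as
#'   `"pre_induction"`, `"post_exposure"`, `"passage_1"`, ...), `p_hat`, and
#'   optionally `replicate` and `generations`.
#' @param reference Phase label used as reference (default
#'   `"post_exposure"`); its fraction must be > 0.
#' @return The input tibble with added columns `reference_fraction`,
#'   `relative_change` (`p_hat / reference - 1`; negative = decline), plus a
#'   pooled summary in attribute `"pooled"` when a `replicate` column is
#'   present.
#' @export
stability_track <- function(track, reference = "post_exposure") {
  d <- as_tibble(track)
  if (!all(c("phase", "p_hat") %in% names(d))) {
    abort("`track` needs columns `phase` and `p_hat`.")
  }
  if (!reference %in% d$phase) {
    abort(sprintf("reference phase '%s' not present in `track`.", reference))
  }
  if (!"replicate" %in% names(d)) d$replicate <- "r1"
  d <- d |>
    dplyr::group_by(.data$replicate) |>
    dplyr::mutate(reference_fraction = .data$p_hat[.data$phase == reference][1]) |>
    dplyr::ungroup()
  if (any(d$reference_fraction <= 0)) {
    abort("reference fraction is 0; relative decline undefined.")
  }
  d$relative_change <- d$p_hat / d$reference_fraction - 1
  pooled <- d |>
    dplyr::group_by(.data$phase) |>
    dplyr::summarise(
      mean_relative_change = mean(.data$relative_change),
      n = dplyr::n(), .groups = "drop"
    )
  attr(d, "pooled") <- pooled
  d
}

#' Convert a mass concentration in ppb to nanomolar
#'
#' `1 ppb = 1 ug/L`; dividing by the molar mass (g/mol) gives umol/m3 =
#' nmol/L. The default molar mass is elemental arsenic (74.92 g/mol), the
#' analyte of the arsenite biosensor: the 10 ppb drinking-water limit is
#' about 133 nM As.
#'
#' @param ppb Mass concentration in ppb (ug/L).
#' @param molar_mass Molar mass in g/mol (default 74.92, elemental As).
#' @return Concentration in nmol/L.
#' @examples
#' ppb_to_nM(10) # ~133 nM
#' @export
ppb_to_nM <- function(ppb, molar_mass = 74.92) {
  if (any(molar_mass <= 0)) abort("`molar_mass` must be > 0.")
  1000 * ppb / molar_mass
}
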