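#' Single-cell fluorescence model for synthetic cytometry events
#'
#' Describes the per-genotype FL1-A (fluorescence area) distributions and the
#' shared FSC-A / SSC-A (scatter) distributions used by
#' [simulate_cytometry_events()]. All channels are log-normal, the standard
#' first-order approximation for cytometry intensity distributions; only the
#' ordering and separability of the dim and bright populations matter for
#' gating.
#'
#' `immature_fraction` models cells that recombined recently and have not yet
#' expressed and matured the fluorescent protein: that proportion of
#' recombined cells is drawn from the dim (unrecombined-like) FL1-A
#' distribution, so they are invisible to a fluorescence gate.
#'
#' @param fl1_meanlog_dim,fl1_sdlog_dim Log-scale mean and sd of FL1-A for
#'   unrecombined (dim) cells.
#' @param fl1_meanlog_bright,fl1_sdlog_bright Same for recombined (bright)
#'   cells; `fl1_meanlog_bright` must exceed `fl1_meanlog_dim`.
#' @param fsc_meanlog,fsc_sdlog Shared FSC-A log-scale parameters.
#' @param ssc_meanlog,ssc_sdlog Shared SSC-A log-scale parameters.
#' @param immature_fraction Fraction in `[0, 1]` of recombined cells drawn
#'   from the dim FL1-A distribution.
#' @return An object of class `cytometry_model`.
#' @examples
#' cytometry_model(immature_fraction = 0.2)
#' @export
cytometry_model <- function(fl1_meanlog_dim = log(100), fl1_sdlog_dim = 0.45,
                            fl1_meanlog_bright = log(20000), fl1_sdlog_bright = 0.45,
                            fsc_meanlog = log(50000), fsc_sdlog = 0.5,
                            ssc_meanlog = log(20000), ssc_sdlog = 0.6,
                            immature_fraction = 0) {
  if (fl1_sdlog_dim <= 0 || fl1_sdlog_bright <= 0 || fsc_sdlog <= 0 || ssc_sdlog <= 0) {
    abort("all log-sd parameters must be > 0.")
  }
  assert_fraction(immature_fraction, "immature_fraction")
  if (fl1_meanlog_bright <= fl1_meanlog_dim) {
    abort("`fl1_meanlog_bright` must exceed `fl1_meanlog_dim` (bright cells are brighter).")
  }
  structure(
    list(
      fl1_meanlog_dim = fl1_meanlog_dim, fl1_sdlog_dim = fl1_sdlog_dim,
      fl1_meanlog_bright = fl1_meanlog_bright, fl1_sdlog_bright = fl1_sdlog_bright,
      fsc_meanlog = fsc_meanlog, fsc_sdlog = fsc_sdlog,
      ssc_meanlog = ssc_meanlog, ssc_sdlog = ssc_sdlog,
      immature_fraction = immature_fraction
    ),
    class = "cytometry_model"
  )
}

#' @export
print.cytometry_model <- function(x, ...) {
  cat("<cytometry_model>\n")
  cat(sprintf("  FL1-A dim:    lognormal(meanlog = %.3f, sdlog = %.3f)\n",
              x$fl1_meanlog_dim, x$fl1_sdlog_dim))
  cat(sprintf("  FL1-A bright: lognormal(meanlog = %.3f, sdlog = %.3f)\n",
              x$fl1_meanlog_bright, x$fl1_sdlog_bright))
  cat(sprintf("  immature fraction of recombined cells: %.3f\n", x$immature_fraction))
  invisible(x)
}

#' Synthesise an event-level flow-cytometry table
#'
#' Draws `n_events` single-cell events from a two-genotype mixture: each event
#' is recombined with probability `fraction`; recombined cells are bright
#' except for a proportion `immature_fraction` drawn from the dim FL1-A
#' distribution (fluorophore not yet matured). Scatter channels are shared
#' between genotypes. True genotype and maturity labels are kept as hidden
#' ground truth for testing estimators; a real cytometer never reports them.
#'
#' @param fraction True recombined fraction in `[0, 1]`.
#' @param n_events Number of events (>= 1).
#' @param model A [cytometry_model()].
#' @param sample_id Label copied into the output.
#' @param seed Optional integer seed.
#' @return A tibble with columns `sample_id`, `fsc_a`, `ssc_a`, `fl1_a`,
#'   `true_recombined` (logical), `true_mature` (logical).
#' @examples
#' ev <- simulate_cytometry_events(0.05, 1000, seed = 1)
#' mean(ev$true_recombined)
#' @export
simulate_cytometry_events <- function(fraction, n_events, model = cytometry_model(),
                                      sample_id = "sample", seed = NULL) {
  assert_fraction(fraction, "fraction")
  assert_scalar_number(n_events, "n_events", min = 1)
  if (!inherits(model, "cytometry_model")) abort("`model` must be a cytometry_model().")
  n_events <- as.integer(n_events)

  with_seed_(seed, {
    recombined <- runif(n_events) < fraction
    mature <- recombined & (runif(n_events) >= model$immature_fraction)
    fl1 <- numeric(n_events)
    n_bright <- sum(mature)
    fl1[mature] <- rlnorm(n_bright, model$fl1_meanlog_bright, model$fl1_sdlog_bright)
    fl1[!mature] <- rlnorm(n_events - n_bright, model$fl1_meanlog_dim, model$fl1_sdlog_dim)
    tibble(
      sample_id = sample_id,
      fsc_a = rlnorm(n_events, model$fsc_meanlog, model$fsc_sdlog),
      ssc_a = rlnorm(n_events, model$ssc_meanlog, model$ssc_sdlog),
      fl1_a = fl1,
      true_recombined = recombined,
      true_mature = mature
    )
  })
}
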