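#' Derive a fluorescence gate from a non-fluorescent control sample
#'
#' Reproducible surrogate for a manually drawn cytometry gate: the lower
#' FL1-A boundary is placed so that it excludes the control (dark) strain,
#' i.e. at most `1 - q` of FSC-passing control events fall above it. A debris
#' cut on FSC-A is set at a low quantile of the control's FSC-A. Optionally
#' the FL1-A boundary is computed per FSC-A bin (a piecewise-constant
#' approximation of a sloped polygon boundary).
#'
#' @param control An event table (tibble with `fsc_a`, `fl1_a`, and
#'   optionally `sample_id`) measured on the non-fluorescent control strain;
#'   at least 1000 events.
#' @param q Tail quantile in `(0.5, 1)`; default 0.999. At most `1 - q` of
#'   FSC-passing control events lie above the returned boundary. Use
#'   stringent values (e.g. 0.9999) when target fractions are of order
#'   `1e-4`–`1e-3`, so the gate's false-positive tail sits well below the
#'   signal.
#' @param fsc_quantile Debris cut: quantile of control FSC-A used as the
#'   lower FSC-A threshold (default 0.01).
#' @param fsc_bins Optional number of FSC-A bins for a per-bin FL1-A
#'   boundary; `NULL` (default) gives a single threshold.
#' @return An object of class `lox_gate` with fields `fsc_low`, `fl1_low`
#'   (scalar threshold, or tibble `fsc_lo`/`fsc_hi`/`fl1_low` when binned),
#'   and provenance (`control_id`, `q`, `n_control`).
#' @examples
#' ctrl <- simulate_cytometry_events(0, 5000, seed = 1)
#' derive_gate(ctrl, q = 0.999)
#' @export
derive_gate <- function(control, q = 0.999, fsc_quantile = 0.01, fsc_bins = NULL) {
  check_event_table(control)
  if (nrow(control) < 1000) {
    abort(sprintf("`control` has %d events; at least 1000 are required to place a gate.",
                  nrow(control)))
  }
  if (!(q > 0.5 && q < 1)) abort("`q` must be in (0.5, 1).")
  fsc_low <- unname(quantile(control$fsc_a, fsc_quantile, type = 7))
  passing <- control[control$fsc_a >= fsc_low, ]

  if (is.null(fsc_bins)) {
    fl1_low <- unname(quantile(passing$fl1_a, q, type = 7))
  } else {
    breaks <- unique(quantile(passing$fsc_a, seq(0, 1, length.out = fsc_bins + 1)))
    bin <- cut(passing$fsc_a, breaks, include.lowest = TRUE, labels = FALSE)
    fl1_low <- tibble(
      fsc_lo = breaks[-length(breaks)],
      fsc_hi = breaks[-1],
      fl1_low = vapply(
        seq_len(length(breaks) - 1),
        function(b) unname(quantile(passing$fl1_a[bin == b], q, type = 7)),
        numeric(1)
      )
    )
  }
  structure(
    list(
      fsc_low = fsc_low, fl1_low = fl1_low, q = q, fsc_quantile = fsc_quantile,
      control_id = if ("sample_id" %in% names(control)) control$sample_id[1] else NA_character_,
      n_control = nrow(control)
    ),
    class = "lox_gate"
  )
}

#' @export
print.lox_gate <- function(x, ...) {
  cat("<lox_gate>\n")
  cat(sprintf("  debris cut: FSC-A >= %.4g (control quantile %.3g)\n", x$fsc_low, x$fsc_quantile))
  if (is.data.frame(x$fl1_low)) {
    cat(sprintf("  FL1-A boundary: per-FSC-bin (%d bins), tail quantile q = %g\n",
                nrow(x$fl1_low), x$q))
  } else {
    cat(sprintf("  FL1-A boundary: > %.4g, tail quantile q = %g\n", x$fl1_low, x$q))
  }
  cat(sprintf("  derived from control '%s' (%d events)\n", x$control_id, x$n_control))
  invisible(x)
}

check_event_table <- function(events) {
  if (!is.data.frame(events) || !all(c("fsc_a", "fl1_a") %in% names(events))) {
    abort("an event table needs at least columns `fsc_a` and `fl1_a`.")
  }
  if (nrow(events) < 1) abort("an event table needs at least one event.")
  if (!all(is.finite(events$fsc_a)) || !all(is.finite(events$fl1_a))) {
    abort("all channel values must be finite.")
  }
  invisible(events)
}

# FL1-A lower boundary evaluated at each event's FSC-A value.
fl1_boundary_at <- function(gate, fsc) {
  if (!is.data.frame(gate$fl1_low)) return(rep_len(gate$fl1_low, length(fsc)))
  b <- gate$fl1_low
  idx <- findInterval(fsc, c(b$fsc_lo[1], b$fsc_hi))
  idx <- pmin(pmax(idx, 1L), nrow(b))
  b$fl1_low[idx]
}

#' Classify events against a gate
#'
#' @param events An event table.
#' @param gate A [derive_gate()] result.
#' @return The event table with logical columns `pass_debris` (FSC-A above
#'   the debris cut) and `gated_positive` (FSC-passing and FL1-A above the
#'   boundary).
#' @export
apply_gate <- function(events, gate) {
  check_event_table(events)
  if (!inherits(gate, "lox_gate")) abort("`gate` must be a lox_gate.")
  events <- as_tibble(events)
  events$pass_debris <- events$fsc_a >= gate$fsc_low
  events$gated_positive <- events$pass_debris &
    events$fl1_a > fl1_boundary_at(gate, events$fsc_a)
  events
}

#' Estimate the fluorescent-cell fraction from gated events
#'
#' Counts FSC-passing events above the FL1-A boundary and reports the
#' fraction with its binomial standard error `sqrt(p (1 - p) / n)`. At the
#' boundary cases `x = 0` or `x = n` the Jeffreys-style smoothed estimator
#' `(x + 0.5) / (n + 1)` is used for both the point estimate and the error,
#' so downstream logistic fits (which divide by the t = 0 fraction) remain
#' evaluable.
#'
#' @param sample An event table.
#' @param gate A [derive_gate()] result.
#' @return A one-row tibble: `sample_id`, `x`, `n`, `p_hat`, `se`,
#'   `smoothed` (logical).
#' @examples
#' ctrl <- simulate_cytometry_events(0, 5000, seed = 1)
#' smp <- simulate_cytometry_events(0.05, 5000, seed = 2)
#' estimate_fraction(smp, derive_gate(ctrl))
#' @export
estimate_fraction <- function(sample, gate) {
  gated <- apply_gate(sample, gate)
  n <- sum(gated$pass_debris)
  if (n == 0) abort("no events pass the debris cut; cannot estimate a fraction.")
  x <- sum(gated$gated_positive)
  smoothed <- x == 0 || x == n
  p_hat <- if (smoothed) (x + 0.5) / (n + 1) else x / n
  tibble(
    sample_id = if ("sample_id" %in% names(sample)) sample$sample_id[1] else NA_character_,
    x = as.integer(x), n = as.integer(n),
    p_hat = p_hat,
    se = sqrt(p_hat * (1 - p_hat) / n),
    smoothed = smoothed
  )
}

#' Median single-cell fluorescence with bootstrap standard error
#'
#' The representative expression level for continuous (transcription-based)
#' reporters: median FL1-A over FSC-passing events, with a standard error
#' from the bootstrap distribution of the median.
#'
#' @param sample An event table with at least 100 FSC-passing events.
#' @param gate Optional [derive_gate()] result supplying the debris cut; when
#'   `NULL`, the debris cut is placed at `fsc_quantile` of the sample's own
#'   FSC-A.
#' @param n_boot Bootstrap replicates (>= 200; default 500).
#' @param fsc_quantile Debris-cut quantile used when `gate` is `NULL`.
#' @param seed Optional integer seed for the bootstrap.
#' @return A one-row tibble: `sample_id`, `median`, `se`, `n`, `n_boot`.
#' @export
estimate_median_fluorescence <- function(sample, gate = NULL, n_boot = 500,
                                         fsc_quantile = 0.01, seed = NULL) {
  check_event_table(sample)
  if (n_boot < 200) abort("`n_boot` must be >= 200.")
  fsc_low <- if (is.null(gate)) {
    unname(quantile(sample$fsc_a, fsc_quantile, type = 7))
  } else {
    gate$fsc_low
  }
  fl1 <- sample$fl1_a[sample$fsc_a >= fsc_low]
  n <- length(fl1)
  if (n < 100) abort(sprintf("only %d FSC-passing events; at least 100 required.", n))
  med <- median(fl1)
  boots <- with_seed_(seed, {
    vapply(seq_len(n_boot),
           function(i) median(fl1[sample.int(n, n, replace = TRUE)]),
           numeric(1))
  })
  tibble(
    sample_id = if ("sample_id" %in% names(sample)) sample$sample_id[1] else NA_character_,
    median = med, se = sd(boots), n = n, n_boot = as.integer(n_boot)
  )
}
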