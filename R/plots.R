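#' Plot a replicate ensemble: mean best-fit curve and min--max envelope
#'
#' @param object A [ensemble_summary()] result.
#' @param data Optional trajectory tibble (`time_h`, `fraction`) overlaid as
#'   points.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.switch_ensemble <- function(object, data = NULL, ...) {
  p <- ggplot2::ggplot(object$curves, ggplot2::aes(x = .data$time_h)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$min, ymax = .data$max),
                         alpha = 0.25) +
    ggplot2::geom_line(ggplot2::aes(y = .data$mean)) +
    ggplot2::labs(
      x = "Time (h)", y = "Fraction of fluorescent cells",
      title = sprintf("Mean best fit and min-max envelope (%d replicates)",
                      object$n_replicates)
    )
  if (!is.null(data)) {
    p <- p + ggplot2::geom_point(
      data = data, ggplot2::aes(x = .data$time_h, y = .data$fraction),
      inherit.aes = FALSE, size = 1
    )
  }
  p
}

#' Plot a pointwise dose--response of estimated switching rates
#'
#' Rate estimates per inducer concentration with min--max error bars across
#' technical replicates.
#'
#' @param dose_response A [fit_dose_response()] result (tibble with
#'   `concentration`, `k_min`, `k_mean`, `k_max`).
#' @return A ggplot.
#' @export
plot_dose_response <- function(dose_response) {
  ggplot2::ggplot(dose_response,
                  ggplot2::aes(x = .data$concentration, y = .data$k_mean)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$k_min, ymax = .data$k_max)) +
    ggplot2::labs(x = "Inducer concentration (M)",
                  y = expression(paste("Recombination rate ", k, " (", h^-1, ")")))
}

#' Plot events in FL1-A vs FSC-A space with the gate boundary
#'
#' @param events An event table.
#' @param gate A [derive_gate()] result.
#' @param max_points Subsample cap for plotting (default 20000).
#' @return A ggplot (log-log scales, gate boundary drawn).
#' @export
plot_gate <- function(events, gate, max_points = 20000) {
  check_event_table(events)
  if (nrow(events) > max_points) {
    events <- events[seq(1, nrow(events), length.out = max_points), ]
  }
  p <- ggplot2::ggplot(events, ggplot2::aes(x = .data$fsc_a, y = .data$fl1_a)) +
    ggplot2::geom_point(alpha = 0.2, size = 0.4) +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::geom_vline(xintercept = gate$fsc_low, linetype = 2) +
    ggplot2::labs(x = "FSC-A (a.u.)", y = "FL1-A (a.u.)")
  if (is.data.frame(gate$fl1_low)) {
    seg <- gate$fl1_low
    p <- p + ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$fsc_lo, xend = .data$fsc_hi,
                   y = .data$fl1_low, yend = .data$fl1_low),
      inherit.aes = FALSE, linetype = 2
    )
  } else {
    p <- p + ggplot2::geom_hline(yintercept = gate$fl1_low, linetype = 2)
  }
  p
}
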