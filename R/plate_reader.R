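#' Read a plate-reader export
#'
#' Two delimited-text dialects are supported. `"long"` has one row per
#' well, time and channel: columns `well`, `time_h`, `channel` (values
#' `od600` / `fluor`), `value`, plus optional `role` and `treatment`.
#' `"wide"` has one row per well and time: columns `well`, `time_h`,
#' `od600`, `fluor`, plus optional `role` and `treatment`. Wells without a
#' `role` column are assumed to be samples unless their id starts with "B".
#'
#' @param path File path.
#' @param format `"long"` or `"wide"`.
#' @return A plate series tibble: `well`, `role`, `treatment`, `time_h`,
#'   `od600`, `fluor`.
#' @export
read_plate <- function(path, format = c("long", "wide")) {
  format <- match.arg(format)
  raw <- readr::read_delim(path, show_col_types = FALSE, progress = FALSE)
  names(raw) <- tolower(names(raw))
  if (format == "long") {
    need <- c("well", "time_h", "channel", "value")
    if (!all(need %in% names(raw))) {
      abort(sprintf("long plate export needs columns %s.", paste(need, collapse = ", ")))
    }
    raw <- tidyr::pivot_wider(raw, names_from = "channel", values_from = "value")
  }
  if (!all(c("well", "time_h", "od600", "fluor") %in% names(raw))) {
    abort("plate export needs well, time_h, od600 and fluor.")
  }
  if (!"role" %in% names(raw)) {
    raw$role <- ifelse(grepl("^B", raw$well), "blank", "sample")
  }
  if (!"treatment" %in% names(raw)) raw$treatment <- NA
  check_plate(as_tibble(raw[c("well", "role", "treatment", "time_h", "od600", "fluor")]))
}

check_plate <- function(plate) {
  need <- c("well", "role", "time_h", "od600", "fluor")
  if (!is.data.frame(plate) || !all(need %in% names(plate))) {
    abort(sprintf("a plate series needs columns %s.", paste(need, collapse = ", ")))
  }
  if (!any(plate$role == "blank")) abort("a plate series needs at least one blank well.")
  if (!all(is.finite(plate$od600)) || !all(is.finite(plate$fluor))) {
    abort("all plate readings must be finite.")
  }
  tgrids <- split(plate$time_h, plate$well)
  ref <- tgrids[[1]]
  if (!all(vapply(tgrids, function(g) length(g) == length(ref) && all(g == ref), logical(1)))) {
    abort("all wells must share the same time grid.")
  }
  invisible(as_tibble(plate))
}

#' Per-time blank means
#'
#' Arithmetic mean of the blank (medium-only) wells at each time point, for
#' both channels; the background measure subtracted or divided out by the
#' normalization routines.
#'
#' @param plate A plate series (see [read_plate()] / [simulate_plate_reader()]).
#' @return A tibble `time_h`, `f_blank`, `od_blank`.
#' @export
blank_means <- function(plate) {
  plate <- check_plate(plate)
  plate |>
    dplyr::filter(.data$role == "blank") |>
    dplyr::group_by(.data$time_h) |>
    dplyr::summarise(
      f_blank = mean(.data$fluor),
      od_blank = mean(.data$od600),
      .groups = "drop"
    )
}

#' Blank-corrected relative fluorescence kinetics
#'
#' For each sample well `i` and time `t`, computes
#' \deqn{F'_i(t) = F_i(t)/F_i(0) - \bar F_{blank}(t)/\bar F_{blank}(0),}
#' \deqn{OD'_i(t) = OD_i(t) - \bar{OD}_{blank}(t),}
#' \deqn{r_i(t) = F'_i(t) / OD'_i(t),}
#' the per-biomass relative fluorescence. `r` is invariant under a common
#' multiplicative gain applied to all fluorescence readings.
#'
#' Time points where `OD'` does not exceed `eps` (no growth above blank,
#' so `r` is 0/0-degenerate) are masked: `r` is `NA`, `masked` is `TRUE`,
#' and a warning reports how many points were masked. They are never
#' silently zeroed or dropped.
#'
#' @param plate A plate series.
#' @param eps Guard for the `OD'` denominator, OD units (default `1e-3`).
#' @return A tibble `well`, `treatment`, `time_h`, `f_prime`, `od_prime`,
#'   `r`, `masked`, for sample wells.
#' @examples
#' traj <- tibble::tibble(time_h = 0:10, fraction = rep(0.2, 11))
#' rel <- relative_fluorescence(simulate_plate_reader(traj, seed = 1))
#' @export
relative_fluorescence <- function(plate, eps = 1e-3) {
  plate <- check_plate(plate)
  bl <- blank_means(plate)
  if (bl$f_blank[bl$time_h == min(bl$time_h)] <= 0) {
    abort("mean blank fluorescence at time 0 must be > 0.")
  }
  f_bl0 <- bl$f_blank[which.min(bl$time_h)]
  out <- plate |>
    dplyr::filter(.data$role == "sample") |>
    dplyr::left_join(bl, by = "time_h") |>
    dplyr::group_by(.data$well) |>
    dplyr::arrange(.data$time_h, .by_group = TRUE) |>
    dplyr::mutate(
      f0 = .data$fluor[1],
      f_prime = .data$fluor / .data$f0 - .data$f_blank / f_bl0,
      od_prime = .data$od600 - .data$od_blank
    ) |>
    dplyr::ungroup()
  if (any(out$f0 <= 0)) abort("every sample well needs fluorescence > 0 at time 0.")
  out$masked <- out$od_prime <= eps
  out$r <- ifelse(out$masked, NA_real_, out$f_prime / out$od_prime)
  if (any(out$masked)) {
    warn(sprintf(
      "%d of %d well-time points have OD' <= %g (no growth above blank); r set to NA.",
      sum(out$masked), nrow(out), eps
    ))
  }
  out[c("well", "treatment", "time_h", "f_prime", "od_prime", "r", "masked")]
}

#' Endpoint relative fluorescence
#'
#' Single-time-point variant used when only one read exists (no within-well
#' time normalization is possible): `F'_i(t) = F_i(t)/\bar F_{blank}(t) - 1`,
#' divided by `OD'_i(t)` as in [relative_fluorescence()].
#'
#' @param plate A plate series.
#' @param time Time point to evaluate (default: the last read).
#' @param eps Guard for the `OD'` denominator.
#' @return A tibble `well`, `treatment`, `time_h`, `value` for sample wells.
#' @export
endpoint_relative_fluorescence <- function(plate, time = NULL, eps = 1e-3) {
  plate <- check_plate(plate)
  time <- time %||% max(plate$time_h)
  at <- plate[plate$time_h == time, ]
  if (nrow(at) == 0) abort(sprintf("no readings at time %g h.", time))
  bl <- blank_means(at)
  if (bl$f_blank <= 0) abort("mean blank fluorescence must be > 0.")
  smp <- at[at$role == "sample", ]
  od_prime <- smp$od600 - bl$od_blank
  if (any(od_prime <= eps)) {
    abort(sprintf("OD' <= %g in wells: %s; endpoint value undefined there.",
                  eps, paste(smp$well[od_prime <= eps], collapse = ", ")))
  }
  tibble(
    well = smp$well, treatment = smp$treatment, time_h = time,
    value = (smp$fluor / bl$f_blank - 1) / od_prime
  )
}

#' Maximum specific growth rate from blank-corrected OD
#'
#' Convenience estimator (the study design only needs growth-rate
#' comparisons, not a mechanistic fit): the maximum slope of
#' `ln(OD')` over a sliding window of consecutive reads.
#'
#' @param plate A plate series.
#' @param window Number of consecutive points per window (default 5).
#' @param eps Only points with `OD' > eps` enter the fit.
#' @return A tibble `well`, `rate` (per hour), `t_start`, `t_end` (window
#'   location), for each sample well.
#' @export
growth_rate <- function(plate, window = 5, eps = 1e-3) {
  plate <- check_plate(plate)
  bl <- blank_means(plate)
  smp <- plate |>
    dplyr::filter(.data$role == "sample") |>
    dplyr::left_join(bl, by = "time_h") |>
    dplyr::mutate(od_prime = .data$od600 - .data$od_blank)
  one_well <- function(d, well) {
    d <- d[order(d$time_h), ]
    d <- d[d$od_prime > eps, ]
    if (nrow(d) < max(window, 5)) {
      abort(sprintf("well %s: only %d points with OD' > %g; >= %d required.",
                    well, nrow(d), eps, max(window, 5)))
    }
    y <- log(d$od_prime)
    t <- d$time_h
    n_win <- nrow(d) - window + 1
    slopes <- vapply(seq_len(n_win), function(i) {
      idx <- i:(i + window - 1)
      tc <- t[idx] - mean(t[idx])
      sum(tc * (y[idx] - mean(y[idx]))) / sum(tc^2)
    }, numeric(1))
    best <- which.max(slopes)
    tibble(rate = slopes[best], t_start = t[best], t_end = t[best + window - 1])
  }
  smp |>
    dplyr::group_by(.data$well) |>
    dplyr::group_modify(function(d, g) one_well(d, g$well)) |>
    dplyr::ungroup()
}
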