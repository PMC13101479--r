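#' Synthesise plate-reader OD600 and fluorescence kinetics
#'
#' Generates a long-format plate series for one treatment: `n_sample_wells`
#' culture wells following a shared switching trajectory, plus
#' `n_blank_wells` medium-only wells. OD600 follows logistic bulk growth on
#' top of a blank (medium) offset; well fluorescence is the blank background
#' plus per-cell brightness times the recombined-cell density
#' (`od * fraction`); both channels get additive Gaussian measurement noise.
#' Blank wells contain background only.
#'
#' @param trajectory A tibble with columns `time_h` and `fraction`
#'   (e.g. from [simulate_switching()] or built from [logistic_fraction()]):
#'   the recombined fraction at each read time.
#' @param n_sample_wells,n_blank_wells Numbers of culture and blank wells
#'   (at least one blank).
#' @param od0,od_max,growth_rate Initial OD, carrying capacity and per-hour
#'   logistic growth rate of the bulk culture.
#' @param od_blank Medium blank OD offset added to every well.
#' @param fluor_blank Background fluorescence of medium (a.u.).
#' @param brightness Fluorescence per unit of recombined-cell OD (a.u.).
#' @param od_noise_sd,fluor_noise_sd Additive measurement noise sd per read.
#' @param treatment Treatment label copied to sample wells.
#' @param seed Optional integer seed.
#' @return A tibble with columns `well`, `role` (`"sample"`/`"blank"`),
#'   `treatment`, `time_h`, `od600`, `fluor`.
#' @examples
#' traj <- tibble::tibble(time_h = 0:10, fraction = logistic_fraction(0:10, 0.01, 0.9, 0.4))
#' plate <- simulate_plate_reader(traj, seed = 1)
#' @export
simulate_plate_reader <- function(trajectory,
                                  n_sample_wells = 3, n_blank_wells = 3,
                                  od0 = 0.005, od_max = 1.0, growth_rate = 0.8,
                                  od_blank = 0.09, fluor_blank = 120,
                                  brightness = 5e4,
                                  od_noise_sd = 0.003, fluor_noise_sd = 6,
                                  treatment = NA, seed = NULL) {
  if (!all(c("time_h", "fraction") %in% names(trajectory))) {
    abort("`trajectory` needs columns `time_h` and `fraction`.")
  }
  if (n_blank_wells < 1) abort("at least one blank well is required.")
  t <- trajectory$time_h
  frac <- trajectory$fraction
  od_cells <- od_max / (1 + (od_max / od0 - 1) * exp(-growth_rate * t))

  with_seed_(seed, {
    one_well <- function(well, role) {
      cells <- if (role == "sample") od_cells else 0
      fl_sig <- if (role == "sample") brightness * od_cells * frac else 0
      tibble(
        well = well, role = role,
        treatment = if (role == "sample") treatment else NA,
        time_h = t,
        od600 = od_blank + cells + rnorm(length(t), 0, od_noise_sd),
        fluor = fluor_blank + fl_sig + rnorm(length(t), 0, fluor_noise_sd)
      )
    }
    wells <- c(
      lapply(seq_len(n_sample_wells), function(i) one_well(sprintf("S%02d", i), "sample")),
      lapply(seq_len(n_blank_wells), function(i) one_well(sprintf("B%02d", i), "blank"))
    )
    dplyr::bind_rows(wells)
  })
}
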