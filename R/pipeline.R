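#' Default pipeline configuration
#'
#' Study-design defaults for an end-to-end synthetic run: a 4-point inducer
#' ladder, 3 biological x 3 technical replicates, 7 sampling times over
#' 16 h, Hill-type ground-truth dose model, and the default cytometry model.
#'
#' @param seed Global integer seed (mandatory for any stochastic stage; each
#'   stage derives its own independent sub-seed from it).
#' @param ... Overrides for any default field.
#' @return A named list (class `run_config`).
#' @export
pipeline_config <- function(seed, ...) {
  cfg <- list(
    seed = seed,
    concentrations = c(0, 1e-6, 5e-6, 2e-5),
    n_biological = 3,
    n_technical = 3,
    t_grid = seq(0, 16, length.out = 7),
    n_cells = 1e5,
    f0 = 0.01,
    fmax = 0.9,
    n_events = 5000,
    n_control_events = 20000,
    gate_q = 0.999,
    alpha = 0.05,
    dose = list(k_max = 0.6, K_half = 5e-6, hill_n = 1.5, k_leak = 0)
  )
  dots <- list(...)
  cfg[names(dots)] <- dots
  if (is.null(cfg$seed)) abort("`seed` is mandatory.")
  structure(cfg, class = c("run_config", "list"))
}

#' Run the simulate -> gate -> fit -> report pipeline
#'
#' Executes the full synthetic analysis: (1) evaluate the ground-truth dose
#' model; (2) simulate switching trajectories per concentration and
#' replicate; (3) synthesise cytometry events at each sampling time, derive a
#' control-based gate, and estimate fractions; (4) fit per-replicate
#' switching rates with AICc model selection and summarise the dose-response;
#' (5) run the Welch + Fisher detection ladder on the endpoint fractions.
#' All artifacts are written as delimited text / JSON under `out_dir`
#' together with a manifest (parameter echo, per-stage seeds, file MD5
#' hashes, collected warnings). Re-running with the same config reproduces
#' every stochastic output bit-exactly.
#'
#' @param config A [pipeline_config()] (or a YAML file path with the same
#'   fields).
#' @param out_dir Output directory (created if needed).
#' @return The manifest, invisibly a list; also written as
#'   `manifest.json`.
#' @export
run_pipeline <- function(config, out_dir = tempfile("switchrate_run_")) {
  if (is.character(config)) {
    config <- do.call(pipeline_config, yaml::read_yaml(config))
  }
  if (!inherits(config, "run_config")) abort("`config` must be a pipeline_config().")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  warnings_log <- character()
  log_warning <- function(w) {
    warnings_log <<- c(warnings_log, conditionMessage(w))
    invokeRestart("muffleWarning")
  }

  withCallingHandlers(
    {
      # stage 1: ground truth
      dm <- do.call(dose_model, config$dose)
      truth <- dose_response_rates(dm, config$concentrations)
      readr::write_csv(truth, file.path(out_dir, "ground_truth_rates.csv"))

      # stage 2: switching trajectories (one per bio x tech x concentration)
      grid <- tidyr::expand_grid(
        experiment = seq_len(config$n_biological),
        tech = seq_len(config$n_technical),
        concentration = config$concentrations
      )
      traj <- purrr::pmap(grid, function(experiment, tech, concentration) {
        i <- which(grid$experiment == experiment & grid$tech == tech &
                     grid$concentration == concentration)[1]
        k <- truth$k[truth$concentration == concentration]
        simulate_switching(
          config$n_cells, f0 = config$f0,
          k = k, t_grid = config$t_grid, fmax = config$fmax,
          mechanism = "logistic_mean",
          replicate_id = sprintf("e%d_t%d", experiment, tech),
          treatment = concentration,
          seed = derive_seed(config$seed, i)
        ) |>
          dplyr::mutate(experiment = experiment, tech = tech)
      }) |> dplyr::bind_rows()
      readr::write_csv(traj, file.path(out_dir, "trajectories_true.csv"))

      # stage 3: cytometry sampling + gating
      cyto <- cytometry_model()
      control <- simulate_cytometry_events(
        0, config$n_control_events, cyto, sample_id = "control",
        seed = derive_seed(config$seed, 9000)
      )
      gate <- derive_gate(control, q = config$gate_q)
      write_gate(gate, file.path(out_dir, "gate.json"))

      est <- traj |>
        dplyr::group_by(.data$experiment, .data$tech, .data$treatment,
                        .data$replicate, .data$time_h) |>
        dplyr::group_modify(function(d, g) {
          ev_seed <- derive_seed(
            config$seed,
            10000 + g$experiment * 997 + g$tech * 101 +
              round(g$time_h * 13) + which(config$concentrations == g$treatment)[1] * 7919
          )
          ev <- simulate_cytometry_events(d$fraction, config$n_events, cyto, seed = ev_seed)
          estimate_fraction(ev, gate)[c("x", "n", "p_hat", "se")]
        }) |>
        dplyr::ungroup()
      readr::write_csv(est, file.path(out_dir, "estimated_fractions.csv"))

      # stage 4: rate fits + dose-response summary
      fit_input <- est |>
        dplyr::mutate(recombined = .data$x, total = .data$n)
      dr <- fit_dose_response(fit_input, seed = derive_seed(config$seed, 20000))
      readr::write_csv(dr, file.path(out_dir, "dose_response.csv"))

      # stage 5: detection ladder on endpoint fractions
      endpoint <- est |>
        dplyr::filter(.data$time_h == max(.data$time_h)) |>
        dplyr::transmute(
          experiment = .data$experiment,
          concentration = .data$treatment,
          value = .data$p_hat
        )
      ladder <- detection_ladder(endpoint, alpha = config$alpha)
      steps_out <- ladder$steps[c("c_low", "c_high", "chi2", "df", "p_combined")]
      readr::write_csv(steps_out, file.path(out_dir, "detection_steps.csv"))
    },
    warning = log_warning
  )

  files <- c("ground_truth_rates.csv", "trajectories_true.csv", "gate.json",
             "estimated_fractions.csv", "dose_response.csv", "detection_steps.csv")
  manifest <- list(
    package_version = as.character(utils::packageVersion("switchrate")),
    seed = config$seed,
    config = unclass(config),
    lowest_detected = ladder$lowest_detected,
    artifacts = lapply(stats::setNames(files, files), function(f) {
      list(path = f, md5 = unname(tools::md5sum(file.path(out_dir, f))))
    }),
    warnings = warnings_log
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE)
  invisible(manifest)
}

#' Generate a named synthetic fixture bundle
#'
#' Writes small, seeded synthetic datasets plus a ground-truth JSON sidecar
#' for four study designs: a cumate-style dose--response time course
#' (`"cumate_dose_response"`), an arsenite-style endpoint ladder with three
#' biological replicates (`"arsenite_endpoint"`), an anoxic-exposure /
#' delayed-oxic-readout design in which an immature (dim) subpopulation
#' matures over the readout times (`"anoxic_memory"`), and a serial-passage
#' stability assay with selection against recombined cells
#' (`"stability_passaging"`).
#'
#' @param scenario One of `"cumate_dose_response"`, `"arsenite_endpoint"`,
#'   `"anoxic_memory"`, `"stability_passaging"`.
#' @param seed Integer seed.
#' @param dir Output directory.
#' @param selection_coefficient Per-generation fitness disadvantage of
#'   recombined cells (stability scenario only).
#' @return A list with the written file paths and the ground truth, invisibly.
#' @export
make_fixtures <- function(scenario = c("cumate_dose_response", "arsenite_endpoint",
                                       "anoxic_memory", "stability_passaging"),
                          seed = 1, dir = tempfile("fixtures_"),
                          selection_coefficient = 0.017) {
  scenario <- tryCatch(match.arg(scenario), error = function(e) {
    abort(paste0(
      "unknown scenario; available: cumate_dose_response, arsenite_endpoint, ",
      "anoxic_memory, stability_passaging."
    ))
  })
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  out <- switch(
    scenario,
    cumate_dose_response = {
      concs <- c(0, 1e-6, 5e-6, 2e-5)
      truth <- dose_response_rates(dose_model(), concs)
      traj <- purrr::map2(truth$concentration, truth$k, function(cc, k) {
        purrr::map(1:3, function(r) {
          simulate_switching(
            1e5, f0 = 0.01, k = k, t_grid = seq(0, 16, length.out = 7),
            fmax = 0.9, replicate_id = sprintf("t%d", r), treatment = cc,
            seed = derive_seed(seed, r * 100 + which(concs == cc))
          )
        }) |> dplyr::bind_rows()
      }) |> dplyr::bind_rows()
      path <- file.path(dir, "cumate_trajectories.csv")
      readr::write_csv(traj, path)
      list(files = path, truth = truth)
    },
    arsenite_endpoint = {
      concs <- c(0, 15e-9, 30e-9, 60e-9)
      base <- 0.0011
      truth <- tibble(
        concentration = concs,
        endpoint_fraction = base + c(0, 0.0017, 0.0033, 0.0066)
      )
      grid <- tidyr::expand_grid(experiment = 1:3, concentration = concs, tech = 1:3)
      grid$value <- purrr::pmap_dbl(grid, function(experiment, concentration, tech) {
        f <- truth$endpoint_fraction[truth$concentration == concentration]
        s <- derive_seed(seed, experiment * 1000 + tech * 10 +
                           which(concs == concentration))
        with_seed_(s, rbinom(1, 150000, f) / 150000)
      })
      path <- file.path(dir, "arsenite_endpoint_fractions.csv")
      readr::write_csv(grid, path)
      list(files = path, truth = truth)
    },
    anoxic_memory = {
      # post-transfer oxic readouts at 0, 6, 24 h: same true recombined
      # fraction, immature (dim) subpopulation maturing over time (most
      # maturation within the first 6 h); 2e5 events per sample
      true_fraction <- 0.02
      immature <- c(`0` = 0.4, `6` = 0.1, `24` = 0.02)
      files <- purrr::imap_chr(immature, function(im, t_oxic) {
        ev <- simulate_cytometry_events(
          true_fraction, 2e5,
          cytometry_model(immature_fraction = im),
          sample_id = sprintf("oxic_%sh", t_oxic),
          seed = derive_seed(seed, as.integer(t_oxic) + 1)
        )
        p <- file.path(dir, sprintf("anoxic_memory_oxic_%sh.csv", t_oxic))
        write_events(ev, p)
        p
      })
      ctrl <- simulate_cytometry_events(0, 2e5, sample_id = "control",
                                        seed = derive_seed(seed, 999))
      cpath <- file.path(dir, "anoxic_memory_control.csv")
      write_events(ctrl, cpath)
      list(files = c(files, cpath),
           truth = list(true_fraction = true_fraction, immature_fraction = immature))
    },
    stability_passaging = {
      # deterministic two-type competition across generations, binomially
      # sampled at each flow-cytometry measurement
      s <- selection_coefficient
      gens_per_cycle <- log2(1e4)
      f <- 0.4
      phases <- c("post_exposure", paste0("passage_", 1:4))
      fr <- numeric(5); fr[1] <- f
      for (i in 2:5) {
        for (g in seq_len(round(gens_per_cycle))) f <- f * (1 - s) / (1 - s * f)
        fr[i] <- f
      }
      n_ev <- 2e5
      track <- tibble(
        phase = phases,
        generations = c(0, cumsum(rep(gens_per_cycle, 4))),
        true_fraction = fr,
        x = with_seed_(seed, rbinom(5, n_ev, fr)),
        n = n_ev
      )
      track$p_hat <- track$x / track$n
      path <- file.path(dir, "stability_track.csv")
      readr::write_csv(track, path)
      list(files = path,
           truth = list(selection_coefficient = s, generations_per_cycle = gens_per_cycle,
                        true_fractions = fr))
    }
  )
  jsonlite::write_json(out$truth, file.path(dir, paste0(scenario, "_truth.json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(out, dir = dir))
}
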