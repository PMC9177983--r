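# Reproducible orchestration: a YAML run configuration drives simulation
# of fixture files and the full per-condition analysis, with every seed
# either set in the config or derived deterministically from the master
# seed, and a manifest recording versions, seeds and the config digest.

#' Read a run configuration
#'
#' @param config A YAML file path or an already-parsed list.
#' @return The configuration list, with the raw list stored for digesting.
#' @export
read_run_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) abort(sprintf("Config not found: %s", config))
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) abort("`config` must be a YAML path or a list.")
  config
}

config_scheme <- function(sc) {
  if (is.null(sc$states)) abort("Config error at simulate.scheme.states: missing.")
  states <- bind_rows(purrr::map(sc$states, as_tibble))
  k <- nrow(states)
  rates <- matrix(as.numeric(unlist(sc$rates)), nrow = k, byrow = TRUE)
  kinetic_scheme(states, rates, initial_probs = sc$initial_probs)
}

derive_seed <- function(master, k) {
  if (is.null(master)) return(NULL)
  (as.integer(master) * 97L + k * 1009L) %% 2147483647L
}

#' Simulate every fixture file a run consumes
#'
#' Writes intensity traces with their ground-truth sidecars (true state
#' paths, bleach frames, generator parameters), and optionally ensemble
#' decay curves, a binding titration and a spectrum, all driven by one
#' config with one master seed.
#'
#' @param config YAML path or list; see the package vignette for the
#'   schema. Required: `simulate.scheme`; optional: `simulate.photophysics`,
#'   `simulate.decay`, `simulate.binding`, `seed`, `frame_interval`,
#'   `simulate.n_frames`, `simulate.n_molecules`.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the manifest list.
#' @export
run_simulate <- function(config, out_dir) {
  config <- read_run_config(config)
  sim <- config$simulate
  if (is.null(sim)) abort("Config error at simulate: section missing.")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  scheme <- config_scheme(sim$scheme)
  phot <- do.call(photophysics, sim$photophysics %||% list())
  cfg <- sim_config(
    n_frames = sim$n_frames %||% 600,
    frame_interval = config$frame_interval %||% 0.2,
    n_molecules = sim$n_molecules %||% 100,
    seed = derive_seed(config$seed, 1L)
  )
  exp_data <- simulate_experiment(scheme, phot, cfg)
  write_traces(exp_data$traces, file.path(out_dir, "traces.csv"))
  readr::write_csv(exp_data$truth_states,
                   file.path(out_dir, "truth_states.csv"), progress = FALSE)
  readr::write_csv(exp_data$truth_bleach,
                   file.path(out_dir, "truth_bleach.csv"), progress = FALSE)
  written <- c("traces.csv", "truth_states.csv", "truth_bleach.csv")
  if (!is.null(sim$decay)) {
    dc <- sim$decay
    curve <- simulate_ensemble_decay(
      unlist(dc$amplitudes), unlist(dc$lifetimes),
      tgrid = seq(0, dc$tmax %||% 60, by = config$frame_interval %||% 0.2),
      noise_sd = dc$noise_sd %||% 0,
      condition_id = dc$condition_id %||% "decay_1",
      seed = derive_seed(config$seed, 2L))
    write_decay(curve, file.path(out_dir, "decay.csv"))
    written <- c(written, "decay.csv")
  }
  if (!is.null(sim$binding)) {
    bd <- sim$binding
    series <- simulate_binding_series(
      kd = bd$kd, rmax = bd$rmax,
      concentrations = unlist(bd$concentrations) %||%
        c(0, 10, 20, 40, 80, 160, 320, 640),
      noise_frac = bd$noise_frac %||% 0,
      seed = derive_seed(config$seed, 3L))
    write_binding(series, file.path(out_dir, "binding.csv"))
    written <- c(written, "binding.csv")
  }
  truth <- list(
    scheme = list(fret = scheme$states$fret, labels = scheme$states$label,
                  rates = apply(scheme$rates, 1, as.list)),
    photophysics = unclass(phot),
    n_frames = cfg$n_frames, frame_interval = cfg$frame_interval,
    n_molecules = cfg$n_molecules
  )
  yaml::write_yaml(truth, file.path(out_dir, "ground_truth.yaml"))
  manifest <- write_manifest(config, out_dir, stage = "simulate",
                             files = c(written, "ground_truth.yaml"))
  invisible(manifest)
}

#' Run the full per-condition analysis workflow
#'
#' For each configured condition: read the trace table, compute FRET
#' trajectories with bleach detection, idealize by HMM + BIC, tabulate
#' trajectory classes, build the TDP, extract dwells in the configured
#' window, and fit the dwell-time models. A failing condition is logged
#' and the remaining conditions continue; the manifest records per-stage
#' status.
#'
#' @param config YAML path or list with an `analyze.conditions` list; each
#'   condition needs `name` and `traces` (path relative to `out_dir`'s
#'   parent or absolute), and `dwell_window` if dwell fits are requested
#'   (`dwell_fits: true`).
#' @param out_dir Output directory; per-condition results go to
#'   `out_dir/<name>/`.
#' @return Invisibly, the manifest list; `manifest$status` is `"ok"` only
#'   if every condition succeeded.
#' @export
run_analyze <- function(config, out_dir) {
  config <- read_run_config(config)
  an <- config$analyze
  if (is.null(an) || is.null(an$conditions)) {
    abort("Config error at analyze.conditions: section missing.")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  dt <- config$frame_interval %||% 0.2
  bounds <- do.call(regime_bounds, an$bounds %||% list())
  results <- purrr::map(an$conditions, function(cond) {
    name <- cond$name %||% abort("Config error: condition without a name.")
    status <- tryCatch({
      analyze_condition(cond, an, bounds, dt, file.path(out_dir, name),
                        master_seed = config$seed)
      "ok"
    }, error = function(e) {
      message(sprintf("[fretkin] condition %s failed: %s", name,
                      conditionMessage(e)))
      paste("error:", conditionMessage(e))
    })
    list(name = name, status = status)
  })
  manifest <- write_manifest(
    config, out_dir, stage = "analyze",
    files = vapply(results, function(r) r$name, character(1)),
    conditions = results)
  manifest$status <- if (all(vapply(results, function(r) r$status,
                                    character(1)) == "ok")) "ok" else "failed"
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  invisible(manifest)
}

analyze_condition <- function(cond, an, bounds, dt, cond_dir, master_seed) {
  if (is.null(cond$traces)) {
    abort(sprintf("Config error at condition %s: `traces` path missing.",
                  cond$name))
  }
  dir.create(cond_dir, showWarnings = FALSE, recursive = TRUE)
  traces <- read_traces(cond$traces)
  fret <- compute_fret(traces,
                       background_donor = cond$background_donor %||% 0,
                       background_acceptor = cond$background_acceptor %||% 0)
  readr::write_csv(fret, file.path(cond_dir, "fret.csv"), progress = FALSE)
  segments <- idealize(fret,
                       k_max = an$k_max %||% 6,
                       n_restarts = an$restarts %||% 10,
                       seed = derive_seed(master_seed, 10L))
  readr::write_csv(segments, file.path(cond_dir, "segments.csv"),
                   progress = FALSE)
  classes <- class_percentages(segments, bounds)
  readr::write_csv(classes, file.path(cond_dir, "classes.csv"),
                   progress = FALSE)
  trans <- extract_transitions(segments)
  tdp <- build_tdp(trans, grid_size = an$tdp_grid %||% 100)
  utils::write.csv(tdp$density, file.path(cond_dir, "tdp.csv"),
                   row.names = FALSE)
  if (isTRUE(cond$dwell_fits)) {
    if (is.null(cond$dwell_window)) {
      abort(sprintf("Config error at condition %s: dwell fits requested but `dwell_window` missing.",
                    cond$name))
    }
    dwells <- extract_dwells(segments, unlist(cond$dwell_window),
                             frame_interval = dt)
    write_dwells(dwells, file.path(cond_dir, "dwells.csv"))
    usable <- filter(dwells, !.data$left_censored)
    if (sum(!usable$right_censored) >= 1) {
      fe <- fit_exponential(dwells)
      write_fit_report(fe, file.path(cond_dir, "dwell_exp_fit.txt"))
      if (sum(!usable$right_censored) >= 5) {
        fg <- fit_gamma(dwells)
        write_fit_report(fg, file.path(cond_dir, "dwell_gamma_fit.txt"))
      }
    }
  }
  invisible(NULL)
}

write_manifest <- function(config, out_dir, stage, files, conditions = NULL) {
  manifest <- list(
    stage = stage,
    package_version = as.character(utils::packageVersion("fretkin")),
    r_version = as.character(getRversion()),
    seed = config$seed,
    config_digest = rlang::hash(config),
    files = as.list(files),
    conditions = conditions
  )
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  manifest
}
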