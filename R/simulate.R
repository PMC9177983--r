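#' Simulate a continuous-time Markov state path, sampled at frame midpoints
#'
#' Draws one realization of the continuous-time Markov chain defined by a
#' [kinetic_scheme()] using Gillespie sampling (exponential dwell in state
#' `i` with rate `sum(rates[i, ])`, jump destination proportional to the
#' row), then records the state occupying each camera frame's midpoint.
#' Dwells shorter than one frame can therefore be missed, exactly as with a
#' real camera. A state whose exit rate is zero is absorbing: once entered,
#' the path stays there.
#'
#' @param scheme A [kinetic_scheme()].
#' @param config A [sim_config()]; only `n_frames` and `frame_interval` are
#'   used here.
#' @param seed Optional integer seed (overrides `config$seed`).
#'
#' @return Integer vector of state indices (1-based) of length `n_frames`.
#'   The underlying continuous jump path is attached as attribute `"jumps"`,
#'   a tibble with columns `state`, `start_s`, `duration_s` (the final
#'   dwell's duration is truncated at the end of the acquisition and marked
#'   in attribute column `truncated`).
#' @examples
#' sch <- kinetic_scheme(
#'   data.frame(label = c("a", "b"), fret = c(0.9, 0.4), sd = c(0.05, 0.05)),
#'   matrix(c(0, 0.5, 0.5, 0), 2, 2, byrow = TRUE)
#' )
#' path <- simulate_state_path(sch, sim_config(n_frames = 50), seed = 1)
#' table(path)
#' @export
simulate_state_path <- function(scheme, config = sim_config(), seed = NULL) {
  stopifnot(inherits(scheme, "kinetic_scheme"), inherits(config, "sim_config"))
  local_seed(seed %||% config$seed)
  n <- config$n_frames
  dt <- config$frame_interval
  t_end <- n * dt
  k <- nrow(scheme$states)
  exit <- rowSums(scheme$rates)

  s <- if (k == 1) 1L else
    sample.int(k, 1, prob = scheme$initial_probs)
  jump_states <- integer(0)
  jump_starts <- numeric(0)
  t_now <- 0
  while (t_now < t_end) {
    jump_states <- c(jump_states, s)
    jump_starts <- c(jump_starts, t_now)
    if (exit[s] <= 0) break            # absorbing: occupies the remainder
    dwell <- rexp(1, rate = exit[s])
    t_now <- t_now + dwell
    if (t_now >= t_end) break
    s <- sample.int(k, 1, prob = scheme$rates[s, ])
  }
  ends <- c(jump_starts[-1], t_end)
  midpoints <- (seq_len(n) - 0.5) * dt
  path <- jump_states[findInterval(midpoints, jump_starts)]
  jumps <- tibble(
    state = jump_states,
    start_s = jump_starts,
    duration_s = ends - jump_starts,
    truncated = seq_along(jump_states) == length(jump_states)
  )
  attr(path, "jumps") <- jumps
  path
}

#' Render a state path into a donor/acceptor intensity trace
#'
#' Converts a discrete state path into two-channel intensities under donor
#' excitation: the acceptor channel carries `total_intensity * E` and the
#' donor channel `total_intensity * (1 - E)` for the state's FRET level `E`,
#' plus channel backgrounds and additive Gaussian noise. Photobleaching of
#' either dye is drawn as a single exponential-time irreversible event:
#' after acceptor bleach the FRET signal is lost (acceptor falls to
#' background, donor rises to the full intensity); after donor bleach both
#' channels fall to background.
#'
#' @param path Integer state path from [simulate_state_path()].
#' @param scheme The [kinetic_scheme()] that generated `path`.
#' @param phot A [photophysics()] model.
#' @param config A [sim_config()].
#' @param molecule_id Identifier stored in the output.
#' @param seed Optional integer seed.
#'
#' @return A tibble with columns `molecule_id`, `frame` (0-based), `time_s`,
#'   `donor`, `acceptor`, and attributes `donor_bleach_frame` /
#'   `acceptor_bleach_frame` (0-based first bleached frame, `NA` if the dye
#'   survives the acquisition) and `frame_interval`.
#' @export
simulate_intensity_trace <- function(path, scheme, phot = photophysics(),
                                     config = sim_config(),
                                     molecule_id = "mol_1", seed = NULL) {
  stopifnot(inherits(scheme, "kinetic_scheme"),
            inherits(phot, "photophysics"))
  n <- length(path)
  if (n != config$n_frames) {
    abort("`path` length must equal `config$n_frames`.")
  }
  local_seed(seed)
  dt <- config$frame_interval
  midpoints <- (seq_len(n) - 0.5) * dt

  bleach_time <- function(rate) if (rate > 0) rexp(1, rate) else Inf
  t_acc <- bleach_time(phot$acceptor_bleach_rate)
  t_don <- bleach_time(phot$donor_bleach_rate)

  e <- scheme$states$fret[path]
  acceptor <- phot$total_intensity * e
  donor <- phot$total_intensity * (1 - e)
  acc_gone <- midpoints >= t_acc
  don_gone <- midpoints >= t_don
  # acceptor bleach first: FRET lost, donor recovers full intensity
  acceptor[acc_gone] <- 0
  donor[acc_gone & !don_gone] <- phot$total_intensity
  donor[don_gone] <- 0
  acceptor[don_gone] <- 0

  donor <- donor + phot$background_donor
  acceptor <- acceptor + phot$background_acceptor
  if (phot$noise_sd > 0) {
    donor <- donor + rnorm(n, sd = phot$noise_sd)
    acceptor <- acceptor + rnorm(n, sd = phot$noise_sd)
  }

  out <- tibble(
    molecule_id = molecule_id,
    frame = seq_len(n) - 1L,
    time_s = (seq_len(n) - 1L) * dt,
    donor = donor,
    acceptor = acceptor
  )
  first_frame <- function(gone) if (any(gone)) which(gone)[1] - 1L else NA_integer_
  attr(out, "acceptor_bleach_frame") <- first_frame(acc_gone)
  attr(out, "donor_bleach_frame") <- first_frame(don_gone)
  attr(out, "frame_interval") <- dt
  out
}

#' Simulate a full single-molecule FRET experiment
#'
#' Convenience wrapper generating `config$n_molecules` traces from one
#' scheme, together with the ground truth needed for recovery testing.
#'
#' @inheritParams simulate_intensity_trace
#' @param seed Optional master seed; per-molecule seeds are derived from it
#'   deterministically.
#'
#' @return A list with elements `traces` (long tibble: `molecule_id`,
#'   `frame`, `time_s`, `donor`, `acceptor`), `truth_states` (tibble:
#'   `molecule_id`, `frame`, `state`, `fret`) and `truth_bleach` (tibble:
#'   `molecule_id`, `donor_bleach_frame`, `acceptor_bleach_frame`).
#' @export
simulate_experiment <- function(scheme, phot = photophysics(),
                                config = sim_config(), seed = NULL) {
  local_seed(seed %||% config$seed)
  nm <- config$n_molecules
  ids <- sprintf("mol_%03d", seq_len(nm))
  sims <- purrr::map(seq_len(nm), function(i) {
    path <- simulate_state_path(scheme, config)
    trace <- simulate_intensity_trace(path, scheme, phot, config,
                                      molecule_id = ids[i])
    bare <- trace
    attr(bare, "acceptor_bleach_frame") <- NULL
    attr(bare, "donor_bleach_frame") <- NULL
    attr(bare, "frame_interval") <- NULL
    list(
      trace = bare,
      states = tibble(molecule_id = ids[i],
                      frame = seq_along(path) - 1L,
                      state = as.integer(path),
                      fret = scheme$states$fret[path]),
      bleach = tibble(
        molecule_id = ids[i],
        donor_bleach_frame = attr(trace, "donor_bleach_frame"),
        acceptor_bleach_frame = attr(trace, "acceptor_bleach_frame"))
    )
  })
  empty_trace <- tibble(molecule_id = character(), frame = integer(),
                        time_s = double(), donor = double(),
                        acceptor = double())
  list(
    traces = if (nm > 0) bind_rows(purrr::map(sims, "trace")) else empty_trace,
    truth_states = bind_rows(purrr::map(sims, "states")),
    truth_bleach = bind_rows(purrr::map(sims, "bleach")),
    frame_interval = config$frame_interval
  )
}

#' Simulate a multi-exponential ensemble decay curve
#'
#' Generates `y(t) = sum_j A_j exp(-t / tau_j)` plus additive Gaussian
#' noise, the form of an ensemble fluorescence-survival curve in which one
#' component is photobleaching and further components are molecular loss
#' processes.
#'
#' @param amplitudes,lifetimes Numeric vectors of equal length; lifetimes in
#'   seconds, all > 0.
#' @param tgrid Time grid in seconds.
#' @param noise_sd Additive Gaussian noise sd (0 for a noiseless curve).
#' @param condition_id Label stored in the output.
#' @param seed Optional integer seed.
#'
#' @return Tibble with columns `condition_id`, `time_s`, `intensity`.
#' @examples
#' simulate_ensemble_decay(1, 10, tgrid = c(0, 10))
#' @export
simulate_ensemble_decay <- function(amplitudes, lifetimes,
                                    tgrid = seq(0, 60, by = 0.2),
                                    noise_sd = 0,
                                    condition_id = "cond_1", seed = NULL) {
  if (length(amplitudes) != length(lifetimes)) {
    abort("`amplitudes` and `lifetimes` must have equal length.")
  }
  if (any(lifetimes <= 0)) abort("`lifetimes` must be > 0.")
  assert_scalar_number(noise_sd, "noise_sd", nonneg = TRUE)
  local_seed(seed)
  y <- rowSums(vapply(seq_along(amplitudes),
                      function(j) amplitudes[j] * exp(-tgrid / lifetimes[j]),
                      numeric(length(tgrid))))
  if (noise_sd > 0) y <- y + rnorm(length(tgrid), sd = noise_sd)
  tibble(condition_id = condition_id, time_s = as.numeric(tgrid),
         intensity = y)
}

#' Simulate dwell times with optional right censoring
#'
#' Draws i.i.d. residence times from an exponential or gamma distribution;
#' draws exceeding `censor_at` are truncated there and flagged
#' right-censored, emulating dwells cut short by the end of an acquisition
#' or by photobleaching.
#'
#' @param n Number of dwells.
#' @param dist `"exponential"` or `"gamma"`.
#' @param tau Mean dwell for the exponential (seconds).
#' @param shape,scale Gamma parameters (scale in seconds).
#' @param censor_at Right-censoring horizon in seconds, or `NULL` for none.
#' @param state_level FRET level recorded on the records (metadata only).
#' @param seed Optional integer seed.
#'
#' @return A dwell tibble with columns `molecule_id`, `state_level`,
#'   `start_s`, `duration_s`, `left_censored`, `right_censored`.
#' @examples
#' simulate_dwells(5, tau = 5, seed = 1)
#' @export
simulate_dwells <- function(n, dist = c("exponential", "gamma"),
                            tau = 5, shape = 2, scale = 0.7,
                            censor_at = NULL, state_level = NA_real_,
                            seed = NULL) {
  dist <- match.arg(dist)
  assert_scalar_number(n, "n", nonneg = TRUE)
  n <- as.integer(n)
  local_seed(seed)
  d <- if (n == 0) numeric(0)
  else if (dist == "exponential") {
    assert_scalar_number(tau, "tau", positive = TRUE)
    rexp(n, rate = 1 / tau)
  } else {
    assert_scalar_number(shape, "shape", positive = TRUE)
    assert_scalar_number(scale, "scale", positive = TRUE)
    rgamma(n, shape = shape, scale = scale)
  }
  censored <- rep(FALSE, n)
  if (!is.null(censor_at)) {
    assert_scalar_number(censor_at, "censor_at", positive = TRUE)
    censored <- d >= censor_at
    d <- pmin(d, censor_at)
  }
  tibble(
    molecule_id = if (n > 0) sprintf("sim_%05d", seq_len(n)) else character(),
    state_level = rep(as.numeric(state_level), n),
    start_s = rep(0, n),
    duration_s = d,
    left_censored = rep(FALSE, n),
    right_censored = censored
  )
}

#' Simulate a steady-state binding titration
#'
#' Generates equilibrium responses from the 1:1 steady-state affinity model
#' `R_eq = R_max * [A] / ([A] + K_D)` with optional multiplicative Gaussian
#' noise, on a concentration grid. The default grid is an eight-point
#' titration from 0 to 640 nM.
#'
#' @param kd Dissociation constant (same units as `concentrations`), > 0.
#' @param rmax Saturating response, > 0.
#' @param concentrations Analyte concentrations, all >= 0.
#' @param noise_frac Relative sd of multiplicative Gaussian noise.
#' @param seed Optional integer seed.
#'
#' @return Tibble with columns `conc`, `r_eq`.
#' @examples
#' simulate_binding_series(kd = 170, rmax = 100)
#' @export
simulate_binding_series <- function(kd, rmax,
                                    concentrations =
                                      c(0, 10, 20, 40, 80, 160, 320, 640),
                                    noise_frac = 0, seed = NULL) {
  assert_scalar_number(kd, "kd", positive = TRUE)
  assert_scalar_number(rmax, "rmax", positive = TRUE)
  if (any(concentrations < 0)) abort("`concentrations` must be >= 0.")
  assert_scalar_number(noise_frac, "noise_frac", nonneg = TRUE)
  local_seed(seed)
  r <- rmax * concentrations / (concentrations + kd)
  if (noise_frac > 0) {
    r <- r * (1 + rnorm(length(r), sd = noise_frac))
  }
  tibble(conc = as.numeric(concentrations), r_eq = r)
}

#' Sample FRET values from a Gaussian mixture
#'
#' Draws i.i.d. values from a mixture of Gaussian components, the generative
#' model behind a multi-population FRET-state histogram. Values are returned
#' unclipped; the conventional reporting range is noted in the
#' `"reporting_range"` attribute.
#'
#' @param mixture Data frame with columns `weight`, `mean`, `sd`; weights
#'   must be non-negative and sum to 1 (within 1e-8).
#' @param n Sample size.
#' @param seed Optional integer seed.
#'
#' @return Numeric vector of length `n`.
#' @examples
#' x <- simulate_fret_sample(
#'   data.frame(weight = c(1 / 3, 1 / 3, 1 / 3),
#'              mean = c(0.91, 0.63, 0.09), sd = 0.06),
#'   n = 1000, seed = 1)
#' @export
simulate_fret_sample <- function(mixture, n, seed = NULL) {
  mixture <- as_tibble(mixture)
  assert_columns(mixture, c("weight", "mean", "sd"), "`mixture`")
  if (any(mixture$weight < 0)) abort("Mixture weights must be >= 0.")
  if (abs(sum(mixture$weight) - 1) > 1e-8) {
    abort("Mixture weights must sum to 1.")
  }
  if (any(mixture$sd <= 0)) abort("Mixture sds must be > 0.")
  assert_scalar_number(n, "n", nonneg = TRUE)
  n <- as.integer(n)
  local_seed(seed)
  if (n == 0) {
    out <- numeric(0)
  } else {
    comp <- sample.int(nrow(mixture), n, replace = TRUE,
                       prob = mixture$weight)
    out <- rnorm(n, mean = mixture$mean[comp], sd = mixture$sd[comp])
  }
  attr(out, "reporting_range") <- c(-0.1, 1.1)
  out
}
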