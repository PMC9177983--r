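#' Define a discrete-state kinetic scheme for trace simulation
#'
#' A kinetic scheme couples a set of FRET-resolvable states (each with a mean
#' FRET efficiency and an emission standard deviation) to a matrix of
#' first-order transition rates. It is the generative model behind
#' [simulate_state_path()]: the molecule performs a continuous-time Markov
#' walk over the states, so dwell times in state `i` are exponential with
#' rate equal to the `i`-th row sum of `rates`.
#'
#' @param states A data frame with columns `label` (character), `fret`
#'   (mean FRET efficiency in `[0, 1]`, all values distinct) and `sd`
#'   (emission standard deviation, used when intensities are rendered).
#' @param rates Square numeric matrix of transition rates in s^-1;
#'   `rates[i, j]` is the rate from state `i` to state `j`. The diagonal is
#'   ignored (forced to zero); off-diagonal entries must be non-negative.
#'   A state whose row sums to zero is absorbing.
#' @param initial_probs Probability vector over states at time zero.
#'   Defaults to uniform.
#'
#' @return An object of class `kinetic_scheme`.
#' @examples
#' scheme <- kinetic_scheme(
#'   states = data.frame(label = c("inactive", "poised"),
#'                       fret = c(0.9, 0.6), sd = c(0.05, 0.05)),
#'   rates = matrix(c(0, 0.2, 0.2, 0), 2, 2, byrow = TRUE)
#' )
#' scheme
#' @export
kinetic_scheme <- function(states, rates, initial_probs = NULL) {
  states <- as_tibble(states)
  assert_columns(states, c("label", "fret", "sd"), "`states`")
  k <- nrow(states)
  if (k < 1) abort("`states` must contain at least one state.")
  if (anyDuplicated(states$fret)) abort("`fret` levels must be distinct.")
  if (any(states$fret < 0 | states$fret > 1)) {
    abort("`fret` levels must lie in [0, 1].")
  }
  if (any(states$sd < 0)) abort("`sd` must be >= 0.")
  rates <- as.matrix(rates)
  if (!is.numeric(rates) || nrow(rates) != k || ncol(rates) != k) {
    abort("`rates` must be a numeric k x k matrix matching `states`.")
  }
  diag(rates) <- 0
  if (any(rates < 0)) abort("Off-diagonal transition rates must be >= 0.")
  if (is.null(initial_probs)) initial_probs <- rep(1 / k, k)
  if (length(initial_probs) != k || any(initial_probs < 0)) {
    abort("`initial_probs` must be a non-negative vector of length k.")
  }
  if (abs(sum(initial_probs) - 1) > 1e-12) {
    abort("`initial_probs` must sum to 1 (within 1e-12).")
  }
  structure(
    list(states = states, rates = rates,
         initial_probs = as.numeric(initial_probs)),
    class = "kinetic_scheme"
  )
}

#' @export
print.kinetic_scheme <- function(x, ...) {
  cat(sprintf("<kinetic_scheme: %d states>\n", nrow(x$states)))
  print(x$states)
  cat("exit rates (s^-1):",
      paste(signif(rowSums(x$rates), 4), collapse = ", "), "\n")
  invisible(x)
}

#' Photophysical model for intensity rendering
#'
#' Parameters controlling how a state path is turned into donor/acceptor
#' intensities: the total (donor + acceptor) emission per frame, per-dye
#' single-step photobleaching rates, per-channel backgrounds, and additive
#' Gaussian read noise. The default acceptor bleach rate corresponds to a
#' mean bleach lifetime of 11.3 s under red excitation, the regime typical
#' of Cy5 in oxygen-scavenged imaging buffers.
#'
#' @param total_intensity Total emitted intensity per frame (a.u.), > 0.
#' @param donor_bleach_rate,acceptor_bleach_rate Bleaching rates in s^-1
#'   (0 disables bleaching of that dye). Bleaching is a single irreversible
#'   exponential-time event per dye; blinking is not modelled.
#' @param background_donor,background_acceptor Additive channel backgrounds.
#' @param noise_sd Standard deviation of additive Gaussian noise per channel.
#'
#' @return An object of class `photophysics`.
#' @export
photophysics <- function(total_intensity = 1000,
                         donor_bleach_rate = 0,
                         acceptor_bleach_rate = 1 / 11.3,
                         background_donor = 0,
                         background_acceptor = 0,
                         noise_sd = 20) {
  assert_scalar_number(total_intensity, "total_intensity", positive = TRUE)
  assert_scalar_number(donor_bleach_rate, "donor_bleach_rate", nonneg = TRUE)
  assert_scalar_number(acceptor_bleach_rate, "acceptor_bleach_rate",
                       nonneg = TRUE)
  assert_scalar_number(noise_sd, "noise_sd", nonneg = TRUE)
  structure(
    list(total_intensity = total_intensity,
         donor_bleach_rate = donor_bleach_rate,
         acceptor_bleach_rate = acceptor_bleach_rate,
         background_donor = background_donor,
         background_acceptor = background_acceptor,
         noise_sd = noise_sd),
    class = "photophysics"
  )
}

#' Acquisition settings for simulated experiments
#'
#' @param n_frames Frames per molecule. The default, 600 frames at 0.2 s,
#'   corresponds to a 120 s acquisition at 5 frames per second.
#' @param frame_interval Frame interval in seconds.
#' @param n_molecules Number of molecules per simulated experiment.
#' @param seed Optional integer seed; a fixed seed makes every generator
#'   bit-reproducible.
#'
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_frames = 600, frame_interval = 0.2,
                       n_molecules = 100, seed = NULL) {
  assert_scalar_number(n_frames, "n_frames", positive = TRUE)
  assert_scalar_number(frame_interval, "frame_interval", positive = TRUE)
  assert_scalar_number(n_molecules, "n_molecules", nonneg = TRUE)
  structure(
    list(n_frames = as.integer(n_frames),
         frame_interval = frame_interval,
         n_molecules = as.integer(n_molecules),
         seed = seed),
    class = "sim_config"
  )
}
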