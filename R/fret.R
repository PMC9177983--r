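#' Compute FRET efficiency trajectories from intensity traces
#'
#' Converts background-corrected donor/acceptor intensities to the proximity
#' ratio `E = (A - bgA) / ((A - bgA) + (D - bgD))` per frame and per
#' molecule. No gamma, donor-leakage or direct-excitation corrections are
#' applied; the simulator uses the same convention, so analyses on
#' simulated data are internally consistent. Frames whose corrected total
#' intensity falls below `floor_frac` of the molecule's initial ten-frame
#' median are masked (`fret = NA`): post-bleach ratios of two near-zero
#' channels are meaningless. Each molecule's analysis horizon
#' (`valid_until`, the first photobleached frame found by
#' [detect_photobleach()]) is recorded, and `usable` flags the frames that
#' downstream analyses should consume.
#'
#' @param traces Trace tibble (schema of [read_traces()]).
#' @param background_donor,background_acceptor Per-channel backgrounds
#'   subtracted before the ratio.
#' @param floor_frac Masking floor as a fraction of the initial ten-frame
#'   median corrected total intensity.
#' @param ... Passed to [detect_photobleach()] (`threshold`, `persist`).
#'
#' @return Tibble with columns `molecule_id`, `frame`, `time_s`, `fret`,
#'   `valid_until`, `usable`. A molecule in which every frame is masked
#'   yields rows with `usable = FALSE` throughout (not an error).
#' @examples
#' tr <- tibble::tibble(molecule_id = "m1", frame = 0:9,
#'                      time_s = 0.2 * (0:9), donor = 50, acceptor = 50)
#' compute_fret(tr)$fret
#' @export
compute_fret <- function(traces, background_donor = 0,
                         background_acceptor = 0, floor_frac = 0.1, ...) {
  traces <- validate_traces(traces)
  traces %>%
    group_by(.data$molecule_id) %>%
    group_split() %>%
    purrr::map(function(tr) {
      d <- tr$donor - background_donor
      a <- tr$acceptor - background_acceptor
      total <- d + a
      n <- length(total)
      init_med <- median(total[seq_len(min(10, n))])
      masked <- total < floor_frac * init_med | total <= 0
      fret <- ifelse(masked, NA_real_, a / total)
      vu <- detect_photobleach(tr$donor, tr$acceptor,
                               background_donor = background_donor,
                               background_acceptor = background_acceptor,
                               ...)
      tibble(molecule_id = tr$molecule_id,
             frame = tr$frame,
             time_s = tr$time_s,
             fret = fret,
             valid_until = vu,
             usable = !masked & tr$frame < vu)
    }) %>%
    bind_rows()
}

#' Detect single-molecule photobleaching
#'
#' Finds the first frame at which the corrected total intensity
#' (donor + acceptor) drops below `threshold` (default 50%) of its initial
#' ten-frame median and stays below for at least `persist` frames; a
#' below-threshold run that reaches the end of the trace also qualifies
#' even if shorter than `persist` (a bleach in the final frames stays below
#' for the remainder). Returns the trace length if no such drop occurs, and
#' 0 for a trace that starts dark (non-positive initial median).
#'
#' @param donor,acceptor Intensity vectors (equal length, >= 10 frames).
#' @param threshold Drop threshold as a fraction of the initial median.
#' @param persist Minimum below-threshold run length in frames.
#' @param background_donor,background_acceptor Backgrounds subtracted before
#'   totals are formed.
#'
#' @return 0-based frame index of the bleach, or `length(donor)` if none.
#' @export
detect_photobleach <- function(donor, acceptor, threshold = 0.5,
                               persist = 5L, background_donor = 0,
                               background_acceptor = 0) {
  n <- length(donor)
  if (length(acceptor) != n) abort("Channel lengths differ.")
  if (n < 10) abort("Bleach detection needs at least 10 frames.")
  total <- (donor - background_donor) + (acceptor - background_acceptor)
  init_med <- median(total[1:10])
  if (init_med <= 0) return(0L)
  below <- total < threshold * init_med
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  hit <- r$values & (r$lengths >= persist | ends == n)
  if (!any(hit)) return(n)
  starts[which(hit)[1]] - 1L
}

#' Predicted FRET efficiency from dye separation
#'
#' Forward prediction of the FRET efficiency for a donor-acceptor pair at
#' distance `r` given the Forster radius `r0` (same units):
#' `E = 1 / (1 + (r / r0)^6)`. Strictly decreasing in `r`; at a separation
#' equal to the Forster radius the efficiency is 0.5 by definition.
#'
#' @param r Dye separation(s), >= 0.
#' @param r0 Forster radius, > 0.
#' @return Efficiency in (0, 1].
#' @examples
#' forster_efficiency(c(0, 5, 7.5), r0 = 5)
#' @export
forster_efficiency <- function(r, r0) {
  assert_scalar_number(r0, "r0", positive = TRUE)
  if (any(r < 0)) abort("`r` must be >= 0.")
  1 / (1 + (r / r0)^6)
}
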