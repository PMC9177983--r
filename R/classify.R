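# Trajectory classification, class percentages, and transition density
# plots over idealized trajectories.

#' FRET regime boundaries
#'
#' The three-regime partition of the FRET axis used to classify idealized
#' trajectories: low `[0, low_max)`, mid `[low_max, mid_max)`, high
#' `[mid_max, upper]`. Published cutoffs describe 0.7-1 as high, 0.4-0.7 as
#' mid and 0-0.4 as low with overlapping endpoints; the half-open
#' convention here assigns 0.4 to mid and 0.7 to high.
#'
#' @param low_max,mid_max,upper Regime boundaries, `0 < low_max < mid_max
#'   < upper`.
#' @return An object of class `regime_bounds`.
#' @export
regime_bounds <- function(low_max = 0.4, mid_max = 0.7, upper = 1.0) {
  if (!(0 < low_max && low_max < mid_max && mid_max < upper)) {
    abort("Need 0 < low_max < mid_max < upper.")
  }
  structure(list(low_max = low_max, mid_max = mid_max, upper = upper),
            class = "regime_bounds")
}

#' Assign FRET levels to regimes
#'
#' Maps fitted state levels to `"low"`, `"mid"` or `"high"` using the
#' half-open convention of [regime_bounds()]. Levels outside `[0, upper]`
#' (noise excursions) are clamped into range with a warning.
#'
#' @param level Numeric FRET level(s).
#' @param bounds A [regime_bounds()].
#' @return Character vector of regimes.
#' @examples
#' assign_regime(c(0.9, 0.6, 0.2, 0.7, 0.4))
#' @export
assign_regime <- function(level, bounds = regime_bounds()) {
  stopifnot(inherits(bounds, "regime_bounds"))
  out_of_range <- level < 0 | level > bounds$upper
  if (any(out_of_range)) {
    warn(sprintf("%d level(s) outside [0, %g] clamped.",
                 sum(out_of_range), bounds$upper))
    level <- pmin(pmax(level, 0), bounds$upper)
  }
  ifelse(level < bounds$low_max, "low",
         ifelse(level < bounds$mid_max, "mid", "high"))
}

trajectory_classes <- c("static", "high", "mid", "low",
                        "high-mid", "mid-low", "high-low")

classify_one <- function(levels, bounds) {
  if (n_distinct(levels) == 1) return("static")
  regimes <- unique(assign_regime(unique(levels), bounds))
  if (length(regimes) == 1) return(regimes)
  if ("high" %in% regimes && "low" %in% regimes) return("high-low")
  if (setequal(regimes, c("high", "mid"))) return("high-mid")
  "mid-low"
}

#' Classify idealized trajectories by the regimes they visit
#'
#' A trajectory that resides in exactly one state is `static`. A dynamic
#' trajectory visiting states confined to one regime is labelled by that
#' regime (`high`, `mid`, `low`); one visiting two adjacent regimes is
#' `high-mid` or `mid-low`; and any trajectory visiting both the high and
#' low regimes - including those visiting all three - is `high-low`. The
#' classes are mutually exclusive and exhaustive. Regime membership of a
#' state uses its fitted mean level, not per-frame values.
#'
#' @param segments Segment tibble (from [viterbi_path()] or [idealize()]),
#'   one or more molecules.
#' @param bounds A [regime_bounds()].
#' @return Tibble with columns `molecule_id`, `class` (factor over the
#'   seven classes).
#' @export
classify_trajectories <- function(segments, bounds = regime_bounds()) {
  assert_columns(segments, c("molecule_id", "level"), "segment table")
  if (nrow(segments) == 0) abort("No segments to classify.")
  segments %>%
    group_by(.data$molecule_id) %>%
    summarise(class = classify_one(.data$level, bounds), .groups = "drop") %>%
    mutate(class = factor(.data$class, levels = trajectory_classes))
}

#' Tabulate trajectory-class percentages
#'
#' @inheritParams classify_trajectories
#' @return Tibble with one row per class: `class`, `n`, `percent`
#'   (percentages over molecules, summing to 100).
#' @export
class_percentages <- function(segments, bounds = regime_bounds()) {
  cls <- classify_trajectories(segments, bounds)
  total <- nrow(cls)
  cls %>%
    count(.data$class, .drop = FALSE) %>%
    mutate(percent = 100 * n / total)
}

#' Extract state-to-state transitions from idealized trajectories
#'
#' One `(level_before, level_after)` pair per adjacent segment boundary
#' within each molecule; a trajectory with `k` segments contributes
#' `k - 1` pairs. Transitions are pooled across molecules.
#'
#' @param segments Segment tibble.
#' @return Tibble with columns `molecule_id`, `from`, `to`.
#' @export
extract_transitions <- function(segments) {
  assert_columns(segments, c("molecule_id", "start_frame", "level"),
                 "segment table")
  segments %>%
    arrange(.data$molecule_id, .data$start_frame) %>%
    group_by(.data$molecule_id) %>%
    mutate(to = lead(.data$level)) %>%
    ungroup() %>%
    filter(!is.na(.data$to)) %>%
    select("molecule_id", from = "level", to = "to")
}

#' Build a transition density plot (TDP)
#'
#' Gaussian kernel density estimate of the pooled `(FRET before, FRET
#' after)` transition pairs on a regular lattice over `[0, 1]^2`,
#' normalized to integrate to 1 over the grid. With `bandwidth = "auto"`
#' the per-axis bandwidth is Silverman's rule-of-thumb ([stats::bw.nrd0()]),
#' with a floor of 0.01.
#'
#' @param transitions Tibble from [extract_transitions()] (columns `from`,
#'   `to`), possibly empty.
#' @param grid_size Lattice points per axis.
#' @param bandwidth `"auto"` or a numeric bandwidth used for both axes.
#' @return An object of class `tdp_grid`: list with `x`, `y` (grid
#'   centres), `density` (matrix, rows indexed by `from`), `bandwidth`,
#'   `n_transitions`. An empty transition set yields an all-zero density.
#' @export
build_tdp <- function(transitions, grid_size = 100, bandwidth = "auto") {
  assert_columns(transitions, c("from", "to"), "transition table")
  gx <- seq(0, 1, length.out = grid_size)
  n <- nrow(transitions)
  if (n == 0) {
    dens <- matrix(0, grid_size, grid_size)
    bw <- c(NA_real_, NA_real_)
  } else {
    bw <- if (identical(bandwidth, "auto")) {
      c(silverman_bw(transitions$from), silverman_bw(transitions$to))
    } else {
      assert_scalar_number(bandwidth, "bandwidth", positive = TRUE)
      c(bandwidth, bandwidth)
    }
    # product-kernel KDE evaluated on the lattice
    kx <- outer(gx, transitions$from, function(g, c) dnorm(g, c, bw[1]))
    ky <- outer(gx, transitions$to, function(g, c) dnorm(g, c, bw[2]))
    dens <- (kx %*% t(ky)) / n
    cell <- (gx[2] - gx[1])^2
    dens <- dens / (sum(dens) * cell)
  }
  structure(list(x = gx, y = gx, density = dens, bandwidth = bw,
                 n_transitions = n),
            class = "tdp_grid")
}

silverman_bw <- function(v) {
  bw <- if (length(v) >= 2 && sd(v) > 0) bw.nrd0(v) else 0
  max(bw, 0.01)
}

#' @export
print.tdp_grid <- function(x, ...) {
  cat(sprintf("<tdp_grid: %d x %d, %d transitions, bw = (%s)>\n",
              length(x$x), length(x$y), x$n_transitions,
              paste(signif(x$bandwidth, 3), collapse = ", ")))
  invisible(x)
}

#' Off-diagonal asymmetry of a transition density plot
#'
#' Score in `[-1, 1]` quantifying irreversibility:
#' `(mass of FRET-decreasing transitions - mass of FRET-increasing
#' transitions) / total off-diagonal mass`, where a FRET-decreasing
#' transition has `after < before`. +1 means all transitions lower the
#' FRET signal (an irreversible cascade); 0 means a mirror-symmetric,
#' reversible transition set.
#'
#' @param tdp A `tdp_grid` with at least one transition.
#' @return Scalar score.
#' @export
asymmetry_score <- function(tdp) {
  stopifnot(inherits(tdp, "tdp_grid"))
  if (tdp$n_transitions == 0) abort("No transitions: score undefined.")
  below <- outer(tdp$x, tdp$y, ">")   # after (col) < before (row)
  above <- outer(tdp$x, tdp$y, "<")
  dec <- sum(tdp$density[below])
  inc <- sum(tdp$density[above])
  if (dec + inc <= 0) abort("No off-diagonal mass: score undefined.")
  (dec - inc) / (dec + inc)
}
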