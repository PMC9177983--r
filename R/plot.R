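# ggplot2 visualizations: trajectories with idealized overlays, temporal
# heat maps, TDPs, class column plots, and autoplot methods for fits.

#' Plot a FRET trajectory with its idealized fit
#'
#' @param fret_tbl Output of [compute_fret()].
#' @param segments Optional segment tibble for the same molecule; drawn as
#'   a red piecewise-constant overlay (in usable-frame coordinates).
#' @param molecule Molecule id to plot (default: first in the table).
#' @return A ggplot object.
#' @export
plot_trajectory <- function(fret_tbl, segments = NULL, molecule = NULL) {
  assert_columns(fret_tbl, c("molecule_id", "time_s", "fret"), "fret table")
  molecule <- molecule %||% fret_tbl$molecule_id[1]
  tr <- filter(fret_tbl, .data$molecule_id == molecule)
  p <- ggplot(tr, aes(x = .data$time_s, y = .data$fret)) +
    geom_line(linewidth = 0.3, na.rm = TRUE) +
    labs(x = "time (s)", y = "FRET", title = molecule) +
    coord_cartesian(ylim = c(-0.1, 1.1))
  if (!is.null(segments)) {
    seg <- filter(segments, .data$molecule_id == molecule)
    dt <- infer_dt(tr)
    usable_t <- tr$time_s[tr$usable %||% rep(TRUE, nrow(tr))]
    seg_t <- tibble(
      x = usable_t[seg$start_frame + 1L],
      xend = usable_t[pmin(seg$end_frame, length(usable_t))],
      level = seg$level
    )
    p <- p + geom_segment(
      data = seg_t,
      aes(x = .data$x, xend = .data$xend,
          y = .data$level, yend = .data$level),
      colour = "red", linewidth = 0.7, inherit.aes = FALSE)
  }
  p
}

infer_dt <- function(tr) {
  if (nrow(tr) >= 2) tr$time_s[2] - tr$time_s[1] else 0.2
}

#' Temporal heat map of an ensemble of FRET trajectories
#'
#' 2D histogram of pooled usable frames over (time, FRET), the ensemble
#' view of reaction progress.
#'
#' @param fret_tbl Output of [compute_fret()] (all molecules pooled).
#' @param fret_bins,time_bins Bin counts.
#' @return A ggplot object.
#' @export
plot_heatmap <- function(fret_tbl, fret_bins = 60, time_bins = 120) {
  assert_columns(fret_tbl, c("time_s", "fret", "usable"), "fret table")
  dat <- filter(fret_tbl, .data$usable, is.finite(.data$fret))
  ggplot(dat, aes(x = .data$time_s, y = .data$fret)) +
    geom_bin2d(bins = c(time_bins, fret_bins)) +
    scale_fill_viridis_c(name = "frames") +
    coord_cartesian(ylim = c(-0.1, 1.1)) +
    labs(x = "time (s)", y = "FRET")
}

#' Column plot of trajectory-class percentages
#'
#' @param class_tbl Output of [class_percentages()].
#' @return A ggplot object.
#' @export
plot_classes <- function(class_tbl) {
  assert_columns(class_tbl, c("class", "percent"), "class table")
  ggplot(class_tbl, aes(x = .data$class, y = .data$percent)) +
    geom_col(fill = "grey25") +
    labs(x = NULL, y = "% of trajectories")
}

#' @describeIn build_tdp Heat-map rendering of the transition density.
#' @param object A `tdp_grid`.
#' @param ... Ignored.
#' @export
autoplot.tdp_grid <- function(object, ...) {
  df <- tidyr::expand_grid(from = object$x, to = object$y)
  df$density <- as.vector(t(object$density))  # rows of density = from
  ggplot(df, aes(x = .data$from, y = .data$to, fill = .data$density)) +
    geom_raster() +
    geom_abline(slope = 1, intercept = 0, colour = "white",
                linetype = "dashed", linewidth = 0.3) +
    scale_fill_viridis_c() +
    coord_equal() +
    labs(x = "FRET before", y = "FRET after")
}

#' @describeIn fit_three_gaussians Histogram with fitted component curves.
#' @param object A `mixture_fit`.
#' @param ... Ignored.
#' @export
autoplot.mixture_fit <- function(object, ...) {
  h <- object$histogram
  grid <- seq(min(h$mid), max(h$mid), length.out = 400)
  scale_to_counts <- object$n_obs * object$binwidth
  comp_df <- purrr::map(seq_len(nrow(object$components)), function(k) {
    cc <- object$components[k, ]
    tibble(component = factor(k), fret = grid,
           count = scale_to_counts * cc$weight *
             dnorm(grid, cc$mean, cc$sd))
  }) %>% bind_rows()
  ggplot(h, aes(x = .data$mid, y = .data$count)) +
    geom_col(width = object$binwidth, fill = "grey80") +
    geom_line(data = comp_df,
              aes(x = .data$fret, y = .data$count,
                  colour = .data$component)) +
    labs(x = "FRET", y = "count")
}

#' @describeIn fit_ssa Titration points with the fitted binding isotherm.
#' @param object An `ssa_fit`.
#' @param ... Ignored.
#' @export
autoplot.ssa_fit <- function(object, ...) {
  d <- object$data
  grid <- seq(0, max(d$conc), length.out = 200)
  curve <- tibble(conc = grid,
                  r_eq = object$rmax * grid / (grid + object$kd))
  ggplot(d, aes(x = .data$conc, y = .data$r_eq)) +
    geom_line(data = curve, colour = "red") +
    geom_point() +
    labs(x = "[analyte]", y = expression(R[eq]))
}

#' @describeIn global_decay_fit Decay curves with their global fit.
#' @param object A `global_decay_fit`.
#' @param ... Ignored.
#' @export
autoplot.global_decay_fit <- function(object, ...) {
  ggplot(object$fitted, aes(x = .data$time_s, colour = .data$condition_id)) +
    geom_point(aes(y = .data$intensity), size = 0.5, alpha = 0.5) +
    geom_line(aes(y = .data$fitted)) +
    labs(x = "time (s)", y = "normalized intensity", colour = "condition")
}
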