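# On-disk interchange: all tables are comma-delimited UTF-8 with a mandatory
# header, times in seconds as floats, frames 0-based. Writers use a fixed
# column order and readr's default float formatting (full precision), so
# write -> read is the identity on the data model.

trace_cols <- c("molecule_id", "frame", "time_s", "donor", "acceptor")
dwell_cols <- c("molecule_id", "state_level", "start_s", "duration_s",
                "left_censored", "right_censored")

#' Read an intensity trace table
#'
#' Reads a CSV of per-frame donor/acceptor intensities and validates the
#' schema: columns `molecule_id`, `frame`, `time_s`, `donor`, `acceptor`
#' (optional `fret`), frames contiguous from 0 within each molecule, no
#' duplicated `(molecule_id, frame)`, and `time_s = frame * frame_interval`.
#'
#' @param path File path.
#' @return A validated trace tibble, ordered by molecule and frame, with the
#'   inferred frame interval in attribute `"frame_interval"`.
#' @export
read_traces <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_traces(df)
}

#' Validate an in-memory trace table
#'
#' @param df A data frame with the trace-table schema (see [read_traces()]).
#' @return The validated tibble (invisibly ordered by molecule and frame).
#' @export
validate_traces <- function(df) {
  assert_columns(df, trace_cols, "trace table")
  df <- as_tibble(df) %>% arrange(.data$molecule_id, .data$frame)
  if (nrow(df) == 0) {
    attr(df, "frame_interval") <- NA_real_
    return(df)
  }
  dup <- df %>% count(.data$molecule_id, .data$frame) %>% filter(n > 1)
  if (nrow(dup) > 0) {
    abort(sprintf("Duplicated (molecule_id, frame) rows, e.g. molecule %s frame %d.",
                  dup$molecule_id[1], dup$frame[1]))
  }
  bad <- df %>%
    group_by(.data$molecule_id) %>%
    summarise(ok = all(.data$frame == seq_along(.data$frame) - 1L),
              .groups = "drop") %>%
    filter(!.data$ok)
  if (nrow(bad) > 0) {
    abort(sprintf("Frames not contiguous from 0 for molecule %s.",
                  bad$molecule_id[1]))
  }
  dt <- infer_frame_interval(df)
  if (!is.na(dt) && any(abs(df$time_s - df$frame * dt) > 1e-9)) {
    abort("`time_s` is inconsistent with `frame * frame_interval`.")
  }
  attr(df, "frame_interval") <- dt
  df
}

infer_frame_interval <- function(df) {
  with_two <- df %>%
    group_by(.data$molecule_id) %>%
    filter(n() >= 2) %>%
    ungroup()
  if (nrow(with_two) == 0) return(NA_real_)
  with_two$time_s[with_two$frame == 1][1] - with_two$time_s[with_two$frame == 0][1]
}

#' Write an intensity trace table
#'
#' @param df Trace tibble (validated before writing).
#' @param path Output CSV path.
#' @export
write_traces <- function(df, path) {
  df <- validate_traces(df)
  keep <- intersect(c(trace_cols, "fret"), names(df))
  readr::write_csv(df[, keep], path, progress = FALSE)
  invisible(path)
}

#' Read / write dwell tables
#'
#' Dwell tables carry one row per residence interval in a FRET window:
#' `molecule_id`, `state_level`, `start_s`, `duration_s`, `left_censored`,
#' `right_censored`. An empty table is written as a header-only file.
#'
#' @param path File path.
#' @return `read_dwells()` returns the dwell tibble.
#' @export
read_dwells <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                        col_types = readr::cols(
                          molecule_id = readr::col_character(),
                          state_level = readr::col_double(),
                          start_s = readr::col_double(),
                          duration_s = readr::col_double(),
                          left_censored = readr::col_logical(),
                          right_censored = readr::col_logical()))
  assert_columns(df, dwell_cols, "dwell table")
  as_tibble(df)
}

#' @param dwells Dwell tibble.
#' @rdname read_dwells
#' @export
write_dwells <- function(dwells, path) {
  assert_columns(dwells, dwell_cols, "dwell table")
  if (nrow(dwells) > 0 && any(dwells$duration_s <= 0)) {
    abort("`duration_s` must be > 0.")
  }
  readr::write_csv(as_tibble(dwells)[, dwell_cols], path, progress = FALSE)
  invisible(path)
}

#' Read / write two-column curve tables (decay, binding, spectrum)
#'
#' Thin CSV round-trip helpers for the remaining on-disk artifacts:
#' ensemble decay curves (`condition_id`, `time_s`, `intensity`), binding
#' series (`conc`, `r_eq`) and emission spectra (`wavelength`, `intensity`).
#'
#' @param path File path.
#' @param df The corresponding tibble.
#' @return Readers return the tibble; writers return `path` invisibly.
#' @name curve_io
NULL

#' @rdname curve_io
#' @export
read_decay <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  assert_columns(df, c("condition_id", "time_s", "intensity"), "decay table")
  as_tibble(df)
}

#' @rdname curve_io
#' @export
write_decay <- function(df, path) {
  assert_columns(df, c("condition_id", "time_s", "intensity"), "decay table")
  readr::write_csv(df[, c("condition_id", "time_s", "intensity")], path,
                   progress = FALSE)
  invisible(path)
}

#' @rdname curve_io
#' @export
read_binding <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  assert_columns(df, c("conc", "r_eq"), "binding table")
  as_tibble(df)
}

#' @rdname curve_io
#' @export
write_binding <- function(df, path) {
  assert_columns(df, c("conc", "r_eq"), "binding table")
  readr::write_csv(df[, c("conc", "r_eq")], path, progress = FALSE)
  invisible(path)
}

#' @rdname curve_io
#' @export
read_spectrum <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  assert_columns(df, c("wavelength", "intensity"), "spectrum")
  df <- as_tibble(df)
  if (is.unsorted(df$wavelength, strictly = TRUE)) {
    abort("`wavelength` must be strictly increasing.")
  }
  df
}

#' @rdname curve_io
#' @export
write_spectrum <- function(df, path) {
  assert_columns(df, c("wavelength", "intensity"), "spectrum")
  readr::write_csv(df[, c("wavelength", "intensity")], path, progress = FALSE)
  invisible(path)
}

#' Write a fit report as machine-diffable `key: value` text
#'
#' Serializes any fitted object with [tidy()] and [glance()] methods into a
#' stable plain-text report: one `key: value` line per parameter (value,
#' standard error) and per goodness-of-fit summary.
#'
#' @param fit A fitted object (e.g. from [fit_exponential()], [fit_ssa()]).
#' @param path Output path.
#' @param label Report heading.
#' @export
write_fit_report <- function(fit, path, label = class(fit)[1]) {
  td <- tidy(fit)
  gl <- glance(fit)
  lines <- c(sprintf("model: %s", label))
  for (i in seq_len(nrow(td))) {
    lines <- c(lines, sprintf("%s: %.8g", td$term[i], td$estimate[i]))
    if ("std.error" %in% names(td) && is.finite(td$std.error[i])) {
      lines <- c(lines, sprintf("%s_se: %.8g", td$term[i], td$std.error[i]))
    }
  }
  for (nm in names(gl)) {
    v <- gl[[nm]][1]
    if (is.numeric(v)) lines <- c(lines, sprintf("%s: %.8g", nm, v))
  }
  writeLines(lines, path)
  invisible(path)
}
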