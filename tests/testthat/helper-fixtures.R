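# Shared fixture builders: schemes, segment tables, and a converter from a
# true state path to the segment representation (ground-truth idealization
# without the HMM).

two_state_scheme <- function(k12 = 0.2, k21 = 0.2,
                             fret = c(0.9, 0.4), sd = c(0.05, 0.05)) {
  kinetic_scheme(
    states = data.frame(label = c("s1", "s2"), fret = fret, sd = sd),
    rates = matrix(c(0, k12, k21, 0), 2, 2, byrow = TRUE)
  )
}

three_state_scheme <- function(rates = NULL,
                               fret = c(0.9, 0.6, 0.1),
                               sd = rep(0.03, 3)) {
  if (is.null(rates)) {
    rates <- matrix(c(0, 0.25, 0,
                      0.25, 0, 0.25,
                      0, 0.25, 0), 3, 3, byrow = TRUE)
  }
  kinetic_scheme(
    states = data.frame(label = c("high", "mid", "low"),
                        fret = fret, sd = sd),
    rates = rates
  )
}

# Irreversible cascade 0.9 -> 0.6 -> 0.1 (no reverse rates).
cascade_scheme <- function(k = 0.3) {
  kinetic_scheme(
    states = data.frame(label = c("high", "mid", "low"),
                        fret = c(0.9, 0.6, 0.1), sd = rep(0.03, 3)),
    rates = matrix(c(0, k, 0,
                     0, 0, k,
                     0, 0, 0), 3, 3, byrow = TRUE),
    initial_probs = c(1, 0, 0)
  )
}

# Segment tibble from an explicit sequence of (level, n_frames) runs.
make_segments <- function(levels, lengths = NULL, molecule_id = "m1") {
  if (is.null(lengths)) lengths <- rep(10L, length(levels))
  ends <- cumsum(lengths)
  tibble::tibble(
    molecule_id = molecule_id,
    start_frame = as.integer(ends - lengths),
    end_frame = as.integer(ends),
    level = levels
  )
}

# Ground-truth segments from a simulated state path.
path_to_segments <- function(path, scheme, molecule_id = "m1") {
  lev <- scheme$states$fret[path]
  r <- rle(lev)
  make_segments(r$values, r$lengths, molecule_id)
}

# A set of molecules with a known class composition; each entry of
# `composition` is count per class built from prototype level sets.
class_fixture <- function(counts = c(static = 65, high = 10,
                                     `high-mid` = 14, `high-low` = 9,
                                     `mid-low` = 2)) {
  protos <- list(
    static = 0.9,
    high = c(0.95, 0.8),
    mid = c(0.65, 0.5),
    low = c(0.3, 0.1),
    `high-mid` = c(0.9, 0.6),
    `mid-low` = c(0.6, 0.2),
    `high-low` = c(0.9, 0.6, 0.2)
  )
  segs <- list()
  i <- 0
  for (cls in names(counts)) {
    for (j in seq_len(counts[[cls]])) {
      i <- i + 1
      segs[[i]] <- make_segments(protos[[cls]],
                                 molecule_id = sprintf("m_%03d", i))
    }
  }
  dplyr::bind_rows(segs)
}
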