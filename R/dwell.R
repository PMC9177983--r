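# Dwell-time extraction and censored maximum-likelihood kinetics.

#' Extract residence times in a FRET window from idealized trajectories
#'
#' One dwell record per maximal run of consecutive segments whose levels
#' fall inside `window` (closed interval). Duration is the run's frame
#' count times the frame interval. A run that begins with the trajectory's
#' first segment was already in progress at observation start and is
#' flagged left-censored; a run ending at the trajectory's analysis horizon
#' (trace end or photobleach) is flagged right-censored.
#'
#' @param segments Segment tibble from [viterbi_path()] or [idealize()].
#' @param window Numeric length-2 FRET interval, within `[0, 1]`.
#' @param frame_interval Frame interval in seconds.
#' @return Dwell tibble (`molecule_id`, `state_level` - occupancy-weighted
#'   mean level of the run - `start_s`, `duration_s`, `left_censored`,
#'   `right_censored`).
#' @export
extract_dwells <- function(segments, window, frame_interval = 0.2) {
  assert_columns(segments, c("molecule_id", "start_frame", "end_frame",
                             "level"), "segment table")
  if (length(window) != 2 || window[1] >= window[2] ||
      window[1] < 0 || window[2] > 1) {
    abort("`window` must be an interval within [0, 1].")
  }
  assert_scalar_number(frame_interval, "frame_interval", positive = TRUE)
  empty <- tibble(molecule_id = character(), state_level = double(),
                  start_s = double(), duration_s = double(),
                  left_censored = logical(), right_censored = logical())
  out <- segments %>%
    arrange(.data$molecule_id, .data$start_frame) %>%
    group_by(.data$molecule_id) %>%
    group_split() %>%
    purrr::map(function(seg) {
      inw <- seg$level >= window[1] & seg$level <= window[2]
      if (!any(inw)) return(NULL)
      r <- rle(inw)
      idx_end <- cumsum(r$lengths)
      idx_start <- idx_end - r$lengths + 1L
      keep <- which(r$values)
      horizon <- max(seg$end_frame)
      purrr::map(keep, function(k) {
        i0 <- idx_start[k]; i1 <- idx_end[k]
        sf <- seg$start_frame[i0]; ef <- seg$end_frame[i1]
        frames <- seg$end_frame[i0:i1] - seg$start_frame[i0:i1]
        tibble(
          molecule_id = seg$molecule_id[1],
          state_level = sum(seg$level[i0:i1] * frames) / sum(frames),
          start_s = sf * frame_interval,
          duration_s = (ef - sf) * frame_interval,
          left_censored = i0 == 1L,
          right_censored = ef == horizon
        )
      }) %>% bind_rows()
    }) %>%
    bind_rows()
  bind_rows(empty, out)
}

# Shared preprocessing: drop left-censored records (in progress at
# observation start, biased toward long dwells) unless asked otherwise.
dwell_durations <- function(dwells, include_left_censored) {
  assert_columns(dwells, c("duration_s", "left_censored", "right_censored"),
                 "dwell table")
  if (!include_left_censored) dwells <- filter(dwells, !.data$left_censored)
  list(obs = dwells$duration_s[!dwells$right_censored],
       cens = dwells$duration_s[dwells$right_censored])
}

#' Censored exponential maximum likelihood for dwell times
#'
#' Fits a single-exponential dwell model (one Poisson process with a single
#' rate-limiting step) by the censored MLE closed form: `tau-hat = (sum of
#' all durations, censored included) / (number of uncensored events)`, with
#' `SE = tau-hat / sqrt(n_uncensored)`. Right-censored records enter the
#' likelihood through their survival terms; left-censored records are
#' excluded by default.
#'
#' @param dwells Dwell tibble.
#' @param include_left_censored Include left-censored records as ordinary
#'   observations (default `FALSE`).
#' @return An object of class `exp_fit`: `tau`, `se_tau`, `n_events`,
#'   `n_censored`, `logLik`, `AIC`, `BIC`.
#' @examples
#' d <- simulate_dwells(200, tau = 5, censor_at = 120, seed = 1)
#' fit_exponential(d)
#' @export
fit_exponential <- function(dwells, include_left_censored = FALSE) {
  dd <- dwell_durations(dwells, include_left_censored)
  n_unc <- length(dd$obs)
  if (n_unc < 1) abort("No uncensored events: lifetime inestimable.")
  total <- sum(dd$obs) + sum(dd$cens)
  tau <- total / n_unc
  ll <- -n_unc * log(tau) - total / tau
  structure(
    list(tau = tau, se_tau = tau / sqrt(n_unc),
         n_events = n_unc, n_censored = length(dd$cens),
         logLik = ll, AIC = -2 * ll + 2, BIC = -2 * ll + log(n_unc)),
    class = "exp_fit"
  )
}

#' @export
print.exp_fit <- function(x, ...) {
  cat(sprintf("<exp_fit: tau = %.4g +/- %.2g s (n = %d, censored = %d)>\n",
              x$tau, x$se_tau, x$n_events, x$n_censored))
  invisible(x)
}

#' Censored gamma maximum likelihood for dwell times
#'
#' Fits a gamma dwell model (multiple sequential steps with comparable
#' lifetimes) by numerical maximum likelihood over `(shape, scale)`,
#' optimized on the log scale from a method-of-moments start.
#' Right-censored events contribute survival terms; left-censored records
#' are excluded by default. The characteristic lifetime reported is the
#' scale parameter (the per-step lifetime); the mean dwell is
#' `shape * scale`. A degenerate sample drives the shape upward; it is
#' capped at 100 with a warning.
#'
#' @inheritParams fit_exponential
#' @return An object of class `gamma_fit`: `shape`, `scale`, `se_shape`,
#'   `se_scale`, `mean_dwell`, `n_events`, `n_censored`, `logLik`, `AIC`,
#'   `BIC`, `converged`.
#' @examples
#' d <- simulate_dwells(500, dist = "gamma", shape = 2, scale = 0.7, seed = 1)
#' fit_gamma(d)
#' @export
fit_gamma <- function(dwells, include_left_censored = FALSE) {
  dd <- dwell_durations(dwells, include_left_censored)
  n_unc <- length(dd$obs)
  if (n_unc < 5) abort("Need at least 5 uncensored events for a gamma fit.")
  m <- mean(dd$obs); v <- var(dd$obs)
  if (v < 1e-10 * m^2) {
    # all durations (near-)identical: shape MLE diverges upward
    warn("Gamma shape capped at 100 (near-degenerate dwell sample).")
    return(structure(
      list(shape = 100, scale = m / 100, se_shape = NA_real_,
           se_scale = NA_real_, mean_dwell = m, n_events = n_unc,
           n_censored = length(dd$cens), logLik = NA_real_,
           AIC = NA_real_, BIC = NA_real_, converged = FALSE),
      class = "gamma_fit"))
  }
  sh0 <- min(max(m^2 / v, 1e-2), 200)
  sc0 <- max(v / m, 1e-8)
  nll <- function(p) {
    sh <- exp(p[1]); sc <- exp(p[2])
    -(sum(dgamma(dd$obs, shape = sh, scale = sc, log = TRUE)) +
        sum(pgamma(dd$cens, shape = sh, scale = sc,
                   lower.tail = FALSE, log.p = TRUE)))
  }
  opt <- tryCatch(
    optim(log(c(sh0, sc0)), nll, method = "BFGS", hessian = TRUE,
          control = list(maxit = 500)),
    error = function(e) abort(sprintf("Gamma fit failed to converge: %s",
                                      conditionMessage(e)))
  )
  if (!is.finite(opt$value)) abort("Gamma fit failed: non-finite likelihood.")
  sh <- exp(opt$par[1]); sc <- exp(opt$par[2])
  if (sh > 100) {
    warn("Gamma shape capped at 100 (near-degenerate dwell sample).")
    sh <- 100
  }
  ses <- tryCatch({
    cv <- solve(opt$hessian)
    sqrt(pmax(diag(cv), 0)) * c(sh, sc)  # delta method from log scale
  }, error = function(e) c(NA_real_, NA_real_))
  ll <- -opt$value
  structure(
    list(shape = sh, scale = sc, se_shape = ses[1], se_scale = ses[2],
         mean_dwell = sh * sc, n_events = n_unc,
         n_censored = length(dd$cens), logLik = ll,
         AIC = -2 * ll + 4, BIC = -2 * ll + 2 * log(n_unc),
         converged = opt$convergence == 0),
    class = "gamma_fit"
  )
}

#' @export
print.gamma_fit <- function(x, ...) {
  cat(sprintf(
    "<gamma_fit: shape = %.4g, scale = %.4g s (mean %.4g s, n = %d)>\n",
    x$shape, x$scale, x$mean_dwell, x$n_events))
  invisible(x)
}

#' Compare exponential and gamma dwell models
#'
#' Fits both models to the same dwell table and prefers the lower BIC;
#' a BIC difference below 2 is flagged indeterminate.
#'
#' @inheritParams fit_exponential
#' @return List with `exponential`, `gamma` (the fits), `comparison`
#'   (tibble of logLik/AIC/BIC), `preferred` (`"exponential"`, `"gamma"`),
#'   `indeterminate` (logical), `delta_aic`, `delta_bic`.
#' @export
compare_dwell_models <- function(dwells, include_left_censored = FALSE) {
  fe <- fit_exponential(dwells, include_left_censored)
  fg <- fit_gamma(dwells, include_left_censored)
  cmp <- tibble(
    model = c("exponential", "gamma"),
    logLik = c(fe$logLik, fg$logLik),
    AIC = c(fe$AIC, fg$AIC),
    BIC = c(fe$BIC, fg$BIC)
  )
  d_bic <- fe$BIC - fg$BIC
  list(
    exponential = fe, gamma = fg, comparison = cmp,
    preferred = if (d_bic > 0) "gamma" else "exponential",
    indeterminate = abs(d_bic) < 2,
    delta_aic = fe$AIC - fg$AIC,
    delta_bic = d_bic
  )
}
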