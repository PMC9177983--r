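# Ensemble-level model fits: global multi-exponential decay with a shared
# photobleaching lifetime, three-Gaussian FRET-histogram decomposition,
# 1:1 steady-state affinity, and emission-spectrum helpers.

#' Global two-exponential decay fit with a shared lifetime
#'
#' Fits `y_i(t) = A_1i * exp(-t / tau) + A_2i * exp(-t / tau_2i)` jointly
#' across conditions by Levenberg-Marquardt nonlinear least squares,
#' with the first lifetime `tau` (photobleaching) shared by every curve
#' and the second component optional per condition. Conditions named in
#' `single_exponential` have `A_2i` constrained to zero (their `tau_2i` is
#' not a parameter). Iterations stop when the chi-square change falls
#' below `ftol` (default 1e-9). Curves are normalized to their first
#' intensity value before fitting unless `normalize = FALSE`.
#'
#' @param curves Decay tibble (`condition_id`, `time_s`, `intensity`),
#'   one or more conditions.
#' @param single_exponential Character vector of condition ids constrained
#'   to a single exponential.
#' @param normalize Divide each curve by its first intensity value.
#' @param ftol Chi-square convergence tolerance.
#' @param maxfev Maximum residual evaluations before the best-so-far
#'   parameters are returned with a warning.
#' @return An object of class `global_decay_fit`: `tau`, `se_tau`,
#'   `params` (per-condition tibble of amplitudes/lifetimes and SEs),
#'   `chisq`, `n_obs`, `converged`, plus the fitted curves in `fitted`.
#' @examples
#' curves <- dplyr::bind_rows(
#'   simulate_ensemble_decay(0.973, 11.3, condition_id = "alone"),
#'   simulate_ensemble_decay(c(0.49, 0.52), c(11.3, 4.6),
#'                           condition_id = "plus_atp"))
#' global_decay_fit(curves, single_exponential = "alone")
#' @export
global_decay_fit <- function(curves, single_exponential = character(),
                             normalize = TRUE, ftol = 1e-9,
                             maxfev = 10000) {
  assert_columns(curves, c("condition_id", "time_s", "intensity"),
                 "decay table")
  curves <- as_tibble(curves) %>% arrange(.data$condition_id, .data$time_s)
  conds <- unique(curves$condition_id)
  if (length(conds) < 1) abort("Need at least one decay curve.")
  unknown <- setdiff(single_exponential, conds)
  if (length(unknown) > 0) {
    abort(sprintf("Unknown condition(s) in `single_exponential`: %s",
                  paste(unknown, collapse = ", ")))
  }
  two_exp <- setdiff(conds, single_exponential)
  by_cond <- purrr::map(conds, function(cid) {
    cc <- filter(curves, .data$condition_id == cid)
    y <- cc$intensity
    if (normalize) {
      if (y[1] == 0) abort(sprintf("Condition %s starts at zero intensity.",
                                   cid))
      y <- y / y[1]
    }
    list(t = cc$time_s, y = y)
  })
  names(by_cond) <- conds

  # parameter vector: tau, A1 per condition, then (A2, tau2) per two-exp cond
  p0 <- c(tau = guess_tau(by_cond[[1]]$t, by_cond[[1]]$y))
  for (cid in conds) p0[paste0("A1_", cid)] <- by_cond[[cid]]$y[1] * 0.8
  for (cid in two_exp) {
    p0[paste0("A2_", cid)] <- by_cond[[cid]]$y[1] * 0.2
    p0[paste0("tau2_", cid)] <- p0[["tau"]] / 3
  }
  resid_fun <- function(p) {
    unlist(purrr::map(conds, function(cid) {
      d <- by_cond[[cid]]
      yhat <- p[paste0("A1_", cid)] * exp(-d$t / p["tau"])
      if (cid %in% two_exp) {
        yhat <- yhat + p[paste0("A2_", cid)] *
          exp(-d$t / p[paste0("tau2_", cid)])
      }
      d$y - yhat
    }), use.names = FALSE)
  }
  lower <- setNames(rep(-Inf, length(p0)), names(p0))
  lower[grepl("^tau", names(p0))] <- 1e-6
  fit <- minpack.lm::nls.lm(
    par = p0, fn = resid_fun, lower = lower,
    control = minpack.lm::nls.lm.control(ftol = ftol, maxfev = maxfev,
                                         maxiter = 1000))
  if (fit$info == 5) {
    warn("Global decay fit: evaluation budget exhausted; returning best-so-far parameters.")
  }
  est <- fit$par
  ses <- tryCatch({
    sm <- summary(fit)
    setNames(sm$coefficients[, "Std. Error"], rownames(sm$coefficients))
  }, error = function(e) setNames(rep(NA_real_, length(est)), names(est)))

  params <- purrr::map(conds, function(cid) {
    tibble(
      condition_id = cid,
      A1 = est[[paste0("A1_", cid)]],
      se_A1 = ses[[paste0("A1_", cid)]],
      A2 = if (cid %in% two_exp) est[[paste0("A2_", cid)]] else 0,
      se_A2 = if (cid %in% two_exp) ses[[paste0("A2_", cid)]] else NA_real_,
      tau2 = if (cid %in% two_exp) est[[paste0("tau2_", cid)]] else NA_real_,
      se_tau2 = if (cid %in% two_exp) ses[[paste0("tau2_", cid)]] else NA_real_
    )
  }) %>% bind_rows()

  fitted <- purrr::map(conds, function(cid) {
    d <- by_cond[[cid]]
    yhat <- est[[paste0("A1_", cid)]] * exp(-d$t / est[["tau"]])
    if (cid %in% two_exp) {
      yhat <- yhat + est[[paste0("A2_", cid)]] *
        exp(-d$t / est[[paste0("tau2_", cid)]])
    }
    tibble(condition_id = cid, time_s = d$t, intensity = d$y,
           fitted = yhat)
  }) %>% bind_rows()

  structure(
    list(tau = est[["tau"]], se_tau = ses[["tau"]], params = params,
         chisq = fit$deviance, n_obs = nrow(curves),
         converged = fit$info %in% 1:4, fitted = fitted),
    class = "global_decay_fit"
  )
}

guess_tau <- function(t, y) {
  # time at which the curve falls to 1/e of its initial value
  y0 <- y[1]
  idx <- which(y <= y0 / exp(1))[1]
  if (is.na(idx)) max(t[length(t)], 1) else max(t[idx], 1e-3)
}

#' @export
print.global_decay_fit <- function(x, ...) {
  cat(sprintf("<global_decay_fit: shared tau = %.4g +/- %.2g s, chisq = %.4g>\n",
              x$tau, x$se_tau, x$chisq))
  print(x$params)
  invisible(x)
}

#' Three-Gaussian decomposition of a FRET histogram
#'
#' Bins a FRET-state sample (bin width 0.02 over `[-0.1, 1.1]` by default)
#' and fits the sum of three Gaussian curves to the histogram counts by
#' Levenberg-Marquardt least squares, initialized at the three largest
#' modes of a five-point moving-average smoothed histogram. Components are
#' reported sorted by mean with 95% confidence bounds on the means from
#' the parameter covariance; a component whose weight falls below 0.02 is
#' flagged as collapsed. `method = "em"` instead fits the sample directly
#' by Gaussian-mixture EM (requires the mclust package), as an independent
#' route for well-separated mixtures.
#'
#' @param x Numeric FRET sample (>= 100 values for the histogram route).
#' @param binwidth,range Histogram geometry.
#' @param method `"histogram"` (least squares on binned counts, default)
#'   or `"em"`.
#' @return An object of class `mixture_fit`: `components` tibble
#'   (`component`, `weight`, `mean`, `sd`, `mean_lb`, `mean_ub`,
#'   `collapsed`), `rss`, `n_obs`, `method`, plus the binned histogram in
#'   `histogram`.
#' @examples
#' x <- simulate_fret_sample(
#'   data.frame(weight = rep(1 / 3, 3), mean = c(0.91, 0.63, 0.09),
#'              sd = 0.06), n = 3000, seed = 1)
#' fit_three_gaussians(x)
#' @export
fit_three_gaussians <- function(x, binwidth = 0.02, range = c(-0.1, 1.1),
                                method = c("histogram", "em")) {
  method <- match.arg(method)
  x <- as.numeric(x[is.finite(x)])
  if (length(x) < 100) abort("Need at least 100 observations.")
  breaks <- seq(range[1], range[2], by = binwidth)
  x_in <- x[x >= range[1] & x <= range[2]]
  h <- graphics::hist(x_in, breaks = breaks, plot = FALSE)
  histogram <- tibble(mid = h$mids, count = as.numeric(h$counts))

  if (method == "em") {
    if (!requireNamespace("mclust", quietly = TRUE)) {
      abort("method = \"em\" requires the mclust package.")
    }
    mclustBIC <- mclust::mclustBIC  # Mclust resolves this in the caller
    em <- mclust::Mclust(x, G = 3, modelNames = "V", verbose = FALSE)
    comp <- tibble(
      weight = as.numeric(em$parameters$pro),
      mean = as.numeric(em$parameters$mean),
      sd = sqrt(as.numeric(em$parameters$variance$sigmasq)),
      mean_lb = NA_real_, mean_ub = NA_real_
    )
    rss <- NA_real_
  } else {
    init <- mixture_init(histogram)
    p0 <- c(a = init$a, m = init$m, s = init$s)
    model_counts <- function(p) {
      a <- p[1:3]; m <- p[4:6]; s <- p[7:9]
      rowSums(vapply(1:3, function(k) {
        a[k] * exp(-(histogram$mid - m[k])^2 / (2 * s[k]^2))
      }, numeric(nrow(histogram))))
    }
    fit <- minpack.lm::nls.lm(
      par = p0, fn = function(p) histogram$count - model_counts(p),
      lower = c(rep(0, 3), rep(range[1], 3), rep(0.005, 3)),
      upper = c(rep(Inf, 3), rep(range[2], 3), rep(0.5, 3)),
      control = minpack.lm::nls.lm.control(maxiter = 500))
    est <- fit$par
    ses <- tryCatch({
      sm <- summary(fit)
      sm$coefficients[, "Std. Error"]
    }, error = function(e) rep(NA_real_, 9))
    a <- as.numeric(est[1:3]); m <- as.numeric(est[4:6])
    s <- as.numeric(est[7:9])
    se_m <- as.numeric(ses[4:6])
    w_raw <- a * s                     # component area ~ a * s * sqrt(2*pi)
    comp <- tibble(
      weight = w_raw / sum(w_raw),
      mean = m, sd = s,
      mean_lb = m - 1.96 * se_m,
      mean_ub = m + 1.96 * se_m
    )
    rss <- fit$deviance
  }
  comp <- comp %>%
    arrange(.data$mean) %>%
    mutate(component = dplyr::row_number(),
           collapsed = .data$weight < 0.02) %>%
    select("component", "weight", "mean", "sd",
           "mean_lb", "mean_ub", "collapsed")
  if (any(comp$collapsed)) {
    warn("Possible component collapse: a fitted weight is below 0.02.")
  }
  structure(
    list(components = comp, rss = rss, n_obs = length(x),
         method = method, histogram = histogram, binwidth = binwidth),
    class = "mixture_fit"
  )
}

# Three largest local maxima of the smoothed histogram; fall back to
# quantile-spread starts when fewer than three modes resolve.
mixture_init <- function(histogram) {
  cnt <- histogram$count
  sm <- as.numeric(stats::filter(cnt, rep(1 / 5, 5), sides = 2))
  sm[is.na(sm)] <- cnt[is.na(sm)]
  n <- length(sm)
  is_mode <- sm > c(-Inf, sm[-n]) & sm >= c(sm[-1], -Inf) & sm > 0
  modes <- which(is_mode)
  modes <- modes[order(sm[modes], decreasing = TRUE)]
  m <- histogram$mid[modes]
  if (length(m) >= 3) {
    m <- m[1:3]
  } else {
    fill <- c(0.1, 0.5, 0.9)
    m <- c(m, fill[seq_len(3 - length(m))])
  }
  a <- vapply(m, function(mu) {
    max(sm[which.min(abs(histogram$mid - mu))], 1)
  }, numeric(1))
  list(a = a, m = m, s = rep(0.05, 3))
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf("<mixture_fit (%s): n = %d>\n", x$method, x$n_obs))
  print(x$components)
  invisible(x)
}

#' 1:1 steady-state affinity fit
#'
#' Fits the steady-state binding model `R_eq = R_max * [A] / ([A] + K_D)`
#' to equilibrium responses by Levenberg-Marquardt nonlinear least
#' squares, initialized at `K_D` = concentration of half-maximal response
#' and `R_max = 1.1 * max(R_eq)`. A response series that decreases beyond
#' 5% of the maximum between consecutive concentrations is flagged
#' non-monotone (the fit still proceeds).
#'
#' @param series Binding tibble (`conc`, `r_eq`), at least 4 distinct
#'   non-zero concentrations.
#' @return An object of class `ssa_fit`: `kd`, `rmax`, `se_kd`, `se_rmax`,
#'   `rss`, `n_obs`, `monotone`, plus the data in `data`.
#' @examples
#' fit_ssa(simulate_binding_series(kd = 170, rmax = 100))
#' @export
fit_ssa <- function(series) {
  assert_columns(series, c("conc", "r_eq"), "binding series")
  series <- as_tibble(series) %>% arrange(.data$conc)
  if (any(series$conc < 0)) abort("Concentrations must be >= 0.")
  if (n_distinct(series$conc[series$conc > 0]) < 4) {
    abort("Need at least 4 distinct non-zero concentrations.")
  }
  rmax0 <- 1.1 * max(series$r_eq)
  half <- max(series$r_eq) / 2
  above <- which(series$r_eq >= half & series$conc > 0)
  kd0 <- if (length(above) > 0) series$conc[above[1]] else
    stats::median(series$conc[series$conc > 0])
  fit <- minpack.lm::nls.lm(
    par = c(kd = kd0, rmax = rmax0),
    fn = function(p) {
      series$r_eq - p["rmax"] * series$conc / (series$conc + p["kd"])
    },
    lower = c(kd = 1e-12, rmax = 1e-12),
    control = minpack.lm::nls.lm.control(ftol = 1e-12, maxiter = 1000))
  ses <- tryCatch({
    sm <- summary(fit)
    setNames(sm$coefficients[, "Std. Error"], rownames(sm$coefficients))
  }, error = function(e) c(kd = NA_real_, rmax = NA_real_))
  drops <- diff(series$r_eq)
  monotone <- all(drops >= -0.05 * max(series$r_eq))
  if (!monotone) warn("Response series is non-monotone beyond noise.")
  structure(
    list(kd = fit$par[["kd"]], rmax = fit$par[["rmax"]],
         se_kd = ses[["kd"]], se_rmax = ses[["rmax"]],
         rss = fit$deviance, n_obs = nrow(series),
         monotone = monotone, data = series),
    class = "ssa_fit"
  )
}

#' @export
print.ssa_fit <- function(x, ...) {
  cat(sprintf("<ssa_fit: K_D = %.4g +/- %.2g, R_max = %.4g +/- %.2g>\n",
              x$kd, x$se_kd, x$rmax, x$se_rmax))
  invisible(x)
}

#' Average the steady-state window of a sensorgram
#'
#' Extracts the equilibrium response `R_eq` as the mean response inside a
#' configured steady-state time window.
#'
#' @param sensorgram Tibble with columns `time_s`, `response`.
#' @param window Length-2 time window (seconds).
#' @return Scalar `R_eq`.
#' @export
steady_state_response <- function(sensorgram, window) {
  assert_columns(sensorgram, c("time_s", "response"), "sensorgram")
  if (length(window) != 2 || window[1] >= window[2]) {
    abort("`window` must be an increasing length-2 time interval.")
  }
  sel <- sensorgram$time_s >= window[1] & sensorgram$time_s <= window[2]
  if (!any(sel)) abort("No sensorgram points inside the steady-state window.")
  mean(sensorgram$response[sel])
}

#' Affinity trend across overhang lengths
#'
#' Tabulates fitted dissociation constants against single-stranded
#' overhang length and reports the fold change `K_D(longest) /
#' K_D(shortest)` together with a strict-monotonicity flag.
#'
#' @param fits Data frame with columns `overhang_nt` and `kd` (or a list
#'   of `ssa_fit` objects in column `fit`).
#' @return List with `table` (sorted tibble), `fold_change`, `monotone`.
#' @examples
#' overhang_trend(data.frame(overhang_nt = c(0, 15), kd = c(90, 220)))
#' @export
overhang_trend <- function(fits) {
  fits <- as_tibble(fits)
  if ("fit" %in% names(fits) && !("kd" %in% names(fits))) {
    fits$kd <- vapply(fits$fit, function(f) f$kd, numeric(1))
  }
  assert_columns(fits, c("overhang_nt", "kd"), "overhang table")
  if (nrow(fits) < 2) abort("Need at least 2 overhang lengths.")
  tab <- fits %>% select("overhang_nt", "kd") %>%
    arrange(.data$overhang_nt)
  list(
    table = tab,
    fold_change = tab$kd[nrow(tab)] / tab$kd[1],
    monotone = all(diff(tab$kd) > 0)
  )
}

#' Difference of two emission spectra
#'
#' Pointwise `a - b` on identical wavelength grids (no interpolation):
#' the standard route to a melting-induced fluorescence enhancement
#' signal, e.g. bubble-substrate minus duplex-substrate emission.
#'
#' @param a,b Spectrum tibbles (`wavelength`, `intensity`) on identical
#'   grids.
#' @return Spectrum tibble of the difference.
#' @export
difference_spectrum <- function(a, b) {
  assert_columns(a, c("wavelength", "intensity"), "spectrum a")
  assert_columns(b, c("wavelength", "intensity"), "spectrum b")
  if (nrow(a) != nrow(b) || any(abs(a$wavelength - b$wavelength) > 1e-9)) {
    abort("Wavelength grids differ; no interpolation is applied.")
  }
  tibble(wavelength = a$wavelength, intensity = a$intensity - b$intensity)
}

#' Centered moving average of a spectrum
#'
#' Five-point centered moving average by default; windows shrink at the
#' spectrum edges (down to a single point).
#'
#' @param s Spectrum tibble (`wavelength`, `intensity`).
#' @param window Odd window width in points.
#' @return Smoothed spectrum tibble.
#' @export
moving_average <- function(s, window = 5) {
  assert_columns(s, c("wavelength", "intensity"), "spectrum")
  assert_scalar_number(window, "window", positive = TRUE)
  window <- as.integer(window)
  if (window %% 2 == 0) abort("`window` must be odd.")
  h <- (window - 1L) %/% 2L
  n <- nrow(s)
  sm <- vapply(seq_len(n), function(i) {
    mean(s$intensity[max(1, i - h):min(n, i + h)])
  }, numeric(1))
  tibble(wavelength = s$wavelength, intensity = sm)
}
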