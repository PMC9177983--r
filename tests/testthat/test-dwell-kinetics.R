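test_that("dwell extraction handles windows, durations and censoring", {
  seg <- make_segments(c(0.9, 0.45, 0.9), lengths = c(10L, 25L, 10L))
  d <- extract_dwells(seg, window = c(0.35, 0.5), frame_interval = 0.2)
  expect_identical(nrow(d), 1L)
  expect_equal(d$duration_s, 5.0)
  expect_false(d$left_censored)
  expect_false(d$right_censored)

  # run abutting the trace end is right-censored; first-segment run is
  # left-censored
  seg2 <- make_segments(c(0.45, 0.9, 0.4), lengths = c(5L, 10L, 8L))
  d2 <- extract_dwells(seg2, c(0.35, 0.5))
  expect_identical(nrow(d2), 2L)
  expect_true(d2$left_censored[1])
  expect_true(d2$right_censored[2])

  # consecutive in-window segments merge into one run
  seg3 <- make_segments(c(0.9, 0.45, 0.38, 0.9),
                        lengths = c(5L, 10L, 10L, 5L))
  d3 <- extract_dwells(seg3, c(0.35, 0.5))
  expect_identical(nrow(d3), 1L)
  expect_equal(d3$duration_s, 4.0)

  expect_identical(nrow(extract_dwells(make_segments(c(0.9, 0.8)),
                                       c(0.35, 0.5))), 0L)
  expect_error(extract_dwells(seg, c(0.5, 0.35)), "interval")
})

dwell_tbl <- function(obs, cens = numeric(0)) {
  tibble::tibble(
    molecule_id = "m", state_level = 0.45, start_s = 0,
    duration_s = c(obs, cens),
    left_censored = FALSE,
    right_censored = c(rep(FALSE, length(obs)), rep(TRUE, length(cens))))
}

test_that("censored exponential MLE matches its closed forms", {
  expect_equal(fit_exponential(dwell_tbl(c(2, 4, 6)))$tau, 4.0)
  f <- fit_exponential(dwell_tbl(c(2, 4), cens = 6))
  expect_equal(f$tau, 6.0)
  expect_identical(f$n_events, 2L)
  expect_identical(f$n_censored, 1L)
  expect_error(fit_exponential(dwell_tbl(numeric(0), cens = c(1, 2))),
               "inestimable")

  # left-censored records are excluded by default
  d <- dwell_tbl(c(2, 4, 6))
  d$left_censored[1] <- TRUE
  expect_equal(fit_exponential(d)$tau, 5.0)
  expect_equal(fit_exponential(d, include_left_censored = TRUE)$tau, 4.0)
})

test_that("closed-form censored MLE equals the numerical optimizer", {
  d <- simulate_dwells(200, tau = 5, censor_at = 12, seed = 1)
  f <- fit_exponential(d)
  obs <- d$duration_s[!d$right_censored]
  cens <- d$duration_s[d$right_censored]
  nll <- function(tau) length(obs) * log(tau) + (sum(obs) + sum(cens)) / tau
  opt <- optimize(nll, c(0.1, 100), tol = 1e-10)
  expect_equal(f$tau, opt$minimum, tolerance = 1e-6)
})

test_that("exponential recovery has calibrated coverage and is consistent", {
  # coverage at tau = 5 s, n = 200, censoring at 120 s
  hits <- vapply(1:100, function(i) {
    d <- simulate_dwells(200, tau = 5, censor_at = 120, seed = 1000 + i)
    f <- fit_exponential(d)
    abs(f$tau - 5) <= 2 * f$se_tau
  }, logical(1))
  expect_gte(mean(hits), 0.90)

  # median error decreases as n doubles
  med_err <- vapply(c(50, 200, 800), function(n) {
    errs <- vapply(1:50, function(i) {
      abs(fit_exponential(simulate_dwells(n, tau = 5,
                                          seed = n * 100 + i))$tau - 5)
    }, numeric(1))
    median(errs)
  }, numeric(1))
  expect_true(all(diff(med_err) < 0))
})

test_that("gamma MLE nests the exponential and recovers its parameters", {
  d <- simulate_dwells(400, tau = 5, seed = 2)
  fe <- fit_exponential(d)
  fg <- fit_gamma(d)
  # shape near 1 for exponential data; scale * shape near the mean
  expect_lt(abs(fg$shape - 1), 0.15)
  expect_equal(fg$mean_dwell, fe$tau, tolerance = 0.01)

  # parameter recovery from gamma(2, 0.7)
  hits <- vapply(1:50, function(i) {
    dg <- simulate_dwells(500, dist = "gamma", shape = 2, scale = 0.7,
                          seed = 2000 + i)
    f <- fit_gamma(dg)
    abs(f$scale - 0.7) <= 2 * f$se_scale
  }, logical(1))
  expect_gte(mean(hits), 0.9)

  # right-censoring enters through survival terms without large bias
  dc <- simulate_dwells(500, dist = "gamma", shape = 2, scale = 0.7,
                        censor_at = 2.5, seed = 3)
  expect_gt(sum(dc$right_censored), 10)
  fc <- fit_gamma(dc)
  expect_lt(abs(fc$scale - 0.7), 0.15)

  # degenerate sample: shape capped with a warning
  deg <- dwell_tbl(rep(2, 50))
  expect_warning(fd <- fit_gamma(deg), "capped")
  expect_equal(fd$shape, 100)

  expect_error(fit_gamma(dwell_tbl(c(1, 2, 3))), "at least 5")
})

test_that("model comparison prefers the generating family", {
  exp_wins <- vapply(1:10, function(i) {
    d <- simulate_dwells(500, tau = 5, seed = 3000 + i)
    compare_dwell_models(d)$preferred == "exponential"
  }, logical(1))
  expect_gte(mean(exp_wins), 0.9)

  gam_wins <- vapply(1:10, function(i) {
    d <- simulate_dwells(500, dist = "gamma", shape = 3, scale = 2,
                         seed = 4000 + i)
    compare_dwell_models(d)$preferred == "gamma"
  }, logical(1))
  expect_gte(mean(gam_wins), 0.9)

  # tiny samples do not crash and are typically indeterminate
  cmp <- compare_dwell_models(simulate_dwells(5, tau = 5, seed = 5))
  expect_true(is.logical(cmp$indeterminate))
})
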