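test_that("global decay fit is exact on noiseless model data", {
  c1 <- simulate_ensemble_decay(0.973, 11.3, condition_id = "a")
  f1 <- global_decay_fit(c1, single_exponential = "a", normalize = FALSE)
  expect_equal(f1$tau, 11.3, tolerance = 1e-6)
  expect_equal(f1$params$A1, 0.973, tolerance = 1e-6)

  # two identical single-exponential curves: shared tau = individual tau
  c2 <- dplyr::bind_rows(
    simulate_ensemble_decay(1, 8, condition_id = "a"),
    simulate_ensemble_decay(1, 8, condition_id = "b"))
  f2 <- global_decay_fit(c2, single_exponential = c("a", "b"),
                         normalize = FALSE)
  expect_equal(f2$tau, 8, tolerance = 1e-6)
})

test_that("global fit recovers the printed parameter set under noise", {
  curves <- dplyr::bind_rows(
    simulate_ensemble_decay(0.973, 11.3, noise_sd = 0.01,
                            condition_id = "ec_alone", seed = 1),
    simulate_ensemble_decay(c(0.49, 0.52), c(11.3, 4.6), noise_sd = 0.01,
                            condition_id = "mfd_atp", seed = 2))
  fit <- global_decay_fit(curves, single_exponential = "ec_alone",
                          normalize = FALSE)
  expect_true(fit$converged)
  expect_lt(abs(fit$tau - 11.3) / 11.3, 0.05)
  tau2 <- fit$params$tau2[fit$params$condition_id == "mfd_atp"]
  expect_lt(abs(tau2 - 4.6) / 4.6, 0.05)

  # global residual no worse than per-curve fits at the shared tau
  rss_single <- sum(vapply(unique(curves$condition_id), function(cid) {
    cc <- dplyr::filter(curves, condition_id == cid)
    single <- global_decay_fit(
      cc, single_exponential = intersect(cid, "ec_alone"),
      normalize = FALSE)
    # residual of the single fit evaluated with tau forced to the global
    pr <- single$params
    yhat <- pr$A1 * exp(-cc$time_s / fit$tau) +
      ifelse(is.na(pr$tau2), 0, pr$A2 * exp(-cc$time_s / pr$tau2))
    sum((cc$intensity - yhat)^2)
  }, numeric(1)))
  expect_lte(fit$chisq, rss_single + 1e-8)
})

test_that("three-Gaussian histogram fit recovers mixture parameters", {
  x <- simulate_fret_sample(
    data.frame(weight = rep(1 / 3, 3), mean = c(0.91, 0.63, 0.09),
               sd = 0.06), n = 3000, seed = 3)
  fit <- fit_three_gaussians(x)
  expect_equal(fit$components$mean, c(0.09, 0.63, 0.91), tolerance = 0.03)
  expect_equal(sum(fit$components$weight), 1, tolerance = 1e-6)
  expect_true(all(diff(fit$components$mean) > 0))
  # 95% CI bounds bracket the fitted means
  expect_true(all(fit$components$mean_lb < fit$components$mean))
  expect_true(all(fit$components$mean_ub > fit$components$mean))

  # single-component sample: collapse flagged
  x1 <- simulate_fret_sample(data.frame(weight = 1, mean = 0.5, sd = 0.05),
                             2000, seed = 4)
  expect_warning(f1 <- fit_three_gaussians(x1), "collapse")
  expect_gte(sum(f1$components$collapsed), 1)

  expect_error(fit_three_gaussians(rnorm(50)), "100")
})

test_that("histogram and EM mixture routes agree on separated fixtures", {
  skip_if_not_installed("mclust")
  x <- simulate_fret_sample(
    data.frame(weight = c(0.3, 0.4, 0.3), mean = c(0.1, 0.5, 0.9),
               sd = 0.04), n = 4000, seed = 5)
  fh <- fit_three_gaussians(x, method = "histogram")
  fe <- fit_three_gaussians(x, method = "em")
  expect_equal(fh$components$mean, fe$components$mean, tolerance = 0.02)
  expect_equal(fh$components$weight, fe$components$weight, tolerance = 0.05)
})

test_that("mixture mean recovery is stable across replicates", {
  truth <- c(0.09, 0.63, 0.91)
  rmse <- vapply(1:30, function(i) {
    x <- simulate_fret_sample(
      data.frame(weight = rep(1 / 3, 3), mean = rev(truth), sd = 0.06),
      n = 3000, seed = 5000 + i)
    sqrt(mean((fit_three_gaussians(x)$components$mean - truth)^2))
  }, numeric(1))
  expect_lt(sqrt(mean(rmse^2)), 0.03)
})

test_that("SSA fit is exact on noiseless isotherms over a wide range", {
  set.seed(6)
  for (i in 1:20) {
    kd <- 10^runif(1, 0, 3)             # 1 .. 1000 concentration units
    rmax <- 10^runif(1, 1, 3)
    conc <- kd * c(0, 0.1, 0.3, 1, 3, 10, 30)
    f <- fit_ssa(simulate_binding_series(kd, rmax, conc))
    expect_equal(f$kd, kd, tolerance = 1e-6)
    expect_equal(f$rmax, rmax, tolerance = 1e-6)
  }
  # half-saturation identity on the fitted curve
  f <- fit_ssa(simulate_binding_series(170, 100))
  expect_equal(f$rmax * 170 / (170 + f$kd), f$rmax / 2, tolerance = 1e-6)
})

test_that("SSA recovery under 2% noise has small bias", {
  kds <- vapply(1:100, function(i) {
    s <- simulate_binding_series(170, 100, noise_frac = 0.02,
                                 seed = 6000 + i)
    fit_ssa(s)$kd
  }, numeric(1))
  expect_lt(abs(mean(kds) - 170) / 170, 0.05)

  # non-monotone series flagged but fit proceeds
  s <- simulate_binding_series(170, 100)
  s$r_eq[5] <- 5
  expect_warning(f <- fit_ssa(s), "non-monotone")
  expect_false(f$monotone)
})

test_that("overhang trend reports fold change and monotonicity", {
  tr <- overhang_trend(data.frame(overhang_nt = c(0, 3, 6, 9, 12, 15),
                                  kd = c(90, 110, 135, 160, 190, 220)))
  expect_equal(tr$fold_change, 220 / 90, tolerance = 1e-12)
  expect_equal(round(tr$fold_change, 2), 2.44)
  expect_true(tr$monotone)

  flat <- overhang_trend(data.frame(overhang_nt = c(0, 15), kd = c(90, 90)))
  expect_equal(flat$fold_change, 1.0)
  expect_false(flat$monotone)

  expect_error(overhang_trend(data.frame(overhang_nt = 0, kd = 90)),
               "at least 2")
})

test_that("spectrum helpers follow their arithmetic contracts", {
  wl <- seq(350, 460, by = 2)
  a <- tibble::tibble(wavelength = wl,
                      intensity = dnorm(wl, 370, 10) + 0.1)
  b <- tibble::tibble(wavelength = wl, intensity = 0.1)
  expect_equal(difference_spectrum(a, a)$intensity, rep(0, length(wl)))
  expect_equal(difference_spectrum(a, tibble::tibble(
    wavelength = wl, intensity = 0))$intensity, a$intensity)
  d <- difference_spectrum(a, b)
  expect_equal(d$wavelength[which.max(d$intensity)], 370)
  expect_error(difference_spectrum(a, b[-1, ]), "grids")

  const <- tibble::tibble(wavelength = wl, intensity = 2)
  expect_equal(moving_average(const)$intensity, rep(2, length(wl)))
  expect_equal(moving_average(a, window = 1)$intensity, a$intensity)
  spike <- tibble::tibble(wavelength = 1:5, intensity = c(0, 0, 5, 0, 0))
  expect_equal(moving_average(spike, 5)$intensity[3], 1.0)
  expect_error(moving_average(a, window = 4), "odd")
})

test_that("steady-state window averaging extracts R_eq", {
  sg <- tibble::tibble(time_s = seq(0, 100, 1),
                       response = c(seq(0, 50, length.out = 51),
                                    rep(50, 50)))
  expect_equal(steady_state_response(sg, c(60, 90)), 50)
  expect_error(steady_state_response(sg, c(200, 300)), "window")
})
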