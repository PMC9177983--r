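test_that("state path simulation honours the kinetic scheme", {
  one <- kinetic_scheme(data.frame(label = "s", fret = 0.5, sd = 0.05),
                        matrix(0, 1, 1))
  p <- simulate_state_path(one, sim_config(n_frames = 100), seed = 1)
  expect_identical(unique(p), 1L)

  # absorbing state: never returns to state 1 after entering state 2
  abs2 <- two_state_scheme(k12 = 0.5, k21 = 0)
  p <- simulate_state_path(abs2, sim_config(n_frames = 2000), seed = 2)
  first2 <- which(p == 2L)[1]
  expect_false(is.na(first2))
  expect_true(all(p[first2:length(p)] == 2L))

  # negative rate rejected at construction
  expect_error(two_state_scheme(k12 = -0.1), "rates")
})

test_that("continuous dwell times are exponential with the exit rate", {
  sch <- two_state_scheme(k12 = 0.2, k21 = 0.2)
  cfg <- sim_config(n_frames = 50000, frame_interval = 0.2)  # 10^4 s
  p <- simulate_state_path(sch, cfg, seed = 3)
  jumps <- attr(p, "jumps")
  complete <- jumps[!jumps$truncated, ]
  expect_gt(nrow(complete), 1000)
  for (s in 1:2) {
    d <- complete$duration_s[complete$state == s]
    se <- sd(d) / sqrt(length(d))
    expect_lt(abs(mean(d) - 5.0), 3 * se)
  }
  # chi-square GOF of pooled dwells against exponential(mean 5)
  d <- complete$duration_s
  qs <- stats::qexp(seq(0, 1, by = 0.1), rate = 1 / 5)
  obs <- table(cut(d, qs))
  gof <- stats::chisq.test(obs, p = rep(0.1, 10))
  expect_gt(gof$p.value, 0.01)
})

test_that("two-state occupancy converges to the stationary distribution", {
  sch <- two_state_scheme(k12 = 0.3, k21 = 0.1)   # pi_1 = k21/(k12+k21)
  cfg <- sim_config(n_frames = 40000)
  p <- simulate_state_path(sch, cfg, seed = 4)
  jumps <- attr(p, "jumps")
  occ1 <- sum(jumps$duration_s[jumps$state == 1]) / sum(jumps$duration_s)
  n_dwell <- nrow(jumps)
  se <- sqrt(0.25 * 0.75 / n_dwell) * 2   # conservative SE on time fraction
  expect_lt(abs(occ1 - 0.1 / 0.4), 3 * se)
})

test_that("generators are bit-reproducible under a fixed seed", {
  sch <- two_state_scheme()
  cfg <- sim_config(n_frames = 200, n_molecules = 3)
  expect_identical(simulate_state_path(sch, cfg, seed = 7),
                   simulate_state_path(sch, cfg, seed = 7))
  e1 <- simulate_experiment(sch, photophysics(), cfg, seed = 8)
  e2 <- simulate_experiment(sch, photophysics(), cfg, seed = 8)
  expect_identical(e1, e2)
  expect_identical(simulate_dwells(50, tau = 2, seed = 9),
                   simulate_dwells(50, tau = 2, seed = 9))
  expect_identical(
    simulate_fret_sample(data.frame(weight = 1, mean = .5, sd = .1), 50, 10),
    simulate_fret_sample(data.frame(weight = 1, mean = .5, sd = .1), 50, 10))
})

test_that("intensity rendering follows the photophysics model", {
  sch <- two_state_scheme(fret = c(0.9, 0.4))
  cfg <- sim_config(n_frames = 100)
  path <- rep(1L, 100)
  phot <- photophysics(total_intensity = 1000, noise_sd = 0,
                       donor_bleach_rate = 0, acceptor_bleach_rate = 0)
  tr <- simulate_intensity_trace(path, sch, phot, cfg)
  expect_equal(tr$acceptor / tr$donor, rep(9, 100))          # E = 0.9
  expect_equal(tr$donor + tr$acceptor, rep(1000, 100))       # conservation

  # acceptor bleach: FRET ~ 0 afterwards, donor recovers
  phot_b <- photophysics(total_intensity = 1000, noise_sd = 0,
                         acceptor_bleach_rate = 0.5)
  tr <- simulate_intensity_trace(path, sch, phot_b, cfg, seed = 11)
  b <- attr(tr, "acceptor_bleach_frame")
  expect_false(is.na(b))
  post <- tr$frame > b
  expect_true(all(tr$acceptor[post] == 0))
  expect_true(all(tr$donor[post] == 1000))
})

test_that("acceptor survival reproduces the bleaching exponential", {
  sch <- two_state_scheme()
  cfg <- sim_config(n_frames = 300, n_molecules = 400)
  phot <- photophysics(acceptor_bleach_rate = 1 / 11.3, noise_sd = 0)
  ex <- simulate_experiment(sch, phot, cfg, seed = 12)
  bf <- ex$truth_bleach$acceptor_bleach_frame
  for (t_check in c(5, 11.3, 30)) {
    frames <- t_check / cfg$frame_interval
    surv <- mean(is.na(bf) | bf >= frames)
    p_true <- exp(-t_check / 11.3)
    se <- sqrt(p_true * (1 - p_true) / length(bf))
    expect_lt(abs(surv - p_true), 4 * se)
  }
})

test_that("ensemble decay generator matches its closed form", {
  d <- simulate_ensemble_decay(1, 10, tgrid = c(0, 10), noise_sd = 0)
  expect_equal(d$intensity, c(1, exp(-1)))
  # sum of printed-amplitude components at t = 0
  d2 <- simulate_ensemble_decay(c(0.49, 0.52), c(11.3, 4.6),
                                tgrid = seq(0, 60, 0.2), noise_sd = 0)
  expect_equal(d2$intensity[1], 1.01)
  expect_true(all(diff(d2$intensity) <= 0))
  expect_error(simulate_ensemble_decay(1, -5, tgrid = 0:10), "lifetimes")
})

test_that("dwell generator is correct in law and censoring", {
  d <- simulate_dwells(1e5, tau = 5, seed = 13)
  se <- sd(d$duration_s) / sqrt(nrow(d))
  expect_lt(abs(mean(d$duration_s) - 5), 3 * se)
  expect_false(any(d$right_censored))

  # gamma(shape 1, scale tau) is the exponential(tau)
  g <- simulate_dwells(1e4, dist = "gamma", shape = 1, scale = 5, seed = 14)
  e <- simulate_dwells(1e4, tau = 5, seed = 15)
  ks <- suppressWarnings(ks.test(g$duration_s, e$duration_s))
  expect_gt(ks$p.value, 0.01)

  # forced censoring
  cc <- simulate_dwells(100, tau = 100, censor_at = 1, seed = 16)
  expect_true(all(cc$right_censored))
  expect_true(all(cc$duration_s == 1))

  expect_identical(nrow(simulate_dwells(0, tau = 5)), 0L)
})

test_that("binding series follows the 1:1 isotherm", {
  b <- simulate_binding_series(kd = 170, rmax = 100,
                               concentrations = c(0, 170))
  expect_equal(b$r_eq, c(0, 50))
  expect_error(simulate_binding_series(170, 100, concentrations = -1),
               "concentrations")
  grid <- simulate_binding_series(170, 100)$conc
  expect_equal(grid, c(0, 10, 20, 40, 80, 160, 320, 640))
})

test_that("FRET mixture sampler has the analytic moments", {
  x <- simulate_fret_sample(data.frame(weight = 1, mean = 0.5, sd = 0.01),
                            1e4, seed = 17)
  expect_lt(abs(mean(x) - 0.5), 3 * 0.01 / sqrt(1e4))
  x2 <- simulate_fret_sample(
    data.frame(weight = c(0.5, 0.5), mean = c(0, 1), sd = c(0.01, 0.01)),
    1e4, seed = 18)
  se2 <- sd(x2) / sqrt(length(x2))
  expect_lt(abs(mean(x2) - 0.5), 3 * se2)
  expect_length(simulate_fret_sample(
    data.frame(weight = 1, mean = 0.5, sd = 0.1), 0), 0)
  expect_error(simulate_fret_sample(
    data.frame(weight = c(-0.5, 1.5), mean = c(0, 1), sd = c(0.1, 0.1)), 10),
    "weights")
})
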