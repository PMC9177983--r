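test_that("forward likelihood and Viterbi agree with exhaustive enumeration", {
  set.seed(42)
  for (rep in 1:10) {
    model <- random_hmm(2)
    x <- runif(6)
    oracle <- brute_force_loglik(x, model)
    B <- fretkin:::emission_density(x, model$means, model$sds)
    fw <- fretkin:::hmm_forward(B, model$transmat, model$initial_probs)
    expect_equal(fw$loglik, oracle$loglik, tolerance = 1e-10)
    seg <- viterbi_path(x, model)
    expect_identical(as.integer(attr(seg, "viterbi")),
                     as.integer(oracle$best_path))
  }
})

test_that("forward and backward recursions give consistent posteriors", {
  set.seed(43)
  model <- random_hmm(3)
  x <- runif(40)
  B <- fretkin:::emission_density(x, model$means, model$sds)
  fw <- fretkin:::hmm_forward(B, model$transmat, model$initial_probs)
  bw <- fretkin:::hmm_backward(B, model$transmat, fw$scale)
  gamma <- fw$alpha * bw * fw$scale
  expect_true(all(abs(rowSums(gamma) - 1) < 1e-10))
  # backward-route likelihood: sum_j pi_j b_1j beta_1j (scaled identity)
  ll_b <- log(sum(model$initial_probs * B[1, ] * bw[1, ])) +
    sum(log(fw$scale))
  expect_equal(ll_b, fw$loglik, tolerance = 1e-8)
})

test_that("EM recovers constructed inputs", {
  # constant trace, K = 1: closed form
  set.seed(44)
  x <- rnorm(200, 0.5, 0.05)
  m1 <- fit_hmm(x, 1)
  expect_equal(m1$means, mean(x), tolerance = 1e-6)
  expect_equal(m1$sds, sd(x) * sqrt(199 / 200), tolerance = 1e-3)

  # noiseless two-level square wave: means exact, transitions match counts
  x <- rep(rep(c(0.8, 0.3), 10), each = 10) + rnorm(200, sd = 1e-4)
  m2 <- fit_hmm(x, 2, seed = 45)
  expect_equal(m2$means, c(0.3, 0.8), tolerance = 1e-3)
  seg <- viterbi_path(x, m2)
  expect_identical(nrow(seg), 20L)
  # 19 level changes over 199 frame steps, 10 of them leaving state 1
  expect_equal(m2$transmat[1, 2], 10 / 99, tolerance = 0.1)

  expect_error(fit_hmm(x[1:8], 2), "Insufficient")
})

test_that("log-likelihood is non-decreasing in K on a seeded fixture", {
  set.seed(46)
  x <- c(rnorm(100, 0.8, 0.05), rnorm(100, 0.3, 0.05))
  lls <- vapply(1:3, function(k) fit_hmm(x, k, seed = k)$logLik, numeric(1))
  expect_true(all(diff(lls) > -1e-6))
})

test_that("BIC selects the true number of states", {
  # constant noisy traces -> K* = 1
  set.seed(47)
  k_const <- vapply(1:30, function(i) {
    x <- rnorm(200, 0.5, 0.05)
    select_states(x, k_max = 3, n_restarts = 4)$K
  }, integer(1))
  expect_gte(mean(k_const == 1L), 0.95)

  # clean 3-level simulation (levels 0.9/0.6/0.1, sd 0.03, dwell 20) -> K* = 3
  set.seed(48)
  levels3 <- c(0.9, 0.6, 0.1)
  k_three <- vapply(1:20, function(i) {
    # dwell sequence: adjacent states differ by construction
    s <- Reduce(function(prev, .) sample(setdiff(1:3, prev), 1),
                seq_len(14), init = sample(3, 1), accumulate = TRUE)
    lev <- rep(levels3[s], each = 20)
    x <- lev + rnorm(length(lev), sd = 0.03)
    select_states(x, k_max = 4, n_restarts = 6)$K
  }, integer(1))
  expect_gte(mean(k_three == 3L), 0.9)

  expect_identical(select_states(rnorm(50, 0.5, 0.05), k_max = 1)$K, 1L)
})

test_that("Viterbi segments recover simulated ground truth", {
  sch <- three_state_scheme(rates = matrix(c(0, 0.2, 0,
                                             0.2, 0, 0.2,
                                             0, 0.2, 0), 3, 3,
                                           byrow = TRUE),
                            sd = rep(0.02, 3))
  cfg <- sim_config(n_frames = 500)
  path <- simulate_state_path(sch, cfg, seed = 49)
  x <- sch$states$fret[path] + withr::with_seed(50, rnorm(500, sd = 0.02))
  model <- fit_hmm(x, 3, seed = 51)
  seg <- viterbi_path(x, model)
  decoded <- attr(seg, "viterbi")
  # map decoded states to truth by level proximity
  map <- vapply(model$means, function(m) which.min(abs(sch$states$fret - m)),
                integer(1))
  agreement <- mean(map[decoded] == path)
  expect_gte(agreement, 0.98)

  # noiseless one-level trace: a single segment
  seg1 <- viterbi_path(rep(0.7, 60) + rnorm(60, sd = 1e-5),
                       fit_hmm(rep(0.7, 60) + rnorm(60, sd = 1e-5), 1))
  expect_identical(nrow(seg1), 1L)
  expect_identical(seg1$start_frame, 0L)
  expect_identical(seg1$end_frame, 60L)
})
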