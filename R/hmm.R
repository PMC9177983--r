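# Gaussian-emission hidden Markov model for trajectory idealization:
# scaled forward-backward, Baum-Welch EM with multiple restarts, Viterbi
# decoding, and BIC model selection. This is the package's stand-in for
# the variational-Bayes idealization stage used in the smFRET literature.

# Scaled forward pass. Returns list(loglik, alpha, scale); emissions are
# a T x K matrix of densities.
hmm_forward <- function(B, transmat, initial) {
  tt <- nrow(B); k <- ncol(B)
  alpha <- matrix(0, tt, k)
  scale <- numeric(tt)
  a <- initial * B[1, ]
  scale[1] <- sum(a)
  if (scale[1] <= 0) scale[1] <- .Machine$double.xmin
  alpha[1, ] <- a / scale[1]
  if (tt > 1) {
    for (t in 2:tt) {
      a <- as.numeric(alpha[t - 1, ] %*% transmat) * B[t, ]
      scale[t] <- sum(a)
      if (scale[t] <= 0) scale[t] <- .Machine$double.xmin
      alpha[t, ] <- a / scale[t]
    }
  }
  list(loglik = sum(log(scale)), alpha = alpha, scale = scale)
}

hmm_backward <- function(B, transmat, scale) {
  tt <- nrow(B); k <- ncol(B)
  beta <- matrix(0, tt, k)
  beta[tt, ] <- 1 / scale[tt]
  if (tt > 1) {
    for (t in (tt - 1):1) {
      beta[t, ] <- as.numeric(transmat %*% (B[t + 1, ] * beta[t + 1, ])) /
        scale[t]
    }
  }
  beta
}

emission_density <- function(x, means, sds) {
  B <- vapply(seq_along(means),
              function(j) dnorm(x, means[j], sds[j]),
              numeric(length(x)))
  B <- matrix(B, nrow = length(x))
  B[B < 1e-300] <- 1e-300
  B
}

# One EM run from a given initialization; returns an unsorted model.
em_run <- function(x, means, sds, transmat, initial,
                   max_iter = 500, tol = 1e-6) {
  tt <- length(x); k <- length(means)
  ll_old <- -Inf
  converged <- FALSE
  iter <- 0
  repeat {
    iter <- iter + 1
    B <- emission_density(x, means, sds)
    fw <- hmm_forward(B, transmat, initial)
    bw <- hmm_backward(B, transmat, fw$scale)
    gamma <- fw$alpha * bw * fw$scale   # posterior state probs, rows sum 1
    gamma <- gamma / rowSums(gamma)
    if (k > 1 && tt > 1) {
      # with this scaling each per-step xi term already sums to 1 over
      # (i, j), so the expected transition counts are a single product
      xi_num <- (t(fw$alpha[-tt, , drop = FALSE]) %*%
                   (B[-1, , drop = FALSE] * bw[-1, , drop = FALSE])) *
        transmat
      transmat <- xi_num / pmax(rowSums(xi_num), 1e-300)
    }
    initial <- gamma[1, ]
    w <- colSums(gamma)
    means <- as.numeric(crossprod(gamma, x)) / w
    sds <- sqrt(pmax(colSums(gamma * (outer(x, means, "-"))^2) / w, 1e-8))
    ll <- fw$loglik
    if (abs(ll - ll_old) < tol) { converged <- TRUE; break }
    if (iter >= max_iter) break
    ll_old <- ll
  }
  list(means = means, sds = sds, transmat = transmat, initial = initial,
       loglik = ll, n_iter = iter, converged = converged)
}

sort_model <- function(m) {
  o <- order(m$means)
  m$means <- m$means[o]
  m$sds <- m$sds[o]
  m$transmat <- m$transmat[o, o, drop = FALSE]
  m$initial <- m$initial[o]
  m
}

#' Fit a Gaussian-emission hidden Markov model to a FRET trajectory
#'
#' Maximum-likelihood HMM fit via expectation-maximization (Baum-Welch)
#' with multiple restarts from perturbed quantile-based initializations.
#' EM stops when the log-likelihood gain falls below `tol` or after
#' `max_iter` iterations; the best restart by log-likelihood is returned,
#' with states sorted by ascending mean.
#'
#' @param x Numeric vector of FRET values (masked frames already removed),
#'   or a `compute_fret()` tibble for a single molecule, in which case the
#'   `usable` frames are taken.
#' @param K Number of states, >= 1. The trajectory must supply at least
#'   `5 * K` usable frames.
#' @param seed Optional integer seed controlling restart perturbations.
#' @param n_restarts Number of EM restarts (first is unperturbed).
#' @param max_iter,tol EM stopping rule.
#'
#' @return An object of class `hmm_model`: list with `K`, `means`, `sds`,
#'   `transmat` (row-stochastic per-frame transition probabilities),
#'   `initial_probs`, `logLik`, `bic`, `n_obs`, `converged`.
#' @examples
#' x <- rep(c(0.9, 0.4), each = 30) + rnorm(60, sd = 0.02)
#' fit_hmm(x, K = 2, seed = 1)
#' @export
fit_hmm <- function(x, K, seed = NULL, n_restarts = 10,
                    max_iter = 500, tol = 1e-6) {
  x <- fret_values(x)
  assert_scalar_number(K, "K", positive = TRUE)
  K <- as.integer(K)
  if (length(x) < 5 * K) {
    abort(sprintf("Insufficient data: %d usable frames for K = %d (need >= %d).",
                  length(x), K, 5 * K))
  }
  local_seed(seed)
  base_means <- as.numeric(quantile(x, probs = (seq_len(K) - 0.5) / K))
  base_sd <- max(sd(x) / sqrt(K), 1e-3)
  if (K == 1) n_restarts <- 1
  best <- NULL
  for (r in seq_len(n_restarts)) {
    means <- if (r == 1) base_means else
      base_means + rnorm(K, sd = 0.05)
    transmat <- matrix(0.1 / max(K - 1, 1), K, K)
    diag(transmat) <- if (K > 1) 0.9 else 1
    m <- em_run(x, means, rep(base_sd, K), transmat, rep(1 / K, K),
                max_iter = max_iter, tol = tol)
    if (is.null(best) || m$loglik > best$loglik) best <- m
  }
  best <- sort_model(best)
  p <- K^2 + 2 * K - 1
  structure(
    list(K = K, means = best$means, sds = best$sds,
         transmat = best$transmat, initial_probs = best$initial,
         logLik = best$loglik,
         bic = -2 * best$loglik + p * log(length(x)),
         n_obs = length(x), n_iter = best$n_iter,
         converged = best$converged),
    class = "hmm_model"
  )
}

#' @export
print.hmm_model <- function(x, ...) {
  cat(sprintf("<hmm_model: K = %d, logLik = %.3f, BIC = %.3f, n = %d>\n",
              x$K, x$logLik, x$bic, x$n_obs))
  cat("means:", paste(signif(x$means, 4), collapse = ", "), "\n")
  cat("sds:  ", paste(signif(x$sds, 4), collapse = ", "), "\n")
  invisible(x)
}

#' Select the number of FRET states by BIC
#'
#' Fits HMMs with `K = 1..k_max` states and selects the minimum of
#' `BIC = -2 logL + p log(T)` with `p = K^2 + 2K - 1` free parameters
#' (transition matrix, initial distribution, K means, K sds). Ties are
#' broken toward the smaller `K`. Values of `K` requiring more data than
#' the trajectory provides are skipped.
#'
#' @inheritParams fit_hmm
#' @param k_max Largest state count to try.
#' @return The winning `hmm_model`, with the per-K comparison tibble in
#'   attribute `"selection"`.
#' @export
select_states <- function(x, k_max = 6, seed = NULL, n_restarts = 10, ...) {
  x <- fret_values(x)
  assert_scalar_number(k_max, "k_max", positive = TRUE)
  local_seed(seed)
  fits <- list()
  for (K in seq_len(k_max)) {
    if (length(x) < 5 * K) break
    fits[[K]] <- fit_hmm(x, K, n_restarts = n_restarts, ...)
  }
  if (length(fits) == 0) abort("Insufficient data for any model.")
  bics <- vapply(fits, function(f) f$bic, numeric(1))
  best_k <- which(bics <= min(bics) + 1e-9)[1]  # ties toward smaller K
  out <- fits[[best_k]]
  attr(out, "selection") <- tibble(
    K = seq_along(fits),
    logLik = vapply(fits, function(f) f$logLik, numeric(1)),
    bic = bics
  )
  out
}

#' Decode the most probable state path and build an idealized trajectory
#'
#' Runs the Viterbi dynamic program under a fitted [fit_hmm()] model (ties
#' broken toward the lower state index), merges consecutive same-state
#' frames into segments, and collapses degenerate state pairs (fitted means
#' closer than `merge_tol` with overlapping +/- 1 sd intervals) into a
#' single level before segment construction, since classification operates
#' on distinct levels.
#'
#' @inheritParams fit_hmm
#' @param model A fitted `hmm_model`.
#' @param molecule_id Identifier for the output segments.
#' @param merge_tol Mean separation below which overlapping states merge.
#'
#' @return An idealized-trajectory tibble with columns `molecule_id`,
#'   `start_frame`, `end_frame` (half-open, in usable-frame coordinates),
#'   `level` (fitted state mean); attributes `K`, `logLik`, `viterbi`
#'   (the per-frame decoded state index).
#' @export
viterbi_path <- function(x, model, molecule_id = "mol_1",
                         merge_tol = 0.05) {
  stopifnot(inherits(model, "hmm_model"))
  x <- fret_values(x)
  tt <- length(x); k <- model$K
  B <- log(emission_density(x, model$means, model$sds))
  logA <- log(pmax(model$transmat, 1e-300))
  delta <- matrix(-Inf, tt, k)
  psi <- matrix(1L, tt, k)
  delta[1, ] <- log(pmax(model$initial_probs, 1e-300)) + B[1, ]
  if (tt > 1) {
    for (t in 2:tt) {
      for (j in 1:k) {
        cand <- delta[t - 1, ] + logA[, j]
        best <- which.max(cand)          # first max: lower index on ties
        psi[t, j] <- best
        delta[t, j] <- cand[best] + B[t, j]
      }
    }
  }
  path <- integer(tt)
  path[tt] <- which.max(delta[tt, ])
  if (tt > 1) for (t in (tt - 1):1) path[t] <- psi[t + 1, path[t + 1]]

  # collapse degenerate fitted states onto a common level
  level_of <- model$means
  if (k > 1) {
    for (j in 2:k) {
      i <- j - 1
      if (abs(level_of[j] - level_of[i]) < merge_tol &&
          (model$means[j] - model$sds[j]) <= (model$means[i] + model$sds[i])) {
        level_of[j] <- level_of[i]
      }
    }
  }
  lev <- level_of[path]
  r <- rle(lev)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  out <- tibble(molecule_id = molecule_id,
                start_frame = as.integer(starts),
                end_frame = as.integer(ends),
                level = r$values)
  attr(out, "K") <- k
  attr(out, "logLik") <- model$logLik
  attr(out, "viterbi") <- path
  out
}

#' Idealize every molecule in a FRET table
#'
#' Per-molecule convenience pipeline: take the usable frames from a
#' [compute_fret()] table, select the state count by BIC, and decode the
#' Viterbi segments. Molecules with too few usable frames are skipped with
#' a warning.
#'
#' @param fret_tbl Output of [compute_fret()].
#' @param k_max,n_restarts,seed Passed to [select_states()].
#' @param min_frames Minimum usable frames to attempt idealization.
#'
#' @return Segment tibble over all idealized molecules (columns
#'   `molecule_id`, `start_frame`, `end_frame`, `level`, `k_states`).
#' @export
idealize <- function(fret_tbl, k_max = 6, n_restarts = 10, seed = NULL,
                     min_frames = 10) {
  assert_columns(fret_tbl, c("molecule_id", "fret", "usable"), "fret table")
  local_seed(seed)
  skipped <- character(0)
  out <- fret_tbl %>%
    group_by(.data$molecule_id) %>%
    group_split() %>%
    purrr::map(function(tr) {
      x <- tr$fret[tr$usable]
      if (length(x) < max(min_frames, 5)) {
        skipped <<- c(skipped, tr$molecule_id[1])
        return(NULL)
      }
      model <- select_states(x, k_max = k_max, n_restarts = n_restarts)
      seg <- viterbi_path(x, model, molecule_id = tr$molecule_id[1])
      seg$k_states <- model$K
      seg
    }) %>%
    bind_rows()
  if (length(skipped) > 0) {
    warn(sprintf("Skipped %d molecule(s) with too few usable frames.",
                 length(skipped)))
  }
  out
}

# Accept either a numeric vector or a single-molecule compute_fret() tibble.
fret_values <- function(x) {
  if (is.data.frame(x)) {
    assert_columns(x, c("fret", "usable"), "fret table")
    if ("molecule_id" %in% names(x) && n_distinct(x$molecule_id) > 1) {
      abort("Supply one molecule at a time (or use idealize()).")
    }
    x <- x$fret[x$usable]
  }
  x <- as.numeric(x)
  x[is.finite(x)]
}
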