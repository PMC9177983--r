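# Independent oracles for the HMM recursions: likelihood by exhaustive
# summation over all K^T state paths, and the most probable path by
# exhaustive argmax. Deliberately free of the forward/Viterbi code paths
# they check.

brute_force_loglik <- function(x, model) {
  k <- model$K; tt <- length(x)
  paths <- as.matrix(expand.grid(rep(list(1:k), tt)))
  probs <- apply(paths, 1, function(p) {
    pr <- model$initial_probs[p[1]] * dnorm(x[1], model$means[p[1]],
                                            model$sds[p[1]])
    for (t in 2:tt) {
      pr <- pr * model$transmat[p[t - 1], p[t]] *
        dnorm(x[t], model$means[p[t]], model$sds[p[t]])
    }
    pr
  })
  list(loglik = log(sum(probs)), best_path = paths[which.max(probs), ])
}

random_hmm <- function(k = 2) {
  tm <- matrix(runif(k * k, 0.05, 1), k, k)
  tm <- tm / rowSums(tm)
  ip <- runif(k, 0.05, 1); ip <- ip / sum(ip)
  structure(list(K = k, means = sort(runif(k)), sds = runif(k, 0.02, 0.2),
                 transmat = tm, initial_probs = ip,
                 logLik = NA_real_, bic = NA_real_, n_obs = 0L),
            class = "hmm_model")
}
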