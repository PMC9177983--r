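# broom-style tidy()/glance() methods for every fitted-object class.

#' @export
tidy.exp_fit <- function(x, ...) {
  tibble(term = "tau", estimate = x$tau, std.error = x$se_tau)
}

#' @export
glance.exp_fit <- function(x, ...) {
  tibble(logLik = x$logLik, AIC = x$AIC, BIC = x$BIC,
         nobs = x$n_events, n.censored = x$n_censored)
}

#' @export
tidy.gamma_fit <- function(x, ...) {
  tibble(term = c("shape", "scale", "mean_dwell"),
         estimate = c(x$shape, x$scale, x$mean_dwell),
         std.error = c(x$se_shape, x$se_scale, NA_real_))
}

#' @export
glance.gamma_fit <- function(x, ...) {
  tibble(logLik = x$logLik, AIC = x$AIC, BIC = x$BIC,
         nobs = x$n_events, n.censored = x$n_censored,
         converged = x$converged)
}

#' @export
tidy.ssa_fit <- function(x, ...) {
  tibble(term = c("kd", "rmax"),
         estimate = c(x$kd, x$rmax),
         std.error = c(x$se_kd, x$se_rmax))
}

#' @export
glance.ssa_fit <- function(x, ...) {
  tibble(rss = x$rss, nobs = x$n_obs, monotone = x$monotone)
}

#' @export
tidy.global_decay_fit <- function(x, ...) {
  shared <- tibble(condition_id = NA_character_, term = "tau",
                   estimate = x$tau, std.error = x$se_tau)
  per_cond <- x$params %>%
    tidyr::pivot_longer(-"condition_id", names_to = "term",
                        values_to = "value") %>%
    mutate(kind = ifelse(grepl("^se_", .data$term), "std.error", "estimate"),
           term = sub("^se_", "", .data$term)) %>%
    tidyr::pivot_wider(names_from = "kind", values_from = "value") %>%
    filter(!is.na(.data$estimate))
  bind_rows(shared, per_cond)
}

#' @export
glance.global_decay_fit <- function(x, ...) {
  tibble(chisq = x$chisq, nobs = x$n_obs, converged = x$converged)
}

#' @export
tidy.mixture_fit <- function(x, ...) {
  x$components %>%
    tidyr::pivot_longer(c("weight", "mean", "sd"), names_to = "term",
                        values_to = "estimate") %>%
    select("component", "term", "estimate")
}

#' @export
glance.mixture_fit <- function(x, ...) {
  tibble(rss = x$rss, nobs = x$n_obs, method = x$method,
         n.collapsed = sum(x$components$collapsed))
}

#' @export
tidy.hmm_model <- function(x, ...) {
  tibble(term = c(paste0("mean_", seq_len(x$K)),
                  paste0("sd_", seq_len(x$K))),
         estimate = c(x$means, x$sds))
}

#' @export
glance.hmm_model <- function(x, ...) {
  tibble(K = x$K, logLik = x$logLik, BIC = x$bic, nobs = x$n_obs,
         converged = x$converged)
}
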