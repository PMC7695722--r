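#' Power schedules for stepping-stone sampling
#'
#' Exponents `beta_0 = 0 < beta_1 < ... < beta_K = 1` bridging prior
#' (`beta = 0`) and posterior (`beta = 1`). Following common practice the
#' interior exponents are Beta(`shape`, 1) quantiles at `k/K`, which
#' concentrates steps near the prior where the integrand changes fastest.
#'
#' @param K number of steps (>= 2).
#' @param shape Beta quantile parameter (default 0.3).
#' @return an object of class `power_schedule` (numeric vector of `K + 1`
#'   exponents).
#' @export
make_schedule <- function(K, shape = 0.3) {
  if (K < 2) stop("K must be >= 2")
  beta <- stats::qbeta(seq(0, K) / K, shape, 1)
  beta[1] <- 0
  beta[K + 1] <- 1
  structure(beta, class = "power_schedule", K = as.integer(K), shape = shape)
}

#' Stepping-stone estimate from per-step likelihood samples
#'
#' `log Z = sum_k log[(1/n) sum_i L_i^(beta_{k+1} - beta_k)]` with samples
#' drawn from the power posterior at `beta_k`, computed with log-sum-exp.
#' The Monte-Carlo standard error combines per-step delta-method variances
#' with ESS-adjusted sample sizes.
#'
#' @param loglik_samples list of length `K`: element `k` holds the sampled
#'   log-likelihoods at exponent `beta_{k-1}` (so the first element is drawn
#'   from the prior).
#' @param schedule a [make_schedule()].
#' @return an object of class `marginal_likelihood_result` with fields
#'   `log_ml`, `per_step` (tibble of per-step contributions) and `se`.
#' @export
stepping_stone_estimate <- function(loglik_samples, schedule) {
  K <- attr(schedule, "K")
  if (length(loglik_samples) != K) stop("need one sample set per step")
  steps <- purrr::map_dfr(seq_len(K), function(k) {
    ll <- loglik_samples[[k]]
    if (!all(is.finite(ll))) {
      stop("non-finite log-likelihoods at step ", k)
    }
    db <- schedule[k + 1] - schedule[k]
    w <- db * ll
    mx <- max(w)
    contrib <- mx + log(mean(exp(w - mx)))
    # delta-method SE of log mean(exp(w)), with autocorrelation-adjusted n
    ew <- exp(w - mx)
    n_eff <- if (length(ll) >= 10 && stats::var(ll) > 0) {
      as.numeric(effective_sample_size(ll))
    } else {
      length(ll)
    }
    v <- stats::var(ew) / (n_eff * mean(ew)^2)
    tibble::tibble(step = k, beta = schedule[k], delta_beta = db,
                   contribution = contrib, var = v)
  })
  structure(list(log_ml = sum(steps$contribution),
                 per_step = steps[c("step", "beta", "delta_beta", "contribution")],
                 se = sqrt(sum(steps$var))),
            class = "marginal_likelihood_result")
}

#' @export
print.marginal_likelihood_result <- function(x, ...) {
  cat("<marginal_likelihood_result> log ML = ", format(x$log_ml, digits = 6),
      " (SE ", format(x$se, digits = 3), ", ", nrow(x$per_step), " steps)\n",
      sep = "")
  invisible(x)
}

#' Stepping-stone sampling with a user-supplied model
#'
#' Generic power-posterior Metropolis-Hastings for scalar or vector
#' parameters: at each exponent a chain targets
#' `prior(theta) x likelihood(theta)^beta_k`, warm-started from the previous
#' step's final state, with the first 10% of each step discarded as burn-in.
#' Used for closed-form validation models; the phylogenetic pipeline uses
#' [stepping_stone()].
#'
#' @param log_lik,log_prior functions of `theta` returning log densities.
#' @param init starting value of `theta`.
#' @param propose function of `theta` returning
#'   `list(theta = ..., log_hr = ...)`.
#' @param schedule a [make_schedule()].
#' @param samples_per_step kept samples per step.
#' @param seed RNG seed.
#' @return a `marginal_likelihood_result`.
#' @export
stepping_stone_generic <- function(log_lik, log_prior, init, propose, schedule,
                                   samples_per_step = 1000, seed = 1L) {
  set.seed(seed)
  K <- attr(schedule, "K")
  theta <- init
  lp <- log_prior(theta)
  ll <- log_lik(theta)
  if (!is.finite(lp)) stop("init has zero prior density")
  burn <- ceiling(samples_per_step * 0.1)
  out <- vector("list", K)
  for (k in seq_len(K)) {
    beta <- schedule[k]
    keep <- numeric(samples_per_step)
    for (it in seq_len(burn + samples_per_step)) {
      pr <- propose(theta)
      lp2 <- log_prior(pr$theta)
      if (is.finite(lp2)) {
        ll2 <- log_lik(pr$theta)
        d <- beta * (ll2 - ll) + (lp2 - lp) + pr$log_hr
        if (d >= 0 || log(stats::runif(1)) < d) {
          theta <- pr$theta; lp <- lp2; ll <- ll2
        }
      }
      if (it > burn) keep[it - burn] <- ll
    }
    out[[k]] <- keep
  }
  stepping_stone_estimate(out, schedule)
}

#' Stepping-stone marginal likelihood for the phylogenetic model
#'
#' Runs one tempered [run_chain()] per exponent (warm start from the previous
#' step's final state; per-step burn-in 10% of the step's iterations) and
#' combines the sampled log-likelihoods with [stepping_stone_estimate()].
#'
#' @param patterns a [compress_patterns()] object or [binary_matrix()].
#' @param init a [model_state()].
#' @param spec a [prior_spec()].
#' @param cfg an [mcmc_config()] describing ONE step: `chain_length`
#'   iterations per step with its own burn-in/thinning.
#' @param schedule a [make_schedule()].
#' @return a `marginal_likelihood_result`.
#' @export
stepping_stone <- function(patterns, init, spec, cfg, schedule) {
  if (inherits(patterns, "binary_matrix")) patterns <- compress_patterns(patterns)
  K <- attr(schedule, "K")
  state <- init
  out <- vector("list", K)
  for (k in seq_len(K)) {
    run <- run_chain(patterns, state, spec, cfg, beta = schedule[k],
                     chain_id = k)
    ll <- run$trace$likelihood
    if (!all(is.finite(ll)) && schedule[k] > 0) {
      stop("non-finite likelihood samples at step ", k)
    }
    out[[k]] <- ll
    state <- run$final_state
  }
  stepping_stone_estimate(out, schedule)
}

#' Log Bayes factor between two marginal-likelihood estimates
#'
#' `log BF = log Z_1 - log Z_2`, reported with the combined standard error.
#' All Bayes factors in this package are on the natural-log scale.
#'
#' @param m1,m2 `marginal_likelihood_result`s.
#' @return tibble with `log_bf` and `se`.
#' @export
bayes_factor <- function(m1, m2) {
  if (!is.finite(m1$log_ml) || !is.finite(m2$log_ml)) {
    stop("marginal likelihoods must be finite")
  }
  tibble::tibble(log_bf = m1$log_ml - m2$log_ml,
                 se = sqrt(m1$se^2 + m2$se^2))
}

#' Compare candidate models by stepping-stone marginal likelihood
#'
#' Runs [stepping_stone()] for each candidate (a named list of
#' `list(init = model_state, spec = prior_spec)`) on the same data and
#' tabulates log marginal likelihoods and log Bayes factors against the best
#' model.
#'
#' @param patterns a [compress_patterns()] object or [binary_matrix()].
#' @param candidates named list of candidates (see above).
#' @param cfg an [mcmc_config()] for each step.
#' @param schedule a [make_schedule()].
#' @return tibble with `model`, `log_ml`, `se`, `log_bf_vs_best`.
#' @export
compare_models <- function(patterns, candidates, cfg, schedule) {
  res <- purrr::imap_dfr(candidates, function(cand, nm) {
    r <- stepping_stone(patterns, cand$init, cand$spec, cfg, schedule)
    tibble::tibble(model = nm, log_ml = r$log_ml, se = r$se)
  })
  best <- max(res$log_ml)
  res$log_bf_vs_best <- res$log_ml - best
  dplyr::arrange(res, dplyr::desc(.data$log_ml))
}
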