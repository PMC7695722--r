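#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a posterior sample
#'
#' One row per scalar parameter: posterior mean, sd, median, 95% HPD and
#' effective sample size.
#'
#' @param x a [run_chain()] result.
#' @param mass HPD mass.
#' @param ... unused.
#' @return a tibble.
#' @exportS3Method generics::tidy
tidy.posterior_sample <- function(x, mass = 0.95, ...) {
  pars <- setdiff(names(x$trace), "sample")
  purrr::map_dfr(pars, function(p) {
    v <- x$trace[[p]]
    if (anyNA(v)) return(NULL)
    hpd <- hpd_interval(v, mass)
    tibble::tibble(
      parameter = p, mean = mean(v), sd = stats::sd(v),
      median = stats::median(v), hpd_low = hpd[1], hpd_high = hpd[2],
      ess = if (stats::var(v) == 0) length(v) else
        as.numeric(effective_sample_size(v))
    )
  })
}

#' @rdname tidy.posterior_sample
#' @exportS3Method generics::glance
glance.posterior_sample <- function(x, ...) {
  tibble::tibble(
    n_samples = nrow(x$trace),
    chain_length = x$config$chain_length,
    burn_in = x$config$burn_in,
    sample_every = x$config$sample_every,
    beta = x$beta,
    acceptance_rate = x$acceptance_rate,
    mean_posterior = mean(x$trace$posterior),
    mean_root_age = mean(x$trace$root_age)
  )
}

#' Tidy a stepping-stone result
#'
#' @param x a [stepping_stone()] / [stepping_stone_generic()] result.
#' @param ... unused.
#' @return per-step contributions as a tibble (`tidy`), or a one-row overall
#'   summary (`glance`).
#' @exportS3Method generics::tidy
tidy.marginal_likelihood_result <- function(x, ...) x$per_step

#' @rdname tidy.marginal_likelihood_result
#' @exportS3Method generics::glance
glance.marginal_likelihood_result <- function(x, ...) {
  tibble::tibble(log_ml = x$log_ml, se = x$se, n_steps = nrow(x$per_step))
}

#' Tidy an annotated (MCC) tree
#'
#' @param x an [mcc_tree()] result.
#' @param ... unused.
#' @return node annotations as a tibble (`tidy`); a one-row summary with the
#'   clade-score and root-age annotation (`glance`).
#' @exportS3Method generics::tidy
tidy.annotated_tree <- function(x, ...) x$annotations

#' @rdname tidy.annotated_tree
#' @exportS3Method generics::glance
glance.annotated_tree <- function(x, ...) {
  root <- x$annotations[x$annotations$node == x$tree$root, ]
  tibble::tibble(n_trees = x$n_trees, score = x$score, index = x$index,
                 root_age_mean = root$age_mean,
                 root_age_hpd_low = root$age_hpd_low,
                 root_age_hpd_high = root$age_hpd_high)
}
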