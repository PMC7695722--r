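#' Full model state for MCMC
#'
#' Bundles everything sampled: the dated tree, substitution-model parameters,
#' clock model and per-branch multipliers, and the fossilized birth-death
#' parameters. Cached log-likelihood and log-prior are attached by the
#' sampler.
#'
#' @param tree a [time_tree()].
#' @param model a [subst_model()].
#' @param clock a [clock_model()].
#' @param fbd an [fbd_params()].
#' @param branch_rates multipliers indexed by child node id; defaults to all
#'   1 (required form for a strict clock).
#' @return an object of class `model_state`.
#' @export
model_state <- function(tree, model, clock, fbd, branch_rates = NULL) {
  ntot <- length(tree$parent)
  if (is.null(branch_rates)) {
    branch_rates <- rep(1, ntot)
    branch_rates[tree$root] <- NA
  }
  if (clock$kind == "strict" && any(branch_rates[-tree$root] != 1)) {
    stop("strict clock requires all branch multipliers equal to 1")
  }
  structure(list(tree = tree, model = model, clock = clock, fbd = fbd,
                 branch_rates = branch_rates,
                 log_lik = NA_real_, log_prior = NA_real_),
            class = "model_state")
}

#' MCMC run configuration
#'
#' @param chain_length total iterations.
#' @param burn_in iterations discarded before sampling (`< chain_length`).
#' @param sample_every thinning interval; must divide
#'   `chain_length - burn_in`.
#' @param n_chains number of chains run by [run_chains()].
#' @param seed base RNG seed; chain `j` uses `seed + j - 1`.
#' @param move_weights optional named numeric vector of proposal weights
#'   (see [propose()] for move names); unnamed moves keep their defaults.
#' @param kappa scale-move tuning parameter (fixed, no auto-tuning).
#' @param slide_window half-width (ka) of the windowed subtree-slide move.
#' @return an object of class `mcmc_config`.
#' @export
mcmc_config <- function(chain_length, burn_in = 0L, sample_every = 1L,
                        n_chains = 1L, seed = 1L, move_weights = NULL,
                        kappa = 1.5, slide_window = 0.5) {
  if (burn_in >= chain_length) stop("burn_in must be < chain_length")
  if ((chain_length - burn_in) %% sample_every != 0) {
    stop("sample_every must divide chain_length - burn_in")
  }
  structure(list(chain_length = as.integer(chain_length),
                 burn_in = as.integer(burn_in),
                 sample_every = as.integer(sample_every),
                 n_chains = as.integer(n_chains), seed = as.integer(seed),
                 move_weights = move_weights, kappa = kappa,
                 slide_window = slide_window),
            class = "mcmc_config")
}

# default proposal weights: topology 30%, node ages 30%, clock/branch rates
# 20%, substitution + FBD scalars 20% (split within blocks)
default_move_weights <- function(state) {
  w <- c(narrow_exchange = 15, wilson_balding = 15,
         node_age_slide = 20, subtree_slide = 5, root_scaler = 5,
         scale_clock_rate = 10, branch_rate_scaler = 10,
         scale_gain = 4, scale_loss = 4,
         scale_s_on = 2, scale_s_off = 2, scale_alpha = 3,
         scale_lambda = 2, scale_mu = 1, scale_psi = 1, rho_walk = 2)
  if (state$model$kind != "m1p+CV") w[c("scale_s_on", "scale_s_off")] <- 0
  if (state$model$kind != "m1p+G4") w["scale_alpha"] <- 0
  if (state$clock$kind == "strict") w["branch_rate_scaler"] <- 0
  if (state$fbd$mu == 0) w["scale_mu"] <- 0
  if (state$fbd$psi == 0) w["scale_psi"] <- 0
  if (state$fbd$rho %in% c(0, 1)) w["rho_walk"] <- 0   # rho fixed at boundary
  if (state$tree$ntip < 3) w[c("narrow_exchange", "wilson_balding",
                               "node_age_slide", "subtree_slide")] <- 0
  w
}

log_unif_scale <- function(kappa) exp(stats::runif(1, -log(kappa), log(kappa)))

#' Propose a new state
#'
#' Standard time-tree operator suite. Move kinds: `node_age_slide` (uniform
#' resample of an interior node age between its children and parent),
#' `root_scaler`, `subtree_slide` (windowed, non-regrafting age shift),
#' `narrow_exchange`, `wilson_balding` (prune-and-regraft that never
#' re-roots), multiplicative scalers for every scalar rate parameter,
#' `rho_walk` (reflected random walk on `[0, 1]`) and `branch_rate_scaler`.
#' Scale moves draw the factor `f` log-uniformly on `[1/kappa, kappa]` and
#' have log Hastings ratio `log f`; exchange and slide moves are symmetric;
#' the Wilson-Balding ratio is the log ratio of the new to old reattachment
#' age ranges. Moves may propose states that violate calibrations or
#' constraints; those are vetoed by the prior, not here.
#'
#' @param state a [model_state()].
#' @param move move name (see above).
#' @param kappa scale tuning parameter.
#' @param slide_window half-width (ka) for `subtree_slide`.
#' @return list with elements `state`, `log_hr`, and `valid` (`FALSE` for
#'   structurally impossible proposals, which the sampler rejects outright).
#' @export
propose <- function(state, move, kappa = 1.5, slide_window = 0.5) {
  tt <- state$tree
  ntip <- tt$ntip
  ntot <- length(tt$parent)
  internals <- setdiff((ntip + 1L):ntot, tt$root)
  res <- list(state = state, log_hr = 0, valid = TRUE)

  scale_param <- function(get, set) {
    f <- log_unif_scale(kappa)
    st <- set(state, get(state) * f)
    list(state = st, log_hr = log(f), valid = TRUE)
  }

  switch(move,
    node_age_slide = {
      if (!length(internals)) return(list(state = state, log_hr = 0, valid = FALSE))
      nd <- internals[sample.int(length(internals), 1L)]
      kids <- which(tt$parent == nd)
      lo <- max(tt$ages[kids]); hi <- tt$ages[tt$parent[nd]]
      tt$ages[nd] <- stats::runif(1, lo, hi)
      state$tree <- tt
      list(state = state, log_hr = 0, valid = TRUE)
    },
    subtree_slide = {
      if (!length(internals)) return(list(state = state, log_hr = 0, valid = FALSE))
      nd <- internals[sample.int(length(internals), 1L)]
      kids <- which(tt$parent == nd)
      new_age <- tt$ages[nd] + stats::runif(1, -slide_window, slide_window)
      if (new_age <= max(tt$ages[kids]) || new_age >= tt$ages[tt$parent[nd]]) {
        return(list(state = state, log_hr = 0, valid = FALSE))
      }
      tt$ages[nd] <- new_age
      state$tree <- tt
      list(state = state, log_hr = 0, valid = TRUE)
    },
    root_scaler = {
      f <- log_unif_scale(kappa)
      kids <- which(tt$parent == tt$root)
      new_age <- tt$ages[tt$root] * f
      if (new_age <= max(tt$ages[kids])) {
        return(list(state = state, log_hr = 0, valid = FALSE))
      }
      tt$ages[tt$root] <- new_age
      state$tree <- tt
      list(state = state, log_hr = log(f), valid = TRUE)
    },
    narrow_exchange = {
      if (!length(internals)) return(list(state = state, log_hr = 0, valid = FALSE))
      p <- internals[sample.int(length(internals), 1L)]
      gp <- tt$parent[p]
      uncle <- setdiff(which(tt$parent == gp), p)
      kids <- which(tt$parent == p)
      child <- kids[sample.int(2L, 1L)]
      if (tt$ages[uncle] >= tt$ages[p]) {
        return(list(state = state, log_hr = 0, valid = FALSE))
      }
      tt$parent[child] <- gp
      tt$parent[uncle] <- p
      state$tree <- tt
      list(state = state, log_hr = 0, valid = TRUE)
    },
    wilson_balding = {
      eligible <- which(!is.na(tt$parent) & tt$parent != tt$root)
      if (!length(eligible)) return(list(state = state, log_hr = 0, valid = FALSE))
      i <- eligible[sample.int(length(eligible), 1L)]
      p <- tt$parent[i]
      gp <- tt$parent[p]
      sib <- setdiff(which(tt$parent == p), i)
      # subtree of i (excluded as destinations)
      desc <- i
      frontier <- i
      while (length(frontier)) {
        frontier <- which(tt$parent %in% frontier)
        desc <- c(desc, frontier)
      }
      cand <- setdiff(seq_len(ntot), c(tt$root, p, desc))
      cc <- cand[sample.int(length(cand), 1L)]
      pp <- if (cc == sib) gp else tt$parent[cc]
      lo_new <- max(tt$ages[i], tt$ages[cc]); hi_new <- tt$ages[pp]
      if (hi_new <= lo_new) return(list(state = state, log_hr = 0, valid = FALSE))
      lo_old <- max(tt$ages[i], tt$ages[sib]); hi_old <- tt$ages[gp]
      # detach p, reattach on the edge above cc
      tt$parent[sib] <- gp
      tt$parent[p] <- if (cc == sib) gp else tt$parent[cc]
      tt$parent[cc] <- p
      tt$ages[p] <- stats::runif(1, lo_new, hi_new)
      state$tree <- tt
      list(state = state, log_hr = log(hi_new - lo_new) - log(hi_old - lo_old),
           valid = TRUE)
    },
    branch_rate_scaler = {
      nonroot <- setdiff(seq_len(ntot), tt$root)
      e <- nonroot[sample.int(length(nonroot), 1L)]
      f <- log_unif_scale(kappa)
      state$branch_rates[e] <- state$branch_rates[e] * f
      list(state = state, log_hr = log(f), valid = TRUE)
    },
    rho_walk = {
      r <- state$fbd$rho + stats::runif(1, -0.1, 0.1)
      if (r < 0) r <- -r
      if (r > 1) r <- 2 - r
      state$fbd$rho <- r
      list(state = state, log_hr = 0, valid = TRUE)
    },
    scale_gain = scale_param(function(s) s$model$gain,
                             function(s, v) { s$model$gain <- v; s }),
    scale_loss = scale_param(function(s) s$model$loss,
                             function(s, v) { s$model$loss <- v; s }),
    scale_s_on = scale_param(function(s) s$model$s_on,
                             function(s, v) { s$model$s_on <- v; s }),
    scale_s_off = scale_param(function(s) s$model$s_off,
                              function(s, v) { s$model$s_off <- v; s }),
    scale_alpha = scale_param(function(s) s$model$alpha,
                              function(s, v) { s$model$alpha <- v; s }),
    scale_clock_rate = scale_param(function(s) s$clock$rate,
                                   function(s, v) { s$clock$rate <- v; s }),
    scale_lambda = scale_param(function(s) s$fbd$lambda,
                               function(s, v) { s$fbd$lambda <- v; s }),
    scale_mu = scale_param(function(s) s$fbd$mu,
                           function(s, v) { s$fbd$mu <- v; s }),
    scale_psi = scale_param(function(s) s$fbd$psi,
                            function(s, v) { s$fbd$psi <- v; s }),
    stop("unknown move kind: ", move)
  )
}

state_scalars <- function(state) {
  m <- state$model
  c(gain = m$gain, loss = m$loss,
    s_on = if (m$kind == "m1p+CV") m$s_on else NA_real_,
    s_off = if (m$kind == "m1p+CV") m$s_off else NA_real_,
    alpha = if (m$kind == "m1p+G4") m$alpha else NA_real_,
    clock_rate = state$clock$rate,
    lambda = state$fbd$lambda, mu = state$fbd$mu, psi = state$fbd$psi,
    rho = state$fbd$rho,
    root_age = tt_root_age(state$tree),
    tree_length = sum(tt_durations(state$tree), na.rm = TRUE))
}

#' Run a Metropolis-Hastings chain
#'
#' Samples trees and parameters from `prior x likelihood^beta` (`beta = 1`
#' is the posterior; `beta = 0` is prior-only sampling, in which case
#' `patterns` may be `NULL`). Deterministic for a fixed seed.
#'
#' @param patterns a [compress_patterns()] object (or [binary_matrix()]), or
#'   `NULL` for prior-only sampling.
#' @param init a [model_state()]; must not violate the prior (error
#'   otherwise).
#' @param spec a [prior_spec()].
#' @param cfg an [mcmc_config()].
#' @param beta likelihood tempering exponent in `[0, 1]`.
#' @param chain_id offsets the seed for multi-chain runs.
#' @return an object of class `posterior_sample`: `trace` (tibble with
#'   `sample`, `posterior`, `likelihood`, `prior` and every scalar
#'   parameter), `trees` (list of [time_tree()]s, one per trace row), and
#'   the acceptance rate.
#' @export
run_chain <- function(patterns, init, spec, cfg, beta = 1, chain_id = 1L) {
  set.seed(cfg$seed + chain_id - 1L)
  state <- init
  # with beta = 0 but data supplied, the chain samples the prior while still
  # logging the likelihood (needed by stepping-stone's first step)
  prior_only <- is.null(patterns)
  if (!prior_only && inherits(patterns, "binary_matrix")) {
    patterns <- compress_patterns(patterns)
  }
  lp <- joint_log_prior(state, spec)
  if (!is.finite(lp)) stop("initial state violates the prior/constraints")
  llfun <- make_loglik_fun(patterns, init$tree$tip_labels, prior_only)
  ll <- llfun(state)
  weights <- default_move_weights(state)
  if (!is.null(cfg$move_weights)) {
    weights[names(cfg$move_weights)] <- cfg$move_weights
  }
  weights <- weights[weights > 0]
  moves <- names(weights)
  n_keep <- (cfg$chain_length - cfg$burn_in) %/% cfg$sample_every
  trace <- matrix(NA_real_, n_keep, 3 + length(state_scalars(state)))
  colnames(trace) <- c("posterior", "likelihood", "prior", names(state_scalars(state)))
  sample_its <- integer(n_keep)
  trees <- vector("list", n_keep)
  kept <- 0L
  accepted <- 0L
  mv_idx <- sample.int(length(moves), cfg$chain_length, replace = TRUE,
                       prob = weights)
  # these moves change only the tree prior, never the likelihood
  ll_invariant <- moves %in% c("scale_lambda", "scale_mu", "scale_psi",
                               "rho_walk")
  for (it in seq_len(cfg$chain_length)) {
    prop <- propose(state, moves[mv_idx[it]], kappa = cfg$kappa,
                    slide_window = cfg$slide_window)
    if (prop$valid) {
      lp2 <- joint_log_prior(prop$state, spec)
      if (is.finite(lp2)) {
        ll2 <- if (ll_invariant[mv_idx[it]]) ll else llfun(prop$state)
        d <- beta * (ll2 - ll) + (lp2 - lp) + prop$log_hr
        if (d >= 0 || log(stats::runif(1)) < d) {
          state <- prop$state; lp <- lp2; ll <- ll2
          accepted <- accepted + 1L
        }
      }
    }
    if (it > cfg$burn_in && (it - cfg$burn_in) %% cfg$sample_every == 0L) {
      kept <- kept + 1L
      trace[kept, ] <- c(ll + lp, ll, lp, state_scalars(state))
      sample_its[kept] <- it
      trees[[kept]] <- state$tree
    }
  }
  tr <- tibble::as_tibble(trace)
  tr <- dplyr::bind_cols(tibble::tibble(sample = sample_its), tr)
  structure(list(trace = tr, trees = trees,
                 acceptance_rate = accepted / cfg$chain_length,
                 beta = beta, config = cfg, final_state = state),
            class = "posterior_sample")
}

#' @export
print.posterior_sample <- function(x, ...) {
  cat("<posterior_sample> ", nrow(x$trace), " samples (acceptance ",
      round(100 * x$acceptance_rate, 1), "%)\n", sep = "")
  invisible(x)
}

# likelihood closure with pattern/tip-partial preprocessing and machinery
# caching keyed on the substitution parameters
make_loglik_fun <- function(patterns, tip_labels, prior_only) {
  if (prior_only) return(function(state) 0)
  ord <- match(tip_labels, patterns$languages)
  if (anyNA(ord)) stop("patterns and tree tips do not match")
  pm <- patterns$patterns[ord, , drop = FALSE]
  w <- patterns$weights
  n_sites <- patterns$n_sites
  cache_key <- NULL
  cache_m <- NULL
  tipp <- NULL
  function(state) {
    key <- c(state$model$gain, state$model$loss, state$model$s_on,
             state$model$s_off, state$model$alpha)
    if (is.null(cache_key) || !identical(key, cache_key)) {
      cache_m <<- model_machinery(state$model)
      cache_key <<- key
      if (is.null(tipp)) tipp <<- tip_partial_matrix(pm, cache_m$nstate)
    }
    m <- cache_m
    tree <- state$tree
    par0 <- tree$parent
    par0[tree$root] <- 0L
    br0 <- state$branch_rates
    br0[tree$root] <- 1
    K <- length(m$cat_rates)
    np <- ncol(pm)
    lls <- matrix(NA_real_, np, K)
    for (j in seq_len(K)) {
      lls[, j] <- prune_loglik_cpp(par0, tree$root, tree$ages, br0,
                                   state$clock$rate, m$cat_rates[j],
                                   tree$ntip, tipp, m$V, m$d, m$Vinv, m$freq)
    }
    ll <- if (K == 1L) lls[, 1] else {
      mx <- apply(lls, 1, max)
      out <- mx + log(rowMeans(exp(lls - mx)))
      out[!is.finite(mx)] <- -Inf
      out
    }
    total <- sum(w * ll)
    if (state$model$ascertainment) {
      ll0 <- pattern_log_likelihoods(tree, state$model,
                                     matrix(0L, tree$ntip, 1),
                                     state$branch_rates, state$clock$rate,
                                     machinery = m)
      total <- total - n_sites * log1p(-exp(ll0[1]))
    }
    total
  }
}

#' Run several chains with offset seeds
#'
#' @inheritParams run_chain
#' @return a list of [run_chain()] results, one per chain.
#' @export
run_chains <- function(patterns, init, spec, cfg, beta = 1) {
  lapply(seq_len(cfg$n_chains), function(j) {
    run_chain(patterns, init, spec, cfg, beta = beta, chain_id = j)
  })
}

#' Effective sample size of an MCMC trace
#'
#' `ESS = n / (1 + 2 * sum(rho_k))` with the autocorrelation sum truncated at
#' the first non-positive lag (initial positive sequence). A constant series
#' returns `n` by convention with attribute `constant = TRUE`; a series whose
#' lag-1 autocorrelation is negative (antithetic behavior, ESS can exceed
#' `n`) is flagged with attribute `antithetic = TRUE`.
#'
#' @param x numeric trace (>= 10 samples).
#' @return the ESS estimate (with flags as attributes).
#' @export
effective_sample_size <- function(x) {
  n <- length(x)
  if (n < 10) stop("need at least 10 samples")
  if (stats::var(x) == 0) {
    return(structure(as.numeric(n), constant = TRUE))
  }
  rho <- stats::acf(x, lag.max = n - 2L, plot = FALSE)$acf[-1]
  pos <- which(rho <= 0)
  K <- if (length(pos)) pos[1] - 1L else length(rho)
  ess <- n / (1 + 2 * sum(rho[seq_len(K)]))
  ess <- min(ess, n * 10)   # guard against pathological denominators
  if (rho[1] < 0) attr(ess, "antithetic") <- TRUE
  ess
}

#' Convergence diagnostics across chains
#'
#' For every scalar in the trace, computes the between/within-chain variance
#' ratio `rhat = sqrt((W + B) / W)` (`B` is the variance of the chain means,
#' `W` the mean within-chain variance; exactly 1 when chains coincide) and
#' the pooled ESS, flagging parameters with `rhat > 1.05`.
#'
#' @param samples list of >= 2 [run_chain()] results over the same model.
#' @return tibble with columns `parameter`, `rhat`, `ess`, `flagged`.
#' @export
multichain_diagnostics <- function(samples) {
  if (length(samples) < 2) stop("need at least 2 chains")
  cols <- lapply(samples, function(s) names(s$trace))
  if (!all(vapply(cols[-1], identical, logical(1), cols[[1]]))) {
    stop("chains log different parameters")
  }
  pars <- setdiff(cols[[1]], "sample")
  purrr::map_dfr(pars, function(p) {
    xs <- lapply(samples, function(s) s$trace[[p]])
    if (anyNA(xs[[1]])) return(NULL)   # parameter absent from this model
    W <- mean(vapply(xs, stats::var, numeric(1)))
    B <- stats::var(vapply(xs, mean, numeric(1)))
    rhat <- if (W == 0) ifelse(B == 0, 1, Inf) else sqrt((W + B) / W)
    ess <- sum(vapply(xs, function(x) {
      if (stats::var(x) == 0) length(x) else as.numeric(effective_sample_size(x))
    }, numeric(1)))
    tibble::tibble(parameter = p, rhat = rhat, ess = ess,
                   flagged = rhat > 1.05)
  })
}

#' Write a BEAST-style tab-separated trace log
#' @param sample a [run_chain()] result.
#' @param path file path.
#' @export
write_trace <- function(sample, path) {
  tr <- sample$trace
  names(tr)[names(tr) == "sample"] <- "Sample"
  readr::write_tsv(tr, path, progress = FALSE)
  invisible(path)
}

#' Write sampled trees as a NEXUS trees block
#'
#' Standard translate table plus one dated tree per sampled state.
#' @param sample a [run_chain()] result (or a bare list of [time_tree()]s).
#' @param path file path.
#' @export
write_trees_nexus <- function(sample, path) {
  trees <- if (inherits(sample, "posterior_sample")) sample$trees else sample
  phy <- lapply(trees, as_phylo)
  class(phy) <- "multiPhylo"
  ape::write.nexus(phy, file = path, translate = TRUE)
  invisible(path)
}

#' Read a NEXUS trees block (or plain Newick list) into timetrees
#' @param path file path.
#' @param present age (ka BP) of the youngest tip.
#' @return list of [time_tree()]s.
#' @export
read_trees <- function(path, present = 0) {
  first <- toupper(readLines(path, n = 1L, warn = FALSE))
  phy <- if (startsWith(trimws(first), "#NEXUS")) {
    ape::read.nexus(path)
  } else {
    ape::read.tree(path)
  }
  if (inherits(phy, "phylo")) phy <- list(phy)
  lapply(phy, as_timetree, present = present)
}
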