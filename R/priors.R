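#' Clock models
#'
#' Either a strict clock (every branch evolves at the clock rate) or an
#' uncorrelated lognormal relaxed clock: each branch carries an independent
#' multiplier with real-space mean `mu` (default 1.0) and log-space standard
#' deviation `sigma` (default 0.1), so the clock rate keeps its
#' substitutions-per-ka interpretation.
#'
#' @param kind `"strict"` or `"relaxed-lognormal"`.
#' @param rate clock rate in expected substitutions per cognate set per ka.
#' @param mu real-space mean of the branch-rate multipliers.
#' @param sigma log-space standard deviation of the multipliers (>= 0).
#' @return an object of class `clock_model`.
#' @export
clock_model <- function(kind = c("strict", "relaxed-lognormal"),
                        rate = 1, mu = 1.0, sigma = 0.1) {
  kind <- match.arg(kind)
  if (rate <= 0) stop("clock rate must be positive")
  if (sigma < 0) stop("sigma must be >= 0")
  if (mu <= 0) stop("mu must be positive")
  structure(list(kind = kind, rate = rate, mu = mu, sigma = sigma),
            class = "clock_model")
}

#' Expected substitutions per branch
#'
#' `length_e = duration_e x multiplier_e x rate`, indexed by child node id
#' (root entry `NA`).
#'
#' @param tree a [time_tree()].
#' @param clock a [clock_model()].
#' @param branch_rates per-branch multipliers indexed by child node id; for a
#'   strict clock they default to 1, for a relaxed clock they must be given.
#' @return numeric vector of expected substitutions, indexed by child node.
#' @export
clock_branch_lengths <- function(tree, clock, branch_rates = NULL) {
  ntot <- length(tree$parent)
  if (clock$kind == "strict") {
    branch_rates <- branch_rates %||% rep(1, ntot)
  } else if (is.null(branch_rates)) {
    stop("relaxed clock needs per-branch multipliers")
  }
  if (length(branch_rates) != ntot) stop("one multiplier per node is required")
  br <- branch_rates[-tree$root]
  if (anyNA(br)) stop("missing branch multiplier")
  tt_durations(tree) * branch_rates * clock$rate
}

#' Log prior of relaxed-clock branch multipliers
#'
#' Sum of iid lognormal log densities with real-space mean `mu` and log-space
#' sd `sigma` (so `meanlog = log(mu) - sigma^2/2`). For a strict clock the
#' contribution is 0 by contract.
#'
#' @param clock a [clock_model()].
#' @param branch_rates multipliers indexed by child node id (root ignored),
#'   or a bare vector of multipliers.
#' @param tree optional [time_tree()] used to drop the root entry.
#' @return log density; `-Inf` if any multiplier is <= 0.
#' @export
branch_rate_log_prior <- function(clock, branch_rates, tree = NULL) {
  if (clock$kind == "strict") return(0)
  x <- if (!is.null(tree)) branch_rates[-tree$root] else branch_rates[!is.na(branch_rates)]
  if (any(x <= 0)) return(-Inf)
  sum(stats::dlnorm(x, meanlog = log(clock$mu) - clock$sigma^2 / 2,
                    sdlog = clock$sigma, log = TRUE))
}

#' Fossilized birth-death parameters
#'
#' @param lambda lineage birth rate per ka (> 0).
#' @param mu lineage death rate per ka (>= 0).
#' @param psi through-time sampling rate of non-surviving lineages (>= 0); a
#'   psi-sampled lineage is recorded as an extinct tip and removed.
#' @param rho sampling probability of extant languages, in `[0, 1]`.
#' @return an object of class `fbd_params`.
#' @export
fbd_params <- function(lambda, mu = 0, psi = 0, rho = 1) {
  if (lambda <= 0) stop("lambda must be positive")
  if (mu < 0 || psi < 0) stop("mu and psi must be >= 0")
  if (rho < 0 || rho > 1) stop("rho must be in [0, 1]")
  structure(list(lambda = lambda, mu = mu, psi = psi, rho = rho),
            class = "fbd_params")
}

# log q(t) with c1 = |sqrt((la-mu-psi)^2 + 4 la psi)|,
# c2 = -(la - mu - 2 la rho - psi)/c1,
# q(t) = 4 exp(-c1 t) / (exp(-c1 t)(1-c2) + (1+c2))^2
fbd_log_q <- function(t, p) {
  c1 <- abs(sqrt((p$lambda - p$mu - p$psi)^2 + 4 * p$lambda * p$psi))
  if (c1 == 0) {                      # lambda = mu, psi = 0: take the limit
    return(log(4) - 2 * log(2 + 2 * p$lambda * p$rho * t))
  }
  c2 <- -(p$lambda - p$mu - 2 * p$lambda * p$rho - p$psi) / c1
  log(4) - c1 * t - 2 * log(exp(-c1 * t) * (1 - c2) + (1 + c2))
}

#' Log density of a dated tree under the fossilized birth-death prior
#'
#' Density of the sampled, labeled, dated tree given its root age under a
#' constant-rate birth-death process with through-time (psi) sampling of
#' non-surviving lineages and extant (rho) sampling, conditioned on the root
#' having at least one sampled descendant on each side (which any tree whose
#' root is the MRCA of its sample satisfies). Each branch from parent age
#' `s` to child age `t` contributes `q(s)/q(t)`; each non-root internal node
#' contributes `lambda`; each extant tip `rho`; each extinct tip at age `y`
#' contributes `psi / q(y)`. In the pure-birth limit (`mu = psi = 0`,
#' `rho = 1`) this reduces to the Yule density
#' `sum(log lambda) - lambda * total tree length`.
#'
#' @param tree a [time_tree()].
#' @param p an [fbd_params()].
#' @return log density; `-Inf` (with a warning) if the tree has extinct tips
#'   but `psi = 0`, or extant tips but `rho = 0`.
#' @export
fbd_log_density <- function(tree, p) {
  stopifnot(inherits(p, "fbd_params"))
  tip_ages <- tree$ages[seq_len(tree$ntip)]
  extinct <- tip_ages > 1e-8
  if (any(extinct) && p$psi == 0) {
    warning("tree has extinct tips but psi = 0: density is zero")
    return(-Inf)
  }
  if (any(!extinct) && p$rho == 0) {
    warning("tree has extant tips but rho = 0: density is zero")
    return(-Inf)
  }
  ntip <- tree$ntip
  ntot <- 2L * ntip - 1L
  internal <- (ntip + 1L):ntot
  nonroot_int <- internal[internal != tree$root]
  n_ext <- sum(extinct)
  ages <- c(tree$ages[tree$root], tree$ages[nonroot_int],
            if (n_ext) tip_ages[extinct])
  lq <- fbd_log_q(ages, p)
  ll <- 2 * lq[1] + (ntip - 2L) * log(p$lambda) +
    sum(lq[seq_len(ntip - 2L) + 1L]) +
    (ntip - n_ext) * log(p$rho)
  if (n_ext) {
    ll <- ll + n_ext * log(p$psi) - sum(lq[(ntip - 1L) + seq_len(n_ext)])
  }
  ll
}

#' Calibrations: fixed tip dates and minimum clade ages
#'
#' `tip_date` pins an (extinct) language to its last-seen age; `mrca_min_age`
#' is a hard lower bound on the age of the most recent common ancestor of a
#' taxon set — "earlier than" historical records translate into indicator
#' priors, not soft densities.
#'
#' @param kind `"tip_date"` or `"mrca_min_age"`.
#' @param taxa for `tip_date` exactly one language name; for `mrca_min_age`
#'   two or more.
#' @param age_ka the fixed tip age or the minimum MRCA age, in ka BP.
#' @return an object of class `calibration`.
#' @export
calibration <- function(kind = c("tip_date", "mrca_min_age"), taxa, age_ka) {
  kind <- match.arg(kind)
  if (kind == "tip_date" && length(taxa) != 1L) stop("tip_date names exactly one taxon")
  if (kind == "mrca_min_age" && length(taxa) < 2L) stop("mrca_min_age needs >= 2 taxa")
  if (age_ka < 0) stop("calibration age must be >= 0 ka BP")
  structure(list(kind = kind, taxa = taxa, age_ka = age_ka), class = "calibration")
}

#' Log prior contribution of hard calibrations
#'
#' 0 when every calibration holds, `-Inf` otherwise: a tip-date calibration
#' holds when the tip sits at its fixed age (within `tol` ka); a minimum
#' MRCA-age calibration holds when the clade's MRCA is at least as old as the
#' bound.
#'
#' @param tree a [time_tree()].
#' @param cals list of [calibration()]s.
#' @param tol tolerance (ka) for fixed tip ages.
#' @return 0 or `-Inf`.
#' @export
calibration_log_prior <- function(tree, cals, tol = 1e-8) {
  for (cal in cals) {
    if (cal$kind == "tip_date") {
      i <- match(cal$taxa, tree$tip_labels)
      if (is.na(i)) stop("unknown taxon in calibration: ", cal$taxa)
      if (abs(tree$ages[i] - cal$age_ka) > tol) return(-Inf)
    } else {
      if (tree$ages[tt_mrca(tree, cal$taxa)] < cal$age_ka) return(-Inf)
    }
  }
  0
}

#' Monophyly (and outgroup) constraints
#'
#' @param taxa nonempty proper subset of tip labels required to form a clade.
#' @param as_outgroup if `TRUE`, the clade must additionally be one child of
#'   the root (i.e. the taxa form one side of the root split).
#' @return an object of class `monophyly_constraint`.
#' @export
monophyly_constraint <- function(taxa, as_outgroup = FALSE) {
  if (!length(taxa)) stop("constraint needs at least one taxon")
  structure(list(taxa = taxa, as_outgroup = as_outgroup),
            class = "monophyly_constraint")
}

#' Test whether a tree satisfies a monophyly constraint
#'
#' @param tree a [time_tree()].
#' @param con a [monophyly_constraint()].
#' @return `TRUE` iff the taxa form a clade (and, when `as_outgroup`, that
#'   clade is a child of the root).
#' @export
constraint_satisfied <- function(tree, con) {
  ids <- match(con$taxa, tree$tip_labels)
  if (anyNA(ids)) stop("unknown taxa: ", paste(con$taxa[is.na(ids)], collapse = ", "))
  if (length(ids) >= tree$ntip) stop("constraint taxa must be a proper subset of tips")
  if (length(ids) == 1L && !con$as_outgroup) return(TRUE)
  sets <- tt_tipsets(tree)
  target <- sort(ids)
  node <- NULL
  for (nd in seq_along(sets)) {
    if (length(sets[[nd]]) == length(target) && all(sets[[nd]] == target)) {
      node <- nd
      break
    }
  }
  if (is.null(node)) return(FALSE)
  if (!con$as_outgroup) return(TRUE)
  identical(tree$parent[node], tree$root)
}

#' Prior specification for the full model
#'
#' Exponential priors (given by their means) on the substitution, covarion,
#' gamma-shape, clock and birth-death rates; uniform `[0, 1]` on the extant
#' sampling proportion `rho`; optionally a proper uniform prior on the root
#' age (`root_age_max`), otherwise the root age is improper-flat and the tree
#' prior alone shapes it. Defaults: mean 10 on gain and loss, mean 1
#' elsewhere.
#'
#' @param mean_gain,mean_loss,mean_s_on,mean_s_off,mean_alpha,mean_clock_rate,mean_lambda,mean_mu,mean_psi
#'   exponential prior means.
#' @param root_age_max if finite, the root age gets a Uniform(0, root_age_max)
#'   prior.
#' @param calibrations list of [calibration()]s.
#' @param constraints list of [monophyly_constraint()]s.
#' @return an object of class `prior_spec`.
#' @export
prior_spec <- function(mean_gain = 10, mean_loss = 10,
                       mean_s_on = 1, mean_s_off = 1, mean_alpha = 1,
                       mean_clock_rate = 1,
                       mean_lambda = 1, mean_mu = 1, mean_psi = 1,
                       root_age_max = Inf,
                       calibrations = list(), constraints = list()) {
  structure(list(
    mean_gain = mean_gain, mean_loss = mean_loss,
    mean_s_on = mean_s_on, mean_s_off = mean_s_off, mean_alpha = mean_alpha,
    mean_clock_rate = mean_clock_rate,
    mean_lambda = mean_lambda, mean_mu = mean_mu, mean_psi = mean_psi,
    root_age_max = root_age_max,
    calibrations = calibrations, constraints = constraints
  ), class = "prior_spec")
}

dexp_mean <- function(x, mean) {
  if (x <= 0) return(-Inf)
  -log(mean) - x / mean
}

#' Joint log prior of a model state
#'
#' Sum of the tree prior ([fbd_log_density()]), the parameter priors, the
#' relaxed-clock branch-rate prior, the calibration indicator prior, and
#' `-Inf` whenever a monophyly constraint fails.
#'
#' @param state a [model_state()].
#' @param spec a [prior_spec()].
#' @return log prior density.
#' @export
joint_log_prior <- function(state, spec) {
  tree <- state$tree
  for (con in spec$constraints) {
    if (!constraint_satisfied(tree, con)) return(-Inf)
  }
  lp <- calibration_log_prior(tree, spec$calibrations)
  if (!is.finite(lp)) return(-Inf)
  if (is.finite(spec$root_age_max)) {
    ra <- tt_root_age(tree)
    if (ra > spec$root_age_max) return(-Inf)
    lp <- lp - log(spec$root_age_max)
  }
  lp <- lp + suppressWarnings(fbd_log_density(tree, state$fbd))
  if (!is.finite(lp)) return(-Inf)
  m <- state$model
  lp <- lp + dexp_mean(m$gain, spec$mean_gain) + dexp_mean(m$loss, spec$mean_loss)
  if (m$kind == "m1p+CV") {
    lp <- lp + dexp_mean(m$s_on, spec$mean_s_on) + dexp_mean(m$s_off, spec$mean_s_off)
  }
  if (m$kind == "m1p+G4") lp <- lp + dexp_mean(m$alpha, spec$mean_alpha)
  lp <- lp + dexp_mean(state$clock$rate, spec$mean_clock_rate)
  lp <- lp + dexp_mean(state$fbd$lambda, spec$mean_lambda)
  # death and serial-sampling rates fixed at the 0 boundary are treated as
  # fixed constants, not sampled parameters
  lp <- lp + if (state$fbd$mu == 0) 0 else dexp_mean(state$fbd$mu, spec$mean_mu)
  lp <- lp + if (state$fbd$psi == 0) 0 else dexp_mean(state$fbd$psi, spec$mean_psi)
  # rho: Uniform[0,1] contributes 0 on its support
  if (state$fbd$rho < 0 || state$fbd$rho > 1) return(-Inf)
  lp <- lp + branch_rate_log_prior(state$clock, state$branch_rates, tree)
  lp
}
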