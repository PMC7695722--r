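#' Phylogenetic likelihood of binary cognate patterns
#'
#' Felsenstein pruning over the model's state space (2 states for m1p, 4 for
#' the covarion), with per-pattern numerical rescaling. The expected
#' substitution length of a branch is its duration (ka) times its relaxed
#' clock multiplier times the clock rate; under `m1p+G4` the per-site
#' likelihood is the equal-weight average over the gamma categories; root
#' states are weighted by the model's stationary distribution.
#'
#' @param tree a [time_tree()].
#' @param model a [subst_model()].
#' @param pattern a single site pattern: vector over `{0, 1, NA}` (or `"?"`)
#'   named by, or ordered as, the tree's tip labels.
#' @param patterns a [compress_patterns()] object (or a [binary_matrix()],
#'   which is compressed on the fly).
#' @param branch_rates per-branch rate multipliers indexed by child node id
#'   (length `2*ntip-1`, root entry ignored); `NULL` means a strict clock
#'   (all 1).
#' @param clock_rate overall clock rate in expected substitutions per ka.
#' @param ascertainment if `TRUE`, subtract `n_sites * log(1 - P(all-absent))`
#'   to correct for cognate classes that cannot be observed as all-absent
#'   columns. Defaults to the model's `ascertainment` flag.
#' @return `site_log_likelihood`: the log-likelihood of one pattern;
#'   `data_log_likelihood`: the total log-likelihood over weighted patterns.
#' @export
site_log_likelihood <- function(tree, model, pattern, branch_rates = NULL,
                                clock_rate = 1) {
  pat <- normalize_pattern(pattern, tree$tip_labels)
  ll <- pattern_log_likelihoods(tree, model, matrix(pat, ncol = 1),
                                branch_rates, clock_rate)
  ll[1]
}

#' @rdname site_log_likelihood
#' @export
data_log_likelihood <- function(tree, model, patterns, branch_rates = NULL,
                                clock_rate = 1,
                                ascertainment = model$ascertainment) {
  if (inherits(patterns, "binary_matrix")) patterns <- compress_patterns(patterns)
  stopifnot(inherits(patterns, "site_patterns"))
  ord <- match(tree$tip_labels, patterns$languages)
  if (anyNA(ord)) stop("patterns and tree tips do not match")
  pm <- patterns$patterns[ord, , drop = FALSE]
  ll <- pattern_log_likelihoods(tree, model, pm, branch_rates, clock_rate)
  total <- sum(patterns$weights * ll)
  if (ascertainment) {
    ll0 <- pattern_log_likelihoods(tree, model,
                                   matrix(0L, nrow = tree$ntip, ncol = 1),
                                   branch_rates, clock_rate)
    total <- total - patterns$n_sites * log1p(-exp(ll0[1]))
  }
  total
}

# core: patterns as ntip x npattern matrix over {0L, 1L, NA}; returns per-
# pattern log-likelihoods
pattern_log_likelihoods <- function(tree, model, pm, branch_rates = NULL,
                                    clock_rate = 1, machinery = NULL) {
  if (nrow(pm) != tree$ntip) stop("pattern length must equal the number of tips")
  if (clock_rate <= 0) stop("clock_rate must be positive")
  m <- machinery %||% model_machinery(model)
  ntot <- length(tree$parent)
  if (is.null(branch_rates)) branch_rates <- rep(1, ntot)
  br <- branch_rates[-tree$root]
  if (length(branch_rates) != ntot || anyNA(br) || any(br <= 0)) {
    stop("branch_rates must be positive and indexed by child node id")
  }
  par0 <- tree$parent
  par0[tree$root] <- 0L
  br0 <- branch_rates
  br0[tree$root] <- 1
  tipp <- tip_partial_matrix(pm, m$nstate)
  np <- ncol(pm)
  K <- length(m$cat_rates)
  lls <- matrix(NA_real_, np, K)
  for (j in seq_len(K)) {
    lls[, j] <- prune_loglik_cpp(par0, tree$root, tree$ages, br0, clock_rate,
                                 m$cat_rates[j], tree$ntip, tipp,
                                 m$V, m$d, m$Vinv, m$freq)
  }
  if (K == 1L) return(lls[, 1])
  # average site likelihood over categories, in log space
  mx <- apply(lls, 1, max)
  out <- mx + log(rowMeans(exp(lls - mx)))
  out[!is.finite(mx)] <- -Inf
  out
}

# nstate x (np*ntip) tip partial matrix, tip-major columns
tip_partial_matrix <- function(pm, nstate) {
  ntip <- nrow(pm)
  np <- ncol(pm)
  out <- matrix(1, nstate, np * ntip)
  half <- nstate / 2L
  for (tip in seq_len(ntip)) {
    cols <- (tip - 1L) * np + seq_len(np)
    x <- pm[tip, ]
    zero <- which(!is.na(x) & x == 0L)
    one <- which(!is.na(x) & x == 1L)
    bad <- which(!is.na(x) & !(x %in% c(0L, 1L)))
    if (length(bad)) stop("unknown state symbol in pattern")
    if (nstate == 2L) {
      out[2L, cols[zero]] <- 0
      out[1L, cols[one]] <- 0
    } else {
      out[c(2L, 4L), cols[zero]] <- 0
      out[c(1L, 3L), cols[one]] <- 0
    }
  }
  out
}

# coerce a user pattern (possibly character with "?") to integer {0,1,NA}
# in tip-label order
normalize_pattern <- function(pattern, tip_labels) {
  if (!is.null(names(pattern))) {
    idx <- match(tip_labels, names(pattern))
    if (anyNA(idx)) stop("pattern names do not cover all tips")
    pattern <- pattern[idx]
  } else if (length(pattern) != length(tip_labels)) {
    stop("pattern length must equal the number of tips")
  }
  if (is.character(pattern)) {
    out <- ifelse(pattern == "?", NA_integer_, suppressWarnings(as.integer(pattern)))
    if (any(!is.na(pattern) & pattern != "?" & !pattern %in% c("0", "1"))) {
      stop("unknown state symbol in pattern")
    }
    out
  } else {
    as.integer(pattern)
  }
}
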