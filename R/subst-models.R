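#' Substitution models for binary cognate characters
#'
#' Three nested models of cognate-class evolution are supported:
#'
#' * `"m1p"` — the two-state continuous-time Markov model with a gain rate
#'   (absence to presence, 0 to 1) and a loss rate (1 to 0) per ka. Its
#'   stationary distribution is `(loss, gain) / (gain + loss)`.
#' * `"m1p+G4"` — m1p with discrete gamma rate heterogeneity across cognate
#'   sets (`k` equal-probability categories, category means, renormalized to
#'   mean one).
#' * `"m1p+CV"` — m1p wrapped in a binary covarion: each character toggles
#'   between an evolving "on" state and a frozen "off" state, with switch
#'   rates `s_on` (off to on) and `s_off` (on to off). Hidden states are
#'   ordered (0·on, 1·on, 0·off, 1·off).
#'
#' With `normalize = TRUE` (default) the generator is rescaled so the
#' expected visible (0/1) substitution rate at stationarity equals 1, which
#' makes the clock rate interpretable as expected substitutions per cognate
#' set per ka.
#'
#' @param kind one of `"m1p"`, `"m1p+G4"`, `"m1p+CV"`.
#' @param gain,loss m1p gain (0 to 1) and loss (1 to 0) rates, > 0.
#' @param s_on,s_off covarion switch rates off to on and on to off (> 0;
#'   `"m1p+CV"` only).
#' @param alpha gamma shape (> 0; `"m1p+G4"` only).
#' @param k number of gamma categories (default 4).
#' @param normalize rescale to unit expected visible substitution rate.
#' @param ascertainment apply the correction for unobservable all-absent
#'   cognate columns in [data_log_likelihood()]. Off by default.
#' @return an object of class `subst_model`.
#' @export
subst_model <- function(kind = c("m1p", "m1p+G4", "m1p+CV"),
                        gain = 1, loss = 1,
                        s_on = NULL, s_off = NULL,
                        alpha = NULL, k = 4L,
                        normalize = TRUE, ascertainment = FALSE) {
  kind <- match.arg(kind)
  if (gain <= 0 || loss <= 0) stop("gain and loss rates must be positive")
  if (kind == "m1p+CV") {
    if (is.null(s_on) || is.null(s_off)) stop("covarion model needs s_on and s_off")
    if (s_on <= 0 || s_off <= 0) stop("switch rates must be positive")
  } else if (!is.null(s_on) || !is.null(s_off)) {
    stop("switch rates only apply to kind = 'm1p+CV'")
  }
  if (kind == "m1p+G4") {
    if (is.null(alpha)) stop("gamma model needs alpha")
    if (alpha <= 0) stop("alpha must be positive")
  } else if (!is.null(alpha)) {
    stop("alpha only applies to kind = 'm1p+G4'")
  }
  structure(
    list(kind = kind, gain = gain, loss = loss,
         s_on = s_on, s_off = s_off, alpha = alpha, k = as.integer(k),
         normalize = normalize, ascertainment = ascertainment),
    class = "subst_model"
  )
}

#' @export
print.subst_model <- function(x, ...) {
  cat("<subst_model> ", x$kind, ": gain=", x$gain, " loss=", x$loss, sep = "")
  if (x$kind == "m1p+CV") cat(" s_on=", x$s_on, " s_off=", x$s_off, sep = "")
  if (x$kind == "m1p+G4") cat(" alpha=", x$alpha, " k=", x$k, sep = "")
  cat(if (x$normalize) " (normalized)\n" else "\n")
  invisible(x)
}

#' Rate matrix of the two-state gain/loss model
#'
#' @param gain,loss positive rates of 0 to 1 and 1 to 0 change per ka.
#' @return 2x2 generator with rows summing to zero, states ordered (0, 1).
#' @export
m1p_generator <- function(gain, loss) {
  if (gain <= 0 || loss <= 0) stop("gain and loss rates must be positive")
  matrix(c(-gain, gain, loss, -loss), 2, 2, byrow = TRUE,
         dimnames = list(c("0", "1"), c("0", "1")))
}

#' Rate matrix of the binary covarion model
#'
#' Hidden-state order (0·on, 1·on, 0·off, 1·off). In the "on" block the
#' visible state evolves under m1p; in the "off" block it is frozen; the
#' hidden toggle runs at `s_off` (on to off) and `s_on` (off to on) without
#' changing the visible state.
#'
#' @inheritParams m1p_generator
#' @param s_on,s_off positive switch rates (off to on, on to off).
#' @return 4x4 generator with rows summing to zero.
#' @export
covarion_generator <- function(gain, loss, s_on, s_off) {
  if (gain <= 0 || loss <= 0) stop("gain and loss rates must be positive")
  if (s_on <= 0 || s_off <= 0) stop("switch rates must be positive")
  states <- c("0on", "1on", "0off", "1off")
  Q <- matrix(0, 4, 4, dimnames = list(states, states))
  Q["0on", "1on"] <- gain
  Q["1on", "0on"] <- loss
  Q["0on", "0off"] <- s_off
  Q["1on", "1off"] <- s_off
  Q["0off", "0on"] <- s_on
  Q["1off", "1on"] <- s_on
  diag(Q) <- -rowSums(Q)
  Q
}

# stationary distribution, visible-substitution normalizer and eigensystem
# for a subst_model; the generator is reversible so the eigensystem is real
# (computed on the pi-symmetrized matrix).
model_machinery <- function(model) {
  if (model$kind == "m1p+CV") {
    Q <- covarion_generator(model$gain, model$loss, model$s_on, model$s_off)
    pi_on <- model$s_on / (model$s_on + model$s_off)
    f <- c(model$loss, model$gain) / (model$gain + model$loss)
    freq <- c(pi_on * f, (1 - pi_on) * f)
    vis_rate <- pi_on * 2 * model$gain * model$loss / (model$gain + model$loss)
  } else {
    Q <- m1p_generator(model$gain, model$loss)
    freq <- c(model$loss, model$gain) / (model$gain + model$loss)
    vis_rate <- 2 * model$gain * model$loss / (model$gain + model$loss)
  }
  if (model$normalize) Q <- Q / vis_rate
  s <- sqrt(freq)
  B <- diag(s) %*% Q %*% diag(1 / s)
  B <- (B + t(B)) / 2             # symmetrize roundoff
  es <- eigen(B, symmetric = TRUE)
  V <- es$vectors / s             # diag(1/s) U
  Vinv <- t(es$vectors * s)       # U' diag(s)
  rates <- if (model$kind == "m1p+G4") gamma_category_rates(model$alpha, model$k) else 1
  list(Q = Q, freq = freq, V = V, d = es$values, Vinv = Vinv,
       nstate = nrow(Q), cat_rates = rates)
}

#' Transition probability matrix P(t) = exp(Qt)
#'
#' Computed by eigendecomposition of the reversible generator.
#' @param model a [subst_model()].
#' @param t elapsed expected-substitution length (>= 0).
#' @param machinery optional precomputed internal machinery (for reuse in
#'   loops); if supplied `model` is ignored.
#' @return transition matrix with rows summing to 1.
#' @export
transition_matrix <- function(model, t, machinery = NULL) {
  if (t < 0) stop("t must be >= 0")
  m <- machinery %||% model_machinery(model)
  P <- m$V %*% (exp(m$d * t) * m$Vinv)
  P[P < 0] <- 0
  P / rowSums(P)
}

#' Stationary distribution of a substitution model
#' @param model a [subst_model()].
#' @return named numeric vector over the model's (hidden) states.
#' @export
stationary_distribution <- function(model) {
  m <- model_machinery(model)
  stats::setNames(m$freq, rownames(m$Q))
}

#' Discrete gamma rate categories
#'
#' `k` equal-probability categories of a Gamma(alpha, alpha) distribution,
#' each represented by its category mean, renormalized to mean exactly one.
#'
#' @param alpha shape parameter (> 0).
#' @param k number of categories (>= 1).
#' @return nondecreasing numeric vector of length `k` with mean 1.
#' @export
gamma_category_rates <- function(alpha, k = 4L) {
  if (alpha <= 0) stop("alpha must be positive")
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1")
  if (k == 1L) return(1)
  # category mean of Gamma(a, a) between quantiles: uses the identity
  # E[X; X <= q] = P(Gamma(a+1, a) <= q) for mean-one gamma
  br <- stats::qgamma(seq_len(k - 1L) / k, shape = alpha, rate = alpha)
  upper <- stats::pgamma(c(br, Inf), shape = alpha + 1, rate = alpha)
  lower <- c(0, upper[-k])
  r <- (upper - lower) * k
  r <- r / mean(r)
  r
}

#' Partial-likelihood vector for an observed tip symbol
#'
#' Maps a tip observation to its conditional-likelihood vector over the
#' model's state space: observed 0/1 pin the visible state (both hidden
#' covarion states allowed), `?`/`NA` is complete uncertainty.
#'
#' @param observed one of `0`, `1`, `"?"` (or `NA`).
#' @param model a [subst_model()].
#' @return numeric vector of length 2 (m1p) or 4 (covarion).
#' @export
tip_partials <- function(observed, model) {
  nstate <- if (model$kind == "m1p+CV") 4L else 2L
  if (is.na(observed) || observed == "?") return(rep(1, nstate))
  obs <- as.character(observed)
  if (!obs %in% c("0", "1")) stop("unknown state symbol: ", obs)
  v <- if (obs == "0") c(1, 0) else c(0, 1)
  if (nstate == 4L) rep(v, 2L) else v
}

`%||%` <- function(a, b) if (is.null(a)) b else a
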