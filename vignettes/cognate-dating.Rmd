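---
title: "Bayesian tip-dated inference from binary cognate data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian tip-dated inference from binary cognate data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glottochron)
```

glottochron infers time-calibrated language phylogenies from basic-vocabulary
cognate data. This vignette is the package's account of the model it
implements, the numerical and design choices behind it, and what its
synthetic-data tests do and do not establish.

## The data model

The raw material is a lexical cognacy table: for each language and each
concept (a Swadesh-style meaning such as *hand* or *sun*), the cognate
class(es) that language attests. A class groups words descending from a
common ancestral word. Loanwords are flagged in the source data and removed
before inference, because they reflect contact, not descent. Each concept is
a multistate character; for analysis it is exploded into one binary
presence/absence column per (concept, class) pair:

* a language scores 1 in the column of each class it attests,
* 0 in the other columns of concepts it attests,
* `?` in every column of a concept for which it has no datum.

Two coding decisions deserve emphasis. First, a (language, concept) cell
whose only entries were loans becomes *missing*, not absent: after removing
the borrowed word we do not know the native cognate, and a 0 would assert a
loss event. Second, synonyms (two classes attested for one meaning) simply
put two 1s in that concept's columns, which is the standard "additional
binary trait" coding. Both choices are exercised directly by the test suite.

Identical binary columns are pooled into weighted site patterns before
likelihood evaluation; this is exact, not an approximation.

## Models of cognate evolution

The elementary process is a two-state continuous-time Markov chain (`m1p`)
with a gain rate $a$ ($0 \to 1$) and a loss rate $b$ ($1 \to 0$) per
thousand years (ka); its stationary distribution is $(b, a)/(a+b)$. Two
extensions are available:

* **Gamma rate heterogeneity** (`m1p+G4`): cognate sets evolve at rates
  drawn from a discretized Gamma($\alpha,\alpha$) with four equal-probability
  categories represented by their category means, renormalized to mean one.
  Category means (not medians) are the package convention; the choice is
  recorded here because the two conventions differ noticeably for
  $\alpha < 1$.
* **Binary covarion** (`m1p+CV`): each cognate set toggles between an
  evolving "on" state and a frozen "off" state with switch rates
  $s_{\mathrm{on}}$ (off→on) and $s_{\mathrm{off}}$ (on→off). We use the
  two-switch-rate form with hidden states ordered
  (0·on, 1·on, 0·off, 1·off), a frozen off block, and the full 4-state
  stationary distribution at the root. The stationary law factorizes as
  (on/off) ⊗ (m1p), which the tests verify by solving $\pi Q = 0$.

Generators are rescaled so the expected *visible* substitution rate at
stationarity is 1 (toggleable); the clock rate then has units of expected
gains-plus-losses per cognate set per ka. Transition matrices come from the
eigendecomposition of the reversible generator (computed on the
$\pi$-symmetrized matrix, so eigenvalues are real); likelihoods use scaled
Felsenstein pruning over the 2- or 4-state space, implemented in C++ with
per-pattern rescaling triggered only near underflow. An ascertainment
correction for the unobservability of all-absent columns is implemented
(`ascertainment = TRUE`) but off by default; with ~16 classes per concept the
all-absent probability is small, and leaving it off matches the plain
binarized-likelihood convention.

## Tree prior, clocks and calibrations

Trees are rooted, bifurcating, and dated in ka before present; extinct
(historically attested) languages sit at fixed positive tip ages. The tree
prior is a constant-rate fossilized birth–death (FBD) process: birth rate
$\lambda$, death rate $\mu$, through-time sampling rate $\psi$ (a sampled
lineage is recorded as an extinct tip and removed), and extant sampling
probability $\rho$ with a Uniform[0, 1] prior.

We condition on the root age: the density is that of the sampled labeled
tree given the root, whose support is trees with at least one sampled
descendant on each side of the root. With
$c_1 = |\sqrt{(\lambda-\mu-\psi)^2 + 4\lambda\psi}|$,
$c_2 = -(\lambda-\mu-2\lambda\rho-\psi)/c_1$ and
$q(t) = 4e^{-c_1 t}\big(e^{-c_1 t}(1-c_2) + (1+c_2)\big)^{-2}$,
each branch from parent age $s$ to child age $t$ contributes $q(s)/q(t)$,
each non-root internal node a factor $\lambda$, each extant sampled tip
$\rho$, and each extinct tip at age $y$ a factor $\psi/q(y)$. No additional
division by a survival probability is applied. This choice is not cosmetic:
it is the unique conditioning under which (i) the pure-birth limit
($\mu=\psi=0$, $\rho=1$) collapses to the textbook Yule density
$\lambda^{n-2}e^{-\lambda L}$ ($L$ the total branch duration), and (ii)
prior-only MCMC on a fixed number of tips agrees distribution-for-
distribution with forward simulation of the same process conditioned on that
tip count — the package's strongest sampler test. Because the density is
conditional on the root age, a separate root-age prior may be supplied
(`root_age_max` gives a proper uniform); by default the root age is
improper-flat and the data plus calibrations must inform it.

Clocks are either strict or uncorrelated lognormal ("relaxed"): iid branch
multipliers with real-space mean $\mu_r = 1.0$ and log-sd $\sigma = 0.1$
(so `meanlog` $= \log\mu_r - \sigma^2/2$); the expected substitutions on a
branch are duration × multiplier × clock rate.

Calibrations are hard bounds, matching the "earlier than" character of
historical records: extinct tips are pinned to their last-seen dates, and a
clade calibration forces the MRCA of a taxon set to be at least as old as
the record. Soft calibration densities are deliberately out of scope. The
actual calibration values for any real dataset are user-supplied through the
YAML run configuration; the package does not hard-code any.

Default hyperpriors where nothing else is stated: exponential with mean 10
on the gain and loss rates, exponential with mean 1 on the covarion switch
rates, gamma shape, clock rate, $\lambda$, $\mu$ and $\psi$. Rates fixed at
the $\mu = 0$ or $\psi = 0$ boundary are treated as constants rather than
sampled parameters.

## MCMC

The sampler is plain Metropolis–Hastings over the joint state (topology,
node ages, substitution, clock and FBD parameters, branch-rate multipliers).
The operator suite: interior node-age resampling between parent and
children (symmetric), a windowed node-age slide, a root-age scaler,
narrow exchange, a Wilson–Balding prune-and-regraft, multiplicative scalers
for every positive scalar, a reflected random walk for $\rho$, and
single-branch multiplier scalers. Scale moves draw the factor $f$
log-uniformly on $[1/\kappa, \kappa]$ with $\kappa = 1.5$ fixed (no
auto-tuning, for reproducibility) and log Hastings ratio $\log f$; the
Wilson–Balding ratio is the log ratio of new to old reattachment-age
ranges.

Two deliberate simplifications: the "subtree slide" does not cross nodes
(it is a windowed age shift; regrafting topology changes are delegated to
narrow exchange and Wilson–Balding), and Wilson–Balding never prunes a
child of the root, so it cannot re-root — the root split still mixes via
narrow exchange across the root. Both are documented because they change
the operator mix, not the stationary distribution; the forward-simulation
agreement test is the evidence that the implemented mix targets the correct
prior. Default operator weights are 30% topology, 30% node ages, 20%
clock/branch rates, 20% remaining scalars, with inapplicable moves (e.g.
switch-rate scalers under `m1p`) dropped automatically.

Proposals that violate a calibration or constraint are vetoed by the prior
($-\infty$), not silently repaired. Chains are deterministic given a seed;
multiple chains offset the seed by the chain index. Burn-in is discarded
during the run. Convergence reporting uses an in-package ESS
($n / (1 + 2\sum \hat\rho_k)$, truncated at the first non-positive
autocorrelation; constant traces return $n$ flagged `constant`, antithetic
traces are flagged rather than reported above $n$) and a between/within
variance ratio $\hat R = \sqrt{(W + B)/W}$ with $B$ the variance of chain
means — exactly 1 for coinciding chains, flagged above 1.05.

## Marginal likelihoods

Model comparison uses stepping-stone sampling: power posteriors
$\pi(\theta)L(\theta)^{\beta_k}$ along $\beta_k = $ Beta(0.3, 1) quantiles
(endpoints exactly 0 and 1; the shape concentrates steps near the prior,
where the integrand varies fastest), each step warm-started from the last
and discarding 10% burn-in, with the estimator
$\log Z = \sum_k \log \frac1n \sum_i L_i^{\beta_{k+1}-\beta_k}$ computed by
log-sum-exp. The reported standard error combines per-step delta-method
variances with ESS-adjusted sample sizes; it is a within-run error estimate,
not a replication SE. Bayes factors are always reported on the natural-log
scale as $\log Z_1 - \log Z_2$ — published Bayes-factor values whose scale
is ambiguous should be compared against `log_bf` directly.

## Posterior summarization

Clade supports are posterior frequencies of tip subsets (bitset keys over
the sorted taxon ordering; output ordered by frequency then name, so it is
invariant to tree order). The outgroup question is answered by root-split
support: the fraction of sampled trees in which a taxon set forms one child
of the root. The maximum clade credibility tree is the *sampled* tree
maximizing the sum of log clade frequencies (ties: first in sample order);
its nodes are annotated with clade posteriors and the mean, median and 95%
HPD of the clade's MRCA age across trees containing it. Mean heights are
the primary annotation (median alongside); common-ancestor heights are not
implemented. HPD intervals are the shortest window containing
$\lceil 0.95 n \rceil$ sorted samples, ties resolved toward the smaller
lower bound — on the integers 1..100 this gives exactly (1, 95).

## The synthetic-data generator

Because the real lexical database cannot be redistributed, the generator is
first-class, tested code that emulates the *structure* of a curated
basic-vocabulary collection: an FBD language tree with extinct tips,
lognormal branch-rate variation, per-concept cognate classes, flagged
loans, synonyms and missing entries. Cognate classes within a concept arise
as one ancestral class plus replacement innovations along branches (a
Poisson process at `innovation_rate` per ka, scaled by the branch
multiplier); a class column in the binarization is therefore the footprint
of a lexical replacement history, while the covarion character simulator
(`simulate_covarion_characters`) provides exact model-matched data for
parameter-recovery tests.

Defaults are fixed at the emulation target of the motivating use case —
about 131 languages (sampled-tip window 127–135 under
$\lambda=0.85, \mu=0.2, \psi=0.05, \rho=0.55$ from a root at 8 ka), 110
concepts, loan rate 0.02, synonym rate 0.05, missing rate 0.05 — and
`innovation_rate = 0.07`, calibrated once so the expected number of binary
cognate sets is about 1.7 thousand (roughly 16 classes per concept).
Per-seed counts vary by roughly ±250 columns because total tree length
varies; tests therefore pin the mean over seeds, not each seed.

What passing these tests shows — and does not show. The generator matches
the model family, so recovery tests validate the inference machinery
(likelihood, priors, sampler, summarization), not the model's adequacy for
real lexical data: real cognacy judgments carry correlated borrowing,
undetected loans, dialect chains and coder idiosyncrasies that the
generator deliberately omits (no geographic or wave-model borrowing).
Note also that the generator's binarized class columns are *not*
covarion-distributed — a class arises once and its columns are mutually
exclusive within a concept — so inference on generator output probes
robustness under model misfit (in our runs, node ages shrink somewhat
toward the present), while inference on `simulate_covarion_characters`
output probes correctness under the fitted model; the calibration tests use
the latter.

## Problem sizes and numerical choices

The shipped tests run at desk scale, chosen as the smallest sizes at which
each property is informative: enumeration oracles on 4-taxon trees (the
4³-term sum is exact), sampler calibration on 5 extant tips with 2000
samples against 2000 forward simulations (two-sample KS), stepping-stone on
a conjugate binomial–Beta toy (30 steps × 5000 samples against the closed
form), and simulation-based calibration with 20 replicates of 10 tips
(2 extinct), 300 covarion columns and 100k-iteration chains, requiring the
95% root-age HPD to cover the truth in at least 15 of 20 — the binomial
tolerance around a nominal 95% rate. Degenerate inputs are pinned by tests:
zero-length branches (transition matrix = identity), all-missing patterns
(likelihood 1), constant traces (ESS = n, flagged), one-tree posteriors
(all supports 1, zero-width HPDs).

Matrix exponentials use the reversible eigendecomposition everywhere; the
independent test oracle uses dense `Matrix::expm` so the two routes never
share code. Pruning rescales per pattern only when the partial maximum
drops below 1e-120, keeping the log-space bookkeeping cheap; likelihoods of
impossible patterns return $-\infty$ and are rejected by the sampler.

## Known limitations

* No sampled-ancestor representation: $\psi$-sampled lineages terminate.
* No soft calibrations, no coalescent/skyline priors, no Mk multistate
  likelihood, no pseudo-Dollo models.
* Single-threaded; desk-scale problems run in seconds to minutes, but the
  sampler is not tuned for hundreds of taxa at publication-length chains.
* The relaxed clock assigns iid multipliers to branches keyed by node id;
  after topology moves a multiplier follows its child node, which is the
  usual convention but one of several possible.
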