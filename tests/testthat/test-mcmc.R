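make_toy_state <- function(ntip = 5, kind = "m1p", clock = "strict") {
  td <- stats::setNames(rep(0, ntip), paste0("L", seq_len(ntip)))
  tt <- init_time_tree(td, root_age = 2)
  model <- if (kind == "m1p") subst_model("m1p", 1, 1) else
    subst_model("m1p+CV", 1, 1, s_on = 0.5, s_off = 0.5)
  ck <- if (clock == "strict") clock_model("strict", rate = 0.5) else
    clock_model("relaxed-lognormal", rate = 0.5)
  model_state(tt, model, ck, fbd_params(0.8, 0.1, 0, 0.9))
}

test_that("proposals keep trees valid and report exact Hastings ratios", {
  set.seed(1)
  st <- make_toy_state(6)
  for (mv in c("node_age_slide", "subtree_slide", "root_scaler",
               "narrow_exchange", "wilson_balding", "scale_gain",
               "scale_lambda", "rho_walk")) {
    for (i in 1:50) {
      pr <- propose(st, mv)
      if (!pr$valid) next
      expect_silent(glottochron:::validate_timetree(pr$state$tree))
      if (mv %in% c("node_age_slide", "subtree_slide", "narrow_exchange",
                    "rho_walk")) {
        expect_identical(pr$log_hr, 0)
      }
    }
  }
  expect_error(propose(st, "no_such_move"), "unknown move")
})

test_that("narrow exchange swaps a child with its uncle, preserving ages", {
  set.seed(2)
  st <- make_toy_state(5)
  ages <- st$tree$ages
  for (i in 1:30) {
    pr <- propose(st, "narrow_exchange")
    if (!pr$valid) next
    expect_equal(pr$state$tree$ages, ages)   # topology move: ages unchanged
    expect_false(identical(pr$state$tree$parent, st$tree$parent))
  }
})

test_that("scale moves target their stationary distribution exactly", {
  # with only the gain-rate scaler active (a parameter the tree prior does
  # not touch), prior-only MCMC must reproduce the Exp(mean 10) prior: a
  # direct check of the log-f Hastings ratio
  st <- make_toy_state(3)
  spec <- prior_spec(root_age_max = 100)
  cfg <- mcmc_config(chain_length = 60000, burn_in = 5000, sample_every = 25,
                     seed = 3,
                     move_weights = c(node_age_slide = 0, subtree_slide = 0,
                                      root_scaler = 0, narrow_exchange = 0,
                                      wilson_balding = 0, scale_lambda = 0,
                                      scale_loss = 0, scale_clock_rate = 0,
                                      scale_mu = 0, rho_walk = 0,
                                      scale_gain = 10))
  out <- run_chain(NULL, st, spec, cfg)
  g <- out$trace$gain
  expect_gt(suppressWarnings(stats::ks.test(g, stats::pexp, 0.1))$p.value, 0.01)
})

test_that("chains are deterministic given a seed and count samples correctly", {
  st <- make_toy_state(4)
  spec <- prior_spec(root_age_max = 20)
  cfg <- mcmc_config(chain_length = 1000, burn_in = 200, sample_every = 8,
                     seed = 42)
  a <- run_chain(NULL, st, spec, cfg)
  b <- run_chain(NULL, st, spec, cfg)
  expect_identical(a$trace, b$trace)
  expect_equal(nrow(a$trace), 100)
  expect_equal(length(a$trees), 100)
  expect_error(mcmc_config(1000, burn_in = 1000), "burn_in")
  expect_error(mcmc_config(1000, burn_in = 100, sample_every = 7), "divide")
})

test_that("initial states violating the prior are refused", {
  st <- make_toy_state(4)
  spec <- prior_spec(constraints = list(
    monophyly_constraint(c("L1", "L3"))))
  cfg <- mcmc_config(chain_length = 100, sample_every = 1, seed = 1)
  if (!constraint_satisfied(st$tree, spec$constraints[[1]])) {
    expect_error(run_chain(NULL, st, spec, cfg), "violates")
  }
  # and hard calibrations are never violated in the sample
  cal <- calibration("mrca_min_age", c("L1", "L2"), 0.4)
  spec2 <- prior_spec(root_age_max = 10, calibrations = list(cal))
  st2 <- make_toy_state(4)
  out <- run_chain(NULL, st2, spec2,
                   mcmc_config(chain_length = 20000, burn_in = 0,
                               sample_every = 20, seed = 5))
  ok <- vapply(out$trees, function(tt) {
    tt$ages[tt_mrca(tt, c("L1", "L2"))] >= 0.4
  }, logical(1))
  expect_true(all(ok))
})

test_that("posterior means agree with the likelihood surface on toy data", {
  # fixed 2-tip tree, strict clock: the gain/loss posterior should settle
  # near parameters that maximize the toy likelihood
  set.seed(9)
  tt <- time_tree(c(3L, 3L, NA), c(0, 0, 1), c("L1", "L2"))
  m <- subst_model("m1p", 1, 1)
  bm <- simulate_binary_matrix(tt, m, 400, clock_rate = 1)
  st <- model_state(tt, m, clock_model("strict", 1), fbd_params(1))
  cfg <- mcmc_config(chain_length = 30000, burn_in = 5000, sample_every = 25,
                     seed = 2,
                     move_weights = c(node_age_slide = 0, subtree_slide = 0,
                                      narrow_exchange = 0, wilson_balding = 0,
                                      root_scaler = 0, scale_lambda = 0,
                                      scale_mu = 0, rho_walk = 0,
                                      scale_clock_rate = 0))
  out <- run_chain(compress_patterns(bm), st, prior_spec(), cfg)
  # reference: long independent chain with a different seed
  cfg2 <- mcmc_config(chain_length = 60000, burn_in = 10000,
                      sample_every = 25, seed = 77, move_weights =
                        cfg$move_weights)
  ref <- run_chain(compress_patterns(bm), st, prior_spec(), cfg2)
  mcse <- stats::sd(ref$trace$gain) /
    sqrt(as.numeric(effective_sample_size(ref$trace$gain)))
  expect_lt(abs(mean(out$trace$gain) - mean(ref$trace$gain)),
            3 * mcse + 6 * stats::sd(ref$trace$gain) /
              sqrt(as.numeric(effective_sample_size(out$trace$gain))))
})

test_that("effective sample size follows its oracles", {
  set.seed(31)
  iid <- stats::rnorm(1000)
  expect_gt(effective_sample_size(iid), 700)
  expect_lt(effective_sample_size(iid), 1300)
  # AR(1), coefficient 0.9: ESS ~ n (1 - phi) / (1 + phi)
  n <- 5000
  ar <- as.numeric(stats::arima.sim(list(ar = 0.9), n))
  want <- n * 0.1 / 1.9
  got <- as.numeric(effective_sample_size(ar))
  expect_lt(abs(got - want) / want, 0.3)
  # constant series: n by convention, flagged
  cst <- effective_sample_size(rep(2, 50))
  expect_equal(as.numeric(cst), 50)
  expect_true(attr(cst, "constant"))
  # alternating series: antithetic flag (ESS beyond n regime)
  alt <- effective_sample_size(rep(c(1, -1), 50))
  expect_true(isTRUE(attr(alt, "antithetic")))
  expect_error(effective_sample_size(1:5), "at least 10")
})

test_that("multichain diagnostics flag disagreement and list every scalar", {
  st <- make_toy_state(4)
  spec <- prior_spec(root_age_max = 20)
  cfg <- mcmc_config(chain_length = 2000, burn_in = 0, sample_every = 10,
                     seed = 1, n_chains = 2)
  chains <- run_chains(NULL, st, spec, cfg)
  d <- multichain_diagnostics(chains)
  expect_true(all(c("posterior", "likelihood", "prior", "gain", "loss",
                    "clock_rate", "lambda", "mu", "rho", "root_age",
                    "tree_length") %in% d$parameter))
  # two identical chains: rhat exactly 1
  d2 <- multichain_diagnostics(list(chains[[1]], chains[[1]]))
  expect_true(all(d2$rhat == 1))
  # chains from offset distributions: rhat must blow past 1.5
  fake <- function(mu) {
    f <- chains[[1]]
    f$trace$gain <- stats::rnorm(nrow(f$trace), mu, 1)
    f
  }
  set.seed(4)
  d3 <- multichain_diagnostics(list(fake(0), fake(5)))
  expect_gt(d3$rhat[d3$parameter == "gain"], 1.5)
  expect_true(d3$flagged[d3$parameter == "gain"])
  expect_error(multichain_diagnostics(chains[1]), "at least 2")
})

test_that("trace and trees artifacts round-trip", {
  st <- make_toy_state(4)
  out <- run_chain(NULL, st, prior_spec(root_age_max = 20),
                   mcmc_config(chain_length = 500, burn_in = 100,
                               sample_every = 20, seed = 6))
  tr_path <- withr::local_tempfile(fileext = ".tsv")
  write_trace(out, tr_path)
  tr <- readr::read_tsv(tr_path, show_col_types = FALSE)
  expect_equal(names(tr)[1], "Sample")
  expect_equal(nrow(tr), nrow(out$trace))
  nx_path <- withr::local_tempfile(fileext = ".nex")
  write_trees_nexus(out, nx_path)
  back <- read_trees(nx_path)
  expect_equal(length(back), length(out$trees))
  expect_setequal(back[[1]]$tip_labels, st$tree$tip_labels)
})
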