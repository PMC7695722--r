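test_that("FBD density reduces to the Yule closed form", {
  # mu = psi = 0, rho = 1: log f = (n-2) log lambda - lambda * tree length
  p <- fbd_params(lambda = 0.7)
  tt <- toy_tree4()
  expect_equal(fbd_log_density(tt, p), 2 * log(0.7) - 0.7 * 6.5,
               tolerance = 1e-12)
  set.seed(11)
  for (i in 1:5) {
    tt <- random_dated_tree(6)
    L <- sum(glottochron:::tt_durations(tt), na.rm = TRUE)
    expect_equal(fbd_log_density(tt, p), 4 * log(0.7) - 0.7 * L,
                 tolerance = 1e-10)
  }
})

test_that("FBD density guards its support", {
  expect_error(fbd_params(lambda = 0), "positive")
  tt <- time_tree(c(5L, 5L, 4L, NA, 4L), c(0, 0, 0.5, 2, 1.2),
                  c("A", "B", "C"))
  expect_warning(
    out <- fbd_log_density(tt, fbd_params(lambda = 1, mu = 0.1, psi = 0)),
    "psi")
  expect_identical(out, -Inf)
  # psi > 0 gives a finite density for the same tree
  expect_true(is.finite(
    fbd_log_density(tt, fbd_params(lambda = 1, mu = 0.1, psi = 0.2))))
})

test_that("simulated FBD trees always have finite density", {
  set.seed(5)
  p <- fbd_params(lambda = 0.6, mu = 0.2, psi = 0.15, rho = 0.7)
  for (i in 1:20) {
    tt <- simulate_fbd_tree(p, root_age = 4, min_tips = 3, max_tips = 60)
    expect_true(is.finite(fbd_log_density(tt, p)))
  }
})

test_that("clock branch lengths multiply duration, rate and multiplier", {
  tt <- toy_tree4()
  strict <- clock_model("strict", rate = 0.1)
  len <- clock_branch_lengths(tt, strict)
  expect_equal(len[1], 0.1 * 1)        # tip A: duration 1 ka
  expect_equal(len[4], 0.1 * 1.5)      # tip D
  expect_true(is.na(len[tt$root]))
  # relaxed with sigma -> 0 equals strict
  r0 <- simulate_branch_rates(tt, mu = 1, sigma = 0)
  relaxed <- clock_model("relaxed-lognormal", rate = 0.1, sigma = 0)
  expect_equal(clock_branch_lengths(tt, relaxed, r0)[-tt$root], len[-tt$root])
  expect_error(clock_branch_lengths(tt, clock_model("relaxed-lognormal", 0.1)),
               "multipliers")
})

test_that("branch-rate prior matches the lognormal closed form", {
  clock <- clock_model("relaxed-lognormal", rate = 1, mu = 1, sigma = 0.1)
  meanlog <- -0.1^2 / 2
  x <- c(0.9, 1, 1.15)
  expect_equal(branch_rate_log_prior(clock, x),
               sum(stats::dlnorm(x, meanlog, 0.1, log = TRUE)))
  # mode of the lognormal: each term equals the mode density
  mode <- exp(meanlog - 0.1^2)
  expect_equal(branch_rate_log_prior(clock, rep(mode, 3)),
               3 * stats::dlnorm(mode, meanlog, 0.1, log = TRUE))
  expect_identical(branch_rate_log_prior(clock, c(1, -0.2)), -Inf)
  expect_identical(branch_rate_log_prior(clock_model("strict", 1), c(1, 1)), 0)
  # doubling sigma changes the density per the closed form
  clock2 <- clock_model("relaxed-lognormal", rate = 1, mu = 1, sigma = 0.2)
  expect_equal(branch_rate_log_prior(clock2, x),
               sum(stats::dlnorm(x, -0.02, 0.2, log = TRUE)))
})

test_that("sampled branch-rate multipliers have real-space mean mu", {
  set.seed(2)
  tt <- random_dated_tree(4)
  big <- replicate(6000, simulate_branch_rates(tt, mu = 1, sigma = 0.1)[-tt$root])
  expect_equal(mean(big), 1, tolerance = 0.01)
  expect_gt(stats::shapiro.test(sample(log(big), 4000))$p.value, 0.01)
  expect_equal(unique(as.vector(
    simulate_branch_rates(tt, mu = 2, sigma = 0)[-tt$root])), 2)
  expect_error(simulate_branch_rates(tt, 1, -1), "sigma")
})

test_that("calibrations act as hard indicator priors", {
  tt <- toy_tree4()
  expect_equal(calibration_log_prior(
    tt, list(calibration("mrca_min_age", c("A", "B"), 0.5))), 0)
  expect_identical(calibration_log_prior(
    tt, list(calibration("mrca_min_age", c("A", "B"), 1.5))), -Inf)
  expect_equal(calibration_log_prior(
    tt, list(calibration("tip_date", "A", 0))), 0)
  expect_identical(calibration_log_prior(
    tt, list(calibration("tip_date", "A", 0.3))), -Inf)
  expect_error(calibration_log_prior(
    tt, list(calibration("tip_date", "Z", 0))), "unknown")
  expect_error(calibration("tip_date", c("A", "B"), 1), "one taxon")
  expect_error(calibration("mrca_min_age", "A", 1), "2 taxa")
})

test_that("monophyly and outgroup tests agree with set-based brute force", {
  tt <- toy_tree4()   # ((A,B),(C,D))
  expect_true(constraint_satisfied(tt, monophyly_constraint(c("A", "B"),
                                                            as_outgroup = TRUE)))
  expect_false(constraint_satisfied(tt, monophyly_constraint(c("A", "C"))))
  # exhaustive: all 15 labeled rooted 4-tip topologies vs brute force
  set.seed(8)
  seen <- character(0)
  while (length(seen) < 15) {
    tt <- random_dated_tree(4)
    key <- paste(sort(glottochron:::tt_clade_keys(tt)), collapse = "|")
    seen <- union(seen, key)
    sets <- glottochron:::tt_tipsets(tt)
    for (taxa in list(c("t1", "t2"), c("t1", "t3"), c("t2", "t3", "t4"))) {
      ids <- sort(match(taxa, tt$tip_labels))
      brute <- any(vapply(sets, function(s) identical(s, ids), logical(1)))
      expect_equal(constraint_satisfied(tt, monophyly_constraint(taxa)), brute)
    }
  }
})

test_that("joint prior adds its components and vetoes violations", {
  tt <- toy_tree4()
  fbd <- fbd_params(lambda = 0.7)
  spec <- prior_spec()
  st <- model_state(tt, subst_model("m1p", gain = 10, loss = 2),
                    clock_model("strict", rate = 0.5), fbd)
  lp <- joint_log_prior(st, spec)
  # a = 10 under Exp(mean 10) contributes log(1/10) - 1
  expect_equal(lp, fbd_log_density(tt, fbd) +
                 (log(1 / 10) - 1) + (log(1 / 10) - 0.2) +
                 (-0.5) + (-0.7), tolerance = 1e-12)
  spec2 <- prior_spec(constraints = list(monophyly_constraint(c("A", "C"))))
  expect_identical(joint_log_prior(st, spec2), -Inf)
})
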