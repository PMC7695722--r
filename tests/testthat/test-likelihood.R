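test_that("covarion pruning equals brute-force enumeration on the toy tree", {
  tt <- toy_tree4()
  m <- subst_model("m1p+CV", 1.2, 0.7, s_on = 0.4, s_off = 0.6,
                   normalize = FALSE)
  Q <- covarion_generator(1.2, 0.7, 0.4, 0.6)
  pi <- unname(stationary_distribution(m))
  for (pat in list(c(1, 0, 1, NA), c(0, 0, 0, 0), c(1, 1, 1, 1),
                   c(NA, 1, 0, 1))) {
    expect_equal(site_log_likelihood(tt, m, pat),
                 brute_site_loglik(tt, Q, pi, pat), tolerance = 1e-10)
  }
})

test_that("degenerate limits: zero-length tree and all-missing patterns", {
  # two tips joined at age ~0: likelihood of identical states is the
  # stationary probability of that state
  eps <- 1e-12
  tt <- time_tree(c(3L, 3L, NA), c(0, 0, eps), c("A", "B"))
  m <- subst_model("m1p", 3, 1, normalize = FALSE)
  expect_equal(site_log_likelihood(tt, m, c(1, 1)), log(0.75),
               tolerance = 1e-6)
  expect_equal(site_log_likelihood(tt, m, c(0, 0)), log(0.25),
               tolerance = 1e-6)
  # all-? pattern has likelihood 1
  expect_equal(site_log_likelihood(toy_tree4(), m, c(NA, NA, NA, NA)), 0)
})

test_that("covarion likelihood collapses to m1p when switching off is rare", {
  # s_off -> 0 concentrates the stationary law on the on block, where the
  # process is plain m1p
  set.seed(41)
  m1 <- subst_model("m1p", 1.4, 0.6, normalize = FALSE)
  cv <- subst_model("m1p+CV", 1.4, 0.6, s_on = 5, s_off = 1e-9,
                    normalize = FALSE)
  for (i in 1:5) {
    tt <- random_dated_tree(4)
    pat <- sample(c(0, 1), 4, replace = TRUE)
    expect_equal(site_log_likelihood(tt, cv, pat),
                 site_log_likelihood(tt, m1, pat), tolerance = 1e-6)
  }
})

test_that("weighted pattern likelihood equals the uncompressed sum", {
  set.seed(99)
  tt <- random_dated_tree(6)
  m <- subst_model("m1p+CV", 1, 0.8, s_on = 0.5, s_off = 0.5)
  vals <- matrix(sample(c(0L, 1L, NA), 6 * 40, replace = TRUE,
                        prob = c(0.45, 0.45, 0.1)), nrow = 6,
                 dimnames = list(tt$tip_labels, NULL))
  # ensure every column has at least one presence
  vals[1, ] <- 1L
  bm <- binary_matrix(vals, tibble::tibble(
    concept = sprintf("c%02d", 1:40), cognate_class = "1"))
  sp <- compress_patterns(bm)
  expect_lt(length(sp$weights), 40)
  full <- sum(vapply(seq_len(40), function(j) {
    site_log_likelihood(tt, m, vals[, j])
  }, numeric(1)))
  expect_equal(data_log_likelihood(tt, m, sp), full, tolerance = 1e-8)
  # one pattern with weight w contributes w times its site value
  one <- structure(list(patterns = sp$patterns[, 1, drop = FALSE],
                        weights = 3, n_sites = 3,
                        languages = sp$languages), class = "site_patterns")
  expect_equal(data_log_likelihood(tt, m, one),
               3 * site_log_likelihood(tt, m, sp$patterns[, 1]))
})

test_that("likelihood is invariant to tip order permutation", {
  set.seed(7)
  tt <- random_dated_tree(5)
  m <- subst_model("m1p+CV", 0.9, 1.1, s_on = 0.4, s_off = 0.8)
  pat <- c(t1 = 1, t2 = 0, t3 = 1, t4 = NA, t5 = 0)
  perm <- sample(5)
  expect_equal(site_log_likelihood(tt, m, pat),
               site_log_likelihood(tt, m, pat[perm]))
})

test_that("gamma heterogeneity converges monotonically to the plain model", {
  set.seed(13)
  tt <- random_dated_tree(5)
  base <- subst_model("m1p", 1.2, 0.9)
  pat <- c(1, 0, 1, 1, 0)
  ll0 <- site_log_likelihood(tt, base, pat)
  alphas <- c(1, 10, 100, 1e4, 1e6)
  diffs <- vapply(alphas, function(a) {
    abs(site_log_likelihood(tt, subst_model("m1p+G4", 1.2, 0.9, alpha = a),
                            pat) - ll0)
  }, numeric(1))
  expect_true(all(diff(diffs) < 0))
  expect_lt(diffs[length(diffs)], 1e-5)
})

test_that("higher likelihood at true parameters than at perturbed ones", {
  # likelihood-consistency: on simulated alignments the per-site mean
  # log-likelihood at the generating parameters beats a 2x gain rate, on
  # average over replicates
  set.seed(71)
  true_m <- subst_model("m1p+CV", 1, 1, s_on = 0.5, s_off = 0.5)
  pert_m <- subst_model("m1p+CV", 2, 1, s_on = 0.5, s_off = 0.5)
  diffs <- replicate(20, {
    tt <- random_dated_tree(6, max_age = 6)
    bm <- simulate_binary_matrix(tt, true_m, 500, clock_rate = 0.3)
    sp <- compress_patterns(bm)
    (data_log_likelihood(tt, true_m, sp, clock_rate = 0.3) -
        data_log_likelihood(tt, pert_m, sp, clock_rate = 0.3)) / 500
  })
  expect_gt(mean(diffs), 0)
})

test_that("ascertainment correction subtracts the all-absent probability", {
  tt <- toy_tree4()
  m <- subst_model("m1p", 1, 1, ascertainment = TRUE)
  m0 <- subst_model("m1p", 1, 1)
  vals <- matrix(c(1L, 0L, 1L, 0L), 4, 1, dimnames = list(tt$tip_labels, NULL))
  bm <- binary_matrix(vals, tibble::tibble(concept = "c", cognate_class = "1"))
  ll0 <- data_log_likelihood(tt, m0, bm)
  p_absent <- exp(site_log_likelihood(tt, m0, c(0, 0, 0, 0)))
  expect_equal(data_log_likelihood(tt, m, bm), ll0 - log(1 - p_absent),
               tolerance = 1e-10)
})

test_that("mismatched tips raise errors", {
  tt <- toy_tree4()
  m <- subst_model("m1p", 1, 1)
  expect_error(site_log_likelihood(tt, m, c(1, 0)), "length")
  expect_error(site_log_likelihood(tt, m, c(X = 1, Y = 0, Z = 1, W = 0)),
               "names")
})
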