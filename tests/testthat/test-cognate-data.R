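test_that("CSV cognate tables read back with loans, flags and tip dates", {
  path <- withr::local_tempfile(fileext = ".csv")
  toy_cognate_csv(path)
  ds <- read_cognate_table(path, tip_dates = c(L4 = 1.2))
  expect_s3_class(ds, "cognate_dataset")
  expect_setequal(ds$languages, paste0("L", 1:4))
  expect_equal(ds$concepts, c("hand", "sun"))
  expect_equal(sum(ds$entries$is_loan), 1L)
  expect_equal(ds$tip_dates$age_ka[ds$tip_dates$language == "L4"], 1.2)
  expect_equal(ds$tip_dates$age_ka[ds$tip_dates$language == "L1"], 0)
})

test_that("empty or malformed files raise parse errors", {
  empty <- withr::local_tempfile(fileext = ".csv")
  writeLines("language,concept,cognate_class,is_loan", empty)
  expect_error(read_cognate_table(empty), "parse error")
  expect_error(read_cognate_table(tempfile()), "no such file")
  dup <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("language,concept,cognate_class,is_loan",
               "L1,hand,A,FALSE", "L1,hand,A,FALSE"), dup)
  expect_error(read_cognate_table(dup), "duplicate")
})

test_that("simulated datasets survive a CSV round trip", {
  cfg <- sim_config(fbd = fbd_params(0.4, 0.05, 0.05, 0.9), root_age = 4,
                    n_concepts = 12L, min_tips = 5L, max_tips = 12L, seed = 21L)
  sim <- make_cognate_dataset(cfg)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cognate_csv(sim$dataset, path)
  td <- stats::setNames(sim$dataset$tip_dates$age_ka,
                        sim$dataset$tip_dates$language)
  back <- read_cognate_table(path, tip_dates = td[td > 0])
  expect_equal(back$entries, sim$dataset$entries)
  expect_setequal(back$languages, sim$dataset$languages)
  expect_equal(
    back$tip_dates[order(back$tip_dates$language), ],
    sim$dataset$tip_dates[order(sim$dataset$tip_dates$language), ])
})

test_that("exclude_taxa drops languages, records them and rejects typos", {
  ds <- toy_binarization_dataset()
  out <- exclude_taxa(ds, c("L1", "L5"))
  expect_setequal(out$languages, c("L2", "L3", "L4"))
  expect_equal(out$excluded_taxa, c("L1", "L5"))
  expect_equal(exclude_taxa(ds, character(0)), ds)
  expect_error(exclude_taxa(ds, "nope"), "unknown")
  expect_error(exclude_taxa(ds, c("L1", "L1")), "duplicate")
})

test_that("remove_loans deletes flagged classes and is idempotent", {
  ds <- cognate_dataset(tibble::tibble(
    language = c("L1", "L1", "L2"),
    concept = "hand",
    cognate_class = c("A", "B", "A"),
    is_loan = c(TRUE, FALSE, TRUE)
  ), languages = c("L1", "L2"))
  out <- remove_loans(ds)
  # L1 keeps B; L2's only label was a loan -> missing datum
  expect_equal(out$entries$language, "L1")
  expect_equal(out$entries$cognate_class, "B")
  expect_equal(remove_loans(out), out)
  bm <- multistate_to_binary(ds)
  expect_true(all(is.na(bm$values["L2", ])))
  # a dataset with no flags is unchanged
  clean <- toy_binarization_dataset()
  expect_equal(remove_loans(clean), clean)
})

test_that("binarization matches the worked single-concept example", {
  bm <- multistate_to_binary(toy_binarization_dataset())
  expect_equal(bm$n_cognate_sets, 2L)
  expect_equal(bm$columns$cognate_class, c("A", "B"))
  expect_equal(unname(bm$values[, 1]), c(1L, 1L, 0L, 1L, NA))
  expect_equal(unname(bm$values[, 2]), c(0L, 0L, 1L, 1L, NA))
  # all languages sharing one class -> single column of ones
  ds1 <- cognate_dataset(tibble::tibble(
    language = paste0("L", 1:4), concept = "sun",
    cognate_class = "A", is_loan = FALSE))
  bm1 <- multistate_to_binary(ds1)
  expect_equal(bm1$n_cognate_sets, 1L)
  expect_true(all(bm1$values == 1L))
  expect_error(multistate_to_binary(
    cognate_dataset(tibble::tibble(language = "L1", concept = "c",
                                   cognate_class = "A", is_loan = TRUE))),
    "empty")
})

test_that("binarization conserves the multistate assignment for loan-free data", {
  cfg <- sim_config(fbd = fbd_params(0.4, 0, 0, 1), root_age = 4,
                    n_concepts = 10L, loan_rate = 0, synonym_rate = 0.1,
                    missing_rate = 0.1, min_tips = 6L, max_tips = 12L,
                    seed = 33L)
  ds <- make_cognate_dataset(cfg)$dataset
  bm <- multistate_to_binary(ds)
  # per language and concept, the 1-columns recover the class set
  for (lang in ds$languages) {
    got <- bm$columns[which(bm$values[lang, ] == 1L), ]
    got <- got[order(got$concept, got$cognate_class), ]
    want <- ds$entries[ds$entries$language == lang, c("concept", "cognate_class")]
    want <- want[order(want$concept, want$cognate_class), ]
    expect_equal(got$concept, want$concept)
    expect_equal(got$cognate_class, want$cognate_class)
  }
  # column count invariant under language reordering
  ds2 <- ds
  perm <- rev(ds$languages)
  ds2 <- cognate_dataset(ds$entries[order(match(ds$entries$language, perm)), ],
                         languages = perm, concepts = ds$concepts,
                         tip_dates = ds$tip_dates)
  expect_equal(multistate_to_binary(ds2)$n_cognate_sets, bm$n_cognate_sets)
})

test_that("pattern compression conserves weights and uniqueness", {
  v <- matrix(c(1L, 0L, 1L, 0L,
                1L, 0L, 1L, 0L,
                0L, 1L, NA, 1L), nrow = 4,
              dimnames = list(paste0("L", 1:4), NULL))
  bm <- binary_matrix(v, tibble::tibble(concept = c("a", "a", "b"),
                                        cognate_class = c("1", "2", "1")))
  sp <- compress_patterns(bm)
  expect_equal(length(sp$weights), 2L)
  expect_equal(sum(sp$weights), bm$n_cognate_sets)
  expect_equal(sp$weights, c(2, 1))
  # all-distinct columns keep weight 1
  v2 <- matrix(c(1L, 0L, 0L, 1L), 2, dimnames = list(c("L1", "L2"), NULL))
  bm2 <- binary_matrix(v2, tibble::tibble(concept = c("a", "b"),
                                          cognate_class = "1"))
  expect_equal(compress_patterns(bm2)$weights, c(1, 1))
})

test_that("binary NEXUS round-trips values including missing cells", {
  v <- matrix(c(1L, 0L, NA, 0L, 1L, 1L), nrow = 3,
              dimnames = list(c("La", "Lb", "Lc"), NULL))
  bm <- binary_matrix(v, tibble::tibble(concept = c("a", "b"),
                                        cognate_class = c("1", "1")))
  path <- withr::local_tempfile(fileext = ".nex")
  write_binary_nexus(bm, path)
  back <- read_binary_nexus(path)
  expect_equal(unname(back$values), unname(v))
  expect_equal(back$languages, bm$languages)
})

test_that("a large simulated matrix parses in an external NEXUS reader", {
  cfg <- sim_config(fbd = fbd_params(0.5, 0.05, 0.05, 0.8), root_age = 5,
                    n_concepts = 20L, min_tips = 10L, max_tips = 30L,
                    seed = 7L)
  bm <- multistate_to_binary(make_cognate_dataset(cfg)$dataset)
  path <- withr::local_tempfile(fileext = ".nex")
  write_binary_nexus(bm, path)
  nx <- ape::read.nexus.data(path)     # third-party parser
  expect_equal(length(nx), length(bm$languages))
  expect_equal(length(nx[[1]]), bm$n_cognate_sets)
})
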