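#' Read and validate a run configuration
#'
#' YAML schema for an end-to-end inference run. Top-level keys: `data`
#' (cognate CSV path), `data_format`, `exclude_taxa`, `tip_dates` (language
#' to ka BP), `model`, `clock`, `fbd`, `priors`, `calibrations`,
#' `constraints`, `mcmc`, `init_tree` (optional Newick path), `output_dir`,
#' `seed`. Unknown keys anywhere are rejected before any computation.
#'
#' @param path YAML file.
#' @return a validated config list of class `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  allowed <- c("data", "data_format", "exclude_taxa", "tip_dates", "model",
               "clock", "fbd", "priors", "calibrations", "constraints",
               "mcmc", "init_tree", "output_dir", "seed")
  check_keys(cfg, allowed, "top level")
  for (k in c("data", "mcmc", "output_dir")) {
    if (is.null(cfg[[k]])) stop("config is missing required key: ", k)
  }
  check_keys(cfg$model, c("kind", "gain", "loss", "s_on", "s_off", "alpha",
                          "k", "normalize", "ascertainment"), "model")
  check_keys(cfg$clock, c("kind", "rate", "mu", "sigma"), "clock")
  check_keys(cfg$fbd, c("lambda", "mu", "psi", "rho"), "fbd")
  check_keys(cfg$priors, c("mean_gain", "mean_loss", "mean_s_on",
                           "mean_s_off", "mean_alpha", "mean_clock_rate",
                           "mean_lambda", "mean_mu", "mean_psi",
                           "root_age_max"), "priors")
  check_keys(cfg$mcmc, c("chain_length", "burn_in", "sample_every",
                         "n_chains", "seed"), "mcmc")
  for (cal in cfg$calibrations) {
    check_keys(cal, c("type", "taxon", "taxa", "age_ka", "min_age_ka"),
               "calibration")
    if (!cal$type %in% c("tip_date", "mrca_min_age")) {
      stop("unknown calibration type: ", cal$type)
    }
  }
  for (con in cfg$constraints) check_keys(con, c("taxa", "outgroup"), "constraint")
  cfg$data_format <- cfg$data_format %||% "csv"
  cfg$seed <- cfg$seed %||% 1L
  structure(cfg, class = "run_config")
}

check_keys <- function(x, allowed, where) {
  if (is.null(x)) return(invisible(NULL))
  bad <- setdiff(names(x), allowed)
  if (length(bad)) {
    stop("unknown config key(s) in ", where, ": ", paste(bad, collapse = ", "))
  }
  invisible(NULL)
}

config_calibrations <- function(cfg) {
  lapply(cfg$calibrations, function(cal) {
    if (cal$type == "tip_date") {
      calibration("tip_date", cal$taxon, cal$age_ka)
    } else {
      calibration("mrca_min_age", unlist(cal$taxa), cal$min_age_ka)
    }
  })
}

config_constraints <- function(cfg) {
  lapply(cfg$constraints, function(con) {
    monophyly_constraint(unlist(con$taxa), isTRUE(con$outgroup))
  })
}

#' Build a valid starting tree for MCMC
#'
#' Deterministic sequential-join initializer: taxa under a monophyly
#' constraint are joined first so constraints hold; node ages stack above
#' the oldest descendant tip; MRCA minimum-age calibrations are enforced by
#' lifting the relevant nodes (and their ancestors).
#'
#' @param tip_dates named numeric vector of tip ages (ka BP).
#' @param constraints list of [monophyly_constraint()]s.
#' @param calibrations list of [calibration()]s.
#' @param root_age target root age; defaults to comfortably above every tip
#'   and calibration bound.
#' @return a [time_tree()].
#' @export
init_time_tree <- function(tip_dates, constraints = list(),
                           calibrations = list(), root_age = NULL) {
  labs <- names(tip_dates)
  ntip <- length(labs)
  if (ntip < 2) stop("need at least 2 tips")
  min_root <- max(c(tip_dates,
                    vapply(calibrations, function(cal) cal$age_ka, numeric(1))),
                  0)
  root_age <- root_age %||% (min_root * 1.5 + 2)
  if (root_age <= min_root) stop("root_age below a tip or calibration bound")
  parent <- rep(NA_integer_, 2L * ntip - 1L)
  ages <- c(unname(tip_dates), numeric(ntip - 1L))
  next_id <- ntip
  join <- function(a, b, age) {
    next_id <<- next_id + 1L
    parent[a] <<- next_id; parent[b] <<- next_id
    ages[next_id] <<- age
    next_id
  }
  # ladderize within groups: constrained sets first (largest last so an
  # outgroup constraint ends up as a root child)
  cons <- constraints[order(vapply(constraints, function(x) length(x$taxa),
                                   numeric(1)))]
  grouped <- character(0)
  roots <- integer(0)
  step <- (root_age - min_root) / (ntip + length(cons) + 1)
  build_group <- function(ids) {
    cur <- ids[1]
    for (i in ids[-1]) {
      age <- max(ages[cur], ages[i]) + step
      cur <- join(cur, i, age)
    }
    cur
  }
  for (con in cons) {
    ids <- match(setdiff(con$taxa, grouped), labs)
    if (!length(ids)) next
    roots <- c(roots, build_group(ids))
    grouped <- union(grouped, con$taxa)
  }
  rest <- match(setdiff(labs, grouped), labs)
  if (length(rest)) roots <- c(roots, build_group(rest))
  cur <- roots[length(roots)]
  for (r in rev(roots[-length(roots)])) {
    cur <- join(cur, r, max(ages[cur], ages[r]) + step)
  }
  ages[cur] <- root_age
  # enforce minimum MRCA ages, lifting ancestors as needed
  tt <- time_tree(parent, ages, labs)
  for (cal in calibrations) {
    if (cal$kind != "mrca_min_age") next
    nd <- tt_mrca(tt, cal$taxa)
    if (tt$ages[nd] < cal$age_ka) {
      tt$ages[nd] <- cal$age_ka + step
      while (!is.na(tt$parent[nd])) {
        pa <- tt$parent[nd]
        if (tt$ages[pa] <= tt$ages[nd]) tt$ages[pa] <- tt$ages[nd] + step
        nd <- pa
      }
    }
  }
  validate_timetree(tt)
  tt
}

config_model <- function(cfg) {
  m <- cfg$model %||% list()
  kind <- m[["kind"]] %||% "m1p+CV"
  # [[ indexing throughout: $ would partial-match (e.g. m$k against m$kind)
  subst_model(kind = kind,
              gain = m[["gain"]] %||% 1, loss = m[["loss"]] %||% 1,
              s_on = if (kind == "m1p+CV") m[["s_on"]] %||% 0.5,
              s_off = if (kind == "m1p+CV") m[["s_off"]] %||% 0.5,
              alpha = if (kind == "m1p+G4") m[["alpha"]] %||% 1,
              k = m[["k"]] %||% 4L,
              normalize = m[["normalize"]] %||% TRUE,
              ascertainment = m[["ascertainment"]] %||% FALSE)
}

config_clock <- function(cfg) {
  cl <- cfg$clock %||% list()
  clock_model(kind = cl$kind %||% "relaxed-lognormal",
              rate = cl$rate %||% 0.2,
              mu = cl$mu %||% 1.0, sigma = cl$sigma %||% 0.1)
}

config_fbd <- function(cfg) {
  f <- cfg$fbd %||% list()
  fbd_params(lambda = f$lambda %||% 0.25, mu = f$mu %||% 0.05,
             psi = f$psi %||% 0.05, rho = f$rho %||% 0.5)
}

config_priors <- function(cfg, calibrations, constraints) {
  p <- cfg$priors %||% list()
  prior_spec(mean_gain = p$mean_gain %||% 10, mean_loss = p$mean_loss %||% 10,
             mean_s_on = p$mean_s_on %||% 1, mean_s_off = p$mean_s_off %||% 1,
             mean_alpha = p$mean_alpha %||% 1,
             mean_clock_rate = p$mean_clock_rate %||% 1,
             mean_lambda = p$mean_lambda %||% 1, mean_mu = p$mean_mu %||% 1,
             mean_psi = p$mean_psi %||% 1,
             root_age_max = p$root_age_max %||% Inf,
             calibrations = calibrations, constraints = constraints)
}

#' Run the full inference pipeline from a configuration
#'
#' Curation (taxon exclusion, loan removal), binarization, pattern
#' compression and MCMC, writing three artifacts to the output directory:
#' `trace.tsv` (BEAST-style log), `trees.nex` (sampled dated trees) and
#' `report.yaml` (resolved configuration, seed, acceptance rate and, for
#' multiple chains, convergence diagnostics).
#'
#' @param config a [read_run_config()] result or a path to a YAML config.
#' @return invisibly, a list with the per-chain [run_chain()] results, the
#'   binarized data and the artifact paths.
#' @export
run_inference <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  tip_dates <- unlist(config$tip_dates) %||% NULL
  ds <- read_cognate_table(config$data, format = config$data_format,
                           tip_dates = tip_dates)
  if (length(config$exclude_taxa)) ds <- exclude_taxa(ds, unlist(config$exclude_taxa))
  ds <- remove_loans(ds)
  bm <- multistate_to_binary(ds)
  patterns <- compress_patterns(bm)
  cals <- config_calibrations(config)
  cons <- config_constraints(config)
  for (cal in cals) {
    missing <- setdiff(cal$taxa, ds$languages)
    if (length(missing)) {
      stop("calibration names taxa absent from the data: ",
           paste(missing, collapse = ", "))
    }
  }
  model <- config_model(config)
  clock <- config_clock(config)
  fbd <- config_fbd(config)
  spec <- config_priors(config, cals, cons)
  td <- stats::setNames(ds$tip_dates$age_ka, ds$tip_dates$language)
  tree <- if (!is.null(config$init_tree)) {
    read_timetree_newick(config$init_tree, present = 0)
  } else {
    init_time_tree(td, cons, cals)
  }
  init <- model_state(tree, model, clock, fbd)
  mc <- config$mcmc
  cfg <- mcmc_config(chain_length = mc$chain_length,
                     burn_in = mc$burn_in %||% 0L,
                     sample_every = mc$sample_every %||% 1L,
                     n_chains = mc$n_chains %||% 1L,
                     seed = mc$seed %||% config$seed)
  chains <- run_chains(patterns, init, spec, cfg)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(trace = file.path(config$output_dir, "trace.tsv"),
             trees = file.path(config$output_dir, "trees.nex"),
             report = file.path(config$output_dir, "report.yaml"))
  write_trace(chains[[1]], paths["trace"])
  write_trees_nexus(chains[[1]], paths["trees"])
  report <- list(
    config = unclass(config),
    seed = cfg$seed,
    n_cognate_sets = bm$n_cognate_sets,
    n_patterns = length(patterns$weights),
    acceptance_rate = chains[[1]]$acceptance_rate
  )
  if (length(chains) > 1) {
    report$diagnostics <- as.list(multichain_diagnostics(chains))
  }
  yaml::write_yaml(report, paths["report"])
  invisible(list(chains = chains, binary = bm, patterns = patterns,
                 paths = paths, spec = spec, init = init, config = cfg))
}

#' Summarize a posterior tree sample
#'
#' Runs the posterior-summary stage end to end: MCC tree with node ages and
#' HPDs, clade-support and root-split tables, root-age summary, and supports
#' for user-named taxon groups.
#'
#' @param trees a list of [time_tree()]s, a [run_chain()] result, or a path
#'   readable by [read_trees()].
#' @param clades optional named list of taxon sets to report supports for.
#' @param output_dir optional directory: writes `mcc.nwk`,
#'   `clade_support.tsv` and `summary.yaml`.
#' @param mass HPD mass.
#' @return a list with `mcc`, `clade_support`, `root_splits`, `root_age`
#'   (mean, median, HPD) and `named_clades` (tibble).
#' @export
summarize_run <- function(trees, clades = NULL, output_dir = NULL,
                          mass = 0.95) {
  if (is.character(trees)) trees <- read_trees(trees)
  if (inherits(trees, "posterior_sample")) trees <- trees$trees
  if (!length(trees)) stop("empty tree sample")
  support <- clade_frequencies(trees)
  mcc <- mcc_tree(trees, mass = mass)
  root_ages <- vapply(trees, tt_root_age, numeric(1))
  hpd <- hpd_interval(root_ages, mass)
  named <- NULL
  if (!is.null(clades)) {
    unknown <- setdiff(unique(unlist(clades)), trees[[1]]$tip_labels)
    if (length(unknown)) {
      stop("unknown taxa in clade queries: ", paste(unknown, collapse = ", "))
    }
    named <- purrr::imap_dfr(clades, function(taxa, nm) {
      tibble::tibble(name = nm,
                     n_taxa = length(taxa),
                     support = clade_posterior(trees, taxa),
                     root_split_support = root_split_support(trees, taxa))
    })
  }
  out <- list(mcc = mcc, clade_support = support,
              root_splits = root_split_table(trees),
              root_age = list(mean = mean(root_ages),
                              median = stats::median(root_ages),
                              hpd_low = hpd[1], hpd_high = hpd[2]),
              named_clades = named)
  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    write_annotated_newick(mcc, file.path(output_dir, "mcc.nwk"))
    write_clade_support(support, file.path(output_dir, "clade_support.tsv"))
    yaml::write_yaml(list(root_age = out$root_age,
                          named_clades = if (!is.null(named)) as.list(named)),
                     file.path(output_dir, "summary.yaml"))
  }
  out
}
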