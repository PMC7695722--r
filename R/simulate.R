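#' Simulate a dated tree under the fossilized birth-death process
#'
#' Forward simulation from a root at `root_age` ka BP with two initial
#' lineages: births at rate `lambda`, deaths at rate `mu`, through-time
#' sampling (an extinct, historically attested tip) at rate `psi`, and
#' extant-tip sampling with probability `rho` at the present. Unsampled
#' lineages are pruned and unifurcations suppressed, so the returned tree is
#' the sampled tree; its root is the MRCA of the sample (equal to `root_age`
#' exactly when both initial lineages leave sampled descendants).
#'
#' @param p an [fbd_params()].
#' @param root_age root age in ka BP.
#' @param min_tips,max_tips accepted range of sampled tip counts; trees
#'   outside it are re-simulated.
#' @param max_tries simulation attempts before giving up with an error.
#' @param tip_prefix prefix for generated tip labels.
#' @return a [time_tree()]; attribute `"root_is_mrca"` says whether the
#'   sampled root age equals `root_age`.
#' @export
simulate_fbd_tree <- function(p, root_age, min_tips = 3L, max_tips = 500L,
                              max_tries = 1000L, tip_prefix = "L") {
  stopifnot(inherits(p, "fbd_params"), root_age > 0)
  total <- p$lambda + p$mu + p$psi
  for (try in seq_len(max_tries)) {
    parent <- NA_integer_; age <- root_age; kind <- "birth"
    # stack of lineages: (start age, parent node id)
    st_age <- c(root_age, root_age); st_par <- c(1L, 1L)
    overflow <- FALSE
    while (length(st_age)) {
      t0 <- st_age[1]; pa <- st_par[1]
      st_age <- st_age[-1]; st_par <- st_par[-1]
      ev_age <- t0 - stats::rexp(1, total)
      id <- length(age) + 1L
      if (ev_age <= 0) {
        sampled <- stats::runif(1) < p$rho
        parent[id] <- pa; age[id] <- 0
        kind[id] <- if (sampled) "extant" else "dead"
      } else {
        what <- sample(c("birth", "dead", "fossil"), 1L,
                       prob = c(p$lambda, p$mu, p$psi))
        parent[id] <- pa; age[id] <- ev_age; kind[id] <- what
        if (what == "birth") {
          st_age <- c(st_age, ev_age, ev_age)
          st_par <- c(st_par, id, id)
        }
      }
      if (length(age) > 20L * max_tips + 1000L) { overflow <- TRUE; break }
    }
    if (overflow) next
    sampled <- kind %in% c("extant", "fossil")
    n <- sum(sampled)
    if (n < min_tips || n > max_tips) next
    tt <- prune_sim_tree(parent, age, kind, tip_prefix)
    if (is.null(tt)) next
    attr(tt, "root_is_mrca") <- abs(tt_root_age(tt) - root_age) < 1e-12
    return(tt)
  }
  stop("no acceptable tree in ", max_tries, " attempts; check parameters")
}

# prune unsampled lineages from a raw simulation and build a timetree
prune_sim_tree <- function(parent, age, kind, tip_prefix) {
  nall <- length(parent)
  kids <- vector("list", nall)
  for (i in seq_len(nall)[-1]) kids[[parent[i]]] <- c(kids[[parent[i]]], i)
  good <- kind %in% c("extant", "fossil")
  # postorder mark: does subtree contain a sampled tip
  ord <- rev(seq_len(nall))            # children always have larger ids
  has <- good
  for (i in ord) if (length(kids[[i]])) has[i] <- any(has[kids[[i]]])
  if (!has[1]) return(NULL)
  tips <- which(good)
  ntip <- length(tips)
  if (ntip < 2L) return(NULL)
  # build pruned binary tree: new ids, tips first
  new_parent <- rep(NA_integer_, 2L * ntip - 1L)
  new_age <- numeric(2L * ntip - 1L)
  tip_id <- stats::setNames(seq_len(ntip), tips)
  next_int <- ntip
  build <- function(node, new_pa) {
    # returns new id of the pruned subtree root under `node`
    repeat {
      ch <- kids[[node]]
      ch <- ch[has[ch]]
      if (good[node] && !length(ch)) {       # sampled tip
        id <- tip_id[[as.character(node)]]
        new_parent[id] <<- new_pa; new_age[id] <<- age[node]
        return(id)
      }
      if (length(ch) == 2L) break
      if (length(ch) == 1L) { node <- ch[1] } else return(NULL)
    }
    next_int <<- next_int + 1L
    id <- next_int
    new_parent[id] <<- new_pa; new_age[id] <<- age[node]
    for (c2 in ch) build(c2, id)
    id
  }
  build(1L, NA_integer_)
  labs <- character(ntip)
  ext <- new_age[seq_len(ntip)] > 1e-12
  labs[!ext] <- paste0(tip_prefix, seq_len(sum(!ext)))
  labs[ext] <- paste0(tip_prefix, "x", seq_len(sum(ext)))
  time_tree(new_parent, new_age, labs)
}

#' Simulate relaxed-clock branch-rate multipliers
#'
#' Independent lognormal multipliers with real-space mean `mu` and log-space
#' standard deviation `sigma`, indexed by child node id (root entry `NA`).
#'
#' @param tree a [time_tree()].
#' @param mu real-space mean (default 1.0).
#' @param sigma log-space sd (>= 0; `sigma = 0` gives all multipliers `mu`).
#' @return numeric vector of length `2*ntip - 1` with `NA` at the root.
#' @export
simulate_branch_rates <- function(tree, mu = 1.0, sigma = 0.1) {
  if (sigma < 0) stop("sigma must be >= 0")
  ntot <- length(tree$parent)
  r <- rep(NA_real_, ntot)
  nonroot <- setdiff(seq_len(ntot), tree$root)
  r[nonroot] <- if (sigma == 0) mu else
    stats::rlnorm(length(nonroot), meanlog = log(mu) - sigma^2 / 2, sdlog = sigma)
  r
}

#' Simulate binary (covarion) characters on a dated tree
#'
#' Root states are drawn from the model's stationary distribution and evolved
#' tipward by exact endpoint sampling from the transition matrices; for the
#' covarion, the hidden on/off component is discarded and only the visible
#' 0/1 state is returned.
#'
#' @param tree a [time_tree()].
#' @param model a [subst_model()].
#' @param n_sites number of characters (>= 1).
#' @param branch_rates optional multipliers indexed by child node id.
#' @param clock_rate clock rate in substitutions per ka.
#' @return integer matrix (`ntip` x `n_sites`) over `{0, 1}`, rows named by
#'   tip label.
#' @export
simulate_covarion_characters <- function(tree, model, n_sites,
                                         branch_rates = NULL, clock_rate = 1) {
  if (n_sites < 1) stop("n_sites must be >= 1")
  m <- model_machinery(model)
  ntot <- length(tree$parent)
  if (is.null(branch_rates)) branch_rates <- rep(1, ntot)
  states <- matrix(NA_integer_, ntot, n_sites)
  cat_rates <- m$cat_rates
  site_cat <- sample.int(length(cat_rates), n_sites, replace = TRUE)
  states[tree$root, ] <- sample.int(m$nstate, n_sites, replace = TRUE, prob = m$freq)
  ord <- rev(tt_postorder(tree))        # preorder: parents before children
  for (nd in ord[-1]) {
    elen <- (tree$ages[tree$parent[nd]] - tree$ages[nd]) *
      branch_rates[nd] * clock_rate
    for (k in unique(site_cat)) {
      P <- transition_matrix(t = elen * cat_rates[k], machinery = m)
      sel <- which(site_cat == k)
      ps <- states[tree$parent[nd], sel]
      for (s in unique(ps)) {
        idx <- sel[ps == s]
        states[nd, idx] <- sample.int(m$nstate, length(idx), replace = TRUE,
                                      prob = P[s, ])
      }
    }
  }
  vis <- states[seq_len(tree$ntip), , drop = FALSE]
  # states are ordered (0on, 1on[, 0off, 1off]): even ids carry visible 1
  vis <- matrix(as.integer(vis %% 2L == 0L), nrow = tree$ntip)
  rownames(vis) <- tree$tip_labels
  vis
}

#' Wrap simulated characters as a binary cognate-set matrix
#'
#' @param tree a [time_tree()].
#' @param model a [subst_model()].
#' @inheritParams simulate_covarion_characters
#' @return a [binary_matrix()] with one synthetic concept per character.
#' @export
simulate_binary_matrix <- function(tree, model, n_sites, branch_rates = NULL,
                                   clock_rate = 1) {
  vis <- simulate_covarion_characters(tree, model, n_sites, branch_rates,
                                      clock_rate)
  binary_matrix(vis, tibble::tibble(
    concept = sprintf("site%04d", seq_len(n_sites)), cognate_class = "present"
  ))
}

#' Configuration for the cognate-dataset simulator
#'
#' The generator emulates the structure of curated basic-vocabulary cognacy
#' data: a dated language tree with extinct tips, lognormal branch-rate
#' variation, per-concept cognate classes arising by lexical innovation along
#' branches, contact-induced loans (flagged), occasional synonyms, and
#' missing entries. Defaults mirror a Swadesh-style collection of 110
#' concepts.
#'
#' @param fbd an [fbd_params()] for the language tree.
#' @param root_age root age in ka BP.
#' @param clock_mu,clock_sigma lognormal branch-rate parameters.
#' @param n_concepts number of concepts (default 110).
#' @param innovation_rate lexical replacement rate: new cognate classes arise
#'   along each lineage as a Poisson process with this rate per ka (scaled by
#'   the branch-rate multiplier), each replacing the lineage's current class.
#' @param loan_rate per-(language, concept) probability of an added,
#'   flagged loan class copied from another language.
#' @param synonym_rate per-(language, concept) probability of carrying a
#'   second (synonymous) class.
#' @param missing_rate per-(language, concept) probability the datum is
#'   missing.
#' @param min_tips,max_tips accepted sampled-tip range for the tree.
#' @param seed RNG seed recorded in the ground truth.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(fbd = fbd_params(lambda = 0.85, mu = 0.2, psi = 0.05,
                                        rho = 0.55),
                       root_age = 8, clock_mu = 1.0, clock_sigma = 0.1,
                       n_concepts = 110L, innovation_rate = 0.07,
                       loan_rate = 0.02, synonym_rate = 0.05,
                       missing_rate = 0.05,
                       min_tips = 127L, max_tips = 135L, seed = 1L) {
  stopifnot(inherits(fbd, "fbd_params"), root_age > 0, n_concepts >= 1,
            innovation_rate >= 0, loan_rate >= 0, loan_rate <= 1,
            synonym_rate >= 0, synonym_rate <= 1,
            missing_rate >= 0, missing_rate <= 1)
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate a fully structured cognate dataset with ground truth
#'
#' Simulates a dated tree, branch rates, and per-concept cognate classes
#' (ancestral class plus replacement innovations along branches), then
#' overlays synonyms, flagged loans and missing data.
#'
#' @param cfg a [sim_config()].
#' @return a list with elements `dataset` (a [cognate_dataset()]) and
#'   `truth` (tree, branch rates, config, seed).
#' @export
make_cognate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  tree <- simulate_fbd_tree(cfg$fbd, cfg$root_age,
                            min_tips = cfg$min_tips, max_tips = cfg$max_tips)
  rates <- simulate_branch_rates(tree, cfg$clock_mu, cfg$clock_sigma)
  ntip <- tree$ntip
  ord <- rev(tt_postorder(tree))
  durs <- tt_durations(tree)
  entries <- vector("list", cfg$n_concepts)
  for (ci in seq_len(cfg$n_concepts)) {
    concept <- sprintf("concept%03d", ci)
    cls <- character(length(tree$parent))
    counter <- 1L
    cls[tree$root] <- "k1"
    for (nd in ord[-1]) {
      cur <- cls[tree$parent[nd]]
      n_inn <- stats::rpois(1, cfg$innovation_rate * durs[nd] * rates[nd])
      if (n_inn > 0) {
        counter <- counter + n_inn
        cur <- paste0("k", counter)
      }
      cls[nd] <- cur
    }
    tip_cls <- cls[seq_len(ntip)]
    rows <- tibble::tibble(language = tree$tip_labels,
                           concept = concept,
                           cognate_class = tip_cls, is_loan = FALSE)
    # synonyms: a language keeps a second class for the meaning
    syn <- which(stats::runif(ntip) < cfg$synonym_rate)
    for (i in syn) {
      others <- setdiff(unique(tip_cls), tip_cls[i])
      if (length(others)) {
        rows <- dplyr::bind_rows(rows, tibble::tibble(
          language = tree$tip_labels[i], concept = concept,
          cognate_class = sample(others, 1L), is_loan = FALSE))
      }
    }
    # loans: copy a donor's class to an arbitrary recipient, flagged
    loan <- which(stats::runif(ntip) < cfg$loan_rate)
    for (i in loan) {
      donor <- sample(setdiff(seq_len(ntip), i), 1L)
      dcls <- setdiff(tip_cls[donor], rows$cognate_class[rows$language == tree$tip_labels[i]])
      if (length(dcls)) {
        rows <- dplyr::bind_rows(rows, tibble::tibble(
          language = tree$tip_labels[i], concept = concept,
          cognate_class = dcls[1], is_loan = TRUE))
      }
    }
    # missing data: blank the whole (language, concept) cell
    miss <- tree$tip_labels[stats::runif(ntip) < cfg$missing_rate]
    rows <- rows[!rows$language %in% miss, ]
    entries[[ci]] <- rows
  }
  entries <- dplyr::bind_rows(entries)
  ds <- cognate_dataset(entries,
                        tip_dates = stats::setNames(tree$ages[seq_len(ntip)],
                                                    tree$tip_labels),
                        languages = tree$tip_labels,
                        concepts = sprintf("concept%03d", seq_len(cfg$n_concepts)))
  list(dataset = ds,
       truth = list(tree = tree, branch_rates = rates, config = cfg,
                    seed = cfg$seed))
}

#' Write a simulated dataset, its true tree and ground truth to disk
#'
#' Emits the CSV cognate dialect, a Newick true tree (branch lengths in ka)
#' and a YAML ground-truth sidecar.
#'
#' @param sim result of [make_cognate_dataset()].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    data = file.path(dir, "cognates.csv"),
    tree = file.path(dir, "true_tree.nwk"),
    truth = file.path(dir, "ground_truth.yaml")
  )
  write_cognate_csv(sim$dataset, paths["data"])
  write_timetree_newick(sim$truth$tree, paths["tree"])
  cfg <- sim$truth$config
  yaml::write_yaml(list(
    seed = sim$truth$seed,
    root_age_ka = tt_root_age(sim$truth$tree),
    n_tips = sim$truth$tree$ntip,
    fbd = unclass(cfg$fbd),
    clock = list(mu = cfg$clock_mu, sigma = cfg$clock_sigma),
    innovation_rate = cfg$innovation_rate,
    loan_rate = cfg$loan_rate, synonym_rate = cfg$synonym_rate,
    missing_rate = cfg$missing_rate,
    tip_dates = as.list(stats::setNames(
      sim$truth$tree$ages[seq_len(sim$truth$tree$ntip)],
      sim$truth$tree$tip_labels))
  ), paths["truth"])
  invisible(paths)
}
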