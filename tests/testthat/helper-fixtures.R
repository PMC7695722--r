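# Shared fixtures and independent oracles for the test suite.

# fixed 4-tip dated tree: ((A:1,B:1):1,(C:1.5,D:1.5):0.5), root at 2 ka
toy_tree4 <- function() {
  time_tree(parent = c(6L, 6L, 7L, 7L, NA, 5L, 5L),
            ages = c(0, 0, 0, 0, 2, 1, 1.5),
            tip_labels = c("A", "B", "C", "D"))
}

# random rooted dated tree by sequential joins; extant tips unless tip_ages
random_dated_tree <- function(ntip, max_age = 3, tip_ages = rep(0, ntip)) {
  labs <- paste0("t", seq_len(ntip))
  parent <- rep(NA_integer_, 2L * ntip - 1L)
  ages <- c(tip_ages, numeric(ntip - 1L))
  free <- seq_len(ntip)
  nid <- ntip
  while (length(free) > 1) {
    pair <- sample(free, 2)
    nid <- nid + 1L
    parent[pair] <- nid
    ages[nid] <- max(ages[pair]) + stats::runif(1, 0.1, max_age / ntip)
    free <- c(setdiff(free, pair), nid)
  }
  time_tree(parent, ages, labs)
}

# brute-force site likelihood by enumeration over internal-node states,
# with transition matrices from Matrix::expm (independent of the eigen path)
brute_site_loglik <- function(tt, Q, freq, pattern) {
  ns <- nrow(Q)
  ntip <- tt$ntip
  ntot <- length(tt$parent)
  P <- vector("list", ntot)
  for (nd in seq_len(ntot)) {
    if (is.na(tt$parent[nd])) next
    t <- tt$ages[tt$parent[nd]] - tt$ages[nd]
    P[[nd]] <- as.matrix(Matrix::expm(Q * t))
  }
  tipvec <- function(x) {
    if (is.na(x)) return(rep(1, ns))
    v <- if (x == 0) c(1, 0) else c(0, 1)
    if (ns == 4) rep(v, 2) else v
  }
  internals <- (ntip + 1L):ntot
  grid <- as.matrix(expand.grid(rep(list(seq_len(ns)), length(internals))))
  total <- 0
  for (g in seq_len(nrow(grid))) {
    st <- integer(ntot)
    st[internals] <- grid[g, ]
    pr <- freq[st[tt$root]]
    for (nd in internals) {
      if (nd == tt$root) next
      pr <- pr * P[[nd]][st[tt$parent[nd]], st[nd]]
    }
    for (tp in seq_len(ntip)) {
      pr <- pr * sum(P[[tp]][st[tt$parent[tp]], ] * tipvec(pattern[tp]))
    }
    total <- total + pr
  }
  log(total)
}

# small 4-language toy cognate table (one loan flag)
toy_cognate_csv <- function(path) {
  writeLines(c(
    "language,concept,cognate_class,is_loan",
    "L1,hand,A,FALSE",
    "L2,hand,A,FALSE",
    "L3,hand,B,FALSE",
    "L4,hand,B,TRUE",
    "L1,sun,X,FALSE",
    "L2,sun,Y,FALSE",
    "L3,sun,X,FALSE",
    "L4,sun,X,FALSE"
  ), path)
  path
}

# worked binarization example: one concept, classes A/A/B/{A,B}/missing
toy_binarization_dataset <- function() {
  cognate_dataset(tibble::tibble(
    language = c("L1", "L2", "L3", "L4", "L4"),
    concept = "hand",
    cognate_class = c("A", "A", "B", "A", "B"),
    is_loan = FALSE
  ), languages = paste0("L", 1:5), concepts = "hand")
}
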