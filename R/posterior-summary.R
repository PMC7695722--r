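#' Posterior clade frequencies
#'
#' Counts, for every clade (tip subset) appearing in a sample of trees, the
#' fraction of trees containing it. Clades are keyed by tip bitsets over the
#' canonical (sorted) taxon ordering; output is ordered by descending
#' frequency, then lexicographically, so it is invariant to the order of the
#' input trees.
#'
#' @param trees list of [time_tree()]s on a common tip set.
#' @return a tibble of class `clade_support` with columns `clade`
#'   (comma-separated tip labels), `n_tips`, `count`, `frequency`; attribute
#'   `n_trees` holds the sample size.
#' @export
clade_frequencies <- function(trees) {
  if (!length(trees)) stop("empty tree sample")
  canon <- sort(trees[[1]]$tip_labels)
  keys <- lapply(trees, function(tt) {
    if (!identical(sort(tt$tip_labels), canon)) {
      stop("trees are not on a common tip set")
    }
    tt_clade_keys(tt, canon)
  })
  tab <- table(unlist(keys))
  clade_names <- vapply(strsplit(names(tab), ",", fixed = TRUE), function(i) {
    paste(canon[as.integer(i)], collapse = ",")
  }, character(1))
  out <- tibble::tibble(
    clade = clade_names,
    n_tips = lengths(strsplit(names(tab), ",", fixed = TRUE)),
    count = as.integer(tab),
    frequency = as.integer(tab) / length(trees)
  )
  out <- out[order(-out$frequency, out$clade), ]
  out <- structure(out, class = c("clade_support", class(out)))
  attr(out, "n_trees") <- length(trees)
  out
}

#' Posterior probability that a taxon set is monophyletic
#'
#' @param trees list of [time_tree()]s.
#' @param taxa tip labels.
#' @return fraction of trees in which `taxa` form a clade.
#' @export
clade_posterior <- function(trees, taxa) {
  con <- monophyly_constraint(taxa)
  mean(vapply(trees, constraint_satisfied, logical(1), con = con))
}

#' Posterior support for a root split (outgroup hypothesis)
#'
#' Fraction of sampled trees in which `taxa` constitute exactly one child of
#' the root, i.e. form one side of the first divergence.
#'
#' @param trees list of [time_tree()]s.
#' @param taxa proper nonempty subset of the tip labels.
#' @return frequency in `[0, 1]`.
#' @export
root_split_support <- function(trees, taxa) {
  if (!length(trees)) stop("empty tree sample")
  n <- trees[[1]]$ntip
  if (!length(taxa) || length(taxa) >= n) {
    stop("taxa must be a proper nonempty subset of the tips")
  }
  con <- monophyly_constraint(taxa, as_outgroup = TRUE)
  mean(vapply(trees, constraint_satisfied, logical(1), con = con))
}

#' Table of all sampled root splits
#'
#' Each tree contributes its root split once; splits are canonicalized to the
#' side not containing the alphabetically first taxon, so frequencies sum
#' to 1.
#'
#' @param trees list of [time_tree()]s on a common tip set.
#' @return tibble with `split` (comma-separated tips of the canonical side)
#'   and `frequency`.
#' @export
root_split_table <- function(trees) {
  canon <- sort(trees[[1]]$tip_labels)
  sides <- vapply(trees, function(tt) {
    kids <- which(tt$parent == tt$root)
    sets <- tt_tipsets(tt)
    side <- sets[[kids[1]]]
    labs <- sort(tt$tip_labels[side])
    if (canon[1] %in% labs) labs <- setdiff(canon, labs)
    paste(labs, collapse = ",")
  }, character(1))
  tab <- table(sides)
  out <- tibble::tibble(split = names(tab),
                        frequency = as.integer(tab) / length(trees))
  out[order(-out$frequency, out$split), ]
}

#' Highest posterior density interval
#'
#' The shortest contiguous interval of sorted samples containing
#' `ceiling(mass * n)` of them; ties are broken toward the smallest lower
#' bound.
#'
#' @param samples numeric vector (>= 2 values).
#' @param mass posterior mass (default 0.95).
#' @return numeric `c(low, high)`.
#' @export
hpd_interval <- function(samples, mass = 0.95) {
  if (!length(samples)) stop("empty input")
  if (length(samples) < 2) stop("need at least 2 samples")
  if (mass <= 0 || mass > 1) stop("mass must be in (0, 1]")
  x <- sort(samples)
  n <- length(x)
  m <- ceiling(mass * n)
  if (m >= n) return(c(x[1], x[n]))
  starts <- seq_len(n - m + 1L)
  widths <- x[starts + m - 1L] - x[starts]
  i <- which.min(widths)     # which.min takes the first minimum: smallest low
  c(x[i], x[i + m - 1L])
}

#' Maximum clade credibility tree with node annotations
#'
#' Selects the sampled tree maximizing the sum of the log posterior
#' frequencies of its clades (ties broken by sample order), then annotates
#' each internal node with its clade's posterior frequency and the mean,
#' median and 95% HPD of that clade's MRCA age across all trees containing
#' it.
#'
#' @param trees list of [time_tree()]s on a common tip set.
#' @param mass HPD mass for node-age intervals.
#' @return an object of class `annotated_tree`: fields `tree` (the MCC
#'   [time_tree()]), `annotations` (tibble with `node`, `clade`, `posterior`,
#'   `age_mean`, `age_median`, `age_hpd_low`, `age_hpd_high`), `score` and
#'   `index` (position of the MCC tree in the sample).
#' @export
mcc_tree <- function(trees, mass = 0.95) {
  if (!length(trees)) stop("empty tree sample")
  canon <- sort(trees[[1]]$tip_labels)
  keys <- lapply(trees, function(tt) {
    if (!identical(sort(tt$tip_labels), canon)) {
      stop("trees are not on a common tip set")
    }
    tt_clade_keys(tt, canon)
  })
  counts <- table(unlist(keys))
  freq <- as.numeric(counts) / length(trees)
  names(freq) <- names(counts)
  scores <- vapply(keys, function(k) sum(log(freq[k])), numeric(1))
  idx <- which.max(scores)            # first maximum: deterministic tie rule
  best <- trees[[idx]]
  # per-clade age samples over all trees containing the clade
  ages <- lapply(trees, function(tt) tt$ages[(tt$ntip + 1L):length(tt$ages)])
  age_by_clade <- split(unlist(ages), unlist(keys))
  bk <- tt_clade_keys(best, canon)
  ann <- purrr::map_dfr(seq_along(bk), function(j) {
    a <- age_by_clade[[bk[j]]]
    hpd <- if (length(a) >= 2) hpd_interval(a, mass) else c(a, a)
    tibble::tibble(
      node = best$ntip + j,
      clade = paste(sort(strsplit_clade(bk[j], canon)), collapse = ","),
      posterior = freq[[bk[j]]],
      age_mean = mean(a), age_median = stats::median(a),
      age_hpd_low = hpd[1], age_hpd_high = hpd[2]
    )
  })
  structure(list(tree = best, annotations = ann, score = scores[idx],
                 index = idx, n_trees = length(trees)),
            class = "annotated_tree")
}

strsplit_clade <- function(key, canon) {
  canon[as.integer(strsplit(key, ",", fixed = TRUE)[[1]])]
}

#' @export
print.annotated_tree <- function(x, ...) {
  cat("<annotated_tree> MCC tree of ", x$n_trees, " samples; root age mean ",
      format(x$annotations$age_mean[x$annotations$node == x$tree$root],
             digits = 5),
      " ka BP (posterior ",
      format(x$annotations$posterior[x$annotations$node == x$tree$root],
             digits = 3), ")\n", sep = "")
  invisible(x)
}

#' Write an annotated tree as Newick with bracketed node comments
#'
#' Internal nodes carry `[&posterior=..,age_mean=..,age_hpd_low=..,
#' age_hpd_high=..]` comments; branch lengths are durations in ka.
#'
#' @param at an [mcc_tree()] result.
#' @param path file path.
#' @export
write_annotated_newick <- function(at, path) {
  tt <- at$tree
  ann <- at$annotations
  kids <- tt_children(tt)
  fmt <- function(x) sprintf("%.10g", x)
  build <- function(nd) {
    if (nd <= tt$ntip) {
      s <- tt$tip_labels[nd]
    } else {
      a <- ann[ann$node == nd, ]
      s <- paste0("(", build(kids[[nd]][1]), ",", build(kids[[nd]][2]), ")",
                  "[&posterior=", fmt(a$posterior),
                  ",age_mean=", fmt(a$age_mean),
                  ",age_hpd_low=", fmt(a$age_hpd_low),
                  ",age_hpd_high=", fmt(a$age_hpd_high), "]")
    }
    if (nd == tt$root) return(s)
    paste0(s, ":", fmt(tt$ages[tt$parent[nd]] - tt$ages[nd]))
  }
  writeLines(paste0(build(tt$root), ";"), path)
  invisible(path)
}

#' Write a clade-support table as TSV
#' @param support a [clade_frequencies()] table (or any tibble).
#' @param path file path.
#' @export
write_clade_support <- function(support, path) {
  readr::write_tsv(tibble::as_tibble(support), path, progress = FALSE)
  invisible(path)
}
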