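#' Dated rooted trees
#'
#' A `timetree` is a rooted, bifurcating tree whose nodes carry absolute ages
#' in thousands of years before present (ka BP). Tips are sampled languages:
#' extant tips sit at age 0, extinct (historically attested) tips at their
#' fixed last-seen ages. Branch durations are derived as parent age minus
#' child age, so the object stays internally consistent under node-age moves.
#'
#' Internally the tree is stored as a parent vector over node ids
#' `1..ntip` (tips, in `tip_labels` order) and `ntip+1..2*ntip-1` (internal
#' nodes); conversion to and from [ape::as.phylo] objects is lossless.
#'
#' @param parent integer vector of length `2*ntip - 1`; `parent[i]` is the
#'   node id of node `i`'s parent, `NA` for the root.
#' @param ages numeric vector of node ages in ka BP, same length as `parent`.
#' @param tip_labels character vector of tip names (length `ntip`).
#' @return An object of class `timetree`.
#' @export
time_tree <- function(parent, ages, tip_labels) {
  ntip <- length(tip_labels)
  ntot <- 2L * ntip - 1L
  stopifnot(length(parent) == ntot, length(ages) == ntot)
  if (anyDuplicated(tip_labels)) stop("duplicate tip labels")
  root <- which(is.na(parent))
  if (length(root) != 1L) stop("tree must have exactly one root")
  tt <- structure(
    list(ntip = ntip, tip_labels = tip_labels,
         parent = as.integer(parent), ages = as.numeric(ages),
         root = as.integer(root)),
    class = "timetree"
  )
  validate_timetree(tt)
  tt
}

validate_timetree <- function(tt, tol = 1e-9) {
  kids <- tt_children(tt)
  n_kids <- lengths(kids)
  if (any(n_kids[seq_len(tt$ntip)] != 0L)) stop("tips must be leaves")
  if (any(n_kids[-seq_len(tt$ntip)] != 2L)) stop("tree must be bifurcating")
  nonroot <- setdiff(seq_along(tt$parent), tt$root)
  if (any(tt$ages[tt$parent[nonroot]] <= tt$ages[nonroot] - tol)) {
    stop("every parent must be older than its children")
  }
  if (any(tt$ages < -tol)) stop("node ages must be >= 0 (ka BP)")
  invisible(tt)
}

#' @export
print.timetree <- function(x, ...) {
  cat("<timetree> ", x$ntip, " tips, root age ", format(tt_root_age(x), digits = 5),
      " ka BP (", sum(tt_is_extinct(x)), " extinct tips)\n", sep = "")
  invisible(x)
}

# children list indexed by node id
tt_children <- function(tt) {
  kids <- vector("list", length(tt$parent))
  idx <- which(!is.na(tt$parent))
  for (i in idx) kids[[tt$parent[i]]] <- c(kids[[tt$parent[i]]], i)
  kids
}

#' Root age of a dated tree
#' @param tt a [time_tree()].
#' @return root age in ka BP.
#' @export
tt_root_age <- function(tt) tt$ages[tt$root]

tt_is_extinct <- function(tt, tol = 1e-8) tt$ages[seq_len(tt$ntip)] > tol

# duration of the branch above each node (NA for root), indexed by child node
tt_durations <- function(tt) {
  d <- rep(NA_real_, length(tt$parent))
  nr <- which(!is.na(tt$parent))
  d[nr] <- tt$ages[tt$parent[nr]] - tt$ages[nr]
  d
}

# postorder node ordering (children before parents); internal nodes only if
# internal_only
tt_postorder <- function(tt) {
  kids <- tt_children(tt)
  out <- integer(0)
  # iterative DFS
  stack <- tt$root
  visit <- integer(0)
  while (length(stack)) {
    nd <- stack[length(stack)]
    stack <- stack[-length(stack)]
    visit <- c(visit, nd)
    stack <- c(stack, kids[[nd]])
  }
  rev(visit)
}

# descendant tip-id list per node
tt_tipsets <- function(tt) {
  kids <- tt_children(tt)
  sets <- vector("list", length(tt$parent))
  for (nd in tt_postorder(tt)) {
    sets[[nd]] <- if (nd <= tt$ntip) nd else
      sort(c(sets[[kids[[nd]][1]]], sets[[kids[[nd]][2]]]))
  }
  sets
}

#' Find the most recent common ancestor of a set of tips
#' @param tt a [time_tree()].
#' @param taxa character vector of tip labels.
#' @return node id of the MRCA.
#' @export
tt_mrca <- function(tt, taxa) {
  ids <- match(taxa, tt$tip_labels)
  if (anyNA(ids)) stop("unknown taxa: ", paste(taxa[is.na(ids)], collapse = ", "))
  # walk up from the first tip, collecting ancestors; then find deepest
  # ancestor common to all
  anc <- function(i) {
    path <- i
    while (!is.na(tt$parent[i])) { i <- tt$parent[i]; path <- c(path, i) }
    path
  }
  common <- anc(ids[1])
  for (i in ids[-1]) common <- intersect(common, anc(i))
  common[1]
}

#' Convert a timetree to an ape phylo
#'
#' Branch lengths are durations in ka.
#' @param x a [time_tree()].
#' @param ... unused.
#' @return an [ape::as.phylo] object.
#' @export
as_phylo <- function(x, ...) UseMethod("as_phylo")

#' @export
as_phylo.timetree <- function(x, ...) {
  ntip <- x$ntip
  ntot <- length(x$parent)
  # ape wants root = ntip+1; build an id remapping for internal nodes
  internals <- (ntip + 1L):ntot
  remap <- seq_len(ntot)
  ord <- c(x$root, setdiff(internals, x$root))
  remap[ord] <- internals
  child <- setdiff(seq_len(ntot), x$root)
  edge <- cbind(remap[x$parent[child]], remap[child])
  phy <- list(edge = edge,
              edge.length = x$ages[x$parent[child]] - x$ages[child],
              Nnode = ntip - 1L,
              tip.label = x$tip_labels)
  class(phy) <- "phylo"
  attr(phy, "order") <- NULL
  ape::reorder.phylo(phy, "cladewise")
}

#' Convert an ape phylo with branch lengths in ka to a timetree
#'
#' Node ages are reconstructed from root-to-node depths; the youngest tip is
#' anchored at `present` (default 0 ka BP).
#' @param phy a rooted, bifurcating [ape::as.phylo] with branch lengths.
#' @param present age (ka BP) of the youngest tip.
#' @return a [time_tree()].
#' @export
as_timetree <- function(phy, present = 0) {
  if (!ape::is.rooted(phy)) stop("tree must be rooted")
  if (!ape::is.binary(phy)) stop("tree must be bifurcating")
  ntip <- length(phy$tip.label)
  ntot <- ntip + phy$Nnode
  depth <- ape::node.depth.edgelength(phy)
  ages <- max(depth) - depth + present
  parent <- rep(NA_integer_, ntot)
  parent[phy$edge[, 2]] <- phy$edge[, 1]
  time_tree(parent, ages, phy$tip.label)
}

#' Write / read dated trees as Newick
#'
#' Serialization keeps branch lengths in ka; ages are recovered on read by
#' anchoring the youngest tip at `present`.
#' @param tt a [time_tree()].
#' @param path file path.
#' @param present age (ka BP) of the youngest tip, used on read.
#' @return `read_timetree_newick` returns a [time_tree()].
#' @export
write_timetree_newick <- function(tt, path) {
  ape::write.tree(as_phylo(tt), file = path)
  invisible(path)
}

#' @rdname write_timetree_newick
#' @export
read_timetree_newick <- function(path, present = 0) {
  as_timetree(ape::read.tree(path), present = present)
}

# clade key: canonical string over tip labels, used for support tables
tt_clade_keys <- function(tt, canonical_order = sort(tt$tip_labels)) {
  sets <- tt_tipsets(tt)
  idx <- match(tt$tip_labels, canonical_order)
  vapply(sets[(tt$ntip + 1L):length(sets)], function(s) {
    paste(sort(idx[s]), collapse = ",")
  }, character(1))
}
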