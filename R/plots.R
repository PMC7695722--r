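#' Trace plots for a posterior sample
#'
#' Line plots of every scalar parameter against the MCMC iteration, faceted
#' with free y scales — the standard first-look convergence diagnostic.
#'
#' @param object a [run_chain()] result.
#' @param parameters optional subset of trace columns to show.
#' @param ... unused.
#' @return a ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.posterior_sample <- function(object, parameters = NULL, ...) {
  tr <- object$trace
  pars <- parameters %||% setdiff(names(tr), "sample")
  keep <- pars[vapply(pars, function(p) !anyNA(tr[[p]]), logical(1))]
  long <- tidyr::pivot_longer(tr[c("sample", keep)], -"sample",
                              names_to = "parameter", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$sample, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::labs(x = "iteration", y = NULL) +
    ggplot2::theme_minimal()
}

#' Clade-support bar plot
#'
#' Posterior frequencies of the best-supported non-trivial clades.
#'
#' @param object a [clade_frequencies()] table.
#' @param n number of clades to show.
#' @param ... unused.
#' @return a ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.clade_support <- function(object, n = 20, ...) {
  df <- tibble::as_tibble(object)
  df <- df[df$n_tips > 1 & df$n_tips < max(df$n_tips), ]
  df <- utils::head(df[order(-df$frequency), ], n)
  df$clade <- factor(df$clade, levels = rev(df$clade))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$frequency, y = .data$clade)) +
    ggplot2::geom_col() +
    ggplot2::geom_vline(xintercept = 0.95, linetype = "dashed") +
    ggplot2::labs(x = "posterior frequency", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot an annotated MCC tree
#'
#' Base-graphics tree plot (via ape) with posterior probabilities at the
#' internal nodes and an axis in ka BP.
#'
#' @param x an [mcc_tree()] result.
#' @param ... passed to [ape::plot.phylo].
#' @export
plot.annotated_tree <- function(x, ...) {
  phy <- as_phylo(x$tree)
  ape::plot.phylo(phy, ...)
  # as_phylo remaps internal ids (root first); align annotations with it
  ntip <- x$tree$ntip
  ntot <- 2L * ntip - 1L
  ord <- c(x$tree$root, setdiff((ntip + 1L):ntot, x$tree$root))
  post <- x$annotations$posterior[match(ord, x$annotations$node)]
  ape::nodelabels(text = sprintf("%.2f", post),
                  frame = "none", adj = c(1.1, -0.3), cex = 0.7)
  ape::axisPhylo()
  invisible(x)
}
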