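#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Per-triplet consistency report of a TripNet fit
#'
#' @param x A `tripnet` object.
#' @param ... Unused.
#' @return A tibble with one row per input triplet (`cherry1`, `cherry2`,
#'   `outgroup`, `consistent`).
#' @export
tidy.tripnet <- function(x, ...) {
  tibble::tibble(cherry1 = x$input$cherry1,
                 cherry2 = x$input$cherry2,
                 outgroup = x$input$outgroup,
                 consistent = x$consistent)
}

#' One-row summary of a TripNet fit
#'
#' @param x A `tripnet` object.
#' @param ... Unused.
#' @return A one-row tibble: taxon and triplet counts, reticulation
#'   count, level, consistent fraction, patching additions and the speed
#'   mode.
#' @export
glance.tripnet <- function(x, ...) {
  tibble::tibble(
    n_taxa = length(network_leaves(x$network)),
    n_triplets = nrow(x$input),
    n_reticulations = x$n_reticulations,
    level = x$level,
    consistent_fraction = mean(x$consistent),
    step9_added = sum(unlist(x$log$step9)),
    speed = x$speed
  )
}

# layered layout: leaves spread on x by serialization order, internal nodes
# at the mean of their children, y = -longest-path depth
network_layout <- function(N) {
  idx <- pn_index(N)
  ord <- regmatches(to_enewick(N), gregexpr("[^(),;#]+", to_enewick(N)))[[1]]
  leaves <- idx$nodes[idx$leaves]
  ord <- ord[ord %in% leaves]
  xs <- stats::setNames(rep(NA_real_, idx$n), idx$nodes)
  xs[ord] <- seq_along(ord)
  for (u in rev(idx$topo)) {
    if (is.na(xs[idx$nodes[u]])) {
      xs[idx$nodes[u]] <- mean(xs[idx$nodes[idx$children[[u]]]])
    }
  }
  tibble::tibble(node = idx$nodes, x = unname(xs),
                 y = -idx$depth[match(idx$nodes, idx$nodes)],
                 leaf = idx$outdeg == 0,
                 reticulation = idx$indeg >= 2)
}

#' Plot a tree or network
#'
#' Nodes are laid out by longest-path depth (root on top); reticulation
#' arcs are drawn dashed.
#'
#' @param object A `phylo_net`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.phylo_net <- function(object, ...) {
  lay <- network_layout(object)
  seg <- tibble::tibble(parent = object$parent, child = object$child)
  seg <- dplyr::left_join(seg, lay, by = c(parent = "node"))
  seg <- dplyr::left_join(seg, lay, by = c(child = "node"),
                          suffix = c("", "_c"))
  # the second in-edge of a reticulation child is drawn as the hybrid arc
  seg$hybrid <- duplicated(seg$child)
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$x_c,
                   yend = .data$y_c, linetype = .data$hybrid),
      show.legend = FALSE) +
    ggplot2::geom_point(
      data = lay[lay$reticulation, ],
      ggplot2::aes(x = .data$x, y = .data$y), shape = 21, fill = "white") +
    ggplot2::geom_text(
      data = lay[lay$leaf, ],
      ggplot2::aes(x = .data$x, y = .data$y, label = .data$node),
      vjust = 1.4) +
    ggplot2::scale_linetype_manual(values = c(`FALSE` = "solid",
                                              `TRUE` = "dashed")) +
    ggplot2::theme_void()
}

#' @rdname autoplot.phylo_net
#' @export
autoplot.tripnet <- function(object, ...) {
  autoplot.phylo_net(object$network) +
    ggplot2::labs(
      title = sprintf("%d reticulation(s), level %d, %.0f%% of triplets consistent",
                      object$n_reticulations, object$level,
                      100 * mean(object$consistent)))
}

#' @export
plot.phylo_net <- function(x, ...) print(autoplot.phylo_net(x))

#' @export
plot.tripnet <- function(x, ...) print(autoplot.tripnet(x))
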