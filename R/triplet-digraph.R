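#' @importFrom rlang .data
NULL

# canonical key for an unordered taxon pair
pair_key <- function(i, j) {
  paste(pmin(i, j), pmax(i, j), sep = "\r")
}

pair_key_split <- function(keys) {
  if (length(keys) == 0) {
    return(matrix(character(), ncol = 2,
                  dimnames = list(NULL, c("taxon1", "taxon2"))))
  }
  m <- do.call(rbind, strsplit(keys, "\r", fixed = TRUE))
  colnames(m) <- c("taxon1", "taxon2")
  m
}

all_pair_keys <- function(taxa) {
  taxa <- sort(taxa)
  if (length(taxa) < 2) return(character())
  as.vector(utils::combn(taxa, 2, paste, collapse = "\r"))
}

#' Directed graph on taxon pairs induced by a triplet set
#'
#' The node set is every unordered pair of taxa of `ts` (pairs occurring in
#' no triplet are kept as isolated nodes). Each triplet `ij|k` contributes
#' the arcs `ij -> ik` and `ij -> jk`: the cherry pair must sit strictly
#' lower than both mixed pairs in any realizing tree or network, and the
#' acyclicity of this digraph is exactly feasibility of the height
#' constraint system (see [ip_min_s()]).
#'
#' @param ts A triplet tibble.
#' @param taxa Taxon universe; defaults to `leaf_set(ts)` but may be a
#'   superset (extra taxa contribute isolated pair nodes).
#' @return An object of class `triplet_digraph`: list with `nodes`
#'   (pair keys), `arcs` (two-column character matrix `from`/`to`,
#'   deduplicated) and `taxa`.
#' @export
build_triplet_digraph <- function(ts, taxa = leaf_set(ts)) {
  if (!all(leaf_set(ts) %in% taxa)) stop("taxa must cover the triplet labels")
  taxa <- sort(taxa)
  if (length(taxa) < 3) stop("need at least 3 taxa")
  from <- rep(pair_key(ts$cherry1, ts$cherry2), 2L)
  to <- c(pair_key(ts$cherry1, ts$outgroup), pair_key(ts$cherry2, ts$outgroup))
  arcs <- unique(cbind(from = from, to = to))
  arcs <- arcs[order(arcs[, 1], arcs[, 2]), , drop = FALSE]
  structure(list(nodes = all_pair_keys(taxa), arcs = arcs, taxa = taxa),
            class = "triplet_digraph")
}

#' @export
print.triplet_digraph <- function(x, ...) {
  cat("triplet digraph: ", length(x$nodes), " pair nodes, ",
      nrow(x$arcs), " arcs on ", length(x$taxa), " taxa\n", sep = "")
  invisible(x)
}

digraph_igraph <- function(g) {
  igraph::graph_from_data_frame(
    as.data.frame(g$arcs, stringsAsFactors = FALSE),
    directed = TRUE,
    vertices = data.frame(name = g$nodes, stringsAsFactors = FALSE)
  )
}

#' Is the pair digraph acyclic?
#'
#' @param g A `triplet_digraph`.
#' @return Logical scalar.
#' @export
is_dag <- function(g) {
  if (nrow(g$arcs) == 0) return(TRUE)
  igraph::is_dag(digraph_igraph(g))
}

# adjacency list (sorted successors) keyed by node
digraph_adj <- function(g) {
  adj <- split(g$arcs[, "to"], factor(g$arcs[, "from"], levels = g$nodes))
  lapply(adj, sort)
}

# Shortest directed cycle, deterministically: nodes are scanned in
# lexicographic order, a BFS from each gives the shortest cycle through it,
# and the globally shortest (first scanned on ties) wins. NULL when acyclic.
# Returned as the node sequence (v1, ..., vm) with an arc vm -> v1.
find_cycle <- function(g) {
  adj <- digraph_adj(g)
  preds <- split(g$arcs[, "from"], factor(g$arcs[, "to"], levels = g$nodes))
  best <- NULL
  for (u in g$nodes) {
    if (!is.null(best) && length(best) == 2) break
    dist <- stats::setNames(rep(NA_integer_, length(g$nodes)), g$nodes)
    par <- stats::setNames(rep(NA_character_, length(g$nodes)), g$nodes)
    dist[u] <- 0L
    queue <- u
    while (length(queue)) {
      x <- queue[1]; queue <- queue[-1]
      for (w in adj[[x]]) {
        if (is.na(dist[w])) {
          dist[w] <- dist[x] + 1L
          par[w] <- x
          queue <- c(queue, w)
        }
      }
    }
    back <- sort(preds[[u]])
    back <- back[!is.na(dist[back])]
    if (length(back) == 0) next
    len <- dist[back] + 1L
    w <- back[len == min(len)][1]
    if (is.null(best) || min(len) < length(best)) {
      path <- w
      while (path[1] != u) path <- c(par[path[1]], path)
      best <- path
    }
  }
  best
}

#' Heuristic feedback-arc removal
#'
#' Repeatedly finds a shortest directed cycle (ties broken by scanning
#' nodes lexicographically), takes the cycle nodes of maximum total degree
#' in the current graph, and removes the lexicographically smallest cycle
#' arc entering one of them, until the graph is acyclic. An arc into a
#' high-degree pair node encodes a constraint pushing that pair upward, so
#' deleting it deflates the longest paths touching the busiest pair while
#' discarding a single triplet's worth of information. Idempotent on DAGs;
#' the information lost here is recaptured by the final patching step of
#' [tripnet()].
#'
#' @param g A `triplet_digraph`.
#' @param seed Unused; kept for interface stability (every choice is
#'   determinized lexicographically).
#' @return An acyclic `triplet_digraph` whose arc set is a subset of the
#'   input's, with attribute `removed` (matrix of removed arcs).
#' @export
feedback_arc_removal <- function(g, seed = 1L) {
  removed <- g$arcs[0, , drop = FALSE]
  repeat {
    cyc <- find_cycle(g)
    if (is.null(cyc)) break
    deg <- table(factor(c(g$arcs[, "from"], g$arcs[, "to"]), levels = g$nodes))
    cmax <- cyc[deg[cyc] == max(deg[cyc])]
    m <- length(cyc)
    cyc_arcs <- cbind(from = cyc, to = cyc[c(seq_len(m)[-1], 1)])
    cand <- cyc_arcs[cyc_arcs[, "to"] %in% cmax, , drop = FALSE]
    cand <- cand[order(cand[, "from"], cand[, "to"]), , drop = FALSE]
    kill <- cand[1, ]
    keep <- !(g$arcs[, "from"] == kill["from"] & g$arcs[, "to"] == kill["to"])
    removed <- rbind(removed, g$arcs[!keep, , drop = FALSE])
    g$arcs <- g$arcs[keep, , drop = FALSE]
  }
  attr(g, "removed") <- removed
  g
}

# longest path length starting at each node (DAG dynamic programming)
longest_from <- function(g) {
  f <- stats::setNames(rep(0L, length(g$nodes)), g$nodes)
  if (nrow(g$arcs) > 0) {
    ig <- digraph_igraph(g)
    ord <- rev(names(igraph::topo_sort(ig, mode = "out")))
    adj <- digraph_adj(g)
    for (u in ord) {
      s <- adj[[u]]
      if (length(s)) f[u] <- 1L + max(f[s])
    }
  }
  f
}

new_height_tbl <- function(keys, values, ceiling) {
  m <- pair_key_split(keys)
  tb <- tibble::tibble(taxon1 = m[, "taxon1"], taxon2 = m[, "taxon2"],
                       height = as.integer(values))
  tb <- dplyr::arrange(tb, .data$taxon1, .data$taxon2)
  attr(tb, "ceiling") <- as.integer(ceiling)
  class(tb) <- c("height_tbl", class(tibble::tibble()))
  tb
}

# named integer vector keyed by pair key
height_lookup <- function(h) {
  stats::setNames(h$height, pair_key(h$taxon1, h$taxon2))
}

#' Layered height function of an acyclic pair digraph
#'
#' Peels sink nodes layer by layer: with `l` the longest directed path
#' length, sinks (and isolated pairs) receive height `l + 1`, and each
#' node receives `l + 1` minus the longest path length starting at it.
#'
#' @param g An acyclic `triplet_digraph`.
#' @return A height tibble (`taxon1`, `taxon2`, `height`) with attribute
#'   `ceiling = l + 1`; heights lie in `1..ceiling`.
#' @export
height_from_digraph <- function(g) {
  if (!is_dag(g)) stop("pair digraph has a directed cycle; remove feedback arcs first")
  f <- longest_from(g)
  l <- max(f)
  new_height_tbl(g$nodes, l + 1L - f, l + 1L)
}

#' Minimum feasible ceiling of the height constraint system
#'
#' The constraint system on integer pair heights has, for every triplet
#' `ij|k`, the rows `h(i,j) + 1 <= h(i,k)` and `h(i,j) + 1 <= h(j,k)`,
#' with `1 <= h <= s`. It is feasible for some `s` iff the pair digraph is
#' acyclic, and the minimum feasible `s` is then the longest path length
#' of the digraph plus one; the layered height function attains it and
#' pointwise dominates every feasible solution.
#'
#' @param ts A triplet tibble.
#' @return The minimal feasible ceiling as an integer, or `Inf` when the
#'   system is infeasible (cyclic digraph).
#' @export
ip_min_s <- function(ts) {
  g <- build_triplet_digraph(ts)
  if (!is_dag(g)) return(Inf)
  max(longest_from(g)) + 1L
}

#' Verify that a height function is the dominant optimum
#'
#' Checks that `h` is feasible for the constraint system of `ts` at
#' ceiling `l + 1` and equals the layered height function of the pair
#' digraph (which pointwise dominates every feasible solution).
#'
#' @param ts A triplet tibble.
#' @param h A height tibble.
#' @return Logical scalar.
#' @export
verify_optimal_height <- function(ts, h) {
  g <- build_triplet_digraph(ts)
  if (!is_dag(g)) stop("pair digraph is cyclic; no feasible height function exists")
  hv <- height_lookup(h)
  if (!setequal(names(hv), g$nodes)) return(FALSE)
  s <- max(longest_from(g)) + 1L
  if (any(hv < 1L) || any(hv > s)) return(FALSE)
  ij <- pair_key(ts$cherry1, ts$cherry2)
  ik <- pair_key(ts$cherry1, ts$outgroup)
  jk <- pair_key(ts$cherry2, ts$outgroup)
  if (any(hv[ij] + 1L > hv[ik]) || any(hv[ij] + 1L > hv[jk])) return(FALSE)
  opt <- height_lookup(height_from_digraph(g))
  all(hv[names(opt)] == opt)
}
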