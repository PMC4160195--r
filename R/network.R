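#' Rooted phylogenetic trees and networks as edge lists
#'
#' A `phylo_net` is a rooted directed acyclic graph stored as a
#' parent/child edge list with character node ids. Leaves are the nodes of
#' outdegree zero and their ids are the taxon labels; internal node ids are
#' arbitrary. The same class carries both trees (no indegree-2 nodes,
#' internal outdegree possibly > 2) and binary networks obeying the degree
#' rules checked by [validate_network()].
#'
#' @param edges Two-column matrix or data frame (`parent`, `child`) of node
#'   ids.
#' @param nodes Optional character vector of all node ids, allowing
#'   isolated single-node graphs; defaults to the ids appearing in `edges`.
#' @return An object of class `phylo_net`.
#' @export
phylo_net <- function(edges, nodes = NULL) {
  edges <- if (is.null(edges)) matrix(character(), 0, 2) else as.matrix(edges)
  if (length(edges) == 0) {
    parent <- child <- character()
  } else {
    parent <- as.character(edges[, 1])
    child <- as.character(edges[, 2])
  }
  if (is.null(nodes)) nodes <- c(parent, child)
  structure(list(parent = parent, child = child, nodes = sort(unique(nodes))),
            class = "phylo_net")
}

#' @export
print.phylo_net <- function(x, ...) {
  idx <- pn_index(x)
  kind <- if (sum(idx$indeg >= 2) == 0) "tree" else "network"
  cat("phylo_net ", kind, ": ", length(idx$leaves), " leaves, ",
      length(x$nodes), " nodes, ", sum(idx$indeg >= 2), " reticulation(s)\n",
      sep = "")
  cat(to_enewick(x), "\n")
  invisible(x)
}

#' Edge table of a tree or network
#'
#' @param N A `phylo_net`.
#' @return A tibble with `parent` and `child` columns.
#' @export
network_edges <- function(N) {
  tibble::tibble(parent = N$parent, child = N$child)
}

#' Leaf labels of a tree or network
#'
#' @param N A `phylo_net`.
#' @return Sorted character vector of leaf (outdegree-0 node) labels.
#' @export
network_leaves <- function(N) {
  idx <- pn_index(N)
  sort(idx$nodes[idx$leaves])
}

# Integer-indexed view of a phylo_net: adjacency, degrees, root, longest-path
# depths from the root, and the full reachability matrix (reach[u, v] is TRUE
# iff there is a directed path u -> v; reach[u, u] is TRUE).
pn_index <- function(N) {
  nodes <- N$nodes
  n <- length(nodes)
  pid <- match(N$parent, nodes)
  cid <- match(N$child, nodes)
  children <- lapply(split(cid, factor(pid, levels = seq_len(n))), unname)
  parents <- lapply(split(pid, factor(cid, levels = seq_len(n))), unname)
  outdeg <- lengths(children)
  indeg <- lengths(parents)
  # Kahn topological order
  topo <- integer(0)
  rem <- indeg
  queue <- which(rem == 0L)
  while (length(queue)) {
    u <- queue[1]
    queue <- queue[-1]
    topo <- c(topo, u)
    for (w in children[[u]]) {
      rem[w] <- rem[w] - 1L
      if (rem[w] == 0L) queue <- c(queue, w)
    }
  }
  acyclic <- length(topo) == n
  reach <- diag(n) > 0
  depth <- rep(-Inf, n)
  root <- which(indeg == 0L)
  if (acyclic) {
    for (u in rev(topo)) {
      for (w in children[[u]]) reach[u, ] <- reach[u, ] | reach[w, ]
    }
    depth[root] <- 0
    for (u in topo) {
      for (w in children[[u]]) depth[w] <- max(depth[w], depth[u] + 1)
    }
  }
  list(nodes = nodes, n = n, children = children, parents = parents,
       indeg = indeg, outdeg = outdeg, root = root,
       leaves = which(outdeg == 0L), topo = topo, acyclic = acyclic,
       reach = reach, depth = depth)
}

#' Check the structural invariants of a rooted phylogenetic network
#'
#' A valid binary network has a unique indegree-0 root of outdegree 2,
#' every other node with (in, out) degree (1, 2), (2, 1) or (1, 0), an
#' acyclic edge relation without parallel edges, and every node reachable
#' from the root.
#'
#' @param N A `phylo_net`.
#' @return Character vector of human-readable violations; empty when valid.
#' @export
validate_network <- function(N) {
  idx <- pn_index(N)
  v <- character()
  if (anyDuplicated(paste(N$parent, N$child))) v <- c(v, "parallel edges present")
  if (!idx$acyclic) {
    return(c(v, "graph contains a directed cycle"))
  }
  roots <- which(idx$indeg == 0L)
  if (length(roots) != 1) {
    v <- c(v, sprintf("expected exactly 1 indegree-0 node, found %d", length(roots)))
  } else {
    if (idx$n > 1 && idx$outdeg[roots] != 2) {
      v <- c(v, sprintf("root '%s' has outdegree %d, expected 2",
                        idx$nodes[roots], idx$outdeg[roots]))
    }
    if (any(!idx$reach[roots, ])) {
      v <- c(v, "some nodes are unreachable from the root")
    }
  }
  others <- setdiff(seq_len(idx$n), roots)
  for (u in others) {
    di <- idx$indeg[u]; do <- idx$outdeg[u]
    ok <- (di == 2 && do == 1) || (di == 1 && do == 2) || (di == 1 && do == 0)
    if (!ok) {
      v <- c(v, sprintf("node '%s' has (in, out) = (%d, %d)",
                        idx$nodes[u], di, do))
    }
  }
  v
}

#' Count reticulation nodes
#'
#' @param N A `phylo_net`.
#' @return Number of indegree-2 nodes.
#' @export
reticulation_count <- function(N) {
  sum(pn_index(N)$indeg >= 2)
}

#' Level of a network
#'
#' The level is the maximum number of reticulation nodes inside any
#' biconnected component of the underlying undirected graph; a tree is
#' level 0.
#'
#' @param N A valid `phylo_net` (see [validate_network()]).
#' @return Integer level.
#' @export
network_level <- function(N) {
  viol <- validate_network(N)
  if (length(viol)) stop("invalid network: ", viol[1])
  idx <- pn_index(N)
  retic <- which(idx$indeg >= 2)
  if (length(retic) == 0) return(0L)
  g <- igraph::graph_from_data_frame(
    data.frame(from = N$parent, to = N$child, stringsAsFactors = FALSE),
    directed = FALSE)
  bc <- igraph::biconnected_components(g)
  edge_key <- paste(N$parent, N$child)
  best <- 0L
  for (comp in bc$component_edges) {
    ends <- igraph::ends(g, comp)
    keys <- c(paste(ends[, 1], ends[, 2]), paste(ends[, 2], ends[, 1]))
    # reticulations whose two in-edges both lie in this component
    k <- 0L
    for (r in retic) {
      rn <- idx$nodes[r]
      inkeys <- paste(idx$nodes[idx$parents[[r]]], rn)
      if (all(inkeys %in% keys)) k <- k + 1L
    }
    best <- max(best, k)
  }
  best
}

#' Height function of a tree or network
#'
#' With `l_N` the longest root-to-leaf path length and `d(r, u)` the
#' longest-path depth of `u`, the height of a leaf pair `(i, j)` is the
#' minimum of `l_N - d(r, c)` over the lowest common ancestors `c` of `i`
#' and `j` (ancestors from which no lower common ancestor is reachable).
#' For a tree this reduces to `l_T` minus the depth of the unique LCA.
#'
#' @param N A `phylo_net` (arbitrary degrees are tolerated; only acyclicity
#'   and a unique root are required).
#' @return A height tibble (`taxon1`, `taxon2`, `height`) with attributes
#'   `ceiling` (`= l_N`) and `l` (the same), covering all leaf pairs.
#' @export
network_height_function <- function(N) {
  idx <- pn_index(N)
  if (!idx$acyclic) stop("graph contains a directed cycle")
  if (length(idx$root) != 1) stop("graph must have a unique root")
  lv <- idx$leaves
  lN <- max(idx$depth[lv])
  m <- length(lv)
  keys <- character()
  vals <- integer()
  for (a in seq_len(m - 1)) {
    for (b in (a + 1):m) {
      i <- lv[a]; j <- lv[b]
      ca <- which(idx$reach[, i] & idx$reach[, j])
      # lowest common ancestors: no other common ancestor reachable from them
      low <- ca[vapply(ca, function(u) !any(idx$reach[u, setdiff(ca, u)]),
                       logical(1))]
      keys <- c(keys, pair_key(idx$nodes[i], idx$nodes[j]))
      vals <- c(vals, min(lN - idx$depth[low]))
    }
  }
  h <- new_height_tbl(keys, vals, lN)
  attr(h, "l") <- as.integer(lN)
  h
}

# all directed paths u -> v (as integer node sequences); DAG so all simple
enumerate_paths <- function(idx, u, v, max_paths = 10000L) {
  out <- list()
  walk <- function(path) {
    last <- path[length(path)]
    if (last == v) {
      out[[length(out) + 1L]] <<- path
      return()
    }
    for (w in idx$children[[last]]) {
      if (idx$reach[w, v]) walk(c(path, w))
    }
    if (length(out) > max_paths) stop("path enumeration limit exceeded")
  }
  walk(u)
  out
}

# Are there two internally node-disjoint directed paths u -> i and u -> j
# avoiding the node set `avoid` entirely? Unit-node-capacity max flow on the
# split graph, needing flow value 2 (at most two BFS augmentations).
two_disjoint_paths <- function(idx, u, i, j, avoid = integer()) {
  n <- idx$n
  if (length(avoid) && (u %in% avoid || i %in% avoid || j %in% avoid)) return(FALSE)
  # split node w -> (w_in = w, w_out = w + n); supersink = 2n + 1
  nn <- 2L * n + 1L
  cap <- matrix(0L, nn, nn)
  free <- rep(1L, n)
  if (length(avoid)) free[avoid] <- 0L
  for (w in seq_len(n)) cap[w, w + n] <- free[w]
  for (p in seq_len(n)) {
    for (w in idx$children[[p]]) cap[p + n, w] <- cap[p + n, w] + 1L
  }
  # flow starts at u_out (u's own capacity exempt) and terminates at the
  # in-halves of i and j, so their capacities are irrelevant
  cap[i, nn] <- 1L
  cap[j, nn] <- 1L
  src <- u + n
  flow <- 0L
  repeat {
    prev <- rep(NA_integer_, nn)
    prev[src] <- src
    queue <- src
    while (length(queue) && is.na(prev[nn])) {
      x <- queue[1]; queue <- queue[-1]
      nxt <- which(cap[x, ] > 0L & is.na(prev))
      prev[nxt] <- x
      queue <- c(queue, nxt)
    }
    if (is.na(prev[nn])) break
    x <- nn
    while (x != src) {
      p <- prev[x]
      cap[p, x] <- cap[p, x] - 1L
      cap[x, p] <- cap[x, p] + 1L
      x <- p
    }
    flow <- flow + 1L
    if (flow >= 2L) return(TRUE)
  }
  FALSE
}

# nodes reachable from u when the node set `avoid` is deleted
reachable_avoiding <- function(idx, u, avoid) {
  seen <- rep(FALSE, idx$n)
  if (u %in% avoid) return(seen)
  seen[u] <- TRUE
  queue <- u
  while (length(queue)) {
    x <- queue[1]; queue <- queue[-1]
    for (w in idx$children[[x]]) {
      if (!seen[w] && !(w %in% avoid)) {
        seen[w] <- TRUE
        queue <- c(queue, w)
      }
    }
  }
  seen
}

# Exact decision: does N display the triplet ij|k, i.e. do there exist
# distinct nodes u, v with pairwise internally node-disjoint paths
# u -> i, u -> j, v -> u, v -> k?  In a DAG the v -> u path is automatically
# internally disjoint from the u -> i / u -> j paths (its inner nodes are
# ancestors of u, theirs are descendants), so the search reduces to: choose
# v and a path P: v -> k, then ask for a v -> u path and two disjoint
# u -> {i, j} paths all avoiding P's interior.
tc_decide <- function(idx, i, j, k) {
  ucand <- which(idx$reach[, i] & idx$reach[, j] & idx$outdeg >= 2)
  ucand <- ucand[ucand != i & ucand != j]
  ucand <- ucand[vapply(ucand, function(u) two_disjoint_paths(idx, u, i, j),
                        logical(1))]
  if (length(ucand) == 0) return(FALSE)
  vcand <- which(idx$reach[, k] & idx$outdeg >= 2)
  vcand <- vcand[vapply(vcand, function(v) any(idx$reach[v, ucand] &
                                                 ucand != v), logical(1))]
  for (v in vcand) {
    paths <- enumerate_paths(idx, v, k)
    for (P in paths) {
      interior <- P[-c(1, length(P))]
      if (length(interior)) {
        ok_u <- reachable_avoiding(idx, v, interior)
      } else {
        ok_u <- idx$reach[v, ]
      }
      for (u in ucand) {
        if (u == v || !ok_u[u] || (u %in% interior)) next
        if (two_disjoint_paths(idx, u, i, j, avoid = interior)) return(TRUE)
      }
    }
  }
  FALSE
}

#' Exact triplet consistency on a network
#'
#' Decides for each triplet `ij|k` whether the network contains a
#' subdivision of it: distinct nodes `u`, `v` with pairwise internally
#' node-disjoint paths `u -> i`, `u -> j`, `v -> u`, `v -> k`. The
#' decision is exact; a sufficient height-function criterion (strict
#' inequality of pair heights) short-circuits the search when
#' `use_heights = TRUE`.
#'
#' @param N A `phylo_net`.
#' @param ts A triplet tibble (all labels must be leaves of `N`).
#' @param use_heights Use the height-function sufficient condition as a
#'   fast accept before the exact search?
#' @return Logical vector, one entry per triplet of `ts`.
#' @export
triplet_consistent <- function(N, ts, use_heights = TRUE) {
  ts <- as_triplets(ts)
  idx <- pn_index(N)
  labs <- idx$nodes[idx$leaves]
  miss <- setdiff(leaf_set(ts), labs)
  if (length(miss)) stop("labels not among network leaves: ",
                         paste(miss, collapse = ", "))
  if (nrow(ts) == 0) return(logical())
  res <- rep(NA, nrow(ts))
  if (use_heights && nrow(ts) > 0) {
    hv <- height_lookup(network_height_function(N))
    hij <- hv[pair_key(ts$cherry1, ts$cherry2)]
    hik <- hv[pair_key(ts$cherry1, ts$outgroup)]
    hjk <- hv[pair_key(ts$cherry2, ts$outgroup)]
    res[hij < hik | hij < hjk] <- TRUE
  }
  todo <- which(is.na(res))
  ii <- match(ts$cherry1, idx$nodes)
  jj <- match(ts$cherry2, idx$nodes)
  kk <- match(ts$outgroup, idx$nodes)
  for (r in todo) res[r] <- tc_decide(idx, ii[r], jj[r], kk[r])
  res
}

#' All triplets consistent with a network
#'
#' Enumerates every 3-subset of the leaves and every cherry choice,
#' keeping the consistent ones; for a binary tree the result is dense with
#' exactly one triplet per 3-subset.
#'
#' @param N A `phylo_net` with at least 3 leaves.
#' @return A triplet tibble.
#' @export
consistent_triplet_set <- function(N) {
  labs <- network_leaves(N)
  if (length(labs) < 3) stop("need at least 3 leaves")
  trio <- utils::combn(labs, 3)
  cand <- triplets(
    cherry1 = c(trio[1, ], trio[1, ], trio[2, ]),
    cherry2 = c(trio[2, ], trio[3, ], trio[3, ]),
    outgroup = c(trio[3, ], trio[2, ], trio[1, ])
  )
  cand[triplet_consistent(N, cand), , drop = FALSE] |> as_triplets()
}

#' Are two networks isomorphic (respecting leaf labels)?
#'
#' Directed VF2 isomorphism with leaves colored by label and internal
#' nodes interchangeable.
#'
#' @param a,b `phylo_net` objects.
#' @return Logical scalar.
#' @export
network_isomorphic <- function(a, b) {
  la <- network_leaves(a); lb <- network_leaves(b)
  if (!identical(la, lb)) return(FALSE)
  if (length(a$parent) != length(b$parent)) return(FALSE)
  mkg <- function(N) {
    igraph::graph_from_data_frame(
      data.frame(from = N$parent, to = N$child, stringsAsFactors = FALSE),
      directed = TRUE,
      vertices = data.frame(name = N$nodes, stringsAsFactors = FALSE))
  }
  col <- function(N) {
    ifelse(N$nodes %in% la, match(N$nodes, la), 0L)
  }
  igraph::is_isomorphic_to(mkg(a), mkg(b), method = "vf2",
                           vertex.color1 = col(a), vertex.color2 = col(b))
}

fresh_ids <- function(prefix, k, used) {
  out <- character(0)
  i <- 1L
  while (length(out) < k) {
    cand <- paste0(prefix, i)
    if (!(cand %in% used)) out <- c(out, cand)
    i <- i + 1L
  }
  out
}

# replace edge (p, c) by a path p -> v1 -> ... -> vm -> c
subdivide_edge <- function(N, p, c, new_ids) {
  hit <- which(N$parent == p & N$child == c)
  if (length(hit) == 0) stop("no such edge: ", p, " -> ", c)
  hit <- hit[1]
  N$parent <- N$parent[-hit]
  N$child <- N$child[-hit]
  chain <- c(p, new_ids, c)
  N$parent <- c(N$parent, chain[-length(chain)])
  N$child <- c(N$child, chain[-1])
  N$nodes <- sort(unique(c(N$nodes, new_ids)))
  N
}

add_arc <- function(N, from, to) {
  N$parent <- c(N$parent, from)
  N$child <- c(N$child, to)
  N$nodes <- sort(unique(c(N$nodes, from, to)))
  N
}

# drop duplicate arcs, then splice out indegree-1/outdegree-1 nodes
suppress_unary <- function(N) {
  repeat {
    keep <- !duplicated(paste(N$parent, N$child, sep = "\r"))
    N$parent <- N$parent[keep]
    N$child <- N$child[keep]
    N$nodes <- sort(unique(c(N$parent, N$child)))
    indeg <- table(factor(N$child, levels = N$nodes))
    outdeg <- table(factor(N$parent, levels = N$nodes))
    un <- N$nodes[indeg == 1 & outdeg == 1]
    if (length(un) == 0) return(N)
    u <- un[1]
    p <- N$parent[N$child == u]
    c <- N$child[N$parent == u]
    drop <- (N$child == u) | (N$parent == u)
    N$parent <- c(N$parent[!drop], p)
    N$child <- c(N$child[!drop], c)
  }
}

# split children of over-branching nodes into binary cherries; children are
# grouped first-(k-1) under a fresh node, ordered by smallest descendant leaf
binarize_node_children <- function(N) {
  repeat {
    idx <- pn_index(N)
    fat <- which(idx$outdeg > 2)
    if (length(fat) == 0) return(N)
    u <- fat[1]
    kids <- idx$children[[u]]
    minlab <- vapply(kids, function(w) min(idx$nodes[idx$leaves[idx$reach[w, idx$leaves]]]),
                     character(1))
    kids <- kids[order(minlab)]
    y <- fresh_ids("b", 1L, N$nodes)
    first <- idx$nodes[kids[seq_len(length(kids) - 1L)]]
    un <- idx$nodes[u]
    drop <- N$parent == un & N$child %in% first
    N$parent <- c(N$parent[!drop], un, rep(y, length(first)))
    N$child <- c(N$child[!drop], y, first)
    N$nodes <- sort(unique(c(N$nodes, y)))
  }
}

#' Construct a network realizing a height function (shifted by one)
#'
#' Builds the meeting-point construction: every pair whose height is below
#' the maximum gets a fresh node joining its two taxa, hung under the root
#' at depth `h_max - h`; maximal-height pairs are joined only at the root.
#' The raw object (`normalize = FALSE`) has `h_N = h + 1` exactly but
#' arbitrary degrees; normalization collapses parallel arcs, suppresses
#' unary nodes, replaces fan-in nodes by chains of indegree-2 nodes and
#' binarizes over-branching nodes, yielding a valid network whose
#' consistent triplet set contains that of the raw construction.
#'
#' @param h A height tibble covering all pairs of `X`.
#' @param X Character vector of taxa.
#' @param normalize Return the valid binary network (default) or the raw
#'   construction?
#' @return A `phylo_net`.
#' @export
network_from_height <- function(h, X, normalize = TRUE) {
  X <- sort(as.character(X))
  if (length(X) < 2) stop("need at least 2 taxa")
  hv <- height_lookup(h)
  need <- all_pair_keys(X)
  if (!all(need %in% names(hv))) stop("height function must cover all pairs of X")
  hmax <- max(hv[need])
  parent <- child <- character()
  ctr <- 0L
  path_to <- function(from, to, len) {
    # path of `len` edges from `from` to `to` through fresh inner nodes
    inner <- if (len > 1) paste0("q", ctr + seq_len(len - 1L)) else character()
    ctr <<- ctr + max(0L, len - 1L)
    chain <- c(from, inner, to)
    parent <<- c(parent, chain[-length(chain)])
    child <<- c(child, chain[-1])
  }
  prime <- function(x) paste0("p_", x)
  for (key in need) {
    pr <- pair_key_split(key)
    xi <- pr[1, 1]; xj <- pr[1, 2]
    hij <- hv[[key]]
    if (hij == hmax) {
      path_to("r", prime(xi), hmax)
      path_to("r", prime(xj), hmax)
    } else {
      ctr <- ctr + 1L
      m <- paste0("m", ctr)
      path_to("r", m, hmax - hij)
      parent <- c(parent, m, m)
      child <- c(child, prime(xi), prime(xj))
    }
  }
  parent <- c(parent, prime(X))
  child <- c(child, X)
  N <- phylo_net(cbind(parent, child))
  if (!normalize) return(N)
  N <- suppress_unary(N)
  # fan-in replacement: indegree-d (d > 2) nodes become chains of
  # indegree-2 nodes feeding the single child
  repeat {
    idx <- pn_index(N)
    fat <- which(idx$indeg > 2)
    if (length(fat) == 0) break
    u <- fat[1]
    un <- idx$nodes[u]
    if (idx$outdeg[u] != 1) stop("fan-in node with outdegree != 1")
    par <- sort(idx$nodes[idx$parents[[u]]])
    ch <- idx$nodes[idx$children[[u]]]
    d <- length(par)
    w <- fresh_ids("f", d - 2L, N$nodes)
    drop <- (N$child == un & N$parent %in% par[-(1:2)]) | (N$parent == un & N$child == ch)
    N$parent <- N$parent[!drop]
    N$child <- N$child[!drop]
    chain <- c(un, w, ch)
    N$parent <- c(N$parent, chain[-length(chain)], par[-(1:2)])
    N$child <- c(N$child, chain[-1], w)
    N$nodes <- sort(unique(c(N$nodes, w)))
  }
  N <- binarize_node_children(N)
  suppress_unary(N)
}
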