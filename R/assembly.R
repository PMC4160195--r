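safe_prefix <- function(taxa, base = "v") {
  p <- base
  while (any(grepl(paste0("^", p, "[0-9]+$"), taxa))) p <- paste0(p, "v")
  p
}

# project triplets on original leaves onto a partition given as a named list
# (block name -> leaf set); triplets landing in three distinct blocks survive
project_triplets <- function(ts, blockmap) {
  of <- stats::setNames(rep(names(blockmap), lengths(blockmap)),
                        unlist(blockmap))
  present <- ts$cherry1 %in% names(of) & ts$cherry2 %in% names(of) &
    ts$outgroup %in% names(of)
  ts <- ts[present, , drop = FALSE]
  b1 <- of[ts$cherry1]; b2 <- of[ts$cherry2]; b3 <- of[ts$outgroup]
  keep <- b1 != b2 & b1 != b3 & b2 != b3
  triplets(b1[keep], b2[keep], b3[keep])
}

#' Insert reticulation leaves into a tree (Step 6)
#'
#' Leaves removed during the decomposition loop are re-attached in reverse
#' removal order. For each leaf, every unordered pair of distinct edges of
#' the current network is tried: both edges are subdivided and the two new
#' nodes feed a fresh reticulation node whose single child is the leaf;
#' the pair maximizing the number of consistent context triplets wins
#' (first pair in the deterministic edge enumeration on ties).
#'
#' @param T A binary `phylo_net` tree (or network from earlier insertions).
#' @param leaves Character vector of leaf names in removal order (the last
#'   removed is inserted first).
#' @param ts_context Triplet tibble used for scoring, expressed over
#'   original leaves.
#' @param leafmap Optional named list mapping the names of `T`'s leaves
#'   and of `leaves` to original leaf sets (identity by default); the
#'   scoring context is `ts_context` projected onto the present blocks.
#' @return A `phylo_net` network containing all inserted leaves.
#' @export
insert_reticulation_leaves <- function(T, leaves, ts_context,
                                       leafmap = NULL) {
  N <- T
  if (length(leaves) == 0) return(N)
  if (is.null(leafmap)) {
    all_named <- c(network_leaves(T), leaves)
    leafmap <- stats::setNames(as.list(all_named), all_named)
  }
  for (x in rev(leaves)) {
    present <- c(network_leaves(N), x)
    tau_ctx <- project_triplets(ts_context, leafmap[present])
    N <- insert_one_leaf(N, x, tau_ctx)
  }
  N
}

insert_one_leaf <- function(N, x, tau_ctx) {
  if (length(N$parent) == 0) {
    # single-node network: join under a fresh root
    r <- fresh_ids("v", 1L, c(N$nodes, x))
    return(phylo_net(rbind(c(r, N$nodes[1]), c(r, x))))
  }
  ord <- order(N$parent, N$child)
  ep <- N$parent[ord]; ec <- N$child[ord]
  ne <- length(ep)
  ids <- fresh_ids("y", 3L, c(N$nodes, x))
  best <- NULL; best_score <- -1L
  for (a in seq_len(ne - 1)) {
    for (b in (a + 1):ne) {
      cand <- subdivide_edge(N, ep[a], ec[a], ids[1])
      cand <- subdivide_edge(cand, ep[b], ec[b], ids[2])
      cand <- add_arc(cand, ids[1], ids[3])
      cand <- add_arc(cand, ids[2], ids[3])
      cand <- add_arc(cand, ids[3], x)
      score <- if (nrow(tau_ctx)) sum(triplet_consistent(cand, tau_ctx)) else 0L
      if (score > best_score) {
        best <- cand
        best_score <- score
        if (score == nrow(tau_ctx)) return(best)
      }
    }
  }
  best
}

#' Expand contracted blocks into their own networks (Steps 7-8)
#'
#' Each leaf of `N` standing for a multi-leaf block is replaced by the
#' root of the network built by running the full algorithm on the
#' triplets restricted to that block.
#'
#' @param N A `phylo_net` whose leaves are block names.
#' @param blockmap Named list mapping each leaf of `N` to its original
#'   leaf set.
#' @param ts Triplet tibble over original leaves.
#' @param speed Passed through to the recursive runs.
#' @param log_env Internal diagnostics accumulator.
#' @return A `phylo_net` on the original leaves.
#' @export
recurse_and_expand <- function(N, blockmap, ts, speed = "slow",
                               log_env = NULL) {
  for (nm in network_leaves(N)) {
    B <- blockmap[[nm]]
    if (is.null(B)) stop("no block mapping for leaf '", nm, "'")
    if (length(B) == 1) {
      if (B != nm) N <- rename_node(N, nm, B)
      next
    }
    sub <- tripnet_solve(restrict_triplets(ts, B), sort(B), speed = speed,
                         log_env = log_env)
    N <- graft_subnetwork(N, nm, sub$network)
  }
  N
}

rename_node <- function(N, old, new) {
  N$parent[N$parent == old] <- new
  N$child[N$child == old] <- new
  N$nodes[N$nodes == old] <- new
  N$nodes <- sort(N$nodes)
  N
}

graft_subnetwork <- function(N, leaf, sub) {
  # namespace the sub-network's internal ids
  subleaves <- network_leaves(sub)
  internal <- setdiff(sub$nodes, subleaves)
  map <- stats::setNames(paste0(leaf, ":", internal), internal)
  rn <- function(x) ifelse(x %in% internal, map[x], x)
  if (length(sub$parent) == 0) stop("cannot graft a single-node network")
  sp <- rn(sub$parent); sc <- rn(sub$child)
  subroot <- setdiff(sp, sc)[1]
  p <- N$parent[N$child == leaf]
  keep <- N$child != leaf
  phylo_net(cbind(c(N$parent[keep], p, sp), c(N$child[keep], subroot, sc)))
}

#' Patch remaining inconsistencies with extra reticulations (Step 9)
#'
#' While some input triplet is not displayed by the network, the cherry
#' pair carrying the most inconsistent triplets has its two pendant edges
#' subdivided and joined by a new arc (tail on the lexicographically
#' smaller leaf's side, reversed if that fails to help), creating one
#' reticulation per iteration until every triplet is consistent.
#'
#' @param N A valid `phylo_net` whose leaves cover the triplet labels.
#' @param ts A triplet tibble.
#' @return A `phylo_net` consistent with every triplet of `ts`, with
#'   attribute `patched` counting the added reticulations.
#' @export
patch_inconsistent <- function(N, ts) {
  added <- 0L
  repeat {
    bad <- !triplet_consistent(N, ts)
    if (!any(bad)) break
    tsb <- ts[bad, , drop = FALSE]
    grp <- dplyr::count(tsb, .data$cherry1, .data$cherry2, sort = TRUE)
    grp <- dplyr::arrange(grp, dplyr::desc(.data$n), .data$cherry1,
                          .data$cherry2)
    n_bad <- nrow(tsb)
    improved <- FALSE
    for (gi in seq_len(nrow(grp))) {
      i <- grp$cherry1[gi]; j <- grp$cherry2[gi]
      for (orient in 1:2) {
        cand <- link_pendant(N, i, j, reverse = orient == 2)
        if (is.null(cand)) next
        left <- sum(!triplet_consistent(cand, ts))
        if (left < n_bad) {
          N <- cand
          added <- added + 1L
          improved <- TRUE
          break
        }
      }
      if (improved) break
    }
    if (!improved) stop("patching failed to reduce the inconsistent set")
  }
  attr(N, "patched") <- added
  N
}

# subdivide the pendant edges of leaves i and j and connect the new nodes
link_pendant <- function(N, i, j, reverse = FALSE) {
  ids <- fresh_ids("z", 2L, N$nodes)
  pi <- N$parent[N$child == i]
  pj <- N$parent[N$child == j]
  if (length(pi) != 1 || length(pj) != 1) return(NULL)
  cand <- subdivide_edge(N, pi, i, ids[1])
  cand <- subdivide_edge(cand, pj, j, ids[2])
  if (!reverse) add_arc(cand, ids[1], ids[2]) else add_arc(cand, ids[2], ids[1])
}

# full solver on an explicit taxon universe; returns list(network, retics,
# log). `log_env` accumulates diagnostic records across recursion levels.
tripnet_solve <- function(ts, taxa, speed = "slow", log_env = NULL) {
  taxa <- sort(taxa)
  n <- length(taxa)
  pre <- safe_prefix(taxa)
  if (n == 1) {
    return(list(network = phylo_net(NULL, nodes = taxa),
                retic_order = list()))
  }
  if (n == 2) {
    r <- paste0(pre, 1)
    return(list(network = phylo_net(rbind(c(r, taxa[1]), c(r, taxa[2]))),
                retic_order = list()))
  }
  g <- feedback_arc_removal(build_triplet_digraph(ts, taxa))
  h <- height_from_digraph(g)
  t0 <- hbuild(h, taxa)
  if (!is.null(t0)) {
    # conflicting triplets dropped by the feedback-arc step (if any) are
    # recaptured by patching, a no-op for tree-consistent input
    N <- patch_inconsistent(binarize(t0), ts)
    log_add(log_env, "step9", attr(N, "patched"))
    return(list(network = N, retic_order = list()))
  }
  state <- list(names = taxa,
                leafmap = stats::setNames(as.list(taxa), taxa),
                w = height_lookup(h), tau = ts,
                h_leaf = height_lookup(h), retic = list())
  solve_loop(state, ts, speed, log_env)
}

as_instance <- function(state) {
  structure(list(names = state$names,
                 blocks = stats::setNames(as.list(state$names), state$names),
                 leafmap = state$leafmap, tau = state$tau, w = state$w,
                 h_leaf = state$h_leaf),
            class = "sn_instance")
}

remove_name <- function(state, x) {
  state$retic <- c(state$retic, list(list(name = x,
                                          leaves = state$leafmap[[x]])))
  state$names <- setdiff(state$names, x)
  state$leafmap <- state$leafmap[state$names]
  state$w <- state$w[all_pair_keys(state$names)]
  tau <- state$tau
  keep <- tau$cherry1 != x & tau$cherry2 != x & tau$outgroup != x
  state$tau <- as_triplets(tau[keep, , drop = FALSE])
  state
}

log_add <- function(log_env, field, value) {
  if (is.null(log_env)) return(invisible())
  log_env[[field]] <- c(log_env[[field]], list(value))
  invisible()
}

# tree test inside the loop: the relaxed HBUILD tree on the current weights,
# accepted only when it displays every current triplet
loop_tree <- function(state) {
  if (length(state$names) == 1) return(phylo_net(NULL, nodes = state$names))
  t0 <- hbuild_lax(state$w, state$names)
  if (nrow(state$tau) == 0 || all(tree_consistent_triplet(t0, state$tau))) {
    t0
  } else {
    NULL
  }
}

solve_loop <- function(state, ts_orig, speed, log_env) {
  repeat {
    t0 <- loop_tree(state)
    if (!is.null(t0)) return(finish_steps(state, t0, ts_orig, speed, log_env))
    part <- sn_decompose(state$w, state$tau, state$names)
    log_add(log_env, "partitions",
            lapply(part, function(b) sort(unlist(state$leafmap[b]))))
    if (any(lengths(part) > 1)) {
      inst <- contract(part, state$tau, state$w, leafmap = state$leafmap,
                       h_leaf = state$h_leaf)
      log_add(log_env, "instances",
              list(names = inst$names, w = inst$w, tau = inst$tau))
      state$names <- inst$names
      state$leafmap <- inst$leafmap
      state$w <- inst$w
      state$tau <- inst$tau
      next
    }
    sel <- select_reticulation(as_instance(state), speed)
    log_add(log_env, "cascades", sel)
    if (length(sel$candidates) == 1) {
      state <- remove_name(state, sel$candidates)
      next
    }
    branches <- lapply(sel$candidates, function(x) {
      solve_loop(remove_name(state, x), ts_orig, speed, log_env)
    })
    score <- vapply(branches, function(b) reticulation_count(b$network),
                    integer(1))
    return(branches[[which.min(score)]])
  }
}

finish_steps <- function(state, t0, ts_orig, speed, log_env) {
  T <- if (length(t0$parent)) binarize(t0) else t0
  fullmap <- state$leafmap
  retics <- state$retic
  for (r in retics) fullmap[[r$name]] <- r$leaves
  N <- insert_reticulation_leaves(
    T, vapply(retics, `[[`, character(1), "name"), ts_orig, leafmap = fullmap)
  N <- recurse_and_expand(N, fullmap, ts_orig, speed = speed,
                          log_env = log_env)
  N <- patch_inconsistent(N, ts_orig)
  log_add(log_env, "step9", attr(N, "patched"))
  list(network = N,
       retic_order = lapply(retics, `[[`, "leaves"))
}

#' Construct a rooted phylogenetic network from rooted triplets
#'
#' The full nine-step heuristic: derive a layered height function from the
#' (feedback-arc-cleaned) pair digraph; reconstruct and binarize a tree
#' when one exists; otherwise decompose the taxa into SN-sets, contract,
#' and remove reticulation leaves chosen by the three criteria until a
#' tree remains; then re-insert the reticulation leaves, expand the
#' contracted blocks recursively, and patch any remaining inconsistent
#' triplets with additional reticulations. The result displays every
#' input triplet; when the input is consistent with a tree the result is
#' a binarization of the BUILD tree with zero reticulations.
#'
#' @param ts A triplet tibble (see [triplets()], [parse_triplets()]).
#' @param speed `"slow"` examines every surviving candidate reticulation
#'   leaf (branching on all of them and keeping the branch with fewest
#'   reticulations), `"normal"` two random candidates, `"fast"` one.
#' @param seed Integer seed controlling every random choice.
#' @return A `tripnet` object: list with `network` (a `phylo_net`),
#'   `n_reticulations`, `level`, `reticulation_order` (leaf sets in
#'   removal order), `consistent` (per input triplet), `log` (SN
#'   partitions, criteria cascades, contracted instances, patching
#'   counts) and the call parameters.
#' @examples
#' ts <- parse_triplets("b c a\na c d\nd e b")
#' fit <- tripnet(ts)
#' fit$n_reticulations
#' @export
tripnet <- function(ts, speed = c("slow", "normal", "fast"), seed = 1L) {
  speed <- match.arg(speed)
  ts <- as_triplets(ts)
  taxa <- leaf_set(ts)
  if (length(taxa) < 3) stop("need at least 3 taxa")
  log_env <- new.env(parent = emptyenv())
  res <- withr::with_seed(seed,
                          tripnet_solve(ts, taxa, speed = speed,
                                        log_env = log_env))
  N <- res$network
  structure(list(network = N,
                 n_reticulations = reticulation_count(N),
                 level = network_level(N),
                 reticulation_order = res$retic_order,
                 consistent = triplet_consistent(N, ts),
                 log = as.list(log_env),
                 input = ts, speed = speed, seed = seed),
            class = "tripnet")
}

#' @export
print.tripnet <- function(x, ...) {
  cat("TripNet result: ", length(network_leaves(x$network)), " taxa, ",
      x$n_reticulations, " reticulation(s), level ", x$level, "\n", sep = "")
  cat(sprintf("consistent input triplets: %d / %d\n",
              sum(x$consistent), length(x$consistent)))
  cat(to_enewick(x$network), "\n")
  invisible(x)
}
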