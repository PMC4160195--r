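#' Is a taxon subset an SN-set?
#'
#' `S` is an SN-set of `ts` iff no triplet `ij|k` has its cherry split by
#' `S` with the outgroup inside: one cherry member outside `S` while the
#' other cherry member and the outgroup are inside. Singletons are always
#' SN-sets.
#'
#' @param S Character vector of taxa.
#' @param ts A triplet tibble.
#' @return Logical scalar.
#' @export
is_sn_set <- function(S, ts) {
  in1 <- ts$cherry1 %in% S
  in2 <- ts$cherry2 %in% S
  ino <- ts$outgroup %in% S
  !any(xor(in1, in2) & ino)
}

#' Remove the maximum-weight edge class
#'
#' @param edges Tibble with columns `taxon1`, `taxon2`, `weight`.
#' @return List with `edges` (the surviving class) and `removed_weight`.
#' @export
remove_max_weight_edges <- function(edges) {
  if (nrow(edges) == 0) stop("no edges to remove")
  m <- max(edges$weight)
  list(edges = edges[edges$weight < m, , drop = FALSE], removed_weight = m)
}

complete_edges <- function(taxa, w) {
  keys <- all_pair_keys(taxa)
  m <- pair_key_split(keys)
  tibble::tibble(taxon1 = m[, 1], taxon2 = m[, 2],
                 weight = unname(w[keys]))
}

edge_components <- function(taxa, edges) {
  ig <- igraph::graph_from_data_frame(
    as.data.frame(edges[, c("taxon1", "taxon2")], stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = taxa, stringsAsFactors = FALSE))
  comp <- igraph::components(ig)
  unname(split(sort(names(comp$membership)), comp$membership[order(names(comp$membership))]))
}

#' Height-guided SN-set decomposition
#'
#' Repeatedly removes the maximum-weight edge class of the complete
#' weighted graph on `taxa` until the current component disconnects; each
#' resulting component that is an SN-set of `ts` becomes a block, and
#' non-SN components are decomposed further. The blocks partition `taxa`.
#'
#' @param w Named weight vector over taxon pairs (a height tibble is also
#'   accepted).
#' @param ts A triplet tibble over (a superset of) `taxa`.
#' @param taxa Character vector of current taxa.
#' @return List of blocks (sorted character vectors), ordered by first
#'   member; every block satisfies [is_sn_set()].
#' @export
sn_decompose <- function(w, ts, taxa) {
  if (is.data.frame(w)) w <- height_lookup(w)
  taxa <- sort(taxa)
  rec <- function(sub, edges) {
    if (length(sub) == 1) return(list(sub))
    e <- edges[edges$taxon1 %in% sub & edges$taxon2 %in% sub, , drop = FALSE]
    repeat {
      if (nrow(e) == 0) {
        comps <- as.list(sub)
        break
      }
      e <- remove_max_weight_edges(e)$edges
      comps <- edge_components(sub, e)
      if (length(comps) > 1) break
    }
    out <- list()
    for (comp in comps) {
      if (length(comp) == 1 || is_sn_set(comp, ts)) {
        out <- c(out, list(comp))
      } else {
        out <- c(out, rec(comp, e))
      }
    }
    out
  }
  blocks <- rec(taxa, complete_edges(taxa, w))
  blocks[order(vapply(blocks, `[`, character(1), 1))]
}

#' Contract SN-sets to single nodes
#'
#' Builds the reduced instance: each block becomes one node named by its
#' (original) leaves joined with `+`; triplets whose labels fall in three
#' distinct blocks survive as block triplets, and the weight between two
#' blocks is the minimum height over cross pairs.
#'
#' @param partition List of blocks (character vectors of current taxa).
#' @param ts Current triplet tibble.
#' @param h Current weights (named vector over pairs, or height tibble).
#' @param leafmap Optional named list mapping current taxa to original
#'   leaf sets (identity by default); composed into the new instance.
#' @param h_leaf Optional original leaf-level heights carried along for
#'   the reticulation criteria (defaults to `h`).
#' @return An `sn_instance`: list with `names`, `blocks`, `leafmap`,
#'   `tau`, `w`, `h_leaf`.
#' @export
contract <- function(partition, ts, h, leafmap = NULL, h_leaf = NULL) {
  if (is.data.frame(h)) h <- height_lookup(h)
  cur <- sort(unlist(partition))
  if (is.null(leafmap)) leafmap <- stats::setNames(as.list(cur), cur)
  if (is.null(h_leaf)) h_leaf <- h
  leaves_of <- function(members) sort(unique(unlist(leafmap[members])))
  nm <- vapply(partition, function(b) paste(leaves_of(b), collapse = "+"),
               character(1))
  names(partition) <- nm
  new_leafmap <- stats::setNames(lapply(partition, leaves_of), nm)
  # block membership of each current taxon
  of <- stats::setNames(rep(nm, lengths(partition)), unlist(partition))
  b1 <- of[ts$cherry1]; b2 <- of[ts$cherry2]; b3 <- of[ts$outgroup]
  keep <- b1 != b2 & b1 != b3 & b2 != b3
  tau <- triplets(b1[keep], b2[keep], b3[keep])
  keys <- all_pair_keys(nm)
  wS <- vapply(keys, function(k) {
    pr <- pair_key_split(k)
    a <- partition[[pr[1, 1]]]
    b <- partition[[pr[1, 2]]]
    min(h[pair_key(rep(a, each = length(b)), rep(b, length(a)))])
  }, numeric(1))
  names(wS) <- keys
  structure(list(names = sort(nm), blocks = partition, leafmap = new_leafmap,
                 tau = tau, w = wS, h_leaf = h_leaf),
            class = "sn_instance")
}

#' @export
print.sn_instance <- function(x, ...) {
  cat("SN instance: ", length(x$names), " blocks (",
      paste(vapply(x$leafmap[x$names], paste, character(1), collapse = ","),
            collapse = " | "),
      "), ", nrow(x$tau), " triplets\n", sep = "")
  invisible(x)
}

# surviving original leaves of an instance
instance_leaves <- function(inst) sort(unique(unlist(inst$leafmap)))

#' Reticulation-leaf criterion I: pendant-edge heights
#'
#' For each block, `m_i`/`M_i` are the minimum/maximum leaf-level heights
#' of edges with exactly one end among the block's leaves (restricted to
#' surviving leaves). Candidates minimize `m_i`, ties broken by minimal
#' `M_i`.
#'
#' @param inst An `sn_instance`.
#' @return Character vector of candidate block names (R1).
#' @export
criterion_I <- function(inst) {
  surv <- instance_leaves(inst)
  stat <- t(vapply(inst$names, function(nm) {
    S <- inst$leafmap[[nm]]
    outside <- setdiff(surv, S)
    if (length(outside) == 0) return(c(Inf, Inf))
    keys <- pair_key(rep(S, each = length(outside)),
                     rep(outside, length(S)))
    v <- inst$h_leaf[keys]
    c(min(v), max(v))
  }, numeric(2)))
  m <- stat[, 1]; M <- stat[, 2]
  r1 <- inst$names[m == min(m)]
  r1[M[r1] == min(M[r1])]
}

#' Reticulation-leaf criterion II: degree in the minimum-weight subgraph
#'
#' Within the contracted graph, candidates of R1 with maximum degree in
#' the subgraph induced by the globally minimum-weight edges.
#'
#' @param inst An `sn_instance`.
#' @param R1 Candidates from [criterion_I()].
#' @return Character vector R2.
#' @export
criterion_II <- function(inst, R1) {
  if (length(R1) <= 1) return(R1)
  wmin <- min(inst$w[all_pair_keys(inst$names)])
  keys <- all_pair_keys(inst$names)
  low <- keys[inst$w[keys] == wmin]
  ends <- pair_key_split(low)
  deg <- vapply(R1, function(nm) sum(ends == nm), integer(1))
  R1[deg == max(deg)]
}

#' Reticulation-leaf criterion III: post-deletion SN-set structure
#'
#' Deleting a candidate node (and the triplets naming it) from the
#' contracted instance and re-decomposing, count the resulting blocks that
#' group more than one node; candidates maximizing this count survive —
#' removing the true reticulation leaf lets the most structure coalesce.
#'
#' @param inst An `sn_instance`.
#' @param R2 Candidates from [criterion_II()].
#' @return Character vector R3.
#' @export
criterion_III <- function(inst, R2) {
  if (length(R2) <= 1) return(R2)
  ns <- vapply(R2, function(s) {
    red <- drop_block(inst, s)
    if (length(red$names) == 0) return(0L)
    part <- sn_decompose(red$w, red$tau, red$names)
    sum(lengths(part) > 1L)
  }, integer(1))
  R2[ns == max(ns)]
}

# remove one block (reticulation leaf) from an instance
drop_block <- function(inst, s) {
  keep <- setdiff(inst$names, s)
  tau <- inst$tau
  tau <- tau[tau$cherry1 != s & tau$cherry2 != s & tau$outgroup != s, ,
             drop = FALSE]
  inst$names <- keep
  inst$blocks <- inst$blocks[keep]
  inst$leafmap <- inst$leafmap[keep]
  inst$tau <- as_triplets(tau)
  inst$w <- inst$w[all_pair_keys(keep)]
  inst
}

#' Select the reticulation leaf of the current instance
#'
#' Applies criteria I -> II -> III, short-circuiting as soon as a stage is
#' a singleton. If several candidates survive all three, the speed mode
#' decides how many are examined: `slow` returns all (the caller branches
#' on each), `normal` two seeded-random picks, `fast` one.
#'
#' @param inst An `sn_instance`.
#' @param speed One of `"slow"`, `"normal"`, `"fast"`.
#' @param seed Optional integer seed for the random picks; `NULL` uses the
#'   current RNG stream.
#' @return List with `candidates` (block names to examine) and the
#'   cascade `R1`, `R2`, `R3` (later stages `NULL` when short-circuited).
#' @export
select_reticulation <- function(inst, speed = c("slow", "normal", "fast"),
                                seed = NULL) {
  speed <- match.arg(speed)
  R1 <- criterion_I(inst)
  if (length(R1) == 1) {
    return(list(candidates = R1, R1 = R1, R2 = NULL, R3 = NULL))
  }
  R2 <- criterion_II(inst, R1)
  if (length(R2) == 1) {
    return(list(candidates = R2, R1 = R1, R2 = R2, R3 = NULL))
  }
  R3 <- criterion_III(inst, R2)
  cand <- sort(R3)
  k <- switch(speed, slow = length(cand), normal = 2L, fast = 1L)
  if (k < length(cand)) {
    pick <- function() sort(cand[sample.int(length(cand), k)])
    cand <- if (is.null(seed)) pick() else withr::with_seed(seed, pick())
  }
  list(candidates = cand, R1 = R1, R2 = R2, R3 = R3)
}
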