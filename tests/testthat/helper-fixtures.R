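# Worked-example inputs used across the suite ---------------------------------

# five-taxon tree-consistent set {bc|a, ac|d, de|b}
fix_tree5 <- function() parse_triplets("b c a\na c d\nd e b")

# caterpillar set {kl|j, kl|i, jk|i, jl|i} whose heights drive HBUILD
fix_cat4 <- function() parse_triplets("k l j\nk l i\nj k i\nj l i")

# 15 triplets on {i..o} consistent with a level-1 network but no tree
fix_net15 <- function() {
  parse_triplets(paste(
    "i j l", "j k i", "k l j", "k l i", "n o m",
    "l o k", "j l o", "m n l", "m n j", "n o k",
    "m o i", "j k n", "i j o", "i k m", "i l n",
    sep = "\n"))
}

# 20 triplets on {i..n} (second worked input)
fix_net20 <- function() {
  parse_triplets(paste(
    "j k i", "l i j", "m j i", "j n i", "k l i",
    "i k m", "i k n", "l m i", "l n i", "m n i",
    "k l j", "k m j", "j n k", "l m j", "j l n",
    "m n j", "k l m", "k l n", "m n k", "m n l",
    sep = "\n"))
}

# level-1 network displaying ij|k although h(i,j) = h(i,k) = 3 > h(j,k) = 2:
# the converse of the height sufficient condition fails here
fix_height_counterexample <- function() {
  list(network = from_enewick("((k)#H1,((#H1,j),i));"),
       triplet = triplets("i", "j", "k"))
}

# Independent oracles ----------------------------------------------------------

# all directed paths u -> v by plain recursive enumeration
oracle_paths <- function(children, u, v) {
  out <- list()
  walk <- function(p) {
    last <- p[length(p)]
    if (last == v) {
      out[[length(out) + 1L]] <<- p
      return(invisible())
    }
    for (w in children[[last]]) walk(c(p, w))
  }
  walk(u)
  out
}

# brute-force triplet consistency: enumerate every (u, v) pair and every
# 4-tuple of paths, checking pairwise internal disjointness explicitly
oracle_consistent <- function(N, cherry1, cherry2, outgroup) {
  nodes <- sort(unique(c(N$parent, N$child)))
  n <- length(nodes)
  children <- lapply(seq_len(n), function(u) {
    match(N$child[N$parent == nodes[u]], nodes)
  })
  ii <- match(cherry1, nodes)
  jj <- match(cherry2, nodes)
  kk <- match(outgroup, nodes)
  ok_pair <- function(P, Q) {
    sh <- intersect(P, Q)
    all(sh %in% c(P[1], P[length(P)])) && all(sh %in% c(Q[1], Q[length(Q)]))
  }
  for (u in seq_len(n)) {
    for (v in seq_len(n)) {
      if (u == v) next
      Pui <- oracle_paths(children, u, ii); if (!length(Pui)) next
      Puj <- oracle_paths(children, u, jj); if (!length(Puj)) next
      Pvu <- oracle_paths(children, v, u); if (!length(Pvu)) next
      Pvk <- oracle_paths(children, v, kk); if (!length(Pvk)) next
      for (p1 in Pui) for (p2 in Puj) for (p3 in Pvu) for (p4 in Pvk) {
        ps <- list(p1, p2, p3, p4)
        good <- TRUE
        for (a in 1:3) {
          for (b in (a + 1):4) {
            if (!ok_pair(ps[[a]], ps[[b]])) {
              good <- FALSE
              break
            }
          }
          if (!good) break
        }
        if (good) return(TRUE)
      }
    }
  }
  FALSE
}

# brute-force feasibility of the height constraint system at ceiling s:
# complete backtracking over pair heights (variables ordered by constraint
# participation, values restricted to the interval allowed by already-filled
# neighbors — sound pruning only, every assignment still reachable);
# independent of the digraph longest-path characterization
oracle_ip_feasible <- function(ts, s) {
  taxa <- leaf_set(ts)
  pairs <- t(utils::combn(taxa, 2))
  key <- paste(pairs[, 1], pairs[, 2])
  pk <- function(a, b) paste(pmin(a, b), pmax(a, b))
  np <- length(key)
  # each triplet ij|k gives arcs ij -> ik and ij -> jk (h[from] + 1 <= h[to])
  from <- match(pk(ts$cherry1, ts$cherry2), key)
  to1 <- match(pk(ts$cherry1, ts$outgroup), key)
  to2 <- match(pk(ts$cherry2, ts$outgroup), key)
  preds <- succs <- rep(list(integer()), np)
  for (r in seq_along(from)) {
    succs[[from[r]]] <- c(succs[[from[r]]], to1[r], to2[r])
    preds[[to1[r]]] <- c(preds[[to1[r]]], from[r])
    preds[[to2[r]]] <- c(preds[[to2[r]]], from[r])
  }
  deg <- lengths(preds) + lengths(succs)
  ord <- order(-deg)
  h <- rep(NA_integer_, np)
  rec <- function(pos) {
    if (pos > np) return(TRUE)
    v <- ord[pos]
    pv <- h[preds[[v]]]
    sv <- h[succs[[v]]]
    lo <- max(1L, if (any(!is.na(pv))) max(pv, na.rm = TRUE) + 1L else 1L)
    hi <- min(s, if (any(!is.na(sv))) min(sv, na.rm = TRUE) - 1L else s)
    if (lo > hi) return(FALSE)
    for (val in lo:hi) {
      h[v] <<- val
      if (rec(pos + 1)) return(TRUE)
    }
    h[v] <<- NA_integer_
    FALSE
  }
  rec(1)
}

# minimal feasible ceiling by brute force, Inf if none up to cap
oracle_ip_min_s <- function(ts, cap = NULL) {
  n <- length(leaf_set(ts))
  if (is.null(cap)) cap <- choose(n, 2)
  for (s in seq_len(cap)) {
    if (oracle_ip_feasible(ts, s)) return(s)
  }
  Inf
}

# random triplet set on a small taxon universe (conflicts allowed)
random_triplet_set <- function(n_taxa, n_triplets, seed) {
  withr::with_seed(seed, {
    taxa <- letters[seq_len(n_taxa)]
    m <- t(replicate(n_triplets, sample(taxa, 3)))
    triplets(m[, 1], m[, 2], m[, 3])
  })
}

# random network that retries placement-starved seeds deterministically
fixture_network <- function(n, r, seed) {
  for (k in 0:20) {
    N <- try(random_network(n, r, seed = seed + 10000L * k), silent = TRUE)
    if (!inherits(N, "try-error")) return(N)
  }
  stop("no reticulation placement found")
}

# Shared end-to-end batch (computed once, reused by several tests) -------------

e2e_cache <- new.env(parent = emptyenv())

e2e_runs <- function() {
  if (!is.null(e2e_cache$runs)) return(e2e_cache$runs)
  runs <- list()
  id <- 0L
  add <- function(ts, kind, speed, seed) {
    id <<- id + 1L
    log_keep <- tripnet(ts, speed = speed, seed = seed)
    runs[[id]] <<- list(kind = kind, ts = ts, fit = log_keep)
  }
  # 40 dense tree inputs, 40 full network inputs, 20 subsampled non-dense
  for (s in 1:40) {
    t <- random_binary_tree(4 + (s %% 5), seed = s)
    add(triplets_from(t, 1, seed = s), "tree", "slow", s)
  }
  for (s in 1:40) {
    N <- fixture_network(4 + (s %% 4), 1 + (s %% 2), seed = 100 + s)
    add(triplets_from(N, 1, seed = s), "network",
        if (s %% 2) "slow" else "fast", s)
  }
  for (s in 1:20) {
    N <- fixture_network(5 + (s %% 3), s %% 3, seed = 200 + s)
    ts <- triplets_from(N, 0.6, seed = s)
    if (length(leaf_set(ts)) < 3) next
    add(ts, "subsample", "fast", s)
  }
  e2e_cache$runs <- runs
  runs
}
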