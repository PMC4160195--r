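#' Random rooted binary tree (Yule growth)
#'
#' Starts from a cherry and repeatedly splits a uniformly chosen leaf
#' until `n` leaves exist; labels are `t01, t02, ...` assigned in tree
#' construction order.
#'
#' @param n Number of leaves (>= 2).
#' @param seed Integer seed.
#' @return A binary `phylo_net` tree.
#' @export
random_binary_tree <- function(n, seed = 1L) {
  if (n < 2) stop("need n >= 2")
  labels <- sprintf("t%02d", seq_len(n))
  withr::with_seed(seed, {
    parent <- c("v1", "v1")
    child <- labels[1:2]
    vc <- 1L
    for (k in 3:max(3, n)) {
      if (k > n) break
      lv <- child[!(child %in% parent)]
      x <- lv[sample.int(length(lv), 1)]
      vc <- vc + 1L
      v <- paste0("v", vc)
      child[child == x] <- v
      parent <- c(parent, v, v)
      child <- c(child, x, labels[k])
    }
    phylo_net(cbind(parent, child))
  })
}

#' Random binary network
#'
#' Adds `r` reticulations to a random binary tree: two distinct edges are
#' subdivided and the new nodes joined by an arc, rejecting placements
#' that would create a directed cycle.
#'
#' @param n Number of leaves.
#' @param r Number of reticulations (>= 0).
#' @param seed Integer seed.
#' @param max_tries Rejection-sampling budget per reticulation.
#' @return A valid `phylo_net` with `reticulation_count(N) == r`.
#' @export
random_network <- function(n, r, seed = 1L, max_tries = 100L) {
  N <- random_binary_tree(n, seed)
  if (r == 0) return(N)
  withr::with_seed(seed + 1L, {
    for (k in seq_len(r)) {
      done <- FALSE
      for (try in seq_len(max_tries)) {
        ne <- length(N$parent)
        ab <- sample.int(ne, 2)
        a <- ab[1]; b <- ab[2]
        idx <- pn_index(N)
        # arc tail on edge a, head on edge b: forbid a path from b's child
        # back to a's parent (cycle) and degenerate shared edges
        pa <- N$parent[a]; ca <- N$child[a]
        pb <- N$parent[b]; cb <- N$child[b]
        if (idx$reach[match(cb, idx$nodes), match(pa, idx$nodes)]) next
        ids <- fresh_ids("w", 2L, N$nodes)
        cand <- subdivide_edge(N, pa, ca, ids[1])
        cand <- subdivide_edge(cand, pb, cb, ids[2])
        cand <- add_arc(cand, ids[1], ids[2])
        if (length(validate_network(cand)) == 0) {
          N <- cand
          done <- TRUE
          break
        }
      }
      if (!done) stop("could not place reticulation ", k,
                      " after ", max_tries, " tries")
    }
  })
  N
}

#' Triplets displayed by a tree or network, optionally subsampled
#'
#' With `fraction = 1` the full consistent triplet set (dense for binary
#' trees). Smaller fractions keep each 3-subset of taxa (with all its
#' triplets) independently with the given probability, emulating sparse,
#' non-dense input.
#'
#' @param source A `phylo_net`.
#' @param fraction Keep-probability per 3-subset, in (0, 1].
#' @param seed Integer seed for the subsampling.
#' @return A triplet tibble; every member is consistent with `source`.
#' @export
triplets_from <- function(source, fraction = 1, seed = 1L) {
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  full <- consistent_triplet_set(source)
  if (fraction == 1) return(full)
  key <- apply(cbind(full$cherry1, full$cherry2, full$outgroup), 1,
               function(x) paste(sort(x), collapse = "\r"))
  groups <- unique(key)
  keep_group <- withr::with_seed(seed,
                                 stats::runif(length(groups)) <= fraction)
  as_triplets(full[key %in% groups[keep_group], , drop = FALSE])
}

#' Ultrametric distance matrix from a tree, with optional noise
#'
#' Distances are twice the pair heights (`2 * (l_T -` LCA depth`)`), an
#' ultrametric on the tree's topology under which the TCD rule recovers
#' exactly the tree's triplets; optional symmetric Gaussian noise is
#' added to the off-diagonal entries (floored at a small positive value).
#'
#' @param t A binary `phylo_net` tree.
#' @param noise_sd Standard deviation of the Gaussian perturbation.
#' @param seed Integer seed for the noise.
#' @return A symmetric labeled distance matrix with zero diagonal.
#' @export
distance_matrix_from_tree <- function(t, noise_sd = 0, seed = 1L) {
  hv <- height_lookup(tree_height_function(t))
  labs <- network_leaves(t)
  n <- length(labs)
  d <- matrix(0, n, n, dimnames = list(labs, labs))
  for (a in seq_len(n - 1)) {
    for (b in (a + 1):n) {
      d[a, b] <- d[b, a] <- 2 * hv[[pair_key(labs[a], labs[b])]]
    }
  }
  if (noise_sd > 0) {
    eps <- withr::with_seed(seed, stats::rnorm(n * (n - 1) / 2, 0, noise_sd))
    k <- 0L
    for (a in seq_len(n - 1)) {
      for (b in (a + 1):n) {
        k <- k + 1L
        d[a, b] <- d[b, a] <- max(d[a, b] + eps[k], 1e-6)
      }
    }
  }
  d
}

#' Write a distance matrix in PHYLIP square format
#'
#' @param d Symmetric labeled matrix.
#' @param file Path.
#' @return `file`, invisibly.
#' @export
write_phylip_dist <- function(d, file) {
  check_distance_matrix(d)
  lines <- c(as.character(nrow(d)),
             vapply(seq_len(nrow(d)), function(i) {
               paste(c(rownames(d)[i], format(d[i, ], trim = TRUE)),
                     collapse = " ")
             }, character(1)))
  writeLines(lines, file)
  invisible(file)
}
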