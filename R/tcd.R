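#' Read a PHYLIP square distance matrix
#'
#' Format: first line the number of taxa `n`, then one row per taxon with
#' its label followed by `n` distances.
#'
#' @param file Path to the matrix file.
#' @return A symmetric numeric matrix with taxon labels as dimnames.
#' @export
read_phylip_dist <- function(file) {
  toks <- scan(file, what = character(), quiet = TRUE)
  n <- suppressWarnings(as.integer(toks[1]))
  if (is.na(n) || n < 1) stop("first token must be the number of taxa")
  toks <- toks[-1]
  if (length(toks) != n * (n + 1)) {
    stop("expected ", n, " rows of a label plus ", n, " values")
  }
  rows <- matrix(toks, nrow = n, byrow = TRUE)
  labels <- rows[, 1]
  d <- matrix(as.numeric(rows[, -1, drop = FALSE]), nrow = n,
              dimnames = list(labels, labels))
  check_distance_matrix(d)
  d
}

check_distance_matrix <- function(d) {
  if (!is.matrix(d) || nrow(d) != ncol(d)) stop("distance matrix must be square")
  if (is.null(rownames(d))) stop("distance matrix must have taxon labels")
  if (any(d != t(d))) stop("distance matrix must be symmetric")
  if (any(diag(d) != 0)) stop("distance matrix must have a zero diagonal")
  invisible(d)
}

#' Derive triplets from a distance matrix (the TCD rule)
#'
#' For every three taxa `i, j, k` the triplet `ij|k` is emitted iff
#' `D[i,j] < min(D[i,k], D[j,k])`, i.e. the strictly closest pair forms the
#' cherry. With `dense_mode = TRUE` ties at the minimum are broken by a
#' seeded uniform choice among the triplets whose cherry attains the
#' minimal distance (two tied pairs: choose between those two triplets;
#' all three tied: choose among all three), so the result is dense.
#' Ties are detected by exact comparison on the stored values; callers
#' holding noisy estimates may pre-round.
#'
#' @param d Symmetric labeled distance matrix (see [read_phylip_dist()]).
#' @param dense_mode Break ties randomly so that every 3-subset is covered?
#' @param seed Integer seed used only for tie-breaking in dense mode.
#' @return A triplet tibble; at most (exactly, in dense mode) one triplet
#'   per 3-subset.
#' @export
tcd_triplets <- function(d, dense_mode = FALSE, seed = 1L) {
  check_distance_matrix(d)
  taxa <- rownames(d)
  if (length(taxa) < 3) stop("TCD needs at least 3 taxa")
  trip <- utils::combn(taxa, 3)
  emit <- function(trio) {
    i <- trio[1]; j <- trio[2]; k <- trio[3]
    v <- c(d[i, j], d[i, k], d[j, k])
    # cherry candidates in the order ij|k, ik|j, jk|i
    cand <- list(c(i, j, k), c(i, k, j), c(j, k, i))
    m <- min(v)
    hit <- which(v == m)
    if (length(hit) == 1) return(cand[[hit]])
    if (!dense_mode) return(NULL)
    cand[[hit[sample.int(length(hit), 1)]]]
  }
  rows <- withr::with_seed(seed, apply(trip, 2, emit, simplify = FALSE))
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) return(triplets())
  m <- do.call(rbind, rows)
  triplets(m[, 1], m[, 2], m[, 3])
}
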