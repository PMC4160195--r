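#' Rooted triplet sets as tibbles
#'
#' A rooted triplet `ij|k` is a binary rooted tree on three taxa with cherry
#' `{i, j}` and outgroup `k`. A triplet set is represented as a tibble with
#' character columns `cherry1`, `cherry2` and `outgroup`, kept in canonical
#' form: `cherry1 < cherry2` within each row (the cherry is unordered),
#' exact duplicates collapsed, rows sorted. Conflicting triplets on the same
#' three taxa are allowed; exact duplicates are not.
#'
#' @param cherry1,cherry2 Character vectors of cherry members.
#' @param outgroup Character vector of outgroups.
#' @return A canonical triplet tibble (class `triplet_tbl`).
#' @examples
#' triplets(c("b", "a"), c("c", "c"), c("a", "d"))
#' @export
triplets <- function(cherry1 = character(), cherry2 = character(),
                     outgroup = character()) {
  cherry1 <- as.character(cherry1)
  cherry2 <- as.character(cherry2)
  outgroup <- as.character(outgroup)
  stopifnot(length(cherry1) == length(cherry2),
            length(cherry1) == length(outgroup))
  bad <- cherry1 == cherry2 | cherry1 == outgroup | cherry2 == outgroup |
    cherry1 == "" | cherry2 == "" | outgroup == ""
  if (any(bad)) {
    stop("triplet labels must be three distinct non-empty taxa (row ",
         which(bad)[1], ")")
  }
  c1 <- pmin(cherry1, cherry2)
  c2 <- pmax(cherry1, cherry2)
  tb <- tibble::tibble(cherry1 = c1, cherry2 = c2, outgroup = outgroup)
  tb <- dplyr::distinct(dplyr::arrange(tb, .data$cherry1, .data$cherry2,
                                       .data$outgroup))
  class(tb) <- c("triplet_tbl", class(tibble::tibble()))
  tb
}

#' @export
print.triplet_tbl <- function(x, ...) {
  cat("# A triplet set: ", nrow(x), " triplet(s) on ",
      length(leaf_set(x)), " taxa\n", sep = "")
  NextMethod()
}

as_triplets <- function(df) {
  triplets(df$cherry1, df$cherry2, df$outgroup)
}

#' Parse a triplet file
#'
#' One triplet per line as three whitespace-separated labels `a b c`,
#' meaning `ab|c`. Blank lines and lines starting with `#` are ignored.
#'
#' @param text Character scalar (file contents) or a file path.
#' @return A triplet tibble.
#' @examples
#' parse_triplets("b c a\na c d\nd e b")
#' @export
parse_triplets <- function(text) {
  if (length(text) == 1 && file.exists(text)) {
    lines <- readLines(text)
  } else {
    lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n"))
  }
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  toks <- strsplit(trimws(lines[keep]), "\\s+")
  n <- lengths(toks)
  if (any(n != 3)) {
    bad <- idx[which(n != 3)[1]]
    stop("line ", bad, ": expected 3 whitespace-separated labels, got ",
         n[which(n != 3)[1]])
  }
  m <- do.call(rbind, toks)
  if (length(m) == 0) return(triplets())
  dup <- m[, 1] == m[, 2] | m[, 1] == m[, 3] | m[, 2] == m[, 3]
  if (any(dup)) {
    stop("line ", idx[which(dup)[1]], ": labels within a triplet must be distinct")
  }
  triplets(m[, 1], m[, 2], m[, 3])
}

#' Write a triplet set to its text form
#'
#' Inverse of [parse_triplets()] on canonical form: one line per triplet,
#' cherry members in lexicographic order, lines sorted.
#'
#' @param ts A triplet tibble.
#' @param file Optional path; when `NULL` the text is returned invisibly.
#' @return The text, one element per line, invisibly when writing to a file.
#' @export
write_triplets <- function(ts, file = NULL) {
  ts <- as_triplets(ts)
  out <- sprintf("%s %s %s", ts$cherry1, ts$cherry2, ts$outgroup)
  if (!is.null(file)) {
    writeLines(out, file)
    return(invisible(out))
  }
  out
}

#' Leaf universe of a triplet set
#'
#' @param ts A triplet tibble.
#' @return Sorted character vector of all taxa appearing in `ts`.
#' @export
leaf_set <- function(ts) {
  sort(unique(c(ts$cherry1, ts$cherry2, ts$outgroup)))
}

#' Is a triplet set dense?
#'
#' Dense means every 3-subset of the leaf universe carries at least one
#' triplet.
#'
#' @param ts A triplet tibble.
#' @return Logical scalar.
#' @export
is_dense <- function(ts) {
  taxa <- leaf_set(ts)
  if (length(taxa) < 3) stop("density is undefined for fewer than 3 taxa")
  key <- function(a, b, c) {
    m <- rbind(a, b, c)
    apply(m, 2, function(x) paste(sort(x), collapse = "\r"))
  }
  covered <- unique(key(ts$cherry1, ts$cherry2, ts$outgroup))
  all_keys <- utils::combn(taxa, 3, paste, collapse = "\r")
  all(all_keys %in% covered)
}

# triplets of ts with all three labels inside `subset`
restrict_triplets <- function(ts, subset) {
  keep <- ts$cherry1 %in% subset & ts$cherry2 %in% subset &
    ts$outgroup %in% subset
  as_triplets(ts[keep, , drop = FALSE])
}
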