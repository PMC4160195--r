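#' Serialize a tree or network to (e)Newick
#'
#' Trees serialize as plain branch-length-free Newick. Reticulation nodes
#' are written with `#H1..#Hk` hybrid tags, the subtree expanded at the
#' first occurrence. Children are ordered by smallest descendant leaf
#' label, so equal graphs serialize to identical text.
#'
#' @param N A `phylo_net`.
#' @param file Optional path to write to.
#' @return The eNewick string.
#' @export
to_enewick <- function(N, file = NULL) {
  idx <- pn_index(N)
  if (length(idx$root) != 1) stop("graph must have a unique root")
  n <- idx$n
  minlab <- vapply(seq_len(n), function(u) {
    min(idx$nodes[idx$leaves[idx$reach[u, idx$leaves]]])
  }, character(1))
  # secondary key: the full descendant leaf set, more stable than node ids
  descset <- vapply(seq_len(n), function(u) {
    paste(sort(idx$nodes[idx$leaves[idx$reach[u, idx$leaves]]]),
          collapse = ",")
  }, character(1))
  retic <- which(idx$indeg >= 2)
  retic <- retic[order(minlab[retic], descset[retic], idx$nodes[retic])]
  tag <- stats::setNames(paste0("H", seq_along(retic)), retic)
  expanded <- stats::setNames(rep(FALSE, length(retic)), retic)
  body <- function(u) {
    if (idx$outdeg[u] == 0) return(idx$nodes[u])
    kids <- idx$children[[u]]
    kids <- kids[order(minlab[kids], descset[kids], idx$nodes[kids])]
    paste0("(", paste(vapply(kids, render, character(1)), collapse = ","), ")")
  }
  render <- function(u) {
    key <- as.character(u)
    if (u %in% retic) {
      if (expanded[[key]]) return(paste0("#", tag[[key]]))
      expanded[[key]] <<- TRUE
      return(paste0(body(u), "#", tag[[key]]))
    }
    body(u)
  }
  out <- paste0(render(idx$root), ";")
  if (!is.null(file)) {
    writeLines(out, file)
    return(invisible(out))
  }
  out
}

#' Parse (e)Newick into a `phylo_net`
#'
#' Plain Newick trees and hybrid-tagged extended Newick are both accepted
#' (parsing is delegated to \pkg{ape}). Branch lengths are discarded.
#'
#' @param text An (e)Newick string or a path to a file holding one.
#' @return A `phylo_net`; internal nodes get fresh `n<k>` ids.
#' @export
from_enewick <- function(text) {
  if (length(text) == 1 && !grepl("[();]", text) && file.exists(text)) {
    text <- paste(readLines(text), collapse = "")
  }
  ev <- tryCatch(suppressWarnings(ape::read.evonet(text = text)),
                 error = function(e) ape::read.tree(text = text))
  ntip <- length(ev$tip.label)
  id <- function(v) {
    ifelse(v <= ntip, ev$tip.label[v], paste0("n", v - ntip))
  }
  edges <- ev$edge
  if (!is.null(ev$reticulation)) edges <- rbind(edges, ev$reticulation)
  phylo_net(cbind(id(edges[, 1]), id(edges[, 2])))
}

#' Read/write the edge-list TSV debug format
#'
#' One `parent<TAB>child` pair per line; an unambiguous plain-text dump of
#' the network graph.
#'
#' @param N A `phylo_net`.
#' @param file Path.
#' @return `write_edgelist` returns `file` invisibly; `read_edgelist`
#'   returns a `phylo_net`.
#' @export
write_edgelist <- function(N, file) {
  ord <- order(N$parent, N$child)
  writeLines(paste(N$parent[ord], N$child[ord], sep = "\t"), file)
  invisible(file)
}

#' @rdname write_edgelist
#' @export
read_edgelist <- function(file) {
  df <- utils::read.table(file, sep = "\t", header = FALSE,
                          colClasses = "character")
  phylo_net(as.matrix(df))
}
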