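#' Construct a directed interaction network
#'
#' Builds an `msf_network` from a two-column edge table. Self-loops are
#' dropped (their count is retained in the object) and duplicate edges are
#' collapsed, so the edge set is a set of ordered gene pairs.
#'
#' @param from,to Character vectors of equal length: directed edges
#'   `from[i] -> to[i]`.
#' @param nodes Optional character vector of additional isolated nodes.
#' @return An object of class `msf_network`: list with `nodes` (sorted unique
#'   gene ids), `edges` (data.frame with columns `from`, `to`, sorted,
#'   deduplicated, no self-loops) and `n_self_loops` (count dropped).
#' @export
#' @examples
#' net <- interaction_network(c("a", "b"), c("b", "c"))
#' net$nodes
interaction_network <- function(from, to, nodes = character()) {
  from <- as.character(from)
  to <- as.character(to)
  if (length(from) != length(to)) stop("from and to must have equal length")
  if (any(!nzchar(from)) || any(!nzchar(to))) stop("gene ids must be non-empty")
  self <- from == to
  n_self <- sum(self)
  from <- from[!self]
  to <- to[!self]
  if (length(from)) {
    keep <- !duplicated(paste0(from, "\r", to))
  } else {
    keep <- logical(0) # paste0() on zero-length input would yield "\r"
  }
  edges <- data.frame(from = from[keep], to = to[keep], stringsAsFactors = FALSE)
  if (nrow(edges)) edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  rownames(edges) <- NULL
  out <- list(
    nodes = sort(unique(c(edges$from, edges$to, as.character(nodes)))),
    edges = edges,
    n_self_loops = as.integer(n_self)
  )
  class(out) <- "msf_network"
  out
}

#' Read a directed network from an edge-list file
#'
#' Parses a plain-text edge list with one interaction per line:
#' `from<TAB>to` (any whitespace separator accepted; an optional third column,
#' e.g. an interaction type, is ignored). Lines starting with `#` and blank
#' lines are skipped. Self-loops are dropped with a message; duplicate edges
#' are merged.
#'
#' @param path Path to the edge-list file.
#' @return An [interaction_network()] object.
#' @export
read_network <- function(path) {
  if (!file.exists(path)) stop("network file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")
  idx <- which(keep)
  if (!length(idx)) {
    warning("network file '", path, "' contains no edges; search will find no sub-graphs")
    return(interaction_network(character(), character()))
  }
  parts <- strsplit(trimws(lines[idx]), "[\t ]+")
  nf <- lengths(parts)
  if (any(nf < 2)) {
    bad <- idx[which(nf < 2)[1]]
    stop("network file '", path, "': line ", bad, " has fewer than 2 fields")
  }
  from <- vapply(parts, `[[`, character(1), 1L)
  to <- vapply(parts, `[[`, character(1), 2L)
  net <- interaction_network(from, to)
  if (net$n_self_loops > 0) {
    message("read_network: dropped ", net$n_self_loops, " self-loop(s)")
  }
  net
}

#' Write a network as a two-column edge list
#'
#' Writes the format [read_network()] reads (tab-separated `from`/`to`, no
#' header), so that a written network round-trips to the same node and edge
#' sets.
#'
#' @param network An `msf_network`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_network <- function(network, path) {
  stopifnot(inherits(network, "msf_network"))
  lines <- sprintf("%s\t%s", network$edges$from, network$edges$to)
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.msf_network <- function(x, ...) {
  cat(sprintf(
    "Directed interaction network: %d nodes, %d edges (%d self-loops dropped)\n",
    length(x$nodes), nrow(x$edges), x$n_self_loops
  ))
  invisible(x)
}

# igraph view of the network (vertices = network nodes, directed)
.as_igraph <- function(network) {
  igraph::graph_from_data_frame(
    network$edges,
    directed = TRUE,
    vertices = data.frame(name = network$nodes, stringsAsFactors = FALSE)
  )
}
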