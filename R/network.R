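#' Undirected gene-interaction network
#'
#' Lightweight container for the search-space graph: a set of gene
#' identifiers and undirected edges between them. Self-loops are dropped
#' and duplicate / reversed-duplicate edges merged, so the edge set is a
#' simple graph. An adjacency list is precomputed because the greedy
#' search queries neighbourhoods in its inner loop.
#'
#' @param edges two-column character matrix (or data.frame) of gene id
#'   pairs; each row one undirected edge.
#' @param nodes optional character vector of additional isolated nodes.
#'
#' @return An object of class `interaction_network` with elements
#'   `nodes` (character), `edges` (two-column character matrix with
#'   lexicographically ordered endpoints, unique rows) and `adj` (named
#'   list mapping each node to its neighbour set).
#' @export
interaction_network <- function(edges, nodes = character()) {
  edges <- as.matrix(edges)
  if (ncol(edges) != 2L) stop("edges must have exactly two columns")
  storage.mode(edges) <- "character"
  loops <- edges[, 1L] == edges[, 2L]
  if (any(loops)) {
    warning(sprintf("dropping %d self-loop(s)", sum(loops)))
    edges <- edges[!loops, , drop = FALSE]
  }
  if (nrow(edges) > 0L) {
    swap <- edges[, 1L] > edges[, 2L]
    edges[swap, ] <- edges[swap, c(2L, 1L), drop = FALSE]
    edges <- edges[!duplicated(paste(edges[, 1L], edges[, 2L], sep = "\r")), ,
                   drop = FALSE]
    o <- order(edges[, 1L], edges[, 2L])
    edges <- edges[o, , drop = FALSE]
  }
  all_nodes <- sort(unique(c(as.character(nodes), as.vector(edges))))
  adj <- lapply(setNames(vector("list", length(all_nodes)), all_nodes),
                function(.) character())
  if (nrow(edges) > 0L) {
    nb <- split(c(edges[, 2L], edges[, 1L]), c(edges[, 1L], edges[, 2L]))
    nb <- lapply(nb, function(v) sort(unique(v)))
    adj[names(nb)] <- nb
  }
  structure(list(nodes = all_nodes, edges = edges, adj = adj),
            class = "interaction_network")
}

#' @export
print.interaction_network <- function(x, ...) {
  cat(sprintf("interaction_network: %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Neighbours of a set of nodes
#'
#' @param network an `interaction_network`.
#' @param members character vector of node ids.
#' @return Sorted character vector of nodes adjacent to `members`,
#'   excluding `members` themselves.
#' @export
network_neighbors <- function(network, members) {
  nb <- unlist(network$adj[members], use.names = FALSE)
  sort(setdiff(unique(nb), members))
}

#' Connectivity of an induced subgraph
#'
#' Breadth-first check that `members` induce a connected subgraph of the
#' network. Used by the greedy search's deletion step and by the
#' synthetic-data planting routine.
#'
#' @inheritParams network_neighbors
#' @return `TRUE` if the induced subgraph is connected (single nodes are
#'   connected; the empty set is not).
#' @export
is_connected_subset <- function(network, members) {
  m <- length(members)
  if (m == 0L) return(FALSE)
  if (m == 1L) return(members %in% network$nodes)
  if (!all(members %in% network$nodes)) return(FALSE)
  seen <- structure(logical(m), names = members)
  queue <- members[1L]
  seen[queue] <- TRUE
  while (length(queue) > 0L) {
    v <- queue[1L]
    queue <- queue[-1L]
    nb <- intersect(network$adj[[v]], members)
    new <- nb[!seen[nb]]
    seen[new] <- TRUE
    queue <- c(queue, new)
  }
  all(seen)
}

#' Edges induced by a node set
#'
#' @inheritParams network_neighbors
#' @return Two-column character matrix of the edges with both endpoints
#'   in `members`.
#' @export
induced_edges <- function(network, members) {
  e <- network$edges
  keep <- e[, 1L] %in% members & e[, 2L] %in% members
  e[keep, , drop = FALSE]
}

#' Convert to an igraph object
#'
#' @inheritParams network_neighbors
#' @return An undirected simple `igraph` graph over the same nodes.
#' @export
as_igraph <- function(network) {
  igraph::graph_from_data_frame(as.data.frame(network$edges),
                                directed = FALSE,
                                vertices = network$nodes)
}
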