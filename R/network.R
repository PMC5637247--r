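#' Weighted gene network objects
#'
#' A weighted gene network is stored as a tibble of undirected edges with
#' columns `from`, `to`, `weight`, canonicalised so that `from < to` in string
#' order and rows are sorted by `(from, to)`. The node universe (which may
#' include isolated nodes not incident to any edge) is carried in the `nodes`
#' attribute. `gene_network()` validates and canonicalises an edge table;
#' `network_nodes()` returns the node universe.
#'
#' @param edges A data frame with columns `from`, `to`, `weight` (or the first
#'   three columns are taken in that order).
#' @param nodes Optional character vector of additional node ids (isolated
#'   nodes); the universe is the union with all edge endpoints.
#' @return A tibble of class `iw_network` with attribute `nodes`.
#' @examples
#' gene_network(tibble::tibble(from = c("B", "A"), to = c("C", "B"),
#'                             weight = c(2, 1)))
#' @export
gene_network <- function(edges, nodes = NULL) {
  edges <- as_tibble(edges)
  if (ncol(edges) < 3) abort("edge table needs columns from, to, weight")
  if (!all(c("from", "to", "weight") %in% names(edges))) {
    names(edges)[1:3] <- c("from", "to", "weight")
  }
  edges <- edges[c("from", "to", "weight")]
  edges$from <- as.character(edges$from)
  edges$to <- as.character(edges$to)
  edges$weight <- as.numeric(edges$weight)
  if (anyNA(edges)) abort("edge table contains missing values")
  if (any(edges$from == edges$to)) {
    bad <- edges$from[edges$from == edges$to][1]
    abort(sprintf("self-loop on node '%s' is not allowed", bad))
  }
  if (any(edges$weight < 0)) abort("edge weights must be nonnegative")
  swap <- edges$from > edges$to
  tmp <- edges$from[swap]
  edges$from[swap] <- edges$to[swap]
  edges$to[swap] <- tmp
  # unordered duplicates must agree in weight (within 1e-9), then collapse
  key <- paste(edges$from, edges$to, sep = "\r")
  if (anyDuplicated(key)) {
    rng <- tapply(edges$weight, key, function(w) diff(range(w)))
    if (any(rng > 1e-9)) {
      bad <- names(rng)[which(rng > 1e-9)[1]]
      abort(sprintf("conflicting weights for duplicated edge %s",
                    gsub("\r", " -- ", bad)))
    }
    edges <- edges[!duplicated(key), ]
  }
  edges <- arrange(edges, .data$from, .data$to)
  all_nodes <- sort(unique(c(edges$from, edges$to, as.character(nodes))))
  new_network(edges, all_nodes)
}

new_network <- function(edges, nodes) {
  edges <- as_tibble(as.data.frame(edges))
  structure(edges,
            nodes = nodes,
            class = c("iw_network", "tbl_df", "tbl", "data.frame"))
}

#' @rdname gene_network
#' @param net An `iw_network`.
#' @export
network_nodes <- function(net) {
  n <- attr(net, "nodes")
  if (is.null(n)) sort(unique(c(net$from, net$to))) else n
}

#' @export
print.iw_network <- function(x, ...) {
  cat(sprintf("# A gene network: %d nodes, %d edges\n",
              length(network_nodes(x)), nrow(x)))
  NextMethod()
}

# igraph view of a network; vertex order = network_nodes() (lexicographic)
as_igraph <- function(net, weighted = TRUE) {
  nodes <- network_nodes(net)
  g <- igraph::graph_from_data_frame(as.data.frame(net[c("from", "to")]),
                                     directed = FALSE,
                                     vertices = data.frame(name = nodes))
  if (weighted) igraph::E(g)$weight <- net$weight
  g
}

is_connected_network <- function(net) {
  g <- as_igraph(net, weighted = FALSE)
  igraph::vcount(g) <= 1 || igraph::is_connected(g)
}
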