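#' Build the pathway-pathway graph (the walkers' map)
#'
#' Connects every pair of pathways that share at least one gene; the edge
#' weight is the exact shared-gene count. Pathways sharing no genes with any
#' other remain in the graph as isolated nodes - they stay reachable through
#' the walkers' uniform random branch.
#'
#' @param sets A gene-set collection ([gene_sets()] / [read_gmt()]).
#' @return A tibble of class `iw_pathway_graph` with columns `from`, `to`,
#'   `weight` (shared-gene count) and attribute `pathways` holding every
#'   pathway id (including isolated ones).
#' @export
build_pathway_graph <- function(sets) {
  lst <- geneset_list(sets)
  ids <- names(lst)
  edges <- tibble(from = character(), to = character(), weight = numeric())
  if (length(ids) >= 2) {
    pairs <- combn(seq_along(ids), 2)
    shared <- vapply(seq_len(ncol(pairs)), function(k) {
      length(intersect(lst[[pairs[1, k]]], lst[[pairs[2, k]]]))
    }, numeric(1))
    keep <- shared >= 1
    edges <- tibble(from = ids[pairs[1, keep]], to = ids[pairs[2, keep]],
                    weight = shared[keep])
    swap <- edges$from > edges$to
    tmp <- edges$from[swap]
    edges$from[swap] <- edges$to[swap]
    edges$to[swap] <- tmp
    edges <- arrange(edges, .data$from, .data$to)
  }
  structure(edges, pathways = ids,
            class = c("iw_pathway_graph", "tbl_df", "tbl", "data.frame"))
}

#' @rdname build_pathway_graph
#' @param pgraph An `iw_pathway_graph`.
#' @export
pathway_graph_nodes <- function(pgraph) {
  attr(pgraph, "pathways") %||% sort(unique(c(pgraph$from, pgraph$to)))
}

#' Restrict a gene-set collection to the genes of a network
#'
#' Walkers can only move among genes present in the co-expression network, so
#' each pathway is intersected with the network's node set before any walk.
#' Pathways emptied by the restriction are dropped with a warning; if every
#' pathway empties, no informed move is possible and the call errors.
#'
#' @param sets A gene-set collection.
#' @param net An `iw_network`.
#' @return A list with `sets` (the restricted collection) and `coverage`
#'   (tibble: `pathway`, `n_genes`, `n_retained`, `retained_fraction`).
#' @export
restrict_to_network <- function(sets, net) {
  nodes <- network_nodes(net)
  lst <- geneset_list(sets)
  restricted <- lapply(lst, intersect, y = nodes)
  coverage <- tibble(
    pathway = names(lst),
    n_genes = unname(lengths(lst)),
    n_retained = unname(lengths(restricted)),
    retained_fraction = unname(lengths(restricted) / lengths(lst)))
  dropped <- names(lst)[lengths(restricted) == 0]
  restricted <- restricted[lengths(restricted) > 0]
  if (length(restricted) == 0) {
    abort("no pathway shares any gene with the network; informed moves impossible")
  }
  if (length(dropped) > 0) {
    warn(sprintf("%d pathway(s) share no genes with the network and were dropped: %s",
                 length(dropped), paste(dropped, collapse = ", ")))
  }
  list(sets = gene_sets(restricted), coverage = coverage)
}
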