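#' Extract the top-K passage-frequency subnetwork
#'
#' Retains the K highest-count edges of a frequency network (K = 500 by
#' default, the published cut). Ties at the cut are broken deterministically
#' by (count descending, then min node, then max node in lexicographic
#' order), so every retained count is >= every discarded count and repeated
#' runs select the same edges.
#'
#' @param freq A frequency network (`iw_freqnet` from [run_informed_walks()],
#'   or any edge tibble with a `count` or `weight` column).
#' @param k Number of edges to keep (default 500).
#' @return A tibble of class `iw_subnetwork` with columns `from`, `to`,
#'   `count`, attributes `nodes` (induced node set) and `k`.
#' @export
top_k_edges <- function(freq, k = 500) {
  k <- as.integer(k)
  if (k < 1) abort("k must be >= 1")
  freq <- as_tibble(as.data.frame(freq))
  if (!"count" %in% names(freq) && "weight" %in% names(freq)) {
    freq$count <- freq$weight
  }
  stopifnot(all(c("from", "to", "count") %in% names(freq)))
  lo <- pmin(freq$from, freq$to)
  hi <- pmax(freq$from, freq$to)
  freq$from <- lo; freq$to <- hi
  ranked <- arrange(freq[c("from", "to", "count")],
                    desc(.data$count), .data$from, .data$to)
  kept <- head(ranked, k)
  structure(kept,
            nodes = sort(unique(c(kept$from, kept$to))),
            k = k,
            class = c("iw_subnetwork", "tbl_df", "tbl", "data.frame"))
}

#' @rdname top_k_edges
#' @param subnet An `iw_subnetwork`.
#' @export
subnetwork_nodes <- function(subnet) {
  attr(subnet, "nodes") %||% sort(unique(c(subnet$from, subnet$to)))
}

#' Common and exclusive genes across subnetworks
#'
#' Given two or more named subnetworks (e.g. one per disease), computes the
#' genes common to all of them, the genes exclusive to each (present in that
#' subnetwork and no other), and the full pairwise node-overlap table.
#'
#' @param subnets A named list of `iw_subnetwork` objects or character
#'   vectors of gene ids (at least 2).
#' @return A list with `common` (character), `exclusive` (named list of
#'   character vectors) and `pairwise` (tibble: `a`, `b`, `n_shared`).
#' @export
overlap_sets <- function(subnets) {
  if (length(subnets) < 2) abort("at least 2 subnetworks are required")
  if (is.null(names(subnets)) || any(!nzchar(names(subnets)))) {
    abort("subnets must be a named list")
  }
  node_sets <- lapply(subnets, function(s) {
    if (is.character(s)) unique(s) else subnetwork_nodes(s)
  })
  common <- sort(Reduce(intersect, node_sets))
  exclusive <- imap(node_sets, function(nodes, nm) {
    others <- unique(unlist(node_sets[setdiff(names(node_sets), nm)]))
    sort(setdiff(nodes, others))
  })
  pairs <- combn(names(node_sets), 2)
  pairwise <- tibble(
    a = pairs[1, ], b = pairs[2, ],
    n_shared = vapply(seq_len(ncol(pairs)), function(i) {
      length(intersect(node_sets[[pairs[1, i]]], node_sets[[pairs[2, i]]]))
    }, numeric(1)))
  list(common = common, exclusive = exclusive, pairwise = pairwise)
}

#' Centrality-ranking baseline
#'
#' Ranks genes by the three standard unweighted centralities - degree,
#' betweenness and closeness - on the network topology, the conventional
#' baseline against which walk-based prioritisation is compared. On a
#' disconnected network, closeness is replaced by harmonic centrality
#' (defined across components) and the result is flagged via the
#' `disconnected` attribute and a warning.
#'
#' @param net An `iw_network`.
#' @param top_n Number of genes per ranking (default: all nodes).
#' @return A tibble with columns `metric`, `gene`, `value`, `rank`
#'   (descending value; ties broken by gene id), `top_n` rows per metric.
#' @export
centrality_rankings <- function(net, top_n = NULL) {
  net <- gene_network(net, nodes = attr(net, "nodes"))
  g <- as_igraph(net, weighted = FALSE)
  nodes <- network_nodes(net)
  top_n <- as.integer(top_n %||% length(nodes))
  if (top_n > length(nodes)) abort("top_n exceeds the number of nodes")
  disconnected <- !is_connected_network(net)
  deg <- igraph::degree(g)
  btw <- igraph::betweenness(g, weights = NA)
  clo <- if (disconnected) {
    warn("network is disconnected; using harmonic centrality instead of closeness")
    igraph::harmonic_centrality(g, weights = NA)
  } else {
    igraph::closeness(g, weights = NA)
  }
  one <- function(metric, v) {
    tibble(metric = metric, gene = nodes, value = as.numeric(v[nodes])) |>
      arrange(desc(.data$value), .data$gene) |>
      mutate(rank = row_number()) |>
      head(top_n)
  }
  out <- bind_rows(one("degree", deg), one("betweenness", btw),
                   one(if (disconnected) "harmonic" else "closeness", clo))
  attr(out, "disconnected") <- disconnected
  out
}

#' Split a gene signature by fold-change sign
#'
#' Partitions a gene set into up- and down-regulated lists from an external
#' fold-change table (e.g. produced by a differential-expression analysis).
#' Genes with zero fold change, or missing from the table, are excluded and
#' reported.
#'
#' @param nodes Character vector of gene ids.
#' @param fold_changes A data frame with columns `gene` and `log_fc`, or a
#'   named numeric vector.
#' @return A list with `up` and `down` (character vectors, ordered by
#'   decreasing absolute fold change) and `excluded` (tibble: `gene`,
#'   `reason`).
#' @export
split_signature <- function(nodes, fold_changes) {
  if (is.numeric(fold_changes) && !is.null(names(fold_changes))) {
    fold_changes <- tibble(gene = names(fold_changes),
                           log_fc = as.numeric(fold_changes))
  }
  stopifnot(all(c("gene", "log_fc") %in% names(fold_changes)))
  nodes <- unique(as.character(nodes))
  fc <- setNames(fold_changes$log_fc, fold_changes$gene)[nodes]
  missing <- nodes[is.na(fc)]
  zero <- nodes[!is.na(fc) & fc == 0]
  if (length(missing) > 0) {
    warn(sprintf("%d gene(s) without a fold change were excluded",
                 length(missing)))
  }
  keep <- nodes[!is.na(fc) & fc != 0]
  fc <- fc[keep]
  ord <- keep[order(-abs(fc), keep)]
  list(up = ord[fc[ord] > 0], down = ord[fc[ord] < 0],
       excluded = tibble(
         gene = c(missing, zero),
         reason = c(rep("missing", length(missing)),
                    rep("zero", length(zero)))))
}
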