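#' Connectivity-preserving edge filter
#'
#' Iteratively removes the weakest edges - keeping only edges with weight at
#' or above a threshold - and returns the most stringent threshold `t*` for
#' which the remaining subnetwork is still a single connected component
#' spanning every node of the input. Equivalently, `t*` is the bottleneck of
#' the maximum spanning tree: the largest cutoff under which the graph stays
#' connected.
#'
#' By default the scan is exact over the sorted distinct edge weights (via
#' the maximum-spanning-tree bottleneck). A `resolution` can be given to scan
#' a grid of `resolution` equal fractions of the maximum weight instead,
#' mirroring percentage-step filtering; the exact scan dominates any grid and
#' is the default.
#'
#' @param net A connected `iw_network`.
#' @param resolution Optional number of threshold steps (fractions of the
#'   maximum weight); `NULL` (default) scans exactly.
#' @return A list with `network` (the filtered `iw_network`, spanning all
#'   input nodes) and `threshold` (`t*`).
#' @export
connectivity_filter <- function(net, resolution = NULL) {
  net <- gene_network(net, nodes = attr(net, "nodes"))
  if (nrow(net) == 0) abort("network has no edges")
  if (!is_connected_network(net)) {
    abort(paste("input network is disconnected; filter the largest connected",
                "component first"))
  }
  if (is.null(resolution)) {
    g <- as_igraph(net)
    mst <- igraph::mst(g, weights = max(net$weight) + 1 - net$weight)
    t_star <- min(igraph::E(mst)$weight)
  } else {
    resolution <- as.integer(resolution)
    if (resolution < 1) abort("resolution must be a positive integer")
    grid <- sort(unique(c(0, seq_len(resolution) / resolution * max(net$weight))),
                 decreasing = TRUE)
    t_star <- 0
    for (t in grid) {
      keep <- net[net$weight >= t, ]
      sub <- new_network(keep, network_nodes(net))
      if (length(unique(c(keep$from, keep$to))) == length(network_nodes(net)) &&
          is_connected_network(sub)) {
        t_star <- t
        break
      }
    }
  }
  filtered <- new_network(net[net$weight >= t_star, ], network_nodes(net))
  list(network = filtered, threshold = t_star)
}

#' Infer a co-expression network from expression data
#'
#' The full reconstruction pipeline: pairwise mutual information
#' ([mutual_information()]), MRNETB edge selection ([mrnetb()]), and the
#' connectivity-preserving filter ([connectivity_filter()]). If the selected
#' network does not connect all genes, filtering is skipped with a warning
#' and the unfiltered network is returned. Deterministic given its input.
#'
#' @param expr Expression tibble (`gene` + sample columns).
#' @param estimator,k_or_bins Passed to [mutual_information()].
#' @param filter Apply the connectivity filter? Default `TRUE`.
#' @param resolution Passed to [connectivity_filter()].
#' @return An `iw_network` with attributes `threshold` (filter cutoff, `NA`
#'   when filtering was skipped) and `settings` (the resolved configuration).
#' @export
infer_network <- function(expr, estimator = "knn", k_or_bins = 3,
                          filter = TRUE, resolution = NULL) {
  mi <- mutual_information(expr, estimator = estimator, k_or_bins = k_or_bins)
  net <- mrnetb(mi)
  threshold <- NA_real_
  if (filter) {
    if (nrow(net) > 0 && is_connected_network(net)) {
      res <- connectivity_filter(net, resolution = resolution)
      net <- res$network
      threshold <- res$threshold
    } else {
      warn("inferred network is disconnected; connectivity filter skipped")
    }
  }
  attr(net, "threshold") <- threshold
  attr(net, "settings") <- list(estimator = estimator, k_or_bins = k_or_bins,
                                filter = filter, resolution = resolution)
  net
}
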