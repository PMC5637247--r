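#' Tidy an informed-walks run
#'
#' Returns the passage-frequency edges as a tibble, highest counts first.
#'
#' @param x An `informed_walks` object.
#' @param ... Unused.
#' @return A tibble with columns `from`, `to`, `count`.
#' @method tidy informed_walks
#' @export
tidy.informed_walks <- function(x, ...) {
  as_tibble(as.data.frame(x$frequency)) |>
    arrange(desc(.data$count), .data$from, .data$to)
}

#' One-row summary of an informed-walks run
#'
#' @param x An `informed_walks` object.
#' @param ... Unused.
#' @return A one-row tibble: walker/iteration counts, total traversals,
#'   number of traversed edges, and the empirical informed-branch fraction
#'   among pathway transitions.
#' @method glance informed_walks
#' @export
glance.informed_walks <- function(x, ...) {
  n_inf <- sum(x$log$pathway_informed)
  n_uni <- sum(x$log$pathway_uniform)
  tibble(n_walkers = x$config$n_walkers,
         n_iterations = x$config$n_iterations,
         total_traversals = attr(x$frequency, "total_traversals"),
         n_edges_traversed = nrow(x$frequency),
         n_flights = sum(x$log$flights),
         informed_fraction = if (n_inf + n_uni > 0) {
           n_inf / (n_inf + n_uni)
         } else NA_real_)
}

#' Plot the passage-count distribution of an informed-walks run
#'
#' Histogram of edge passage counts on a log10 x-axis, with the top-K cut
#' marked; heavy-tailed counts are the expected signature of walkers
#' concentrating on a small set of edges.
#'
#' @param object An `informed_walks` object.
#' @param k Mark the count at the K-th ranked edge (default 500, `NA` to
#'   omit).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot informed_walks
#' @export
autoplot.informed_walks <- function(object, k = 500, ...) {
  dat <- tidy(object)
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$count)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey30") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "edge passage count", y = "edges",
                  title = "Passage-frequency distribution") +
    ggplot2::theme_minimal()
  if (!is.na(k) && nrow(dat) >= k) {
    p <- p + ggplot2::geom_vline(xintercept = dat$count[k],
                                 linetype = "dashed")
  }
  p
}

#' Plot a centrality ranking table
#'
#' Dot plot of the top-ranked genes per centrality metric.
#'
#' @param rankings Output of [centrality_rankings()].
#' @param n_show Genes shown per metric.
#' @return A ggplot object.
#' @export
plot_centrality_rankings <- function(rankings, n_show = 15) {
  dat <- rankings |>
    group_by(.data$metric) |>
    slice_min(.data$rank, n = n_show) |>
    ungroup()
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$value,
                                    y = stats::reorder(.data$gene, .data$value))) +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~metric, scales = "free") +
    ggplot2::labs(x = "centrality", y = NULL) +
    ggplot2::theme_minimal()
}
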