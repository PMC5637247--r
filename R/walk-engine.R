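#' Informed random walks with restarts and Levy flights
#'
#' Runs `cfg$n_walkers` independent walkers over the co-expression network
#' `net`, each for `cfg$n_iterations` movement rounds. Every round first makes
#' a Levy decision: a step length `s` is drawn from the discrete power law
#' `P(s) proportional to s^-mu` on `1..levy_max_steps`; if `s >= levy_trigger`
#' the walker takes `s` greedy maximum-weight steps (avoiding nodes already
#' visited within the flight), escaping dense neighbourhoods. Otherwise the
#' round is an informed step: the walker locates the members of its current
#' pathway in the network, relocates along the full shortest path to the
#' nearest member (edge length per `cfg$distance_mode`), and then switches
#' pathway by a Monte-Carlo decision that with probability `p_informed`
#' favours pathways sharing more genes with the current one (weight-
#' proportional over pathway-graph neighbours) and otherwise samples uniformly
#' over all pathways.
#'
#' Every edge traversed by any walker is counted; the accumulated passage
#' frequencies form the frequency network. Walkers use independent RNG
#' streams derived from `cfg$seed`, so the result is reproducible and
#' invariant to walker execution order.
#'
#' @param net A connected `iw_network` (a warning is issued otherwise).
#' @param sets A gene-set collection; it is restricted to the network's genes
#'   and the pathway graph is (re)built from the restricted sets.
#' @param cfg A [walk_config()].
#' @param walker_order Optional permutation of `1:n_walkers` fixing execution
#'   order (parallelisation hook; the result must not depend on it).
#' @return An object of class `informed_walks`: a list with `frequency`
#'   (tibble `from`, `to`, `count`, attributes `nodes`, `total_traversals`),
#'   `log` (one row per walker: start points, branch and move counts),
#'   `coverage` (pathway restriction report) and `config` (resolved).
#' @seealso [top_k_edges()], [tidy.informed_walks()], [glance.informed_walks()]
#' @export
run_informed_walks <- function(net, sets, cfg = walk_config(),
                               walker_order = NULL) {
  net <- gene_network(net, nodes = attr(net, "nodes"))
  if (!is_connected_network(net)) {
    warn("network is not connected; walkers cannot leave their component")
  }
  restricted <- restrict_to_network(sets, net)
  env <- build_walk_env(net, restricted$sets, cfg)
  cfg <- env$cfg
  order <- walker_order %||% seq_len(cfg$n_walkers)
  stopifnot(setequal(order, seq_len(cfg$n_walkers)))
  streams <- rng_streams(cfg$seed, cfg$n_walkers)
  counts <- integer(env$n_edges)
  logs <- vector("list", cfg$n_walkers)
  for (w in order) {
    res <- eval_with_stream(streams[[w]], run_one_walker(env, cfg))
    counts <- counts + res$value$counts
    logs[[w]] <- tibble(
      walker = w,
      start_gene = env$nodes[res$value$start_gene],
      start_pathway = res$value$start_pathway,
      flights = res$value$n_flights,
      flight_noops = res$value$n_noops,
      informed_steps = res$value$n_steps,
      pathway_informed = res$value$n_pw_informed,
      pathway_uniform = res$value$n_pw_uniform,
      traversals = sum(res$value$counts))
  }
  pos <- counts > 0
  freq <- structure(
    tibble(from = env$edge_from[pos], to = env$edge_to[pos],
           count = counts[pos]),
    nodes = env$nodes, total_traversals = sum(counts),
    class = c("iw_freqnet", "tbl_df", "tbl", "data.frame"))
  structure(list(frequency = freq, log = bind_rows(logs),
                 coverage = restricted$coverage, config = cfg),
            class = "informed_walks")
}

#' @export
print.informed_walks <- function(x, ...) {
  cat(sprintf(paste0("Informed walks: %d walkers x %d iterations, ",
                     "%d traversals over %d edges (%d nodes)\n"),
              x$config$n_walkers, x$config$n_iterations,
              attr(x$frequency, "total_traversals"), nrow(x$frequency),
              length(attr(x$frequency, "nodes"))))
  invisible(x)
}

# ---- engine internals -------------------------------------------------------

# precompute everything the per-iteration loop touches: node indexing,
# sorted adjacency, the all-pairs distance matrix under the configured edge
# lengths, an edge-id lookup, pathway membership and the pathway map.
# memory is O(N^2); intended for desk-scale networks (N up to a few thousand)
build_walk_env <- function(net, sets, cfg) {
  nodes <- network_nodes(net)
  n <- length(nodes)
  cfg <- resolve_walk_config(cfg, n)
  ef <- match(net$from, nodes)
  et <- match(net$to, nodes)
  m <- nrow(net)
  eid <- matrix(0L, n, n)
  eid[cbind(ef, et)] <- seq_len(m)
  eid[cbind(et, ef)] <- seq_len(m)
  adj_idx <- vector("list", n)
  adj_w <- vector("list", n)
  deg_from <- split(seq_len(m), factor(ef, levels = seq_len(n)))
  deg_to <- split(seq_len(m), factor(et, levels = seq_len(n)))
  for (v in seq_len(n)) {
    es <- c(deg_from[[v]], deg_to[[v]])
    nb <- ifelse(ef[es] == v, et[es], ef[es])
    o <- order(nb)
    adj_idx[[v]] <- nb[o]
    adj_w[[v]] <- net$weight[es][o]
  }
  g <- as_igraph(net)
  len <- if (cfg$distance_mode == "inverse_weight") {
    1 / pmax(net$weight, 1e-12)
  } else {
    rep(1, m)
  }
  D <- igraph::distances(g, weights = len)
  D <- D[nodes, nodes]  # row/col order = lexicographic node order
  elen <- len
  lst <- geneset_list(sets)
  pw_members <- lapply(lst, function(gs) sort(match(gs, nodes)))
  pgraph <- build_pathway_graph(sets)
  pw_ids <- pathway_graph_nodes(pgraph)
  pw_nb <- pathway_neighbour_lists(pgraph)
  # discrete power-law CDF for flight lengths
  p <- seq_len(cfg$levy_max_steps)^(-cfg$levy_exponent)
  levy_cdf <- cumsum(p / sum(p))
  list(nodes = nodes, n = n, n_edges = m,
       edge_from = net$from, edge_to = net$to,
       eid = eid, adj_idx = adj_idx, adj_w = adj_w,
       D = D, elen = elen,
       pw_members = pw_members, pw_ids = pw_ids, pw_nb = pw_nb,
       levy_cdf = levy_cdf, cfg = cfg)
}

pathway_neighbour_lists <- function(pgraph) {
  ids <- pathway_graph_nodes(pgraph)
  nb <- setNames(vector("list", length(ids)), ids)
  for (i in seq_len(nrow(pgraph))) {
    a <- pgraph$from[i]; b <- pgraph$to[i]; w <- pgraph$weight[i]
    nb[[a]] <- rbind(nb[[a]], c(which(ids == b), w))
    nb[[b]] <- rbind(nb[[b]], c(which(ids == a), w))
  }
  lapply(nb, function(x) {
    if (is.null(x)) list(idx = integer(), w = numeric())
    else list(idx = as.integer(x[, 1]), w = as.numeric(x[, 2]))
  })
}

run_one_walker <- function(env, cfg) {
  counts <- integer(env$n_edges)
  cur <- sample.int(env$n, 1)
  pw <- sample.int(length(env$pw_ids), 1)
  start_gene <- cur
  start_pathway <- env$pw_ids[pw]
  n_flights <- 0L; n_noops <- 0L; n_steps <- 0L
  n_pw_informed <- 0L; n_pw_uniform <- 0L
  it <- 0L
  while (it < cfg$n_iterations) {
    it <- it + 1L
    fl <- engine_levy_flight(env, cur, cfg)
    if (fl$flew) {
      n_flights <- n_flights + 1L
      cur <- fl$cur
      # an edge can repeat within a flight (all-neighbours-visited rule),
      # so accumulate one traversal at a time
      for (e in fl$edges) counts[e] <- counts[e] + 1L
      next
    }
    n_noops <- n_noops + 1L
    st <- engine_informed_step(env, cur, pw, cfg)
    cur <- st$cur
    pw <- st$pw
    n_steps <- n_steps + st$moved
    n_flights <- n_flights + st$fallback_flew
    n_pw_informed <- n_pw_informed + st$n_informed
    n_pw_uniform <- n_pw_uniform + st$n_uniform
    for (e in st$edges) counts[e] <- counts[e] + 1L
  }
  list(counts = counts, start_gene = start_gene,
       start_pathway = start_pathway, n_flights = n_flights,
       n_noops = n_noops, n_steps = n_steps,
       n_pw_informed = n_pw_informed, n_pw_uniform = n_pw_uniform)
}

# one pathway transition; returns new pathway index and which branch resolved
engine_pathway_transition <- function(env, pw, p_informed) {
  nb <- env$pw_nb[[pw]]
  if (runif(1) < p_informed && length(nb$idx) > 0) {
    k <- if (length(nb$idx) == 1) 1L else
      sample.int(length(nb$idx), 1, prob = nb$w)
    list(pw = nb$idx[k], branch = "informed")
  } else {
    list(pw = sample.int(length(env$pw_ids), 1), branch = "uniform")
  }
}

# Levy decision + greedy flight; a sampled length below the trigger is a no-op
engine_levy_flight <- function(env, cur, cfg) {
  s <- findInterval(runif(1), env$levy_cdf) + 1L
  s <- min(s, cfg$levy_max_steps)
  if (s < cfg$levy_trigger) {
    return(list(flew = FALSE, cur = cur, edges = integer()))
  }
  visited <- c(cur)
  edges <- integer(s)
  x <- cur
  taken <- 0L
  for (step in seq_len(s)) {
    nbs <- env$adj_idx[[x]]
    if (length(nbs) == 0) break
    unvis <- !(nbs %in% visited)
    pick <- if (any(unvis)) {
      cand <- which(unvis)
      cand[which.max(env$adj_w[[x]][unvis])]  # first max = lexicographic tie
    } else {
      which.max(env$adj_w[[x]])
    }
    y <- nbs[pick]
    taken <- taken + 1L
    edges[taken] <- env$eid[x, y]
    visited <- c(visited, y)
    x <- y
  }
  list(flew = TRUE, cur = x, edges = edges[seq_len(taken)])
}

# informed relocation: move along the full shortest path to the nearest
# member of the current pathway, then switch pathway; if the pathway offers
# no reachable member, resample the pathway up to 10 times, then fall back
# to a single Levy decision
engine_informed_step <- function(env, cur, pw, cfg) {
  n_informed <- 0L; n_uniform <- 0L
  tries <- 0L
  repeat {
    cands <- env$pw_members[[env$pw_ids[pw]]]
    cands <- cands[cands != cur]
    if (length(cands) > 0) {
      d <- env$D[cur, cands]
      ok <- is.finite(d)
      if (any(ok)) {
        cands <- cands[ok]; d <- d[ok]
        dmin <- min(d)
        tied <- cands[d <= dmin * (1 + 1e-12)]
        target <- if (length(tied) == 1) tied else
          tied[sample.int(length(tied), 1)]
        edges <- reconstruct_path(env, cur, target)
        tr <- engine_pathway_transition(env, pw, cfg$p_informed)
        if (tr$branch == "informed") n_informed <- n_informed + 1L
        else n_uniform <- n_uniform + 1L
        return(list(cur = target, pw = tr$pw, edges = edges, moved = 1L,
                    fallback_flew = 0L, n_informed = n_informed,
                    n_uniform = n_uniform))
      }
    }
    tries <- tries + 1L
    if (tries > 10L) {
      fl <- engine_levy_flight(env, cur, cfg)
      return(list(cur = fl$cur, pw = pw, edges = fl$edges, moved = 0L,
                  fallback_flew = as.integer(fl$flew),
                  n_informed = n_informed, n_uniform = n_uniform))
    }
    tr <- engine_pathway_transition(env, pw, cfg$p_informed)
    if (tr$branch == "informed") n_informed <- n_informed + 1L
    else n_uniform <- n_uniform + 1L
    pw <- tr$pw
  }
}

# the lexicographically-first shortest path from cur to target, as edge ids;
# greedy forward reconstruction over the precomputed distance matrix
reconstruct_path <- function(env, cur, target) {
  edges <- integer()
  x <- cur
  guard <- 0L
  while (x != target) {
    guard <- guard + 1L
    if (guard > env$n) abort("shortest-path reconstruction failed to terminate")
    nbs <- env$adj_idx[[x]]
    ws <- env$adj_w[[x]]
    len <- if (env$cfg$distance_mode == "inverse_weight") {
      1 / pmax(ws, 1e-12)
    } else {
      rep(1, length(ws))
    }
    slack <- abs(len + env$D[nbs, target] - env$D[x, target])
    on_path <- slack <= 1e-9 * pmax(1, env$D[x, target])
    if (!any(on_path)) abort("no shortest-path continuation found")
    y <- nbs[which(on_path)[1]]  # neighbours sorted: lexicographic choice
    edges <- c(edges, env$eid[x, y])
    x <- y
  }
  edges
}
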