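#' Pick a walker's starting gene and pathway
#'
#' The starting gene is drawn uniformly over the network's nodes and the
#' starting pathway uniformly (and independently) over the pathway graph's
#' nodes. Consumes the current RNG state; seed with `set.seed()` for
#' reproducibility.
#'
#' @param net An `iw_network`.
#' @param pgraph An `iw_pathway_graph` (see [build_pathway_graph()]).
#' @return A one-row tibble with columns `gene` and `pathway`.
#' @export
select_start <- function(net, pgraph) {
  nodes <- network_nodes(net)
  pws <- pathway_graph_nodes(pgraph)
  if (length(nodes) == 0) abort("network has no nodes")
  if (length(pws) == 0) abort("pathway graph has no nodes")
  tibble(gene = nodes[sample.int(length(nodes), 1)],
         pathway = pws[sample.int(length(pws), 1)])
}

#' One Monte-Carlo pathway transition
#'
#' With probability `p_informed` the next pathway is sampled among the
#' current pathway's neighbours in the pathway graph, proportionally to the
#' shared-gene edge weight (pathways sharing more genes are favoured); with
#' the complementary probability it is sampled uniformly over all pathways -
#' possibly one sharing no genes with the current one, or the current
#' pathway itself. If the current pathway has no neighbour, the informed
#' branch falls through to the uniform branch. Consumes the current RNG
#' state.
#'
#' @param pgraph An `iw_pathway_graph`.
#' @param current Current pathway id.
#' @param p_informed Probability of the informed branch (default 0.7).
#' @return A one-row tibble with columns `from`, `to` and `branch`
#'   (`"informed"` or `"uniform"`).
#' @export
pathway_transition <- function(pgraph, current, p_informed = 0.7) {
  ids <- pathway_graph_nodes(pgraph)
  if (!current %in% ids) abort(sprintf("unknown pathway '%s'", current))
  nb_from <- pgraph$to[pgraph$from == current]
  nb_to <- pgraph$from[pgraph$to == current]
  nb <- c(nb_from, nb_to)
  w <- c(pgraph$weight[pgraph$from == current],
         pgraph$weight[pgraph$to == current])
  if (runif(1) < p_informed && length(nb) > 0) {
    k <- if (length(nb) == 1) 1L else sample.int(length(nb), 1, prob = w)
    tibble(from = current, to = nb[k], branch = "informed")
  } else {
    tibble(from = current, to = ids[sample.int(length(ids), 1)],
           branch = "uniform")
  }
}

#' Simulate many pathway transitions
#'
#' Vectorised Monte-Carlo simulation of [pathway_transition()]: each draw
#' starts from a uniformly random current pathway (or a fixed one) and
#' records which branch resolved it. Used to verify the 70%/30% informed /
#' uniform branch split empirically.
#'
#' @param pgraph An `iw_pathway_graph`.
#' @param n Number of transitions.
#' @param p_informed Probability of the informed branch.
#' @param seed Integer seed.
#' @param from Optional fixed current pathway id; default random per draw.
#' @return A tibble with `n` rows and columns `from`, `to`, `branch`.
#' @export
simulate_pathway_transitions <- function(pgraph, n, p_informed = 0.7,
                                         seed = 1, from = NULL) {
  ids <- pathway_graph_nodes(pgraph)
  npw <- length(ids)
  nb <- pathway_neighbour_lists(pgraph)
  with_seed(seed, {
    cur <- if (is.null(from)) {
      sample.int(npw, n, replace = TRUE)
    } else {
      rep(match(from, ids), n)
    }
    u <- runif(n)
    has_nb <- lengths(lapply(nb, `[[`, "idx"))[cur] > 0
    informed <- u < p_informed & has_nb
    to <- integer(n)
    if (any(!informed)) {
      to[!informed] <- sample.int(npw, sum(!informed), replace = TRUE)
    }
    for (p in unique(cur[informed])) {
      rows <- which(informed & cur == p)
      cand <- nb[[p]]
      to[rows] <- if (length(cand$idx) == 1) cand$idx else
        sample(cand$idx, length(rows), replace = TRUE, prob = cand$w)
    }
    tibble(from = ids[cur], to = ids[to],
           branch = ifelse(informed, "informed", "uniform"))
  })
}

#' One informed step of a walker
#'
#' Finds the members of the walker's current pathway in the network, moves
#' along the full shortest path (edge length per `cfg$distance_mode`) to the
#' member at minimum distance - distance ties among candidate genes broken
#' uniformly at random, equal-length path ties broken lexicographically -
#' and then updates the current pathway with one [pathway_transition()]. If
#' the pathway has no member present or reachable, the pathway is resampled
#' up to 10 times before falling back to a single Levy decision. Consumes
#' the current RNG state.
#'
#' @param state A list (or one-row tibble) with `gene` and `pathway`.
#' @param net A connected `iw_network`.
#' @param sets A gene-set collection (restricted to `net` internally).
#' @param cfg A [walk_config()].
#' @return A list with `state` (updated gene/pathway) and `edges` (tibble of
#'   traversed edges `from`, `to`, in traversal order).
#' @export
informed_step <- function(state, net, sets, cfg = walk_config()) {
  env <- build_walk_env(net, restrict_to_network(sets, net)$sets, cfg)
  cur <- match(state$gene, env$nodes)
  pw <- match(state$pathway, env$pw_ids)
  if (is.na(cur)) abort("state$gene is not a node of the network")
  if (is.na(pw)) abort("state$pathway is not in the pathway graph")
  st <- engine_informed_step(env, cur, pw, env$cfg)
  list(state = list(gene = env$nodes[st$cur], pathway = env$pw_ids[st$pw]),
       edges = orient_trace(env, state$gene, st$edges))
}

# rewrite a sequence of (canonically stored) edge ids as a directed walk
# starting at `start`
orient_trace <- function(env, start, edge_ids) {
  from <- character(length(edge_ids))
  to <- character(length(edge_ids))
  x <- start
  for (i in seq_along(edge_ids)) {
    a <- env$edge_from[edge_ids[i]]
    b <- env$edge_to[edge_ids[i]]
    from[i] <- x
    to[i] <- if (a == x) b else a
    x <- to[i]
  }
  tibble(from = from, to = to)
}

#' One Levy decision / flight of a walker
#'
#' Samples a step length `s` from the discrete power law
#' `P(s) proportional to s^-mu` on `1..levy_max_steps`. If `s` is below
#' `levy_trigger` the flight is a no-op; otherwise the walker takes `s`
#' greedy steps, each along the incident edge of maximum weight whose far
#' node was not yet visited within this flight (ties: lexicographic node
#' order; if every neighbour was visited, the maximum-weight neighbour
#' regardless). Consumes the current RNG state.
#'
#' @inheritParams informed_step
#' @return A list with `state`, `flew` (logical) and `edges` (tibble of
#'   traversed edges in order; empty for a no-op).
#' @export
levy_flight <- function(state, net, cfg = walk_config()) {
  net <- gene_network(net, nodes = attr(net, "nodes"))
  nodes <- network_nodes(net)
  cfg <- resolve_walk_config(cfg, length(nodes))
  env <- build_flight_env(net, cfg)
  cur <- match(state$gene, env$nodes)
  if (is.na(cur)) abort("state$gene is not a node of the network")
  fl <- engine_levy_flight(env, cur, cfg)
  old_gene <- state$gene
  state$gene <- env$nodes[fl$cur]
  list(state = state, flew = fl$flew,
       edges = orient_trace(env, old_gene, fl$edges))
}

# adjacency-only environment (no distance matrix) for standalone flights
build_flight_env <- function(net, cfg) {
  nodes <- network_nodes(net)
  n <- length(nodes)
  ef <- match(net$from, nodes)
  et <- match(net$to, nodes)
  m <- nrow(net)
  eid <- matrix(0L, n, n)
  eid[cbind(ef, et)] <- seq_len(m)
  eid[cbind(et, ef)] <- seq_len(m)
  adj_idx <- vector("list", n)
  adj_w <- vector("list", n)
  for (v in seq_len(n)) {
    es <- which(ef == v | et == v)
    nbv <- ifelse(ef[es] == v, et[es], ef[es])
    o <- order(nbv)
    adj_idx[[v]] <- nbv[o]
    adj_w[[v]] <- net$weight[es][o]
  }
  p <- seq_len(cfg$levy_max_steps)^(-cfg$levy_exponent)
  list(nodes = nodes, n = n, n_edges = m, eid = eid,
       adj_idx = adj_idx, adj_w = adj_w,
       edge_from = net$from, edge_to = net$to,
       levy_cdf = cumsum(p / sum(p)), cfg = cfg)
}
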