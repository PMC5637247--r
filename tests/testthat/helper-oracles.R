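# Independent oracles used across the suite. Deliberately naive: exhaustive
# enumeration, base-R graph traversal, closed forms. They share no code with
# the implementation paths they check.

# exhaustive MRMR maximisation over every predictor subset per target;
# ties -> smaller subset, then lexicographically first
brute_mrnetb_edges <- function(mi) {
  g <- nrow(mi)
  genes <- rownames(mi)
  edges <- character(0)
  for (y in seq_len(g)) {
    preds <- setdiff(seq_len(g), y)
    best <- list(J = -Inf, S = integer(0))
    for (mask in 0:(2^length(preds) - 1)) {
      S <- preds[bitwAnd(mask, 2^(seq_along(preds) - 1)) > 0]
      J <- brute_mrmr_J(mi, y, S)
      if (J > best$J + 1e-12 ||
          (abs(J - best$J) <= 1e-12 && length(S) < length(best$S))) {
        best <- list(J = J, S = S)
      }
    }
    for (i in best$S) {
      edges <- c(edges, paste(sort(c(genes[i], genes[y])), collapse = "|"))
    }
  }
  sort(unique(edges))
}

brute_mrmr_J <- function(mi, y, S) {
  if (length(S) == 0) return(0)
  rel <- sum(mi[S, y])
  if (length(S) == 1) return(rel)
  rel - sum(mi[S, S]) / (length(S) * (length(S) - 1))
}

edge_keys <- function(net) sort(paste(net$from, net$to, sep = "|"))

# base-R DFS: does the edge subset with weight >= t connect all nodes?
dfs_spanning_connected <- function(edges, nodes) {
  if (length(nodes) <= 1) return(TRUE)
  adj <- lapply(setNames(vector("list", length(nodes)), nodes), identity)
  for (i in seq_len(nrow(edges))) {
    adj[[edges$from[i]]] <- c(adj[[edges$from[i]]], edges$to[i])
    adj[[edges$to[i]]] <- c(adj[[edges$to[i]]], edges$from[i])
  }
  seen <- setNames(rep(FALSE, length(nodes)), nodes)
  stack <- nodes[1]
  seen[stack] <- TRUE
  while (length(stack) > 0) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    for (w in adj[[v]]) {
      if (!seen[w]) {
        seen[w] <- TRUE
        stack <- c(stack, w)
      }
    }
  }
  all(seen)
}

# descending threshold scan: largest cutoff keeping a spanning connected graph
bottleneck_scan <- function(net) {
  nodes <- network_nodes(net)
  for (t in sort(unique(net$weight), decreasing = TRUE)) {
    keep <- net[net$weight >= t, , drop = FALSE]
    if (dfs_spanning_connected(keep, nodes)) return(t)
  }
  stop("no threshold keeps the graph connected")
}

# unweighted all-pairs shortest-path betweenness by explicit path counting
# (BFS distances + shortest-path multiplicity DP, no igraph)
brute_betweenness <- function(net) {
  nodes <- network_nodes(net)
  n <- length(nodes)
  adj <- vector("list", n)
  ef <- match(net$from, nodes)
  et <- match(net$to, nodes)
  for (i in seq_along(ef)) {
    adj[[ef[i]]] <- c(adj[[ef[i]]], et[i])
    adj[[et[i]]] <- c(adj[[et[i]]], ef[i])
  }
  D <- matrix(Inf, n, n)
  SIG <- matrix(0, n, n)
  for (s in seq_len(n)) {
    d <- rep(Inf, n); sig <- rep(0, n)
    d[s] <- 0; sig[s] <- 1
    frontier <- s
    while (length(frontier) > 0) {
      nxt <- integer(0)
      for (v in frontier) {
        for (w in adj[[v]]) {
          if (!is.finite(d[w])) {
            d[w] <- d[v] + 1
            nxt <- c(nxt, w)
          }
          if (d[w] == d[v] + 1) sig[w] <- sig[w] + sig[v]
        }
      }
      frontier <- unique(nxt)
    }
    D[s, ] <- d
    SIG[s, ] <- sig
  }
  btw <- numeric(n)
  for (s in 1:(n - 1)) {
    for (t in (s + 1):n) {
      if (!is.finite(D[s, t])) next
      for (v in seq_len(n)) {
        if (v == s || v == t) next
        if (D[s, v] + D[v, t] == D[s, t]) {
          btw[v] <- btw[v] + SIG[s, v] * SIG[v, t] / SIG[s, t]
        }
      }
    }
  }
  setNames(btw, nodes)
}

# all-pairs hop-count distances by Floyd-Warshall (small graphs)
floyd_warshall_hops <- function(net) {
  nodes <- network_nodes(net)
  n <- length(nodes)
  D <- matrix(Inf, n, n, dimnames = list(nodes, nodes))
  diag(D) <- 0
  for (i in seq_len(nrow(net))) {
    D[net$from[i], net$to[i]] <- 1
    D[net$to[i], net$from[i]] <- 1
  }
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
      }
    }
  }
  D
}

# random connected weighted graph with distinct weights (for filter oracles)
random_connected_net <- function(n, p = 0.3) {
  nodes <- sprintf("N%02d", seq_len(n))
  repeat {
    pairs <- t(combn(nodes, 2))
    keep <- runif(nrow(pairs)) < p
    perm <- sample(nodes)
    tree <- cbind(perm[-1],
                  vapply(2:n, function(i) perm[sample.int(i - 1, 1)],
                         character(1)))
    el <- rbind(pairs[keep, , drop = FALSE], tree)
    key <- paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]))
    el <- el[!duplicated(key), , drop = FALSE]
    net <- gene_network(tibble::tibble(
      from = el[, 1], to = el[, 2],
      weight = sample(seq_len(nrow(el))) / nrow(el)))
    if (length(network_nodes(net)) == n) return(net)
  }
}

# small random gene-set collection over a gene universe
random_gene_sets <- function(genes, n_sets, size_range = c(3, 6)) {
  sets <- lapply(seq_len(n_sets), function(i) {
    sample(genes, sample(size_range[1]:size_range[2], 1))
  })
  gene_sets(setNames(sets, sprintf("RS%02d", seq_len(n_sets))))
}
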