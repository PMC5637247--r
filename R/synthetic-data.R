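#' Specification for the synthetic benchmark generators
#'
#' Bundles every knob of the synthetic study system: an expression matrix with
#' planted co-expressed gene modules, and a pathway collection in which some
#' pathways wrap the planted modules and the remaining "random" pathways form
#' an overlap chain so the pathway graph is connected by construction.
#'
#' Within a module, genes follow the one-factor model
#' `x_i = sqrt(r) * f + sqrt(1 - r) * e_i` with `f` and `e_i` independent
#' standard normals (scaled by `noise_sd`), so the expected pairwise Pearson
#' correlation inside a module is exactly `r = within_module_correlation`.
#'
#' @param n_genes Number of genes.
#' @param n_samples Number of samples.
#' @param n_modules Number of planted co-expressed modules.
#' @param module_size Genes per module (`n_modules * module_size <= n_genes`).
#' @param within_module_correlation Target pairwise correlation `r` in `[0, 1)`.
#' @param noise_sd Marginal standard deviation of every gene.
#' @param n_pathways Number of pathways to generate.
#' @param pathway_size_range Integer pair: inclusive range of pathway sizes.
#' @param pathway_overlap_fraction Fraction of each random pathway's members
#'   shared with the previous random pathway (chains the pathway graph).
#' @param fraction_pathways_aligned_to_modules Fraction of pathways built as
#'   supersets of planted modules.
#' @param seed Integer seed; one independent RNG stream is derived per
#'   generator, so each generator is reproducible in isolation.
#' @return A list of class `synth_spec`.
#' @export
synth_spec <- function(n_genes = 300, n_samples = 200, n_modules = 2,
                       module_size = 25, within_module_correlation = 0.8,
                       noise_sd = 1, n_pathways = 20,
                       pathway_size_range = c(8, 15),
                       pathway_overlap_fraction = 0.5,
                       fraction_pathways_aligned_to_modules = 0.3,
                       seed = 1) {
  spec <- list(n_genes = as.integer(n_genes),
               n_samples = as.integer(n_samples),
               n_modules = as.integer(n_modules),
               module_size = as.integer(module_size),
               within_module_correlation = within_module_correlation,
               noise_sd = noise_sd,
               n_pathways = as.integer(n_pathways),
               pathway_size_range = as.integer(pathway_size_range),
               pathway_overlap_fraction = pathway_overlap_fraction,
               fraction_pathways_aligned_to_modules =
                 fraction_pathways_aligned_to_modules,
               seed = as.integer(seed))
  if (spec$n_modules * spec$module_size > spec$n_genes) {
    abort("infeasible spec: n_modules * module_size exceeds n_genes")
  }
  if (within_module_correlation < 0 || within_module_correlation >= 1) {
    abort("within_module_correlation must lie in [0, 1)")
  }
  if (noise_sd <= 0) abort("noise_sd must be positive")
  if (length(spec$pathway_size_range) != 2 ||
      spec$pathway_size_range[1] < 2 ||
      diff(spec$pathway_size_range) < 0) {
    abort("pathway_size_range must be an increasing pair with minimum >= 2")
  }
  if (spec$pathway_overlap_fraction < 0 || spec$pathway_overlap_fraction > 1) {
    abort("pathway_overlap_fraction must lie in [0, 1]")
  }
  f <- spec$fraction_pathways_aligned_to_modules
  if (f < 0 || f > 1) {
    abort("fraction_pathways_aligned_to_modules must lie in [0, 1]")
  }
  structure(spec, class = "synth_spec")
}

synth_gene_ids <- function(n) {
  sprintf("G%0*d", max(3L, nchar(as.character(n))), seq_len(n))
}

#' Generate an expression matrix with planted co-expressed modules
#'
#' Module genes share a latent factor (see [synth_spec()]); background genes
#' are independent normal draws. Deterministic given `spec$seed`.
#'
#' @param spec A [synth_spec()].
#' @return A list with `expression` (tibble: `gene` + sample columns) and
#'   `modules` (tibble: `gene`, `module`) giving the ground-truth assignment.
#' @export
generate_expression <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  stream <- rng_streams(spec$seed, 1)[[1]]
  eval_with_stream(stream, {
    n <- spec$n_genes; p <- spec$n_samples
    r <- spec$within_module_correlation
    genes <- synth_gene_ids(n)
    module_genes <- sample(genes, spec$n_modules * spec$module_size)
    assignment <- rep(seq_len(spec$n_modules), each = spec$module_size)
    vals <- matrix(rnorm(n * p, sd = spec$noise_sd), nrow = n,
                   dimnames = list(genes, NULL))
    for (m in seq_len(spec$n_modules)) {
      idx <- module_genes[assignment == m]
      f <- rnorm(p)
      eps <- matrix(rnorm(length(idx) * p), nrow = length(idx))
      vals[idx, ] <- spec$noise_sd *
        (sqrt(r) * matrix(f, nrow = length(idx), ncol = p, byrow = TRUE) +
           sqrt(1 - r) * eps)
    }
    expr <- as_tibble(as.data.frame(vals))
    names(expr) <- sprintf("S%03d", seq_len(p))
    list(expression = bind_cols(tibble(gene = genes), expr),
         modules = tibble(gene = module_genes, module = assignment) |>
           arrange(.data$module, .data$gene))
  })$value
}

#' Generate a pathway collection with controlled module alignment and overlap
#'
#' A stated fraction of pathways are supersets of the planted modules (module
#' genes plus random padding); the remaining "random" pathways form a chain in
#' which each pathway shares `pathway_overlap_fraction` of its members with
#' the previous one, so the random part of the pathway graph is connected
#' whenever the overlap fraction is positive. With overlap 0 the random
#' pathways are mutually disjoint.
#'
#' @param spec A [synth_spec()].
#' @param modules Ground-truth module tibble from [generate_expression()];
#'   may be `NULL` when no pathways are module-aligned.
#' @return A list with `sets` (a [gene_sets()] tibble) and `alignment`
#'   (tibble: `pathway`, `module`; `NA` for random pathways).
#' @export
generate_gene_sets <- function(spec, modules = NULL) {
  stopifnot(inherits(spec, "synth_spec"))
  n_aligned <- round(spec$fraction_pathways_aligned_to_modules *
                       spec$n_pathways)
  if (n_aligned > 0 && is.null(modules)) {
    abort("modules must be supplied when some pathways are module-aligned")
  }
  stream <- rng_streams(spec$seed, 2)[[2]]
  eval_with_stream(stream, {
    genes <- synth_gene_ids(spec$n_genes)
    lo <- spec$pathway_size_range[1]; hi <- spec$pathway_size_range[2]
    ids <- sprintf("P%02d", seq_len(spec$n_pathways))
    sets <- vector("list", spec$n_pathways)
    align <- rep(NA_integer_, spec$n_pathways)
    for (j in seq_len(n_aligned)) {
      m <- ((j - 1) %% spec$n_modules) + 1L
      core <- modules$gene[modules$module == m]
      size <- max(length(core), sample(lo:hi, 1))
      pad <- sample(setdiff(genes, core), size - length(core))
      sets[[j]] <- c(core, pad)
      align[j] <- m
    }
    used <- character(0)  # genes consumed by earlier random pathways
    prev <- NULL
    for (j in seq_len(spec$n_pathways - n_aligned)) {
      size <- if (lo == hi) lo else sample(lo:hi, 1)
      n_shared <- if (is.null(prev)) 0L else
        min(round(spec$pathway_overlap_fraction * size), length(prev))
      fresh_pool <- setdiff(genes, used)
      if (size - n_shared > length(fresh_pool)) {
        abort("requested overlap/size infeasible: gene pool exhausted")
      }
      shared <- if (n_shared > 0) sample(prev, n_shared) else character(0)
      fresh <- sample(fresh_pool, size - n_shared)
      pw <- c(shared, fresh)
      sets[[n_aligned + j]] <- pw
      used <- union(used, pw)
      prev <- pw
    }
    list(sets = gene_sets(setNames(sets, ids)),
         alignment = tibble(pathway = ids, module = align))
  })$value
}

#' Generate a weighted benchmark network for the walk engine
#'
#' Three topologies: `scale_free` (preferential attachment), `small_world`
#' (Watts-Strogatz rewiring), and `planted_dense_blocks` - high-weight cliques
#' (dense neighbourhoods that can entrap a topology-driven walker) joined to a
#' sparse low-weight background. All weights lie in (0, 1]; the returned
#' network is connected.
#'
#' @param n_genes Number of nodes (>= 10).
#' @param topology One of `"scale_free"`, `"small_world"`,
#'   `"planted_dense_blocks"`.
#' @param seed Integer seed.
#' @param n_blocks,block_size Planted-blocks parameters (ignored otherwise).
#' @return An `iw_network`; for `planted_dense_blocks` the ground-truth block
#'   assignment is attached as attribute `blocks` (tibble: `gene`, `block`).
#' @export
generate_walk_network <- function(n_genes,
                                  topology = c("scale_free", "small_world",
                                               "planted_dense_blocks"),
                                  seed = 1, n_blocks = 2,
                                  block_size = max(10L, ceiling(n_genes / 12))) {
  topology <- match.arg(topology)
  if (n_genes < 10) abort("n_genes must be at least 10")
  stream <- rng_streams(seed, 3)[[3]]
  eval_with_stream(stream, {
    genes <- synth_gene_ids(n_genes)
    if (topology == "planted_dense_blocks") {
      if (n_blocks * block_size > n_genes) {
        abort("n_blocks * block_size exceeds n_genes")
      }
      block_genes <- sample(genes, n_blocks * block_size)
      block_of <- rep(seq_len(n_blocks), each = block_size)
      background <- setdiff(genes, block_genes)
      edges <- list()
      for (b in seq_len(n_blocks)) {
        g <- sort(block_genes[block_of == b])
        pairs <- t(combn(g, 2))
        edges[[length(edges) + 1]] <- tibble(
          from = pairs[, 1], to = pairs[, 2],
          weight = runif(nrow(pairs), 0.7, 1))
      }
      anchors <- if (length(background) > 0) background else
        vapply(seq_len(n_blocks), function(b)
          sort(block_genes[block_of == b])[1], character(1))
      if (length(background) > 1) {
        # random spanning tree plus extra edges over the background
        perm <- sample(background)
        parent <- vapply(seq_along(perm)[-1],
                         function(i) perm[sample.int(i - 1, 1)], character(1))
        tree <- tibble(from = perm[-1], to = parent)
        n_extra <- max(0L, round(0.5 * length(background)))
        extra <- tibble(from = sample(background, n_extra, replace = TRUE),
                        to = sample(background, n_extra, replace = TRUE))
        bg <- bind_rows(tree, extra) |> filter(.data$from != .data$to)
        bg$weight <- runif(nrow(bg), 0.05, 0.3)
        edges[[length(edges) + 1]] <- bg
      }
      for (b in seq_len(n_blocks)) {
        g <- block_genes[block_of == b]
        targets <- setdiff(anchors, g)
        bridge_to <- sample(targets, min(2, length(targets)))
        edges[[length(edges) + 1]] <- tibble(
          from = sample(g, length(bridge_to), replace = TRUE),
          to = bridge_to, weight = runif(length(bridge_to), 0.05, 0.2))
      }
      if (length(background) == 0 && n_blocks > 2) {
        # chain the block anchors so the block graph cannot fall apart
        edges[[length(edges) + 1]] <- tibble(
          from = anchors[-n_blocks], to = anchors[-1],
          weight = runif(n_blocks - 1, 0.05, 0.2))
      }
      all_edges <- bind_rows(edges)
      lo_nd <- pmin(all_edges$from, all_edges$to)
      hi_nd <- pmax(all_edges$from, all_edges$to)
      all_edges <- all_edges[!duplicated(paste(lo_nd, hi_nd)), ]
      net <- gene_network(all_edges, nodes = genes)
      attr(net, "blocks") <- tibble(gene = block_genes, block = block_of) |>
        arrange(.data$block, .data$gene)
    } else {
      g <- NULL
      for (try in 1:50) {
        g <- if (topology == "scale_free") {
          igraph::sample_pa(n_genes, m = 2, directed = FALSE)
        } else {
          igraph::simplify(igraph::sample_smallworld(1, n_genes, nei = 2,
                                                     p = 0.05))
        }
        if (igraph::is_connected(g)) break
        g <- NULL
      }
      if (is.null(g)) abort("failed to generate a connected topology")
      el <- igraph::as_edgelist(g, names = FALSE)
      net <- gene_network(tibble(from = genes[el[, 1]], to = genes[el[, 2]],
                                 weight = runif(nrow(el), 0.05, 1)),
                          nodes = genes)
    }
    if (!is_connected_network(net)) abort("generated network is disconnected")
    net
  })$value
}
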