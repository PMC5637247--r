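# shared small-world fixture: gene ids match the synthetic pathway universe
walk_fixture <- function(seed = 2) {
  net <- generate_walk_network(50, "small_world", seed = seed)
  spec <- synth_spec(n_genes = 50, n_pathways = 6,
                     pathway_size_range = c(5, 8),
                     pathway_overlap_fraction = 0.5,
                     fraction_pathways_aligned_to_modules = 0,
                     n_modules = 1, module_size = 2, seed = seed)
  list(net = net, sets = generate_gene_sets(spec)$sets)
}

# walk config whose Levy branch never fires: every round is an informed step
no_levy <- function(...) {
  walk_config(levy_max_steps = 1, levy_trigger = 2, ...)
}

test_that("walk starts are uniform and independent over genes and pathways", {
  net <- gene_network(tibble::tibble(from = c("A", "B", "C"),
                                     to = c("B", "C", "D"), weight = 1))
  pg <- build_pathway_graph(gene_sets(list(P1 = c("A", "B"), P2 = c("C"))))
  set.seed(99)
  draws <- purrr::map_dfr(1:5000, function(i) select_start(net, pg))
  freq <- table(draws$gene) / nrow(draws)
  expect_true(all(abs(freq - 0.25) < 0.02))  # ~3 binomial SE at n = 5000
  expect_true(all(abs(table(draws$pathway) / nrow(draws) - 0.5) < 0.025))
  set.seed(123)
  s1 <- select_start(net, pg)
  set.seed(123)
  expect_identical(s1, select_start(net, pg))
})

test_that("informed transitions sample neighbours by shared-gene weight", {
  # P1 shares 3 genes with P2 and 1 with P3 -> 0.75 / 0.25 at p_informed = 1
  sets <- gene_sets(list(P1 = c("a", "b", "c", "d"),
                         P2 = c("a", "b", "c", "x"),
                         P3 = c("d", "y", "z")))
  pg <- build_pathway_graph(sets)
  sim <- simulate_pathway_transitions(pg, 2e4, p_informed = 1, seed = 4,
                                      from = "P1")
  expect_true(all(sim$branch == "informed"))
  expect_equal(mean(sim$to == "P2"), 0.75, tolerance = 0.02)
  expect_equal(mean(sim$to == "P3"), 0.25, tolerance = 0.06)
})

test_that("the uniform branch covers all pathways including the current one", {
  sets <- gene_sets(list(P1 = c("a", "b"), P2 = c("b", "c"), P3 = c("q")))
  pg <- build_pathway_graph(sets)
  sim <- simulate_pathway_transitions(pg, 3e4, p_informed = 0, seed = 6,
                                      from = "P1")
  expect_true(all(sim$branch == "uniform"))
  freq <- table(factor(sim$to, levels = c("P1", "P2", "P3"))) / nrow(sim)
  expect_true(all(abs(freq - 1 / 3) < 0.01))
})

test_that("an isolated pathway falls through to the uniform branch", {
  sets <- gene_sets(list(P1 = c("a", "b"), P2 = c("b", "c"), P3 = c("q")))
  pg <- build_pathway_graph(sets)
  sim <- simulate_pathway_transitions(pg, 5000, p_informed = 1, seed = 2,
                                      from = "P3")
  expect_true(all(sim$branch == "uniform"))
  set.seed(11)
  one <- pathway_transition(pg, "P3", p_informed = 1)
  expect_equal(one$branch, "uniform")
})

test_that("Levy step lengths follow the normalised discrete power law", {
  net <- walk_fixture()$net
  cfg <- walk_config(levy_exponent = 2, levy_max_steps = 100,
                     levy_trigger = 1)
  env <- informedwalks:::build_flight_env(
    gene_network(net, nodes = attr(net, "nodes")),
    informedwalks:::resolve_walk_config(cfg, 50))
  set.seed(13)
  s <- findInterval(runif(1e6), env$levy_cdf) + 1L  # the engine's inversion
  p_exact <- (1:100)^(-2) / sum((1:100)^(-2))       # analytic normalisation
  emp <- tabulate(s, nbins = 100) / length(s)
  expect_true(all(abs(emp[1:10] / p_exact[1:10] - 1) < 0.02))
})

test_that("flights below the trigger are no-ops, greedy steps take max weight", {
  star <- gene_network(tibble::tibble(from = c("C", "C", "C"),
                                      to = c("X", "Y", "Z"),
                                      weight = c(0.9, 0.5, 0.1)))
  state <- list(gene = "C", pathway = NA)
  # max_steps = 1 < trigger = 2: every Levy decision is a no-op
  set.seed(3)
  for (i in 1:10) {
    fl <- levy_flight(state, star, walk_config(levy_max_steps = 1,
                                               levy_trigger = 2))
    expect_false(fl$flew)
    expect_equal(fl$state$gene, "C")
    expect_equal(nrow(fl$edges), 0)
  }
  # trigger = 1, max_steps = 1: s = 1 always fires; greedy takes the 0.9 edge
  set.seed(3)
  fl <- levy_flight(state, star, walk_config(levy_max_steps = 1,
                                             levy_trigger = 1))
  expect_true(fl$flew)
  expect_equal(fl$state$gene, "X")
  expect_equal(fl$edges$to, "X")
})

test_that("flights avoid revisits and backtrack only when forced", {
  path <- gene_network(tibble::tibble(from = c("A", "B"), to = c("B", "C"),
                                      weight = c(0.9, 0.2)))
  # force s = 3 from A: A->B (0.9), then B: A visited, go C; C: dead end ->
  # backtrack over the max-weight edge to B
  cfg <- walk_config(levy_max_steps = 3, levy_trigger = 1,
                     levy_exponent = 1.0001)
  found_long <- FALSE
  set.seed(17)
  for (i in 1:200) {
    fl <- levy_flight(list(gene = "A"), path, cfg)
    if (fl$flew && nrow(fl$edges) == 3) {
      found_long <- TRUE
      expect_equal(fl$edges$to, c("B", "C", "B"))
      break
    }
  }
  expect_true(found_long)
})

test_that("informed steps relocate along the full shortest path", {
  # direct A-C edge is weak (1/w = 10); the A-B-C route costs 1/0.9 + 1/0.8
  net <- gene_network(tibble::tibble(
    from = c("A", "A", "B", "C", "D"),
    to = c("B", "C", "C", "D", "E"),
    weight = c(0.9, 0.1, 0.8, 0.5, 0.5)))
  sets <- gene_sets(list(TARGET = c("C"), OTHER = c("A", "E")))
  set.seed(5)
  st <- informed_step(list(gene = "A", pathway = "TARGET"), net, sets,
                      no_levy())
  expect_equal(st$state$gene, "C")
  expect_equal(st$edges$from, c("A", "B"))
  expect_equal(st$edges$to, c("B", "C"))
})

test_that("a single adjacent pathway member is reached in one recorded edge", {
  net <- gene_network(tibble::tibble(from = c("A", "B"), to = c("B", "C"),
                                     weight = c(0.5, 0.5)))
  sets <- gene_sets(list(P = c("B"), Q = c("A", "C")))
  set.seed(9)
  st <- informed_step(list(gene = "A", pathway = "P"), net, sets, no_levy())
  expect_equal(st$state$gene, "B")
  expect_equal(nrow(st$edges), 1)
})

test_that("a pathway without usable members leaves the gene in place", {
  net <- gene_network(tibble::tibble(from = c("A", "B"), to = c("B", "C"),
                                     weight = c(0.5, 0.5)))
  # every pathway's only network member is the current gene: 10 resamples
  # fail, and the Levy fallback is configured to a no-op
  sets <- gene_sets(list(P1 = c("A", "zz1"), P2 = c("A", "zz2")))
  set.seed(7)
  st <- suppressWarnings(
    informed_step(list(gene = "A", pathway = "P1"), net, sets, no_levy()))
  expect_equal(st$state$gene, "A")
  expect_equal(nrow(st$edges), 0)
})

test_that("hop-count informed steps match exhaustive shortest-path search", {
  set.seed(55)
  for (rep in 1:25) {
    n <- sample(4:6, 1)
    net <- random_connected_net(n, p = 0.4)
    nodes <- network_nodes(net)
    members <- sample(nodes, sample(2:3, 1))
    start <- sample(setdiff(nodes, members), 1)
    sets <- gene_sets(list(P = members, Q = nodes[1:2]))
    st <- informed_step(list(gene = start, pathway = "P"), net, sets,
                        no_levy(distance_mode = "hop_count"))
    D <- floyd_warshall_hops(net)
    cand <- members
    dmin <- min(D[start, cand])
    expect_true(st$state$gene %in% cand[D[start, cand] == dmin])
    expect_equal(nrow(st$edges), dmin)  # full path recorded, hop by hop
    # traversed edges form a contiguous walk ending at the target
    if (nrow(st$edges) > 0) {
      expect_equal(st$edges$from[1], start)
      expect_equal(st$edges$to[nrow(st$edges)], st$state$gene)
      for (e in seq_len(nrow(st$edges))) {
        key <- paste(sort(c(st$edges$from[e], st$edges$to[e])), collapse = "|")
        expect_true(key %in% edge_keys(net))
      }
    }
  }
})

test_that("a zero-iteration run produces an empty frequency network", {
  fx <- walk_fixture()
  run <- run_informed_walks(fx$net, fx$sets,
                            walk_config(n_walkers = 1, n_iterations = 0,
                                        seed = 1))
  expect_equal(nrow(run$frequency), 0)
  expect_equal(attr(run$frequency, "total_traversals"), 0)
})

test_that("passage counts are conserved and closed over network edges", {
  fx <- walk_fixture()
  run <- run_informed_walks(fx$net, fx$sets,
                            walk_config(n_walkers = 4, n_iterations = 60,
                                        seed = 31))
  expect_equal(sum(run$frequency$count),
               attr(run$frequency, "total_traversals"))
  expect_true(all(paste(run$frequency$from, run$frequency$to, sep = "|") %in%
                    edge_keys(fx$net)))
  expect_setequal(attr(run$frequency, "nodes"), network_nodes(fx$net))
  # per-walker accounting: a round is a flight or a no-op; informed moves
  # happen only in no-op rounds
  expect_true(all(run$log$flights + run$log$flight_noops >= 60))
  expect_true(all(run$log$informed_steps <= run$log$flight_noops))
})

test_that("runs are reproducible by seed and invariant to walker order", {
  fx <- walk_fixture()
  cfg <- walk_config(n_walkers = 6, n_iterations = 40, seed = 17)
  r1 <- run_informed_walks(fx$net, fx$sets, cfg)
  r2 <- run_informed_walks(fx$net, fx$sets, cfg)
  expect_identical(r1$frequency, r2$frequency)
  r3 <- run_informed_walks(fx$net, fx$sets, cfg, walker_order = 6:1)
  expect_identical(r1$frequency, r3$frequency)
  r4 <- run_informed_walks(fx$net, fx$sets,
                           walk_config(n_walkers = 6, n_iterations = 40,
                                       seed = 18))
  expect_false(identical(r1$frequency, r4$frequency))
})

test_that("pathway-branch frequencies converge to the configured split", {
  fx <- walk_fixture()
  run <- run_informed_walks(fx$net, fx$sets,
                            no_levy(n_walkers = 20, n_iterations = 100,
                                    seed = 23))
  n_inf <- sum(run$log$pathway_informed)
  n_uni <- sum(run$log$pathway_uniform)
  n <- n_inf + n_uni
  expect_gte(n, 2000)
  se3 <- 3 * sqrt(0.7 * 0.3 / n)
  expect_lt(abs(n_inf / n - 0.7), se3)
})

test_that("tidy, glance and autoplot expose the run coherently", {
  fx <- walk_fixture()
  run <- run_informed_walks(fx$net, fx$sets,
                            walk_config(n_walkers = 3, n_iterations = 50,
                                        seed = 41))
  td <- tidy(run)
  expect_true(all(diff(td$count) <= 0))
  gl <- glance(run)
  expect_equal(gl$total_traversals, sum(td$count))
  expect_s3_class(autoplot(run, k = NA), "ggplot")
})
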