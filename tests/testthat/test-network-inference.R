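gaussian_pair_expr <- function(rho, n, seed = 1) {
  set.seed(seed)
  x <- rnorm(n)
  y <- rho * x + sqrt(1 - rho^2) * rnorm(n)
  out <- tibble::as_tibble(as.data.frame(rbind(x, y)))
  names(out) <- paste0("S", seq_len(n))
  dplyr::bind_cols(tibble::tibble(gene = c("X", "Y")), out)
}

test_that("kNN MI tracks the Gaussian closed form and stays nonnegative", {
  # oracle: I = -0.5 * ln(1 - rho^2) for bivariate normals
  for (rho in c(0, 0.9)) {
    expr <- gaussian_pair_expr(rho, 800, seed = 42)
    mi <- mutual_information(expr, "knn", 3)
    expect_lt(abs(mi[1, 2] - (-0.5 * log(1 - rho^2))), 0.1)
    expect_true(all(mi >= 0))
    expect_equal(mi, t(mi))
    expect_equal(diag(mi), c(X = 0, Y = 0))
  }
})

test_that("a duplicated profile carries the largest MI in its row", {
  set.seed(31)
  base <- rnorm(60)
  expr <- tibble::tibble(gene = c("A", "Acopy", "B", "C"))
  vals <- rbind(base, base, rnorm(60), rnorm(60))
  expr <- dplyr::bind_cols(expr, tibble::as_tibble(as.data.frame(vals)))
  mi <- mutual_information(expr, "knn", 3)
  expect_equal(which.max(mi["A", -1]), c(Acopy = 1))
})

test_that("the Gaussian estimator warns on constant rows and zeroes them", {
  expr <- tibble::tibble(gene = c("flat", "B"))
  expr <- dplyr::bind_cols(expr, tibble::as_tibble(as.data.frame(
    rbind(rep(1, 30), rnorm(30)))))
  expect_warning(mi <- mutual_information(expr, "gaussian"), "constant")
  expect_equal(mi["flat", "B"], 0)
})

test_that("binned MI is zero for independent data, positive for dependence", {
  expr <- gaussian_pair_expr(0.95, 1000, seed = 5)
  mi_dep <- mutual_information(expr, "binned", 8)
  expr0 <- gaussian_pair_expr(0, 1000, seed = 5)
  mi_ind <- mutual_information(expr0, "binned", 8)
  expect_gt(mi_dep[1, 2], mi_ind[1, 2] + 0.3)
})

test_that("MRNETB handles the degenerate cases exactly", {
  m <- matrix(c(0, 0.5, 0.5, 0), 2, 2, dimnames = list(c("A", "B"),
                                                       c("A", "B")))
  net <- mrnetb(m)
  expect_equal(nrow(net), 1)
  expect_equal(net$weight, 0.5)  # no redundancy possible with one predictor

  z <- matrix(0, 3, 3, dimnames = list(LETTERS[1:3], LETTERS[1:3]))
  netz <- mrnetb(z)
  expect_equal(nrow(netz), 0)
  expect_equal(length(network_nodes(netz)), 3)  # isolated nodes retained
})

test_that("MRNETB recovers chain structure and matches exhaustive search", {
  chain <- matrix(0.02, 4, 4)
  chain[1, 2] <- chain[2, 1] <- 0.8
  chain[2, 3] <- chain[3, 2] <- 0.7
  chain[3, 4] <- chain[4, 3] <- 0.9
  diag(chain) <- 0
  rownames(chain) <- colnames(chain) <- LETTERS[1:4]
  net <- mrnetb(chain)
  expect_equal(edge_keys(net), c("A|B", "B|C", "C|D"))
  expect_equal(edge_keys(net), brute_mrnetb_edges(chain))
})

test_that("exhaustively optimal edges are always selected by MRNETB", {
  # the backward/replacement schedule is a local search, so it can retain
  # extra edges at redundant local optima, but it must never miss an edge
  # of the global MRMR optimum
  set.seed(42)
  for (rep in 1:40) {
    g <- sample(4:6, 1)
    X <- matrix(rnorm(50 * g), ncol = g)
    cm <- cor(X)
    mi <- -0.5 * log(1 - pmin(cm^2, 1 - 1e-12))
    diag(mi) <- 0
    rownames(mi) <- colnames(mi) <- LETTERS[seq_len(g)]
    expect_true(all(brute_mrnetb_edges(mi) %in% edge_keys(mrnetb(mi))))
  }
})

test_that("connectivity filter keeps trees intact and prunes cycles exactly", {
  tree <- gene_network(tibble::tibble(from = c("A", "B", "B"),
                                      to = c("B", "C", "D"),
                                      weight = c(0.3, 0.9, 0.1)))
  res <- connectivity_filter(tree)
  expect_equal(nrow(res$network), 3)
  expect_equal(res$threshold, 0.1)

  cyc <- gene_network(tibble::tibble(from = c("A", "B", "C", "D"),
                                     to = c("B", "C", "D", "A"),
                                     weight = c(1, 2, 3, 4)))
  res2 <- connectivity_filter(cyc)
  expect_equal(res2$threshold, 2)
  expect_false("A|B" %in% edge_keys(res2$network))
  expect_equal(nrow(res2$network), 3)
})

test_that("filter threshold equals the max-spanning-tree bottleneck oracle", {
  set.seed(77)
  for (rep in 1:30) {
    net <- random_connected_net(sample(8:16, 1))
    res <- connectivity_filter(net)
    expect_equal(res$threshold, bottleneck_scan(net))
    expect_true(informedwalks:::is_connected_network(res$network))
    expect_setequal(network_nodes(res$network), network_nodes(net))
  }
})

test_that("grid-resolution filtering stays connected and spans all nodes", {
  set.seed(12)
  net <- random_connected_net(12)
  res <- connectivity_filter(net, resolution = 20)
  expect_true(informedwalks:::is_connected_network(res$network))
  expect_setequal(network_nodes(res$network), network_nodes(net))
  expect_lte(res$threshold, bottleneck_scan(net))
})

test_that("disconnected input to the filter is refused with guidance", {
  net <- gene_network(tibble::tibble(from = c("A", "C"), to = c("B", "D"),
                                     weight = c(1, 1)))
  expect_error(connectivity_filter(net), "largest connected component")
})

test_that("inference separates planted modules from background", {
  spec <- synth_spec(n_genes = 14, n_samples = 120, n_modules = 2,
                     module_size = 4, within_module_correlation = 0.85,
                     seed = 19)
  ex <- generate_expression(spec)
  net <- suppressWarnings(infer_network(ex$expression, estimator = "knn",
                                        k_or_bins = 3))
  mod_of <- setNames(ex$modules$module, ex$modules$gene)
  same_module <- !is.na(mod_of[net$from]) & !is.na(mod_of[net$to]) &
    mod_of[net$from] == mod_of[net$to]
  expect_gt(mean(net$weight[same_module]), mean(net$weight[!same_module]))
  # inference is deterministic
  net2 <- suppressWarnings(infer_network(ex$expression, estimator = "knn",
                                         k_or_bins = 3))
  expect_identical(as.data.frame(net), as.data.frame(net2))
})
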