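small_binary <- function() {
  # 4 genes x 100 cells: pair (A,B) co-active in 2 cells; C active with A in
  # 1 cell; D never active
  m <- matrix(0L, 4, 100, dimnames = list(c("A", "B", "C", "D"),
                                          sprintf("c%03d", 1:100)))
  m["A", c(1, 2, 3)] <- 1L
  m["B", c(1, 2)] <- 1L
  m["C", 3] <- 1L
  m
}

test_that("edge prevalence is the co-active cell fraction, without self-edges", {
  prev <- edge_prevalence(small_binary())
  td <- tidy_edge_prevalence(prev)
  expect_equal(td$prevalence[td$gene_a == "A" & td$gene_b == "B"], 0.02)
  expect_equal(td$prevalence[td$gene_a == "A" & td$gene_b == "C"], 0.01)
  expect_equal(nrow(td), 2)  # no self-pairs, no D
  expect_true(all(Matrix::diag(prev$counts) == 0))
})

test_that("mean pairwise prevalence of independent activity matches p^2", {
  withr::with_seed(9, {
    b <- matrix(rbinom(50 * 1000, 1, 0.3), 50, 1000,
                dimnames = list(paste0("g", 1:50), paste0("c", 1:1000)))
  })
  prev <- edge_prevalence(b)
  co <- as.matrix(prev$counts) / prev$n_cells
  mean_prev <- mean(co[upper.tri(co)])
  expect_lt(abs(mean_prev - 0.09), 0.01)
})

test_that("prevalence filter keeps boundary edges and removes strictly above", {
  b <- small_binary()
  prev <- edge_prevalence(b)
  # cell c001 has A and B active; their prevalence is exactly 0.02
  net <- build_cell_network(b, "c001", prev, threshold = 0.02)
  expect_equal(nrow(net$edges), 1)
  net <- build_cell_network(b, "c001", prev, threshold = 0.0199)
  expect_equal(nrow(net$edges), 0)
  expect_equal(net$nodes, c("A", "B"))  # isolated nodes retained
  # threshold 1.0 keeps the full clique
  net <- build_cell_network(b, "c003", prev, threshold = 1)
  expect_equal(nrow(net$edges), choose(length(net$nodes), 2))
  # no active genes: empty network, not an error
  net <- build_cell_network(b, "c050", prev, threshold = 0.01)
  expect_length(net$nodes, 0)
  expect_equal(nrow(net$edges), 0)
})

test_that("raising the threshold can only add edges", {
  sim <- generate_network_activity(network_plan(n_star_cells = 10, n_dense_cells = 10,
                                                n_background_cells = 20), seed = 2)
  prev <- edge_prevalence(sim$binary)
  for (cl in colnames(sim$binary)[c(1, 5, 11, 15)]) {
    e_prev <- -1
    for (th in c(0.005, 0.01, 0.05, 0.2, 1)) {
      ne <- nrow(build_cell_network(sim$binary, cl, prev, th)$edges)
      expect_gte(ne, e_prev)
      e_prev <- ne
    }
    # full clique at threshold 1
    net <- build_cell_network(sim$binary, cl, prev, 1)
    expect_equal(nrow(net$edges), choose(length(net$nodes), 2))
  }
})

test_that("degree centralization matches closed forms", {
  star5 <- list(nodes = c("h", "a", "b", "c", "d"),
                edges = cbind(rep("h", 4), c("a", "b", "c", "d")))
  expect_equal(degree_centralization(star5), 1)
  cg <- function(n) {
    nodes <- paste0("n", 1:n)
    pairs <- t(combn(nodes, 2))
    list(nodes = nodes, edges = pairs)
  }
  for (n in c(3, 5, 8)) expect_equal(degree_centralization(cg(n)), 0)
  path4 <- list(nodes = c("a", "b", "c", "d"),
                edges = cbind(c("a", "b", "c"), c("b", "c", "d")))
  expect_equal(degree_centralization(path4), 1 / 3)
  # undefined below 3 nodes
  expect_true(is.na(degree_centralization(list(nodes = c("a", "b"),
                                               edges = cbind("a", "b")))))
})

test_that("centralization agrees with igraph on random graphs", {
  skip_if_not_installed("igraph")
  withr::with_seed(15, {
    for (i in 1:100) {
      n <- sample(3:12, 1)
      nodes <- paste0("n", 1:n)
      pairs <- t(combn(nodes, 2))
      keep <- runif(nrow(pairs)) < 0.4
      net <- list(nodes = nodes, edges = pairs[keep, , drop = FALSE])
      g <- igraph::graph_from_data_frame(
        as.data.frame(net$edges), directed = FALSE,
        vertices = data.frame(name = nodes))
      ref <- igraph::centr_degree(g, loops = FALSE, normalized = TRUE)$centralization
      expect_equal(degree_centralization(net), ref, tolerance = 1e-12)
    }
  })
})

test_that("centralization is within [0,1] and 1 only for stars on planted data", {
  sim <- generate_network_activity(network_plan(), seed = 4)
  nets <- build_cell_networks(sim$binary, threshold = 0.01, groups = sim$groups)
  cz <- nets$centralization[!is.na(nets$centralization)]
  expect_true(all(cz >= 0 & cz <= 1))
  star <- nets[nets$group == "mature" & nets$n_nodes >= 5, ]
  # single-hub stars are exactly 1
  one_hub <- sapply(star$network, function(x) sum(grepl("^PRIV", x$nodes)) == 1)
  expect_true(all(star$centralization[one_hub] == 1))
})

test_that("identical groups give t near 0, planted contrast is significant", {
  sim <- generate_network_activity(network_plan(), seed = 6)
  cmp <- compare_group_centralization(sim$binary, sim$groups)
  expect_equal(nrow(cmp), 6)
  expect_true(all(cmp$available))
  expect_true(all(cmp$p_value < 0.01))
  expect_true(all(cmp$mean_mature > cmp$mean_immature))
  # two groups of networks with identical centralization values: no difference
  det <- generate_network_activity(network_plan(p_second_hub = 0), seed = 7)
  g_same <- det$groups
  stars <- det$groups$mature_cells
  g_same$mature_cells <- stars[1:25]
  g_same$immature_cells <- stars[26:50]
  cmp2 <- compare_group_centralization(det$binary, g_same, thresholds = 0.01)
  expect_true(abs(cmp2$t_statistic) < 1e-10)
  expect_gte(cmp2$p_value, 0.999)
})

test_that("the minimum-node filter excludes small networks from the counts", {
  # build a population where one mature cell has only 4 active genes
  m <- matrix(0L, 10, 30, dimnames = list(paste0("g", 1:10), paste0("c", 1:30)))
  m[1:4, 1] <- 1L          # 4-node network -> excluded at min_nodes = 5
  m[1:6, 2:6] <- 1L        # 6-node networks
  m[5:10, 7:11] <- 1L
  groups <- structure(list(mature_cells = paste0("c", 1:6),
                           immature_cells = paste0("c", 7:11),
                           excluded_cells = paste0("c", 12:30),
                           mature_marker = NA, immature_marker = NA),
                      class = "maturity_groups")
  cmp <- compare_group_centralization(m, groups, thresholds = 1, min_nodes = 5)
  expect_equal(cmp$n_mature, 5)  # c1 excluded
  expect_equal(cmp$n_immature, 5)
  # a group with < 2 eligible networks is marked unavailable
  groups$immature_cells <- "c7"
  cmp <- compare_group_centralization(m, groups, thresholds = 1, min_nodes = 5)
  expect_false(cmp$available)
})
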