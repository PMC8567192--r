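test_that("network edges satisfy both thresholds and match Spearman on ranks", {
  set.seed(31)
  n <- 12
  base <- cumsum(rnorm(n))
  x <- cbind(
    a = rank(base), b = rank(base),              # perfectly rank-correlated
    c = sample(n), d = sample(n), e = sample(n),
    f = rank(-base)                              # perfectly anti-correlated
  )
  storage.mode(x) <- "integer"
  tab <- community_table(x + 1L)
  net <- build_network(tab, min_prevalence = 2, rho_threshold = 0.6,
                       q_threshold = 0.05)
  key <- paste(pmin(net$edges$otu_a, net$edges$otu_b),
               pmax(net$edges$otu_a, net$edges$otu_b))
  expect_true("a b" %in% key)
  expect_equal(net$edges$rho[key == "a b"], 1)
  expect_true(all(abs(net$edges$rho) > 0.6))
  expect_true(all(net$edges$q < 0.05))
  # negative correlations count by default
  expect_true(any(net$edges$rho < 0))
  net_pos <- build_network(tab, min_prevalence = 2, rho_threshold = 0.6,
                           q_threshold = 0.05, positive_only = TRUE)
  expect_true(all(net_pos$edges$rho > 0.6))
})

test_that("Spearman rho equals Pearson on ranks for tie-free vectors", {
  set.seed(32)
  for (rep in 1:100) {
    a <- sample(1000, 15); b <- sample(1000, 15)
    tab <- community_table(cbind(o1 = a, o2 = b))
    rho <- suppressWarnings(cor(unclass(tab), method = "spearman"))[1, 2]
    expect_equal(rho, cor(rank(a), rank(b), method = "pearson"),
                 tolerance = 1e-12)
  }
})

test_that("network construction is invariant to sample and OTU order", {
  set.seed(33)
  x <- matrix(rpois(15 * 20, 4), 15, 20)
  tab <- community_table(x)
  n1 <- build_network(tab, min_prevalence = 3, rho_threshold = 0.4,
                      q_threshold = 0.2)
  sp <- sample(15); op <- sample(20)
  tab2 <- community_table(unclass(tab)[sp, op])
  n2 <- build_network(tab2, min_prevalence = 3, rho_threshold = 0.4,
                      q_threshold = 0.2)
  canon <- function(net) {
    e <- net$edges
    k <- paste(pmin(e$otu_a, e$otu_b), pmax(e$otu_a, e$otu_b))
    e <- e[order(k), ]
    rownames(e) <- NULL
    e
  }
  expect_equal(canon(n1), canon(n2), tolerance = 1e-12)
})

test_that("constant OTUs are excluded with a warning", {
  x <- cbind(o1 = c(3L, 3L, 3L, 3L, 3L), o2 = c(1L, 2L, 3L, 4L, 5L),
             o3 = c(5L, 4L, 3L, 2L, 1L))
  tab <- community_table(x)
  expect_warning(net <- build_network(tab, min_prevalence = 2,
                                      rho_threshold = 0.5,
                                      q_threshold = 0.5),
                 "constant")
  expect_false("o1" %in% net$nodes$otu_id)
})

test_that("node topology of a star graph is hand-enumerable", {
  g <- igraph::make_star(5, mode = "undirected", center = 1)
  igraph::V(g)$name <- paste0("o", 1:5)
  net <- structure(list(graph = g,
                        nodes = data.frame(otu_id = paste0("o", 1:5),
                                           label = NA_character_)),
                   class = "co_network")
  nt <- node_topology(net)
  ctr <- nt$nodes[nt$nodes$otu_id == "o1", ]
  expect_equal(ctr$degree, 4)
  expect_equal(ctr$betweenness, 6)   # all C(4,2) leaf pairs route via hub
  expect_equal(ctr$transitivity, 0)
  expect_equal(ctr$eigenvector, 1)   # scaled to max 1
  expect_true(all(nt$nodes$degree[-1] == 1))
})

test_that("degenerate group comparisons return p = 1 on a regular ring", {
  g <- igraph::make_ring(8)
  igraph::V(g)$name <- paste0("o", 1:8)
  net <- structure(list(graph = g,
                        nodes = data.frame(
                          otu_id = paste0("o", 1:8),
                          label = rep(c("core", "satellite"), 4))),
                   class = "co_network")
  nt <- node_topology(net)
  expect_equal(nt$tests$kw_p[nt$tests$metric == "degree"], 1)
})

test_that("graph topology matches closed forms on K5 and P4", {
  k5 <- igraph::make_full_graph(5)
  t5 <- graph_topology(k5, modularity_restarts = 2, seed = 1)
  expect_equal(t5$avg_clustering, 1)
  expect_equal(t5$avg_path_length, 1)
  expect_equal(t5$diameter, 1)
  expect_equal(t5$avg_degree, 2 * 10 / 5)
  p4 <- igraph::make_graph(~ a - b, b - c, c - d)
  t4 <- graph_topology(p4, modularity_restarts = 2, seed = 1)
  expect_equal(t4$avg_path_length, (1 + 1 + 1 + 2 + 2 + 3) / 6,
               tolerance = 1e-12)
})

test_that("ER ensembles reach the analytic clustering and handle bounds", {
  er <- er_ensemble(30, 30 * 29 / 2, n_graphs = 3, seed = 1,
                    metrics = c("clustering", "path_length"))
  expect_equal(er$summary$mean[er$summary$metric == "clustering"], 1)
  expect_equal(er$summary$mean[er$summary$metric == "path_length"], 1)
  expect_error(er_ensemble(5, 11), "maximum")
  # law of large numbers: mean clustering -> p = 2m/(n(n-1)) within 3 SE
  n <- 60; m <- 300
  er2 <- er_ensemble(n, m, n_graphs = 200, seed = 2,
                     metrics = "clustering")
  mu <- er2$summary$mean[1]; se <- er2$summary$sd[1] / sqrt(200)
  expect_lt(abs(mu - 2 * m / (n * (n - 1))), 3 * se + 0.002)
})

test_that("natural connectivity matches K3 and declines with edge removal", {
  k3 <- igraph::make_full_graph(3)
  expect_equal(coresat:::natural_connectivity(k3),
               log((exp(2) + 2 * exp(-1)) / 3), tolerance = 1e-12)
  set.seed(34)
  g <- igraph::sample_gnm(25, 60)
  nc <- coresat:::natural_connectivity(g)
  for (rep in 1:5) {
    g2 <- igraph::delete_edges(g, sample(igraph::ecount(g), 10))
    expect_lte(coresat:::natural_connectivity(g2), nc + 1e-12)
  }
})

test_that("robustness curves start at 1 and degrade under targeted removal", {
  set.seed(35)
  g <- igraph::sample_gnm(40, 120)
  rc <- robustness_curve(g, removal = "random",
                         fraction_grid = c(0, 0.2, 0.5), n_rep = 5,
                         seed = 3)
  expect_equal(rc$relative_connectivity[rc$fraction == 0], 1)
  rt <- robustness_curve(g, removal = "degree",
                         fraction_grid = c(0, 0.3, 0.6), seed = 3)
  expect_true(all(diff(rt$relative_connectivity) <= 1e-9))
  expect_error(robustness_curve(g, fraction_grid = c(0, 1)), "< 1")
})

test_that("vulnerability is 0 for complete graphs and 1 for a star", {
  expect_equal(vulnerability(igraph::make_full_graph(6)), 0)
  # hub removal disconnects the star entirely: max relative drop is 1
  star <- igraph::make_star(5, mode = "undirected")
  expect_equal(vulnerability(star), 1)
  # hand enumeration: global efficiency of the intact star
  e <- coresat:::global_efficiency(star)
  expect_equal(e, (8 * 1 + 12 * 0.5) / 20)
  expect_error(vulnerability(igraph::make_full_graph(2)), "3 nodes")
})
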