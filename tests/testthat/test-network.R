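test_that("Spearman matrix is rank-based, symmetric, unit-diagonal", {
  set.seed(3)
  x <- rnorm(20)
  mat <- cbind(a = x, b = x^3, c = rnorm(20))
  rho <- spearman_matrix(mat)
  expect_equal(rho["a", "b"], 1)  # monotone transform
  expect_equal(diag(rho), c(a = 1, b = 1, c = 1))
  expect_equal(rho, t(rho))
})

test_that("Spearman with ties matches the average-rank formula by hand", {
  x <- c(1, 2, 2, 4, 5)
  y <- c(3, 3, 1, 5, 5)
  rho <- spearman_matrix(cbind(x = x, y = y))["x", "y"]
  rx <- rank(x); ry <- rank(y)  # average ranks
  oracle <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  expect_equal(rho, oracle, tolerance = 1e-12)
})

test_that("thresholded network has the right edges and degrees", {
  panel <- generate_panel(stimuli = character(), analytes = character(),
                          freq_subsets = NULL)
  subj <- toy_subjects(30, 0)
  ds <- simulate_measurements(subj, panel,
                              community_spec = default_community_spec(panel),
                              seed = 5)
  net <- build_network(spearman_matrix(ds$measurements))
  expect_equal(nrow(net$nodes), 84)
  ident <- diag(5)
  rownames(ident) <- colnames(ident) <- paste0("n", 1:5)
  net0 <- build_network(ident)
  expect_equal(igraph::ecount(net0$graph), 0)
  expect_equal(net0$nodes$degree, rep(0, 5))
  expect_error(build_network(ident, threshold = 0), "threshold")
  expect_error(build_network(ident, threshold = 1.5), "threshold")
})

test_that("raising the threshold never adds edges", {
  set.seed(6)
  m <- matrix(rnorm(40 * 20), 40)
  colnames(m) <- paste0("n", 1:20)
  rho <- spearman_matrix(m)
  edge_set <- function(th) {
    g <- build_network(rho, threshold = th)$graph
    apply(igraph::as_edgelist(g), 1, paste, collapse = "-")
  }
  e3 <- edge_set(0.3); e5 <- edge_set(0.5); e7 <- edge_set(0.7)
  expect_true(all(e5 %in% e3))
  expect_true(all(e7 %in% e5))
})

test_that("independent features give almost no edges at 0.5", {
  counts <- vapply(1:10, function(s) {
    m <- with_seed(s, matrix(rnorm(100 * 84), 100))
    colnames(m) <- paste0("n", 1:84)
    igraph::ecount(build_network(spearman_matrix(m))$graph)
  }, numeric(1))
  expect_lt(max(counts), 5)
})

test_that("path and star centralities match path enumeration", {
  path <- matrix(0, 5, 5)
  for (i in 1:4) path[i, i + 1] <- path[i + 1, i] <- 1
  net <- node_centralities(build_network(adj_to_corr(path)))
  expect_equal(net$nodes$betweenness[3], 4)
  expect_equal(net$nodes$eccentricity[3], 2)
  expect_equal(net$nodes$eccentricity[1], 4)
  star <- matrix(0, 8, 8); star[1, 2:8] <- star[2:8, 1] <- 1
  snet <- node_centralities(build_network(adj_to_corr(star)))
  expect_equal(snet$nodes$betweenness[1], choose(7, 2))
  expect_equal(snet$nodes$betweenness[-1], rep(0, 7))
  full <- matrix(1, 6, 6); diag(full) <- 0
  fnet <- node_centralities(build_network(adj_to_corr(full)))
  expect_equal(fnet$nodes$betweenness, rep(0, 6))
  expect_equal(fnet$nodes$eccentricity, rep(1, 6))
})

test_that("isolated nodes get zero betweenness and eccentricity", {
  adj <- matrix(0, 4, 4); adj[1, 2] <- adj[2, 1] <- 1
  net <- node_centralities(build_network(adj_to_corr(adj)))
  expect_equal(net$nodes$betweenness, rep(0, 4))
  expect_equal(net$nodes$eccentricity, c(1, 1, 0, 0))
})

test_that("role classification follows the top-20 percent rule with ties", {
  set.seed(2)
  corr <- adj_to_corr(random_adjacency(84, 0.15))
  net <- classify_roles(node_centralities(build_network(corr)))
  expect_gte(sum(net$nodes$hub), 17)        # ceiling(0.2 * 84), plus ties
  expect_equal(sort(unique(net$nodes$role)),
               sort(intersect(c("H-B", "H-NB", "NH-B", "NH-NB"),
                              unique(net$nodes$role))))
  expect_true(all(net$nodes$role[net$nodes$hub & net$nodes$bottleneck] == "H-B"))
  expect_equal(sum(net$nodes$hub) + sum(!net$nodes$hub), 84)
  # ten nodes where the top two degrees are strictly above the rest
  adj <- matrix(0, 10, 10)
  adj[1, 2:10] <- 1                      # hub of degree 9
  adj[2, c(1, 3, 4, 5, 6)] <- 1          # second hub of degree 5
  adj <- pmax(adj, t(adj)); diag(adj) <- 0
  nt <- classify_roles(node_centralities(build_network(adj_to_corr(adj))))
  expect_equal(sum(nt$nodes$hub), 2)
  expect_true(all(which(nt$nodes$hub) == c(1, 2)))
  # all-equal metric classifies nobody
  full <- matrix(1, 6, 6); diag(full) <- 0
  nf <- classify_roles(node_centralities(build_network(adj_to_corr(full))))
  expect_equal(sum(nf$nodes$hub), 0)
})

test_that("two disconnected cliques give Q = 0.5 and two communities", {
  corr <- matrix(0, 10, 10)
  corr[1:5, 1:5] <- 0.9; corr[6:10, 6:10] <- 0.9; diag(corr) <- 1
  rownames(corr) <- colnames(corr) <- paste0("n", 1:10)
  net <- detect_communities(build_network(corr), seed = 4)
  expect_equal(net$modularity, 0.5, tolerance = 1e-12)
  expect_equal(length(unique(net$nodes$community)), 2)
  expect_equal(sort(net$community_composition$composition_pct), c(50, 50))
  one <- matrix(0.9, 6, 6); diag(one) <- 1
  rownames(one) <- colnames(one) <- paste0("m", 1:6)
  nd <- detect_communities(build_network(one), seed = 1)
  expect_equal(length(unique(nd$nodes$community)), 1)
  expect_equal(nd$modularity, 0, tolerance = 1e-12)
  ident <- diag(4); rownames(ident) <- colnames(ident) <- paste0("z", 1:4)
  iso <- detect_communities(build_network(ident), seed = 1)
  expect_equal(length(unique(iso$nodes$community)), 4)
  expect_equal(iso$modularity, 0)
})

test_that("category enrichment validates subsets and finds planted signal", {
  set.seed(12)
  corr <- adj_to_corr(random_adjacency(84, 0.1))
  net <- classify_roles(node_centralities(build_network(corr)))
  cats <- rep(paste0("p", 1:12), each = 7)
  whole <- category_enrichment(net, cats, rep(TRUE, 84))
  expect_true(all(whole$p == 1))
  # subset holding all 7 nodes of one category among 17
  mask <- c(rep(TRUE, 7), rep(FALSE, 77))
  mask[8:17] <- TRUE
  er <- category_enrichment(net, cats, mask)
  p1 <- er$p[er$category == "p1"]
  expect_equal(p1, bf_hyper_upper(7, 7, 84, 17), tolerance = 1e-12)
  expect_error(category_enrichment(net, cats, rep(FALSE, 84)), "empty")
  expect_error(category_enrichment(net, cats[-1], rep(TRUE, 83)), "cover")
})

test_that("robustness p-values behave at the extremes", {
  set.seed(9)
  m <- matrix(rnorm(50 * 20), 50)
  colnames(m) <- paste0("n", 1:20)
  rho <- spearman_matrix(m)
  same <- robustness_test(list(t1 = rho, t2 = rho), n_perm = 100, seed = 2)
  expect_true(all(same$per_node$p == 1))
  coarse <- robustness_test(list(t1 = rho, t2 = rho * 0.5 + diag(20) * 0.5),
                            n_perm = 10, seed = 2)
  expect_true(all(abs(coarse$per_node$p * 10 -
                        round(coarse$per_node$p * 10)) < 1e-12))
  rho2 <- rho; rownames(rho2) <- colnames(rho2) <- paste0("x", 1:20)
  expect_error(robustness_test(list(t1 = rho, t2 = rho2)), "mismatched")
})

test_that("robustness null is not anti-conservative on exchangeable data", {
  ps <- unlist(lapply(1:5, function(s) {
    m1 <- with_seed(s, matrix(rnorm(60 * 30), 60))
    m2 <- with_seed(s + 100, matrix(rnorm(60 * 30), 60))
    colnames(m1) <- colnames(m2) <- paste0("n", 1:30)
    r <- robustness_test(list(t1 = spearman_matrix(m1),
                              t2 = spearman_matrix(m2)),
                         n_perm = 400, seed = s)
    r$per_node$p
  }))
  expect_lte(mean(ps < 0.05), 0.05 + 2.6 * sqrt(0.05 * 0.95 / length(ps)))
})

test_that("topology summaries and tests respond to identical inputs", {
  set.seed(10)
  m <- matrix(rnorm(40 * 15), 40)
  colnames(m) <- paste0("n", 1:15)
  net <- node_centralities(build_network(spearman_matrix(m), threshold = 0.3))
  topo <- topology_over_time(list(a = net, b = net))
  expect_true(all(topo$tests$p == 1))
  med_a <- topo$summary$median[topo$summary$timepoint == "a"]
  med_b <- topo$summary$median[topo$summary$timepoint == "b"]
  expect_equal(med_a, med_b)
})

test_that("igraph centralities match brute force on random small graphs", {
  set.seed(33)
  for (i in 1:40) {
    n <- sample(3:8, 1)
    adj <- random_adjacency(n, runif(1, 0.2, 0.8))
    net <- node_centralities(build_network(adj_to_corr(adj)))
    oracle <- bf_centralities(adj)
    expect_equal(net$nodes$betweenness, oracle$betweenness, tolerance = 1e-9)
    expect_equal(net$nodes$eccentricity, oracle$eccentricity)
  }
})

test_that("graphml export carries node attributes", {
  set.seed(2)
  corr <- adj_to_corr(random_adjacency(10, 0.4))
  net <- detect_communities(classify_roles(node_centralities(
    build_network(corr))), seed = 1)
  f <- tempfile(fileext = ".graphml")
  write_network_graphml(net, f)
  g <- igraph::read_graph(f, format = "graphml")
  expect_equal(igraph::vcount(g), 10)
  expect_true(all(c("degree", "betweenness", "role", "community") %in%
                    igraph::vertex_attr_names(g)))
  unlink(f)
})
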