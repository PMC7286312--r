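test_that("closed-form fixtures are exact", {
  k3 <- simulate_adjacency(3, "complete", weight = 1)
  expect_equal(global_efficiency(k3), 1, tolerance = 1e-10)
  expect_equal(node_strength(k3), c(2, 2, 2), ignore_attr = TRUE)
  expect_equal(betweenness_centrality(k3), c(0, 0, 0), ignore_attr = TRUE)
  expect_equal(transitivity_w(k3), 1, tolerance = 1e-10)
  expect_equal(clustering_coefficient(k3), rep(1, 3), ignore_attr = TRUE,
               tolerance = 1e-10)
  for (n in c(4, 6)) {
    kn <- simulate_adjacency(n, "complete", weight = 0.5)
    expect_equal(synchronizability(kn), 1, tolerance = 1e-10)
    expect_equal(control_centrality(kn), rep(0, n), ignore_attr = TRUE,
                 tolerance = 1e-9)
    expect_equal(eigenvector_centrality(kn), rep(1 / sqrt(n), n),
                 ignore_attr = TRUE, tolerance = 1e-10)
  }
  p3 <- simulate_adjacency(3, "path", weight = 1)
  expect_equal(global_efficiency(p3), 5 / 6, tolerance = 1e-10)
  expect_equal(synchronizability(p3), 1 / 3, tolerance = 1e-10)
  expect_equal(node_strength(p3), c(1, 2, 1), ignore_attr = TRUE)
  expect_equal(betweenness_centrality(p3), c(0, 1, 0), ignore_attr = TRUE)
  expect_equal(control_centrality(p3), c(2, -1, 2), ignore_attr = TRUE,
               tolerance = 1e-10)
  expect_true(which.max(eigenvector_centrality(p3)) == 2)
  expect_equal(clustering_coefficient(p3), rep(0, 3), ignore_attr = TRUE)
})

test_that("degenerate networks take their defined values", {
  iso <- functional_network(matrix(0, 2, 2))
  expect_equal(global_efficiency(iso), 0)
  expect_equal(synchronizability(iso), 0)
  star <- matrix(0, 4, 4); star[1, 2:4] <- 1; star <- star + t(star)
  expect_equal(transitivity_w(functional_network(star)), 0)
  two_comp <- matrix(0, 4, 4)
  two_comp[1, 2] <- two_comp[3, 4] <- 1
  two_comp <- two_comp + t(two_comp)
  expect_equal(synchronizability(functional_network(two_comp)), 0)
  expect_error(control_centrality(functional_network(two_comp)),
               "synchronizability is 0")
  expect_warning(eigenvector_centrality(functional_network(two_comp)),
                 "disconnected")
})

test_that("all metrics match brute-force oracles on small random networks", {
  for (seed in 1:40) {
    n <- sample(3:6, 1)
    net <- random_connected_net(n, seed)
    A <- net$adjacency
    expect_equal(global_efficiency(net), oracle_global_efficiency(A),
                 tolerance = 1e-9)
    expect_equal(unname(betweenness_centrality(net)), oracle_betweenness(A),
                 tolerance = 1e-8)
    expect_equal(transitivity_w(net), oracle_transitivity(A),
                 tolerance = 1e-9)
    expect_equal(unname(clustering_coefficient(net)), oracle_clustering(A),
                 tolerance = 1e-9)
    expect_equal(synchronizability(net), oracle_synchronizability(A),
                 tolerance = 1e-9)
    expect_equal(unname(node_strength(net)), unname(rowSums(A)),
                 tolerance = 1e-12)
    expect_equal(unname(eigenvector_centrality(net)), oracle_eigenvector(A),
                 tolerance = 1e-7)
  }
})

test_that("control centrality equals naive delete-and-recompute and flags cut vertices", {
  net <- random_connected_net(10, seed = 3)
  cc <- control_centrality(net)
  s_old <- synchronizability(net)
  naive <- vapply(1:10, function(i)
    (oracle_synchronizability(net$adjacency[-i, -i]) - s_old) / s_old,
    numeric(1))
  expect_equal(unname(cc), naive, tolerance = 1e-10)
  # removing the centre of a star disconnects: control centrality -1
  star <- matrix(0, 5, 5); star[1, 2:5] <- 1; star <- star + t(star)
  cc_star <- control_centrality(functional_network(star))
  expect_equal(unname(cc_star[1]), -1, tolerance = 1e-10)
})

test_that("metrics are permutation-equivariant and scale as expected", {
  net <- random_connected_net(8, seed = 12)
  perm <- sample(8)
  net_p <- functional_network(net$adjacency[perm, perm],
                              labels = net$labels[perm])
  expect_equal(global_metrics(net_p), global_metrics(net), tolerance = 1e-9)
  for (m in c("node_strength", "betweenness_centrality",
              "clustering_coefficient", "control_centrality")) {
    expect_equal(unname(nodal_metric(m, net_p)),
                 unname(nodal_metric(m, net))[perm], tolerance = 1e-8)
  }
  k <- 3.7
  net_k <- functional_network(k * net$adjacency, labels = net$labels)
  expect_equal(synchronizability(net_k), synchronizability(net),
               tolerance = 1e-10)
  expect_equal(transitivity_w(net_k), transitivity_w(net), tolerance = 1e-10)
  expect_equal(clustering_coefficient(net_k), clustering_coefficient(net),
               tolerance = 1e-10)
  expect_equal(eigenvector_centrality(net_k), eigenvector_centrality(net),
               tolerance = 1e-10)
  expect_equal(node_strength(net_k), k * node_strength(net),
               tolerance = 1e-10)
  expect_equal(global_efficiency(net_k), k * global_efficiency(net),
               tolerance = 1e-10)
})

test_that("regional control centrality reduces, localizes, and matches exhaustive search", {
  # region of size 1 is ordinary control centrality
  net <- random_connected_net(8, seed = 21)
  lay <- simulate_layout(2, 4, 10, 1, 0)
  rcc <- regional_control_centrality(net, lay, region_size = 1)
  expect_equal(rcc$per_seed_values, control_centrality(net),
               tolerance = 1e-12)
  # collinear geometry forces the region
  line <- electrode_layout(paste0("L", 1:5), x_mm = c(0, 10, 20, 30, 40),
                           y_mm = 0)
  net5 <- random_connected_net(5, seed = 2)
  rcc5 <- regional_control_centrality(net5, line, region_size = 2)
  expect_equal(rcc5$regions[[1]], c(1, 2))
  # argmin agrees with exhaustive evaluation on a 12-node network
  net12 <- random_connected_net(12, seed = 5)
  lay12 <- simulate_layout(3, 4, 10, 2, 0)
  rcc12 <- regional_control_centrality(net12, lay12, region_size = 3)
  s_old <- synchronizability(net12)
  d <- as.matrix(dist(as.matrix(lay12[, c("x_mm", "y_mm", "z_mm")])))
  vals <- vapply(1:12, function(i) {
    others <- setdiff(1:12, i)
    r <- c(i, others[order(d[i, others], others)][1:2])
    (oracle_synchronizability(net12$adjacency[-r, -r]) - s_old) / s_old
  }, numeric(1))
  expect_equal(unname(rcc12$per_seed_values), vals, tolerance = 1e-10)
  expect_equal(rcc12$argmin_seed, which.min(vals))
  expect_error(regional_control_centrality(net12, lay12, 11), "region_size")
})
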