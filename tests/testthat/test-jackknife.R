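test_that("confidence sets follow the greedy tally construction", {
  # strength on a network with one dominant hub: the hub wins whenever it
  # is retained (~80% of iterations at 20% removal), so it heads the set
  A <- matrix(0.1, 6, 6); diag(A) <- 0
  A[1, -1] <- A[-1, 1] <- 0.9
  hub <- functional_network(A)
  cs <- jackknife_nodal_confidence_set(hub, "node_strength",
                                       fraction = 0.2, n_iter = 50, seed = 1)
  expect_true(1 %in% cs$contact_idx)
  expect_equal(unname(which.max(cs$counts)), 1)
  expect_gte(cs$coverage, 0.95)
  # no removal: every iteration identical, set size 1
  net <- simulate_adjacency(8, "uniform_random", seed = 2)
  cs0 <- jackknife_nodal_confidence_set(net, "node_strength", fraction = 0,
                                        n_iter = 20, seed = 1)
  expect_length(cs0$contact_idx, 1)
  expect_equal(cs0$coverage, 1)
})

test_that("greedy accumulation hits the documented tally arithmetic", {
  # counts {A:900, B:60, C:40} -> set {A, B}, coverage 0.96
  cs <- ieegjack:::build_confidence_set(c(900L, 60L, 40L),
                                        c("A", "B", "C"), "node_strength",
                                        "max", 0.95, 0L, 1L)
  expect_equal(cs$contacts, c("A", "B"))
  expect_equal(cs$coverage, 0.96)
  # minimality: dropping the lowest-count member falls below 95%
  expect_lt(900 / 1000, 0.95)
})

test_that("confidence sets cover at least 95% and are minimal and reproducible", {
  net <- simulate_adjacency(15, "block", seed = 5)
  for (metric in c("node_strength", "control_centrality")) {
    cs <- jackknife_nodal_confidence_set(net, metric, fraction = 0.2,
                                         n_iter = 200, seed = 3)
    expect_gte(cs$coverage, 0.95)
    expect_equal(cs$optimum_sense,
                 if (metric == "control_centrality") "min" else "max")
    # greedy minimality under the construction
    counts <- cs$counts[cs$contact_idx]
    expect_lt((sum(counts) - min(counts)) / cs$n_iter, 0.95)
  }
  a <- jackknife_nodal_confidence_set(net, "node_strength", 0.2, 100,
                                      seed = 11)
  b <- jackknife_nodal_confidence_set(net, "node_strength", 0.2, 100,
                                      seed = 11)
  expect_identical(a$counts, b$counts)
  expect_identical(a$contacts, b$contacts)
})

test_that("regional confidence sets tally region membership", {
  net <- simulate_adjacency(12, "block", seed = 6)
  lay <- simulate_layout(3, 4, 10, 2, seed = 1)
  res <- jackknife_regional_cc_confidence(net, lay, region_size = 3,
                                          fraction = 0.2, n_iter = 50,
                                          seed = 2)
  expect_gte(res$set$coverage, 0.95)
  expect_equal(res$ratio, length(res$set$contact_idx) / 3)
  expect_gte(res$ratio, 1)
  # same region winning every iteration gives ratio 1
  res0 <- jackknife_regional_cc_confidence(net, lay, region_size = 3,
                                           fraction = 0, n_iter = 10,
                                           seed = 2)
  full <- regional_control_centrality(net, lay, 3)
  expect_setequal(res0$set$contact_idx, full$argmin_region)
  expect_equal(res0$ratio, 1)
  # region_size 1 reduces to the nodal control-centrality construction
  res1 <- jackknife_regional_cc_confidence(net, lay, region_size = 1,
                                           fraction = 0.2, n_iter = 50,
                                           seed = 7)
  cs1 <- jackknife_nodal_confidence_set(net, "control_centrality",
                                        fraction = 0.2, n_iter = 50,
                                        seed = 7)
  expect_identical(res1$set$contact_idx, cs1$contact_idx)
})

test_that("global intervals use interpolated percentiles and degenerate correctly", {
  net <- simulate_adjacency(10, "uniform_random", seed = 8)
  ci0 <- jackknife_global_interval(net, "global_efficiency", fraction = 0,
                                   n_iter = 20, seed = 1)
  expect_equal(ci0$width, 0)
  expect_equal(ci0$lo, ci0$point_value)
  # percentile rule on a known list
  expect_equal(unname(quantile(1:1000, c(0.025, 0.975), type = 7)),
               c(25.975, 975.025))
  # complete networks keep synchronizability 1 under any removal
  kn <- simulate_adjacency(10, "complete", weight = 0.6)
  ci <- jackknife_global_interval(kn, "synchronizability", fraction = 0.2,
                                  n_iter = 100, seed = 4)
  expect_equal(ci$width, 0, tolerance = 1e-12)
  expect_equal(ci$point_value, 1, tolerance = 1e-12)
  a <- jackknife_global_interval(net, "transitivity", 0.2, 100, seed = 5)
  b <- jackknife_global_interval(net, "transitivity", 0.2, 100, seed = 5)
  expect_identical(a$values, b$values)
})

test_that("interval widths grow with removal fraction on block networks", {
  widths <- vapply(c(0.2, 0.6), function(f) {
    mean(vapply(1:5, function(s) {
      net <- simulate_adjacency(20, "block", seed = s)
      jackknife_global_interval(net, "synchronizability", f, 200,
                                seed = s)$width
    }, numeric(1)))
  }, numeric(1))
  expect_lte(widths[1], widths[2])
})
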