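#' @importFrom igraph graph_from_adjacency_matrix distances betweenness E
NULL

# igraph view of the network with Dijkstra edge lengths 1/weight; zero
# weights mean "no edge" (infinite length)
as_igraph_inv <- function(net) {
  g <- igraph::graph_from_adjacency_matrix(net$adjacency,
                                           mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  g
}

inv_lengths <- function(g) 1 / igraph::E(g)$weight

#' Global efficiency
#'
#' Mean inverse shortest weighted path length over all ordered contact
#' pairs, with path lengths computed by Dijkstra's algorithm on edge lengths
#' `1/weight` (strong edges are short). Disconnected pairs contribute 0.
#' Higher values indicate easier information transfer through the network.
#'
#' @param net A [functional_network()] with at least 2 contacts.
#' @return Nonnegative scalar efficiency.
#' @examples
#' global_efficiency(simulate_adjacency(3, "complete"))  # 1
#' global_efficiency(simulate_adjacency(3, "path"))      # 5/6
#' @export
global_efficiency <- function(net) {
  n <- n_contacts(net)
  if (n < 2) stop("global efficiency requires at least 2 contacts")
  g <- as_igraph_inv(net)
  d <- igraph::distances(g, weights = inv_lengths(g), algorithm = "dijkstra")
  inv <- 1 / d
  diag(inv) <- 0
  inv[!is.finite(inv)] <- 0
  sum(inv) / (n * (n - 1))
}

#' Synchronizability
#'
#' Ratio of the second-smallest to the largest eigenvalue of the weighted
#' graph Laplacian `L = D - A` (`D` the diagonal node-strength matrix).
#' Values near 1 indicate a tight Laplacian spectrum and an easily
#' synchronized network. Defined as 0 for disconnected or edgeless networks
#' (the second-smallest eigenvalue vanishes, or the spectrum is all zero).
#'
#' @param net A [functional_network()] (or bare adjacency matrix) with at
#'   least 2 contacts.
#' @return Synchronizability in `[0, 1]`.
#' @examples
#' synchronizability(simulate_adjacency(4, "complete"))  # 1
#' synchronizability(simulate_adjacency(3, "path"))      # 1/3
#' @export
synchronizability <- function(net) {
  A <- if (inherits(net, "functional_network")) net$adjacency else net
  n <- nrow(A)
  if (n < 2) stop("synchronizability requires at least 2 contacts")
  L <- diag(rowSums(A)) - A
  ev <- eigen(L, symmetric = TRUE, only.values = TRUE)$values
  lmax <- ev[1]
  if (lmax <= 1e-12) return(0)
  l2 <- ev[n - 1]
  if (l2 <= 1e-10 * lmax) return(0)
  l2 / lmax
}

#' Transitivity
#'
#' Ratio of the total weight of closed triplets to that of all triplets,
#' with edge weights normalized by the network maximum and combined by
#' cube-root geometric mean (the Brain Connectivity Toolbox weighted
#' convention). 0 when the network has no triplets or no triangles.
#'
#' @param net A [functional_network()] with at least 3 contacts.
#' @return Nonnegative scalar; 1 when every triplet is closed with equal
#'   weights.
#' @export
transitivity_w <- function(net) {
  A <- net$adjacency
  if (nrow(A) < 3) stop("transitivity requires at least 3 contacts")
  mx <- max(A)
  if (mx == 0) return(0)
  W <- (A / mx)^(1 / 3)
  cyc3 <- diag(W %*% W %*% W)
  deg <- rowSums(A > 0)
  denom <- sum(deg * (deg - 1))
  if (denom == 0) return(0)
  sum(cyc3) / denom
}

#' Node strength
#'
#' Row sums of the adjacency matrix: the total weight of edges at each
#' contact.
#'
#' @param net A [functional_network()] with at least 2 contacts.
#' @return Named numeric vector of strengths.
#' @export
node_strength <- function(net) {
  if (n_contacts(net) < 2) stop("node strength requires at least 2 contacts")
  rowSums(net$adjacency)
}

#' Eigenvector centrality
#'
#' The leading eigenvector of the adjacency matrix (the eigenvector of its
#' largest eigenvalue, which by Perron-Frobenius is entrywise nonnegative on
#' a connected network), scaled to unit Euclidean norm. On disconnected
#' input a warning is issued and the vector is computed on the full matrix;
#' entries on components other than the dominant one may then be zero.
#'
#' @param net A [functional_network()].
#' @return Named nonnegative numeric vector with unit Euclidean norm.
#' @export
eigenvector_centrality <- function(net) {
  A <- net$adjacency
  if (!is_connected_net(net))
    warning("network is disconnected; eigenvector centrality computed on the full matrix")
  ev <- eigen(A, symmetric = TRUE)
  v <- ev$vectors[, 1]
  if (sum(v) < 0) v <- -v
  if (any(v < -1e-8))
    warning("leading eigenvector has negative entries (disconnected network); clamping to 0")
  v <- pmax(v, 0)
  v <- v / sqrt(sum(v^2))
  names(v) <- net$labels
  v
}

is_connected_net <- function(net) {
  g <- as_igraph_inv(net)
  igraph::is_connected(g)
}

#' Betweenness centrality
#'
#' Raw (unnormalized) shortest-path betweenness under Dijkstra edge lengths
#' `1/weight`: for each contact, the number of shortest paths between other
#' contact pairs passing through it, with ties over equally short paths
#' credited fractionally.
#'
#' @param net A [functional_network()] with at least 2 contacts.
#' @param normalized If `TRUE`, divide by `(N-1)(N-2)/2` (undirected pair
#'   count); raw counts by default.
#' @return Named nonnegative numeric vector.
#' @export
betweenness_centrality <- function(net, normalized = FALSE) {
  n <- n_contacts(net)
  if (n < 2) stop("betweenness requires at least 2 contacts")
  g <- as_igraph_inv(net)
  b <- igraph::betweenness(g, weights = inv_lengths(g), directed = FALSE)
  if (normalized && n > 2) b <- b / ((n - 1) * (n - 2) / 2)
  names(b) <- net$labels
  b
}

#' Control centrality
#'
#' Relative change in synchronizability caused by deleting each contact:
#' `(Sync_new - Sync_old)/Sync_old` with the contact's row and column
#' removed. Negative values mark synchronizing contacts (their removal
#' lowers synchronizability); a value of -1 means removal disconnects the
#' network. Requires `Sync_old > 0`.
#'
#' @param net A [functional_network()] with at least 3 contacts.
#' @return Named numeric vector.
#' @examples
#' control_centrality(simulate_adjacency(3, "path"))  # c(2, -1, 2)
#' @export
control_centrality <- function(net) {
  A <- net$adjacency
  n <- nrow(A)
  if (n < 3) stop("control centrality requires at least 3 contacts")
  s_old <- synchronizability(net)
  if (s_old <= 0)
    stop("control centrality undefined: original synchronizability is 0")
  cc <- vapply(seq_len(n), function(i) {
    (synchronizability(A[-i, -i, drop = FALSE]) - s_old) / s_old
  }, numeric(1))
  names(cc) <- net$labels
  cc
}

#' Weighted clustering coefficient
#'
#' Per-contact clustering: twice the cube-root geometric-mean weight of
#' closed triplets at the contact, divided by `v(v-1)` where `v` is its
#' neighbor count, with weights normalized by the network maximum (Brain
#' Connectivity Toolbox convention). Contacts with fewer than 2 neighbors
#' score 0.
#'
#' @param net A [functional_network()] with at least 3 contacts.
#' @return Named nonnegative numeric vector.
#' @export
clustering_coefficient <- function(net) {
  A <- net$adjacency
  if (nrow(A) < 3) stop("clustering coefficient requires at least 3 contacts")
  mx <- max(A)
  out <- numeric(nrow(A))
  if (mx > 0) {
    W <- (A / mx)^(1 / 3)
    cyc3 <- diag(W %*% W %*% W)
    deg <- rowSums(A > 0)
    ok <- deg >= 2
    out[ok] <- cyc3[ok] / (deg[ok] * (deg[ok] - 1))
  }
  names(out) <- net$labels
  out
}

#' Regional control centrality
#'
#' Control centrality of contiguous regions rather than single contacts: for
#' every seed contact, the region formed by the seed and its
#' `region_size - 1` nearest neighbors (Euclidean distance on the layout,
#' ties broken by lowest contact index) is deleted and the relative change
#' in synchronizability recorded. The minimizing region — the most
#' synchronizing region of that size, a candidate resection target — is
#' returned alongside all per-seed values.
#'
#' @param net A [functional_network()].
#' @param layout An [electrode_layout()] aligned with the network contacts.
#' @param region_size Number of contacts per region,
#'   `1 <= region_size <= n - 2`.
#' @return A list of class `regional_cc` with `per_seed_values` (named by
#'   seed contact), `regions` (list of index vectors), `argmin_seed`,
#'   `argmin_region` (contact indices), and `region_size`.
#' @export
regional_control_centrality <- function(net, layout, region_size) {
  n <- n_contacts(net)
  check_count(region_size, "region_size")
  if (region_size < 1 || region_size > n - 2)
    stop("region_size must be between 1 and n_contacts - 2")
  if (n_contacts(layout) != n)
    stop("layout does not match network contact count")
  A <- net$adjacency
  s_old <- synchronizability(net)
  if (s_old <= 0)
    stop("regional control centrality undefined: original synchronizability is 0")
  d <- as.matrix(stats::dist(layout_coords(layout)))
  regions <- lapply(seq_len(n), function(i)
    nearest_region(d, i, region_size))
  vals <- vapply(regions, function(r) {
    (synchronizability(A[-r, -r, drop = FALSE]) - s_old) / s_old
  }, numeric(1))
  names(vals) <- net$labels
  best <- unname(which.min(vals))  # ties resolved to lowest seed index
  structure(list(per_seed_values = vals, regions = regions,
                 argmin_seed = best, argmin_region = regions[[best]],
                 region_size = region_size),
            class = "regional_cc")
}

# seed plus its k-1 nearest neighbors; order(dist, index) breaks distance
# ties by lowest contact index
nearest_region <- function(dist_mat, seed, k) {
  others <- setdiff(seq_len(nrow(dist_mat)), seed)
  ord <- others[order(dist_mat[seed, others], others)]
  sort(c(seed, ord[seq_len(k - 1)]))
}

#' All global metrics
#' @param net A [functional_network()].
#' @return Named numeric vector `global_efficiency`, `synchronizability`,
#'   `transitivity`.
#' @export
global_metrics <- function(net) {
  c(global_efficiency = global_efficiency(net),
    synchronizability = synchronizability(net),
    transitivity = transitivity_w(net))
}

#' Evaluate a nodal metric by name
#' @param net A [functional_network()].
#' @param metric One of `"node_strength"`, `"eigenvector_centrality"`,
#'   `"betweenness_centrality"`, `"control_centrality"`,
#'   `"clustering_coefficient"`.
#' @return Named numeric vector over contacts.
#' @export
nodal_metric <- function(metric, net) {
  metric <- match.arg(metric, nodal_metric_names())
  switch(metric,
         node_strength = node_strength(net),
         eigenvector_centrality = eigenvector_centrality(net),
         betweenness_centrality = betweenness_centrality(net),
         control_centrality = control_centrality(net),
         clustering_coefficient = clustering_coefficient(net))
}

#' Metric name sets
#' @return Character vector of nodal (or global) metric names.
#' @export
nodal_metric_names <- function() {
  c("node_strength", "eigenvector_centrality", "betweenness_centrality",
    "control_centrality", "clustering_coefficient")
}

#' @rdname nodal_metric_names
#' @export
global_metric_names <- function() {
  c("global_efficiency", "synchronizability", "transitivity")
}

#' Evaluate a global metric by name
#' @param metric One of [global_metric_names()].
#' @param net A [functional_network()].
#' @return Scalar metric value.
#' @export
global_metric <- function(metric, net) {
  metric <- match.arg(metric, global_metric_names())
  switch(metric,
         global_efficiency = global_efficiency(net),
         synchronizability = synchronizability(net),
         transitivity = transitivity_w(net))
}
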