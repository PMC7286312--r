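# Independent brute-force oracles for graph metrics, usable on networks of
# up to ~8 nodes. Deliberately naive: exhaustive path/triplet enumeration
# and textbook formulas, sharing no code with the package implementation
# beyond base R.

# all simple paths between a and b as lists of node index vectors
enumerate_simple_paths <- function(A, a, b) {
  n <- nrow(A)
  paths <- list()
  walk <- function(path) {
    last <- path[length(path)]
    if (last == b) {
      paths[[length(paths) + 1]] <<- path
      return()
    }
    for (nxt in seq_len(n)) {
      if (A[last, nxt] > 0 && !(nxt %in% path)) walk(c(path, nxt))
    }
  }
  walk(a)
  paths
}

path_length_inv <- function(A, path) {
  if (length(path) < 2) return(0)
  sum(1 / A[cbind(path[-length(path)], path[-1])])
}

# shortest path length between every ordered pair by exhaustive enumeration
oracle_shortest_paths <- function(A) {
  n <- nrow(A)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  for (a in seq_len(n)) for (b in seq_len(n)) {
    if (a == b) next
    paths <- enumerate_simple_paths(A, a, b)
    if (length(paths))
      d[a, b] <- min(vapply(paths, path_length_inv, numeric(1), A = A))
  }
  d
}

oracle_global_efficiency <- function(A) {
  n <- nrow(A)
  d <- oracle_shortest_paths(A)
  inv <- 1 / d
  diag(inv) <- 0
  inv[!is.finite(inv)] <- 0
  sum(inv) / (n * (n - 1))
}

# fractional shortest-path counting over unordered pairs (tolerance for
# floating-point length ties)
oracle_betweenness <- function(A, tol = 1e-9) {
  n <- nrow(A)
  b <- numeric(n)
  for (s in seq_len(n - 1)) for (t in (s + 1):n) {
    paths <- enumerate_simple_paths(A, s, t)
    if (!length(paths)) next
    lens <- vapply(paths, path_length_inv, numeric(1), A = A)
    shortest <- paths[lens <= min(lens) * (1 + tol)]
    for (v in seq_len(n)) {
      if (v == s || v == t) next
      through <- sum(vapply(shortest, function(p) v %in% p, logical(1)))
      b[v] <- b[v] + through / length(shortest)
    }
  }
  b
}

# direct triple loops over the max-normalized cube-root weights
oracle_clustering <- function(A) {
  n <- nrow(A)
  mx <- max(A)
  out <- numeric(n)
  if (mx == 0) return(out)
  for (i in seq_len(n)) {
    v <- sum(A[i, ] > 0)
    if (v < 2) next
    s <- 0
    for (j in seq_len(n)) for (k in seq_len(n)) {
      if (j == i || k == i || j == k) next
      s <- s + (A[i, j] / mx * A[i, k] / mx * A[j, k] / mx)^(1 / 3)
    }
    out[i] <- s / (v * (v - 1))
  }
  out
}

oracle_transitivity <- function(A) {
  n <- nrow(A)
  mx <- max(A)
  if (mx == 0) return(0)
  num <- 0
  den <- 0
  for (i in seq_len(n)) {
    v <- sum(A[i, ] > 0)
    den <- den + v * (v - 1)
    for (j in seq_len(n)) for (k in seq_len(n)) {
      if (j == i || k == i || j == k) next
      num <- num + (A[i, j] / mx * A[i, k] / mx * A[j, k] / mx)^(1 / 3)
    }
  }
  if (den == 0) 0 else num / den
}

oracle_synchronizability <- function(A) {
  L <- diag(rowSums(A)) - A
  ev <- sort(eigen(L, symmetric = TRUE, only.values = TRUE)$values)
  if (ev[length(ev)] <= 1e-12) return(0)
  if (ev[2] <= 1e-10 * ev[length(ev)]) return(0)
  ev[2] / ev[length(ev)]
}

# power iteration for the leading eigenvector, nonnegative, unit norm;
# diagonal shift keeps the dominant eigenvalue strictly largest in
# magnitude (bipartite graphs otherwise make the iteration oscillate)
oracle_eigenvector <- function(A, iters = 5000) {
  A <- A + diag(1 + max(rowSums(A)), nrow(A))
  v <- rep(1, nrow(A))
  for (i in seq_len(iters)) {
    v2 <- A %*% v
    nv <- sqrt(sum(v2^2))
    if (nv == 0) return(v / sqrt(sum(v^2)))
    v2 <- v2 / nv
    if (max(abs(v2 - v)) < 1e-14) { v <- v2; break }
    v <- v2
  }
  as.numeric(v)
}

# textbook Spearman with average ranks
oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  mean((rx - mean(rx)) * (ry - mean(ry))) /
    (sqrt(mean((rx - mean(rx))^2)) * sqrt(mean((ry - mean(ry))^2)))
}

# random connected weighted network (rejection sampling on connectivity)
random_connected_net <- function(n, seed, p_edge = 0.7) {
  set.seed(seed)
  repeat {
    A <- matrix(0, n, n)
    up <- upper.tri(A)
    w <- stats::runif(sum(up))
    w[stats::runif(sum(up)) > p_edge] <- 0
    A[up] <- w
    A <- A + t(A)
    if (all(is.finite(oracle_shortest_paths(A)))) break
  }
  functional_network(A)
}

band_rms_ratio <- function(freq, fs = 512, dur = 2, filter_fun) {
  t <- seq(0, dur - 1 / fs, by = 1 / fs)
  x <- sin(2 * pi * freq * t)
  rec <- recording(rbind(x, x), fs = fs)
  out <- filter_fun(rec)$samples[1, ]
  # trim filter edge transients before measuring
  core <- seq(round(length(out) * 0.2), round(length(out) * 0.8))
  sqrt(mean(out[core]^2)) / sqrt(mean(x[core]^2))
}
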