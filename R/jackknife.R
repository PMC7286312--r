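#' Jackknife 95% confidence contact set for a nodal metric
#'
#' Repeatedly removes a random fraction of contacts (20% by default,
#' emulating minor variability in implantation strategy), recomputes the
#' nodal metric on each subsample, and tallies which contact attains the
#' optimal value (maximum, or minimum for control centrality) in each
#' iteration. Contacts are then sorted by descending occurrence count (ties
#' by lowest contact index) and accumulated greedily until they account for
#' at least `coverage` of all occurrences: the returned confidence contact
#' set. A larger set means the identity of the optimal contact is more
#' sensitive to spatial subsampling, i.e. lower confidence in the
#' localization.
#'
#' @param net A [functional_network()] with at least 5 contacts.
#' @param metric A nodal metric name ([nodal_metric_names()]).
#' @param fraction Removal fraction (0 for no removal; then every iteration
#'   is identical and the set has size 1).
#' @param n_iter Number of jackknife iterations.
#' @param coverage Occurrence fraction the set must cover (0.95).
#' @param seed Master seed.
#' @return A list of class `confidence_set`: `metric`, `contacts` (labels),
#'   `contact_idx`, `counts` (full per-contact tally), `coverage` (achieved,
#'   `>= 0.95`), `optimum_sense` (`"max"`/`"min"`), `n_iter` (successful
#'   iterations), `n_dropped`, `seed`.
#' @export
jackknife_nodal_confidence_set <- function(net, metric, fraction = 0.2,
                                           n_iter = 1000, coverage = 0.95,
                                           seed = 0) {
  metric <- match.arg(metric, nodal_metric_names())
  n <- n_contacts(net)
  if (n < 5) stop("jackknife confidence sets require at least 5 contacts")
  sense <- if (metric == "control_centrality") "min" else "max"
  retained <- jackknife_sets(net, fraction, n_iter, seed)
  counts <- integer(n)
  dropped <- 0L
  for (keep in retained) {
    sub <- remove_contacts(net, setdiff(seq_len(n), keep))
    vals <- tryCatch(nodal_metric(metric, sub), error = function(e) NULL)
    if (is.null(vals)) { dropped <- dropped + 1L; next }
    # which.max/min return the first optimum: ties go to the lowest index
    win <- keep[if (sense == "max") which.max(vals) else which.min(vals)]
    counts[win] <- counts[win] + 1L
  }
  build_confidence_set(counts, net$labels, metric, sense, coverage,
                       dropped, seed)
}

jackknife_sets <- function(net, fraction, n_iter, seed) {
  if (fraction == 0)
    return(replicate(n_iter, seq_len(n_contacts(net)), simplify = FALSE))
  random_subsample(net, fraction, n_iter, seed)$retained
}

# greedy descending-count accumulation to the coverage threshold (>=);
# count ties broken by lowest contact index via order()'s stable tiebreak
build_confidence_set <- function(counts, labels, metric, sense, coverage,
                                 dropped, seed) {
  total <- sum(counts)
  if (total == 0) stop("no successful jackknife iterations")
  ord <- order(-counts, seq_along(counts))
  csum <- cumsum(counts[ord])
  size <- which(csum >= coverage * total)[1]
  idx <- sort(ord[seq_len(size)])
  structure(list(metric = metric, contacts = labels[idx],
                 contact_idx = idx, counts = counts,
                 coverage = csum[size] / total,
                 optimum_sense = sense, n_iter = total,
                 n_dropped = dropped, seed = seed),
            class = "confidence_set")
}

#' @export
print.confidence_set <- function(x, ...) {
  cat(sprintf("<confidence_set> %s (%s): %d contacts covering %.1f%% of %d iterations\n",
              x$metric, x$optimum_sense, length(x$contact_idx),
              100 * x$coverage, x$n_iter))
  invisible(x)
}

#' Jackknife confidence set for the minimum regional control centrality
#'
#' As [jackknife_nodal_confidence_set()], but the per-iteration optimum is
#' the most synchronizing *region* — the seed contact plus its
#' `region_size - 1` nearest neighbors minimizing regional control
#' centrality on the subsampled network — and every member of the winning
#' region is tallied. The confidence set accumulates contacts to 95% of all
#' region-membership occurrences; its size divided by `region_size` gives a
#' ratio comparable across patients (1 when the same region wins every
#' iteration).
#'
#' @param net A [functional_network()].
#' @param layout An [electrode_layout()] aligned with the network.
#' @param region_size Region size, typically the number of resected
#'   contacts; must leave at least 2 contacts in every subsample.
#' @param fraction,n_iter,coverage,seed As in
#'   [jackknife_nodal_confidence_set()].
#' @return A list with `set` (a `confidence_set`) and `ratio`
#'   (`|set| / region_size`).
#' @export
jackknife_regional_cc_confidence <- function(net, layout, region_size,
                                             fraction = 0.2, n_iter = 1000,
                                             coverage = 0.95, seed = 0) {
  n <- n_contacts(net)
  if (n_contacts(layout) != n)
    stop("layout does not match network contact count")
  retained <- jackknife_sets(net, fraction, n_iter, seed)
  if (region_size > min(lengths(retained)) - 2)
    stop("region_size too large for the subsampled networks")
  counts <- integer(n)
  dropped <- 0L
  for (keep in retained) {
    sub <- remove_contacts(net, setdiff(seq_len(n), keep))
    sublay <- layout[keep, , drop = FALSE]
    res <- tryCatch(
      regional_control_centrality(sub, sublay, region_size),
      error = function(e) NULL)
    if (is.null(res)) { dropped <- dropped + 1L; next }
    members <- keep[res$argmin_region]
    counts[members] <- counts[members] + 1L
  }
  cs <- build_confidence_set(counts, net$labels,
                             "regional_control_centrality", "min",
                             coverage, dropped, seed)
  cs$n_iter <- cs$n_iter / region_size  # occurrences per iteration
  list(set = cs, ratio = length(cs$contact_idx) / region_size)
}

#' Jackknife 95% confidence interval for a global metric
#'
#' The interval containing 95% of the global metric values obtained across
#' jackknife subsamples: the 2.5th to 97.5th percentiles (linear
#' interpolation between order statistics). A wider interval means the
#' global statistic is more sensitive to spatial subsampling.
#'
#' @param net A [functional_network()] with at least 5 contacts.
#' @param metric A global metric name ([global_metric_names()]).
#' @param fraction,n_iter,seed As in [jackknife_nodal_confidence_set()].
#' @return A list of class `confidence_interval`: `metric`, `lo`, `hi`,
#'   `width`, `point_value` (full-network value), `values` (per-iteration),
#'   `n_iter` (successful iterations), `n_dropped`, `seed`.
#' @export
jackknife_global_interval <- function(net, metric, fraction = 0.2,
                                      n_iter = 1000, seed = 0) {
  metric <- match.arg(metric, global_metric_names())
  n <- n_contacts(net)
  if (n < 5) stop("jackknife confidence intervals require at least 5 contacts")
  retained <- jackknife_sets(net, fraction, n_iter, seed)
  vals <- vapply(retained, function(keep) {
    sub <- remove_contacts(net, setdiff(seq_len(n), keep))
    tryCatch(global_metric(metric, sub), error = function(e) NA_real_)
  }, numeric(1))
  dropped <- sum(is.na(vals))
  vals <- vals[!is.na(vals)]
  if (!length(vals)) stop("no successful jackknife iterations")
  q <- stats::quantile(vals, c(0.025, 0.975), names = FALSE, type = 7)
  structure(list(metric = metric, lo = q[1], hi = q[2],
                 width = q[2] - q[1],
                 point_value = global_metric(metric, net),
                 values = vals, n_iter = length(vals),
                 n_dropped = dropped, seed = seed),
            class = "confidence_interval")
}

#' @export
print.confidence_interval <- function(x, ...) {
  cat(sprintf("<confidence_interval> %s: [%.4f, %.4f] (width %.4f, point %.4f, %d iterations)\n",
              x$metric, x$lo, x$hi, x$width, x$point_value, x$n_iter))
  invisible(x)
}
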