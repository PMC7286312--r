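#' Remove contacts from a network
#'
#' Deletes the rows and columns of the given contacts from the adjacency
#' matrix, keeping the remaining contacts in their original order with their
#' original labels — the elementary operation behind every subsampling
#' scheme.
#'
#' @param net A [functional_network()].
#' @param removed Integer contact indices or character labels to remove; at
#'   least 2 contacts must remain.
#' @return The reduced [functional_network()].
#' @export
remove_contacts <- function(net, removed) {
  n <- n_contacts(net)
  idx <- resolve_contacts(net, removed)
  if (n - length(idx) < 2)
    stop("removal must leave at least 2 contacts")
  if (!length(idx)) return(net)
  keep <- setdiff(seq_len(n), idx)
  functional_network(net$adjacency[keep, keep, drop = FALSE],
                     labels = net$labels[keep],
                     band = net$band, window = net$window)
}

resolve_contacts <- function(net, contacts) {
  if (is.character(contacts)) {
    idx <- match(contacts, net$labels)
    if (anyNA(idx)) stop("unknown contact label: ",
                         contacts[is.na(idx)][1])
  } else {
    idx <- as.integer(contacts)
    if (any(idx < 1 | idx > n_contacts(net)))
      stop("contact index out of range")
  }
  if (anyDuplicated(idx)) stop("duplicate contacts in removal set")
  idx
}

new_ensemble <- function(scheme, retained, net, fraction = NA_real_,
                         removed_count = NA_integer_, seed = NA_integer_) {
  structure(list(scheme = scheme, retained = retained,
                 fraction = fraction, removed_count = removed_count,
                 n_contacts = n_contacts(net), labels = net$labels,
                 seed = seed),
            class = "subsample_ensemble")
}

#' @export
print.subsample_ensemble <- function(x, ...) {
  cat(sprintf("<subsample_ensemble> scheme %s: %d retained sets of %d contacts\n",
              x$scheme, length(x$retained), x$n_contacts))
  invisible(x)
}

removal_count <- function(n, fraction) {
  if (fraction <= 0 || fraction >= 1) stop("fraction must be in (0, 1)")
  m <- max(1L, round(fraction * n))
  if (n - m < 2)
    stop("removal fraction would leave fewer than 2 contacts")
  m
}

# one master seed; iteration i draws from its own deterministic substream,
# so ensembles are reproducible and extensible in n_iter
iteration_seeds <- function(seed, n_iter) {
  set.seed(seed)
  sample.int(.Machine$integer.max, n_iter)
}

#' Random electrode-contact subsampling
#'
#' Each iteration removes `round(fraction * N)` distinct contacts chosen
#' uniformly without replacement; the default 1000 iterations yield a
#' distribution of subsampled networks per removal fraction.
#'
#' @param net A [functional_network()].
#' @param fraction Removal fraction in `(0, 1)` (e.g. 0.2, 0.4, 0.6, 0.8).
#' @param n_iter Number of random subsamples.
#' @param seed Master seed; identical seeds give identical ensembles.
#' @return A `subsample_ensemble` with `retained`, a list of sorted retained
#'   contact index vectors.
#' @export
random_subsample <- function(net, fraction, n_iter = 1000, seed = 0) {
  n <- n_contacts(net)
  m <- removal_count(n, fraction)
  seeds <- iteration_seeds(seed, n_iter)
  retained <- lapply(seq_len(n_iter), function(i) {
    set.seed(seeds[i])
    sort(setdiff(seq_len(n), sample.int(n, m)))
  })
  new_ensemble("random", retained, net, fraction = fraction,
               removed_count = m, seed = seed)
}

#' Contiguous electrode-contact subsampling
#'
#' Systematic removal of spatially contiguous patches: for every seed
#' contact, the seed and its `round(fraction * N) - 1` nearest neighbors
#' (Euclidean distance on the layout, ties broken by lowest contact index)
#' are removed. Produces exactly one deterministic removal set per contact.
#'
#' @param net A [functional_network()].
#' @param layout An [electrode_layout()] aligned with the network.
#' @param fraction Removal fraction in `(0, 1)`.
#' @return A `subsample_ensemble` with one retained set per seed contact
#'   (in seed order).
#' @export
contiguous_subsample <- function(net, layout, fraction) {
  n <- n_contacts(net)
  if (n_contacts(layout) != n)
    stop("layout does not match network contact count")
  m <- removal_count(n, fraction)
  d <- as.matrix(stats::dist(layout_coords(layout)))
  retained <- lapply(seq_len(n), function(i) {
    region <- nearest_region(d, i, m)
    sort(setdiff(seq_len(n), region))
  })
  new_ensemble("contiguous", retained, net, fraction = fraction,
               removed_count = m)
}

#' Seizure-onset-zone-targeted subsampling
#'
#' Removes all of, and only, the contacts flagged as seizure onset zone: a
#' single deterministic retained set of the non-SOZ contacts.
#'
#' @param net A [functional_network()].
#' @param layout An [electrode_layout()] with at least one SOZ contact and
#'   at least two non-SOZ contacts.
#' @return A `subsample_ensemble` with one retained set.
#' @export
soz_targeted_subsample <- function(net, layout) {
  soz <- soz_indices(net, layout)
  retained <- setdiff(seq_len(n_contacts(net)), soz)
  if (length(retained) < 2)
    stop("fewer than 2 non-SOZ contacts remain after targeted removal")
  new_ensemble("soz_targeted", list(sort(retained)), net,
               removed_count = length(soz))
}

soz_indices <- function(net, layout) {
  if (n_contacts(layout) != n_contacts(net))
    stop("layout does not match network contact count")
  soz <- which(layout$soz)
  if (!length(soz)) stop("layout has no seizure-onset-zone contacts")
  soz
}

#' Seizure-onset-zone-sparing subsampling
#'
#' Each iteration removes a random subset of non-SOZ contacts equal in
#' number to the SOZ, leaving the onset zone intact — the matched control
#' for [soz_targeted_subsample()]. When the SOZ outnumbers the non-SOZ
#' contacts, all non-SOZ contacts are removed instead, as a single
#' deterministic set.
#'
#' @param net A [functional_network()].
#' @param layout An [electrode_layout()] with SOZ flags.
#' @param n_iter Number of random subsamples.
#' @param seed Master seed.
#' @return A `subsample_ensemble`.
#' @export
soz_sparing_subsample <- function(net, layout, n_iter = 1000, seed = 0) {
  n <- n_contacts(net)
  soz <- soz_indices(net, layout)
  non_soz <- setdiff(seq_len(n), soz)
  k <- length(soz)
  if (k >= length(non_soz)) {
    if (length(soz) < 2)
      stop("fewer than 2 contacts would remain")
    return(new_ensemble("soz_sparing", list(sort(soz)), net,
                        removed_count = length(non_soz), seed = seed))
  }
  seeds <- iteration_seeds(seed, n_iter)
  retained <- lapply(seq_len(n_iter), function(i) {
    set.seed(seeds[i])
    sort(setdiff(seq_len(n), sample(non_soz, k)))
  })
  new_ensemble("soz_sparing", retained, net, removed_count = k, seed = seed)
}

#' Centroid distance between contact sets
#'
#' Euclidean distance (mm) between the coordinate centroids of two contact
#' sets — e.g. a removed set and the seizure onset zone.
#'
#' @param removed,soz Nonempty integer contact index vectors into `layout`.
#' @param layout An [electrode_layout()].
#' @return Distance in millimetres.
#' @examples
#' lay <- simulate_layout(3, 3, 10)
#' centroid_distance(1, 9, lay)
#' @export
centroid_distance <- function(removed, soz, layout) {
  if (!length(removed) || !length(soz))
    stop("both contact sets must be nonempty")
  xyz <- layout_coords(layout)
  c1 <- colMeans(xyz[removed, , drop = FALSE])
  c2 <- colMeans(xyz[soz, , drop = FALSE])
  sqrt(sum((c1 - c2)^2))
}

#' Recompute metrics across an ensemble
#'
#' Applies [remove_contacts()] to each retained set and evaluates a nodal or
#' global metric on the subnetwork. Nodal results are returned as an
#' iterations x contacts matrix with `NA` at removed contacts — the input
#' shape expected by [reliability_nodal()] and [rank_stability()]. Global
#' results are a numeric vector. Iterations on which the metric is
#' undefined (e.g. control centrality when the subnetwork's
#' synchronizability is 0) are recorded as `NA` rows/values and counted in
#' attribute `n_dropped`.
#'
#' @param ensemble A `subsample_ensemble`.
#' @param net The original [functional_network()] the ensemble was drawn
#'   from.
#' @param metric A metric name from [nodal_metric_names()] or
#'   [global_metric_names()].
#' @return Matrix (nodal) or vector (global) of subsampled metric values,
#'   with attribute `n_dropped`.
#' @export
ensemble_metric <- function(ensemble, net, metric) {
  nodal <- metric %in% nodal_metric_names()
  if (!nodal && !metric %in% global_metric_names())
    stop("unknown metric: ", metric)
  n <- n_contacts(net)
  n_iter <- length(ensemble$retained)
  dropped <- 0L
  if (nodal) {
    out <- matrix(NA_real_, n_iter, n,
                  dimnames = list(NULL, net$labels))
    for (i in seq_len(n_iter)) {
      keep <- ensemble$retained[[i]]
      sub <- remove_contacts(net, setdiff(seq_len(n), keep))
      vals <- tryCatch(nodal_metric(metric, sub), error = function(e) NULL)
      if (is.null(vals)) dropped <- dropped + 1L
      else out[i, keep] <- vals
    }
  } else {
    out <- rep(NA_real_, n_iter)
    for (i in seq_len(n_iter)) {
      keep <- ensemble$retained[[i]]
      sub <- remove_contacts(net, setdiff(seq_len(n), keep))
      v <- tryCatch(global_metric(metric, sub), error = function(e) NA_real_)
      if (is.na(v)) dropped <- dropped + 1L
      out[i] <- v
    }
  }
  attr(out, "n_dropped") <- dropped
  out
}
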