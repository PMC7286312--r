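#' Frequency band specification
#'
#' Named bands follow the seizure-network literature: high gamma
#' (95-105 Hz), chosen for its role in seizure propagation, and beta
#' (15-25 Hz).
#'
#' @param name `"high_gamma"`, `"beta"`, or `"custom"`.
#' @param lo,hi Band edges in Hz; required (and only used) for `"custom"`.
#' @return A list with `name`, `lo`, `hi`.
#' @examples
#' band_spec("high_gamma")
#' band_spec("custom", 40, 60)
#' @export
band_spec <- function(name = c("high_gamma", "beta", "custom"),
                      lo = NULL, hi = NULL) {
  name <- match.arg(name)
  if (name == "high_gamma") { lo <- 95; hi <- 105 }
  if (name == "beta") { lo <- 15; hi <- 25 }
  if (is.null(lo) || is.null(hi) || lo >= hi)
    stop("custom band requires lo < hi")
  list(name = name, lo = lo, hi = hi)
}

as_band <- function(band) {
  if (is.numeric(band) && length(band) == 2)
    return(band_spec("custom", band[1], band[2]))
  band
}

# Discrete prolate spheroidal (Slepian) tapers via the symmetric
# tridiagonal matrix that commutes with the time-bandwidth concentration
# operator; eigenvectors are exact DPSS. Cached per (n, nw, k).
.dpss_cache <- new.env(parent = emptyenv())

dpss_tapers <- function(n, nw = 2, k = 3) {
  key <- paste(n, nw, k, sep = "_")
  hit <- .dpss_cache[[key]]
  if (!is.null(hit)) return(hit)
  w <- nw / n
  t <- seq_len(n) - 1
  diag_el <- ((n - 1 - 2 * t) / 2)^2 * cos(2 * pi * w)
  off_el <- (t * (n - t) / 2)[seq_len(n - 1)]
  T <- diag(diag_el)
  T[cbind(seq_len(n - 1), seq_len(n - 1) + 1)] <- off_el
  T[cbind(seq_len(n - 1) + 1, seq_len(n - 1))] <- off_el
  ev <- eigen(T, symmetric = TRUE)
  V <- ev$vectors[, seq_len(k), drop = FALSE]
  # unit energy; fix polarity so each taper has nonnegative mean slope sign
  V <- apply(V, 2, function(v) {
    v <- v / sqrt(sum(v^2))
    if (sum(v) < 0 || (abs(sum(v)) < 1e-12 && v[2] < 0)) v <- -v
    v
  })
  .dpss_cache[[key]] <- V
  V
}

#' Multitaper coherence functional network
#'
#' Estimates the magnitude-squared coherence between every contact pair
#' within a short time window using Slepian (DPSS) multitaper spectral
#' estimation, then averages over the FFT bins inside the requested band
#' (inclusive bounds) to obtain one edge weight per pair. The result is an
#' undirected, weighted functional network with weights in `[0, 1]`.
#'
#' @param rec A [recording()].
#' @param window_start Window anchor in seconds from the start of the
#'   recording (the window begins here).
#' @param window_len Window length in seconds (1 s by default; 2 s is a
#'   common sensitivity setting).
#' @param band A [band_spec()] or numeric `c(lo, hi)` Hz; must lie below
#'   Nyquist.
#' @param nw Time-bandwidth product of the tapers.
#' @param k Number of Slepian tapers averaged (defaults: `nw = 2`, `k = 3`,
#'   conventional for 1-s windows).
#' @return A [functional_network()] carrying the band and window metadata.
#' @export
multitaper_coherence_network <- function(rec, window_start = 0,
                                         window_len = 1,
                                         band = band_spec("high_gamma"),
                                         nw = 2, k = 3) {
  band <- as_band(band)
  fs <- rec$fs
  if (band$hi >= fs / 2)
    stop("band upper edge must be below the Nyquist frequency fs/2")
  if (window_start < 0) stop("window_start must be nonnegative")
  i0 <- floor(window_start * fs) + 1L
  nwin <- round(window_len * fs)
  if (nwin < 8) stop("window too short")
  if (i0 + nwin - 1L > ncol(rec$samples))
    stop("window extends beyond the end of the recording")
  X <- rec$samples[, i0:(i0 + nwin - 1L), drop = FALSE]
  nchan <- nrow(X)
  V <- dpss_tapers(nwin, nw, k)
  freqs <- (seq_len(nwin) - 1) * fs / nwin
  bins <- which(freqs >= band$lo & freqs <= band$hi & freqs <= fs / 2)
  if (!length(bins)) stop("no FFT bins fall inside the requested band")
  # tapered FFTs: channels x tapers x in-band bins
  Z <- array(0 + 0i, dim = c(nchan, k, length(bins)))
  for (ch in seq_len(nchan))
    for (tp in seq_len(k))
      Z[ch, tp, ] <- stats::fft(V[, tp] * X[ch, ])[bins]
  A <- matrix(0, nchan, nchan)
  for (b in seq_along(bins)) {
    Zb <- Z[, , b, drop = FALSE]
    dim(Zb) <- c(nchan, k)
    S <- Zb %*% Conj(t(Zb)) / k            # cross-spectral matrix at bin b
    p <- Re(diag(S))
    msc <- Mod(S)^2 / outer(p, p)
    msc[p == 0, ] <- 0; msc[, p == 0] <- 0
    A <- A + msc
  }
  A <- A / length(bins)
  A <- pmin(A, 1)
  diag(A) <- 0
  functional_network((A + t(A)) / 2, labels = rec$labels, band = band,
                     window = c(window_start, window_len))
}

#' Threshold a network to a target density
#'
#' Zeroes all edges whose weight falls strictly below a cutoff `w`, with `w`
#' chosen so that the fraction of retained unordered contact pairs equals
#' the target density to within one edge. Ties at `w` are retained; retained
#' weights are unchanged. If ties make the target unreachable within one
#' edge, a warning reports the closest achievable density.
#'
#' @param net A [functional_network()].
#' @param density Target density in `(0, 1]`; `1` returns the network
#'   unchanged.
#' @return The thresholded [functional_network()], with attribute
#'   `achieved_density`.
#' @examples
#' net <- simulate_adjacency(4, "uniform_random", seed = 1)
#' thr <- threshold_to_density(net, 0.5)
#' attr(thr, "achieved_density")
#' @export
threshold_to_density <- function(net, density = 0.5) {
  if (density <= 0 || density > 1) stop("density must be in (0, 1]")
  A <- net$adjacency
  up <- upper.tri(A)
  w_all <- A[up]
  m <- length(w_all)
  if (density == 1) {
    attr(net, "achieved_density") <- sum(w_all > 0) / m
    return(net)
  }
  k_target <- round(density * m)
  if (k_target == 0) k_target <- 1L
  w <- sort(w_all, decreasing = TRUE)[k_target]
  if (w <= 0) {
    # fewer nonzero edges than requested: nothing to remove
    attr(net, "achieved_density") <- sum(w_all > 0) / m
    return(net)
  }
  keep <- w_all >= w
  achieved <- sum(keep) / m
  if (abs(sum(keep) - k_target) > 1) {
    warning(sprintf(
      "tied weights prevent reaching density %.3f; closest achievable is %.3f",
      density, achieved))
  }
  A[up][!keep] <- 0
  A[lower.tri(A)] <- t(A)[lower.tri(A)]
  net$adjacency <- A
  attr(net, "achieved_density") <- achieved
  net
}

#' Peri-ictal analysis windows
#'
#' Windows anchored at fixed offsets around the earliest electrographic
#' change (EEC): by default 10 s and 5 s before, at, and 5 s and 10 s after
#' the EEC. Each window begins at `eec_time + offset`.
#'
#' @param eec_time EEC time in seconds from the start of the recording.
#' @param offsets Offsets in seconds relative to the EEC.
#' @param window_len Window length in seconds.
#' @return A data.frame with columns `offset`, `start`, `len` (one row per
#'   offset; empty for empty `offsets`).
#' @examples
#' peri_ictal_windows(100, window_len = 1)
#' @export
peri_ictal_windows <- function(eec_time, offsets = c(-10, -5, 0, 5, 10),
                               window_len = 1) {
  if (eec_time < 0) stop("eec_time must be nonnegative")
  data.frame(offset = as.numeric(offsets),
             start = eec_time + as.numeric(offsets),
             len = rep_len(window_len, length(offsets)))
}
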