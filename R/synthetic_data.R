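#' Simulate a planar electrode grid layout
#'
#' Generates a rectangular grid of electrode contacts at fixed intercontact
#' spacing (10 mm by default, the spacing of standard subdural grids) and
#' flags a spatially contiguous seizure onset zone (SOZ). The SOZ is grown
#' from a randomly chosen seed contact by repeatedly adding the non-member
#' contact closest to the current region (ties broken by lowest contact
#' index), which guarantees contiguity on any layout.
#'
#' @param n_rows,n_cols Grid dimensions; `n_rows * n_cols` must be at least 4.
#' @param spacing_mm Intercontact spacing in millimetres.
#' @param n_soz Number of SOZ contacts, `1 <= n_soz < n_rows * n_cols`.
#' @param seed Integer seed controlling SOZ placement.
#' @return An [electrode_layout()] with `n_rows * n_cols` contacts in
#'   row-major order; `resected` mirrors `soz` (the common clinical default
#'   of resecting the onset zone).
#' @examples
#' simulate_layout(2, 2, 10, n_soz = 1, seed = 0)
#' @export
simulate_layout <- function(n_rows, n_cols, spacing_mm = 10,
                            n_soz = 1, seed = 0) {
  check_count(n_rows, "n_rows"); check_count(n_cols, "n_cols")
  n <- n_rows * n_cols
  if (n < 4) stop("layout must have at least 4 contacts")
  if (n_soz < 1 || n_soz >= n) stop("n_soz must satisfy 1 <= n_soz < n")
  coords <- grid_coords(n_rows, n_cols, spacing_mm)
  soz <- grow_soz(coords, n_soz, seed)
  flags <- seq_len(n) %in% soz
  electrode_layout(label = default_labels(n),
                   x_mm = coords[, 1], y_mm = coords[, 2], z_mm = coords[, 3],
                   soz = flags, resected = flags)
}

# row-major planar grid: contact k sits at row (k-1) %/% n_cols,
# column (k-1) %% n_cols
grid_coords <- function(n_rows, n_cols, spacing_mm, n = n_rows * n_cols) {
  k <- seq_len(n) - 1L
  cbind(x = (k %% n_cols) * spacing_mm,
        y = (k %/% n_cols) * spacing_mm,
        z = 0)
}

# contiguous region growth: start at a random contact, then repeatedly add
# the outside contact with minimal distance to any region member
grow_soz <- function(coords, n_soz, seed) {
  n <- nrow(coords)
  set.seed(seed)
  region <- sample.int(n, 1L)
  d <- as.matrix(stats::dist(coords))
  while (length(region) < n_soz) {
    outside <- setdiff(seq_len(n), region)
    dmin <- apply(d[outside, region, drop = FALSE], 1, min)
    region <- c(region, outside[which.min(dmin)])
  }
  sort(region)
}

#' Simulate a multichannel recording with block-coupled coherence structure
#'
#' Contacts are partitioned into `n_groups` contiguous groups; every contact
#' in a group shares that group's latent narrowband source (band-limited
#' Gaussian noise, created by bandpass-filtering white noise to `band`),
#' plus independent Gaussian channel noise. Within-group pairs are therefore
#' coherent in `band` while between-group pairs are not — the statistical
#' structure functional-connectivity estimation assumes, with known ground
#' truth.
#'
#' @param layout An [electrode_layout()] fixing the contact count and labels.
#' @param duration Recording length in seconds (at least 1).
#' @param fs Sampling frequency in Hz (512 by default, a common clinical
#'   iEEG rate).
#' @param n_groups Number of coupling groups (contiguous index blocks).
#' @param band Numeric `c(lo, hi)` Hz of the latent sources; must lie below
#'   the Nyquist frequency.
#' @param noise_sd Standard deviation of i.i.d. Gaussian channel noise, in
#'   units of the (unit-variance) latent sources.
#' @param pink If `TRUE`, adds a 1/f background component to each channel;
#'   off by default since only band-limited coherence matters downstream.
#' @param seed Integer seed; identical seeds give identical recordings.
#' @return A list with `recording` (a [recording()]) and `truth`, the
#'   simulation ground truth: `coupling_blocks` (list of contact index
#'   vectors), `soz_contacts`, `noise_sd`, `band`, and `seed`.
#' @export
simulate_recording <- function(layout, duration, fs = 512, n_groups = 2,
                               band = c(95, 105), noise_sd = 0.5,
                               pink = FALSE, seed = 0) {
  n <- n_contacts(layout)
  if (duration < 1) stop("duration must be at least 1 s")
  if (band[2] >= fs / 2)
    stop("band upper edge must be below the Nyquist frequency fs/2")
  if (band[1] <= 0 || band[1] >= band[2]) stop("invalid band")
  if (n_groups < 1 || n_groups > n) stop("invalid n_groups")
  nt <- round(duration * fs)
  blocks <- split(seq_len(n), cut(seq_len(n), n_groups, labels = FALSE))
  bf <- signal::butter(4, band / (fs / 2), type = "pass")
  set.seed(seed)
  sources <- matrix(0, n_groups, nt)
  for (g in seq_len(n_groups)) {
    s <- signal::filtfilt(bf, stats::rnorm(nt))
    sources[g, ] <- s / stats::sd(s)
  }
  samples <- matrix(0, n, nt)
  for (g in seq_len(n_groups))
    for (i in blocks[[g]])
      samples[i, ] <- sources[g, ] + noise_sd * stats::rnorm(nt)
  if (pink)
    samples <- samples + t(replicate(n, pink_noise(nt)))
  rec <- recording(samples, fs = fs, labels = layout$label)
  truth <- list(coupling_blocks = unname(blocks),
                source_signals = sources,
                soz_contacts = which(layout$soz),
                noise_sd = noise_sd, band = band, seed = seed)
  list(recording = rec, truth = truth)
}

# 1/f-amplitude Gaussian background via spectral shaping
pink_noise <- function(nt) {
  x <- stats::rnorm(nt)
  X <- stats::fft(x)
  f <- c(1, seq_len(nt - 1))
  f <- pmin(f, nt - f + 1)
  X <- X / sqrt(f)
  s <- Re(stats::fft(X, inverse = TRUE)) / nt
  s / stats::sd(s)
}

#' Simulate an adjacency matrix directly
#'
#' Direct fixtures for graph-metric work: symmetric, nonnegative,
#' zero-diagonal weighted networks with known structure.
#'
#' @param n Number of contacts (at least 2).
#' @param model One of `"uniform_random"` (i.i.d. uniform weights on all
#'   pairs), `"block"` (strong within-block, weak between-block weights),
#'   `"complete"` (all off-diagonal weights equal to `weight`), `"path"`
#'   (a chain `1-2-...-n` with weight `weight`).
#' @param weight Edge weight for `"complete"` and `"path"`.
#' @param n_blocks Number of contiguous blocks for `"block"`.
#' @param w_in,w_out Mean within-/between-block weight for `"block"`.
#' @param jitter Half-width of uniform weight jitter for `"block"`.
#' @param seed Integer seed (used by the stochastic models).
#' @return A [functional_network()].
#' @examples
#' simulate_adjacency(3, "complete", weight = 1)
#' simulate_adjacency(50, "uniform_random", seed = 7)
#' @export
simulate_adjacency <- function(n,
                               model = c("uniform_random", "block",
                                         "complete", "path"),
                               weight = 1, n_blocks = 2,
                               w_in = 0.7, w_out = 0.15, jitter = 0.1,
                               seed = 0) {
  model <- match.arg(model)
  check_count(n, "n")
  if (n < 2) stop("n must be at least 2")
  A <- matrix(0, n, n)
  set.seed(seed)
  if (model == "uniform_random") {
    A[upper.tri(A)] <- stats::runif(n * (n - 1) / 2)
  } else if (model == "block") {
    g <- cut(seq_len(n), n_blocks, labels = FALSE)
    base <- ifelse(outer(g, g, "=="), w_in, w_out)
    noise <- matrix(stats::runif(n * n, -jitter, jitter), n, n)
    up <- upper.tri(A)
    A[up] <- pmin(1, pmax(0, base[up] + noise[up]))
  } else if (model == "complete") {
    A[upper.tri(A)] <- weight
  } else { # path
    A[cbind(seq_len(n - 1), seq_len(n - 1) + 1)] <- weight
  }
  A <- A + t(A)
  functional_network(A)
}

#' Simulate a cohort of patients
#'
#' Independent per-patient block-structured networks with matched grid
#' layouts, with heterogeneous contact counts drawn uniformly from
#' `size_range` (default 16-118, the span seen in typical surgical-epilepsy
#' iEEG cohorts).
#'
#' @param n_patients Number of patients (at least 2).
#' @param size_range Integer `c(min, max)` bounds on per-patient contact
#'   counts.
#' @param spacing_mm Grid spacing passed to the layout construction.
#' @param soz_fraction Fraction of contacts flagged as seizure onset zone
#'   (at least 1 contact).
#' @param n_blocks,w_in,w_out,jitter Passed to
#'   [simulate_adjacency()]'s `"block"` model.
#' @param seed Master seed; the same seed reproduces the whole cohort.
#' @return A list of `n_patients` elements, each a list with `network`
#'   (a [functional_network()]) and `layout` (an [electrode_layout()]).
#' @export
simulate_cohort <- function(n_patients, size_range = c(16, 118),
                            spacing_mm = 10, soz_fraction = 0.15,
                            n_blocks = 4, w_in = 0.7, w_out = 0.15,
                            jitter = 0.1, seed = 0) {
  check_count(n_patients, "n_patients")
  if (n_patients < 2) stop("n_patients must be at least 2")
  if (size_range[1] < 4 || size_range[2] < size_range[1])
    stop("invalid size_range")
  set.seed(seed)
  size_pool <- seq(size_range[1], size_range[2])
  sizes <- size_pool[sample.int(length(size_pool), n_patients,
                                replace = TRUE)]
  sub_seeds <- sample.int(.Machine$integer.max, 2 * n_patients)
  lapply(seq_len(n_patients), function(p) {
    n <- sizes[p]
    lay <- trimmed_grid_layout(n, spacing_mm,
                               n_soz = max(1L, round(soz_fraction * n)),
                               seed = sub_seeds[2 * p - 1])
    net <- simulate_adjacency(n, "block", n_blocks = min(n_blocks, n),
                              w_in = w_in, w_out = w_out, jitter = jitter,
                              seed = sub_seeds[2 * p])
    net$labels <- lay$label
    dimnames(net$adjacency) <- list(lay$label, lay$label)
    list(network = net, layout = lay)
  })
}

# near-square grid truncated row-major to exactly n contacts; the truncated
# set is itself contiguous, so SOZ growth stays valid
trimmed_grid_layout <- function(n, spacing_mm, n_soz, seed) {
  n_rows <- max(1L, floor(sqrt(n)))
  n_cols <- ceiling(n / n_rows)
  coords <- grid_coords(n_rows, n_cols, spacing_mm, n = n)
  soz <- grow_soz(coords, n_soz, seed)
  flags <- seq_len(n) %in% soz
  electrode_layout(label = default_labels(n),
                   x_mm = coords[, 1], y_mm = coords[, 2], z_mm = coords[, 3],
                   soz = flags, resected = flags)
}

check_count <- function(x, name) {
  if (length(x) != 1 || is.na(x) || x != round(x) || x < 0)
    stop(name, " must be a single nonnegative integer")
  invisible(x)
}
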