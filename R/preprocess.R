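#' Multichannel recording container
#'
#' @param samples Numeric matrix, contacts x timepoints (microvolts or any
#'   consistent scale); no missing values.
#' @param fs Sampling frequency in Hz.
#' @param labels Contact labels, one per row.
#' @return An object of class `recording`.
#' @export
recording <- function(samples, fs, labels = NULL) {
  if (!is.matrix(samples) || !is.numeric(samples))
    stop("samples must be a numeric matrix (contacts x timepoints)")
  if (anyNA(samples)) stop("samples must not contain missing values")
  if (length(fs) != 1 || fs <= 0) stop("fs must be a positive scalar")
  if (is.null(labels)) labels <- rownames(samples)
  if (is.null(labels)) labels <- default_labels(nrow(samples))
  if (length(labels) != nrow(samples))
    stop("labels length must equal contact count")
  rownames(samples) <- labels
  structure(list(samples = samples, fs = fs, labels = labels),
            class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> %d contacts x %d samples @ %g Hz (%.2f s)\n",
              nrow(x$samples), ncol(x$samples), x$fs,
              ncol(x$samples) / x$fs))
  invisible(x)
}

#' Common average reference
#'
#' Re-references every channel by subtracting, at each timepoint, the mean
#' across all channels, removing sources of noise common to the whole
#' montage.
#'
#' @param rec A [recording()] with at least 2 contacts.
#' @return The re-referenced [recording()]; after this step the mean across
#'   contacts is zero at every timepoint.
#' @examples
#' rec <- recording(matrix(c(1, 3, 3, 5), 2, 2), fs = 512)
#' common_average_reference(rec)$samples
#' @export
common_average_reference <- function(rec) {
  if (nrow(rec$samples) < 2)
    stop("common average reference requires at least 2 contacts")
  rec$samples <- sweep(rec$samples, 2, colMeans(rec$samples))
  rec
}

#' Elliptic bandpass plus power-line notch filtering
#'
#' Applies a zero-phase (forward-backward) elliptic bandpass filter followed
#' by a second-order IIR notch at the power-line frequency. Defaults follow
#' standard iEEG practice: 5-115 Hz passband, 60 Hz notch.
#'
#' @param rec A [recording()].
#' @param lo,hi Bandpass cutoff frequencies in Hz; `hi` must be below
#'   Nyquist.
#' @param notch Notch frequency in Hz (set `NULL` to skip).
#' @param order Elliptic filter order (applied forward-backward, so the
#'   effective order doubles).
#' @param rp Passband ripple in dB.
#' @param rs Stopband attenuation in dB.
#' @param notch_q Notch quality factor (centre frequency / -3 dB width).
#' @return The filtered [recording()].
#' @export
bandpass_and_notch <- function(rec, lo = 5, hi = 115, notch = 60,
                               order = 4, rp = 0.5, rs = 40, notch_q = 30) {
  fs <- rec$fs
  if (hi >= fs / 2) stop("hi must be below the Nyquist frequency fs/2")
  if (lo <= 0 || lo >= hi) stop("need 0 < lo < hi")
  bp <- signal::ellip(order, rp, rs, c(lo, hi) / (fs / 2), type = "pass")
  out <- t(apply(rec$samples, 1, function(x) signal::filtfilt(bp, x)))
  if (!is.null(notch)) {
    nf <- iir_notch(notch, fs, notch_q)
    out <- t(apply(out, 1, function(x) signal::filtfilt(nf, x)))
  }
  rec$samples <- out
  rownames(rec$samples) <- rec$labels
  rec
}

# second-order IIR notch biquad (constant-skirt cookbook design)
iir_notch <- function(f0, fs, q) {
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  signal::Arma(b = b / a[1], a = a / a[1])
}

#' Autoregressive prewhitening
#'
#' Removes order-`p` autoregressive structure from each channel, flattening
#' slow dynamics and accentuating higher frequencies before coherence
#' estimation. Coefficients are fitted per channel by least squares
#' (minimum-norm solution, so a constant channel yields all-zero residuals
#' rather than an error); the returned traces are the fit residuals, of
#' length `timepoints - order`.
#'
#' @param rec A [recording()] with more timepoints than `order`.
#' @param order AR model order (default 1).
#' @return The prewhitened [recording()] (each channel `order` samples
#'   shorter).
#' @export
prewhiten_ar <- function(rec, order = 1) {
  check_count(order, "order")
  nt <- ncol(rec$samples)
  if (nt <= order) stop("recording must have more timepoints than the AR order")
  rec$samples <- t(apply(rec$samples, 1, ar_residuals, order = order))
  rownames(rec$samples) <- rec$labels
  rec
}

ar_residuals <- function(x, order) {
  emb <- stats::embed(x, order + 1)
  y <- emb[, 1]
  X <- emb[, -1, drop = FALSE]
  # minimum-norm least squares tolerates rank-deficient (e.g. constant) input
  b <- MASS::ginv(X) %*% y
  as.numeric(y - X %*% b)
}

#' Full signal-conditioning pipeline
#'
#' Common average reference, then elliptic bandpass + notch, then AR
#' prewhitening — the conventional conditioning order before multitaper
#' coherence estimation. Every stage preserves the channel count.
#'
#' @param rec A [recording()].
#' @param lo,hi,notch Passed to [bandpass_and_notch()].
#' @param ar_order Passed to [prewhiten_ar()].
#' @return The conditioned [recording()].
#' @export
preprocess <- function(rec, lo = 5, hi = 115, notch = 60, ar_order = 1) {
  rec <- common_average_reference(rec)
  rec <- bandpass_and_notch(rec, lo = lo, hi = hi, notch = notch)
  prewhiten_ar(rec, order = ar_order)
}
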