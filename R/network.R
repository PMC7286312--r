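#' Functional network container
#'
#' An undirected, weighted functional connectivity network: a symmetric,
#' nonnegative adjacency matrix with zero diagonal, one row/column per
#' electrode contact. Optionally carries the frequency band and time window
#' the network was estimated from.
#'
#' @param adjacency Square numeric matrix of edge weights. Must be symmetric
#'   (to `tol`), nonnegative, with (near-)zero diagonal. Zero entries mean
#'   "no edge".
#' @param labels Character vector of contact labels, one per row. Defaults to
#'   the matrix dimnames, or `"C001"`, `"C002"`, ... when absent.
#' @param band Optional frequency band, a list with `name`, `lo`, `hi` (Hz);
#'   see [band_spec()].
#' @param window Optional time window, numeric `c(start, length)` in seconds.
#' @param tol Numerical tolerance for the symmetry and zero-diagonal checks.
#' @return An object of class `functional_network`: a list with elements
#'   `adjacency`, `labels`, `band`, `window`.
#' @examples
#' A <- matrix(c(0, 1, 1, 0), 2, 2)
#' net <- functional_network(A)
#' n_contacts(net)
#' @export
functional_network <- function(adjacency, labels = NULL, band = NULL,
                               window = NULL, tol = 1e-10) {
  if (!is.matrix(adjacency) || !is.numeric(adjacency))
    stop("adjacency must be a numeric matrix")
  n <- nrow(adjacency)
  if (ncol(adjacency) != n)
    stop("adjacency must be square")
  if (anyNA(adjacency))
    stop("adjacency must not contain missing values")
  scale <- max(abs(adjacency), 1)
  if (max(abs(adjacency - t(adjacency))) > tol * scale)
    stop("adjacency must be symmetric (residual exceeds tolerance)")
  if (max(abs(diag(adjacency))) > tol * scale)
    stop("adjacency must have a zero diagonal")
  if (any(adjacency < -tol))
    stop("adjacency weights must be nonnegative")
  adjacency <- (adjacency + t(adjacency)) / 2
  adjacency[adjacency < 0] <- 0
  diag(adjacency) <- 0
  if (is.null(labels)) labels <- rownames(adjacency)
  if (is.null(labels)) labels <- default_labels(n)
  if (length(labels) != n) stop("labels length must equal contact count")
  if (anyDuplicated(labels)) stop("contact labels must be unique")
  dimnames(adjacency) <- list(labels, labels)
  structure(list(adjacency = adjacency, labels = labels,
                 band = band, window = window),
            class = "functional_network")
}

default_labels <- function(n) sprintf("C%03d", seq_len(n))

#' Number of contacts in a network, layout, or recording
#' @param x A `functional_network`, `electrode_layout`, or `recording`.
#' @return Integer contact count.
#' @export
n_contacts <- function(x) UseMethod("n_contacts")

#' @export
n_contacts.functional_network <- function(x) nrow(x$adjacency)

#' @export
n_contacts.electrode_layout <- function(x) nrow(x)

#' @export
n_contacts.recording <- function(x) nrow(x$samples)

#' @export
print.functional_network <- function(x, ...) {
  n <- n_contacts(x)
  dens <- network_density(x)
  cat(sprintf("<functional_network> %d contacts, density %.3f\n", n, dens))
  if (!is.null(x$band))
    cat(sprintf("  band: %s [%g, %g] Hz\n", x$band$name, x$band$lo, x$band$hi))
  if (!is.null(x$window))
    cat(sprintf("  window: start %g s, length %g s\n",
                x$window[1], x$window[2]))
  invisible(x)
}

#' Network density
#'
#' Fraction of unordered off-diagonal contact pairs joined by a nonzero edge.
#'
#' @param net A `functional_network`.
#' @return Density in `[0, 1]`.
#' @export
network_density <- function(net) {
  A <- net$adjacency
  n <- nrow(A)
  sum(A[upper.tri(A)] > 0) / (n * (n - 1) / 2)
}

#' Electrode layout table
#'
#' Per-contact 3D coordinates (mm) with seizure-onset-zone and resection
#' flags. The layout row order must match the contact order of any network
#' or recording it is used with.
#'
#' @param label Character vector of unique contact labels.
#' @param x_mm,y_mm,z_mm Numeric coordinates in millimetres.
#' @param soz Logical seizure-onset-zone flag per contact.
#' @param resected Logical resection flag per contact.
#' @return A `data.frame` of class `electrode_layout` with columns
#'   `label`, `x_mm`, `y_mm`, `z_mm`, `soz`, `resected`.
#' @export
electrode_layout <- function(label, x_mm, y_mm, z_mm = 0,
                             soz = FALSE, resected = FALSE) {
  n <- length(label)
  out <- data.frame(label = as.character(label),
                    x_mm = as.numeric(x_mm),
                    y_mm = as.numeric(y_mm),
                    z_mm = rep_len(as.numeric(z_mm), n),
                    soz = rep_len(as.logical(soz), n),
                    resected = rep_len(as.logical(resected), n),
                    stringsAsFactors = FALSE)
  validate_layout(out)
}

validate_layout <- function(df) {
  required <- c("label", "x_mm", "y_mm", "z_mm", "soz", "resected")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("layout is missing columns: ", paste(missing, collapse = ", "))
  if (anyDuplicated(df$label))
    stop("duplicate contact label: ",
         df$label[duplicated(df$label)][1])
  coords <- df[c("x_mm", "y_mm", "z_mm")]
  bad <- which(!stats::complete.cases(coords))
  if (length(bad))
    stop("non-numeric or missing coordinates at row ", bad[1])
  class(df) <- c("electrode_layout", "data.frame")
  df
}

layout_coords <- function(layout) {
  as.matrix(layout[, c("x_mm", "y_mm", "z_mm")])
}

#' @export
print.electrode_layout <- function(x, ...) {
  cat(sprintf("<electrode_layout> %d contacts (%d SOZ, %d resected)\n",
              nrow(x), sum(x$soz), sum(x$resected)))
  NextMethod()
}
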