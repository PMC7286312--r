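#' Read and write electrode layouts
#'
#' Layout CSVs have columns `label,x_mm,y_mm,z_mm,soz,resected`; `soz` and
#' `resected` are parsed as logicals (TRUE/FALSE or 0/1). Validation names
#' the offending row on failure.
#'
#' @param path Path to a layout CSV.
#' @return [read_layout()]: an [electrode_layout()]. [write_layout()]:
#'   `path`, invisibly.
#' @export
read_layout <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("label", "x_mm", "y_mm", "z_mm", "soz", "resected")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("layout file is missing columns: ", paste(missing, collapse = ", "))
  for (col in c("x_mm", "y_mm", "z_mm")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]))
    if (length(bad) || anyNA(v))
      stop("non-numeric coordinate in column ", col, " at row ",
           c(bad, which(is.na(v)))[1])
    df[[col]] <- v
  }
  df$soz <- parse_flag(df$soz, "soz")
  df$resected <- parse_flag(df$resected, "resected")
  validate_layout(df[required])
}

parse_flag <- function(x, col) {
  v <- rep(NA, length(x))
  v[x %in% c("TRUE", "True", "true", "1", 1, TRUE)] <- TRUE
  v[x %in% c("FALSE", "False", "false", "0", 0, FALSE)] <- FALSE
  if (anyNA(v))
    stop("cannot parse logical column ", col, " at row ", which(is.na(v))[1])
  v
}

#' @rdname read_layout
#' @param layout An [electrode_layout()] to write.
#' @export
write_layout <- function(layout, path) {
  utils::write.csv(as.data.frame(layout), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read and write adjacency matrices
#'
#' Adjacency matrices are stored as square delimited (CSV) matrices with a
#' header row of contact labels, written at full double precision. Reading
#' validates squareness, symmetry (tolerance `1e-8` relative), nonnegative
#' weights, and a zero diagonal. Band and window metadata round-trip
#' through a JSON sidecar at `<path>.json`.
#'
#' @param path Path to the adjacency CSV.
#' @return [read_adjacency()]: a [functional_network()].
#'   [write_adjacency()]: `path`, invisibly.
#' @export
read_adjacency <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  A <- as.matrix(df)
  if (!is.numeric(A)) stop("adjacency file contains non-numeric entries")
  if (nrow(A) != ncol(A)) stop("adjacency matrix must be square")
  labels <- colnames(A)
  meta <- paste0(path, ".json")
  band <- window <- NULL
  if (file.exists(meta)) {
    side <- jsonlite::read_json(meta, simplifyVector = TRUE)
    if (!is.null(side$band)) band <- as.list(side$band)
    if (!is.null(side$window)) window <- as.numeric(side$window)
  }
  functional_network(A, labels = labels, band = band, window = window,
                     tol = 1e-8)
}

#' @rdname read_adjacency
#' @param net A [functional_network()] to write.
#' @export
write_adjacency <- function(net, path) {
  A <- net$adjacency
  df <- as.data.frame(apply(A, 2, function(x) sprintf("%.17g", x)))
  colnames(df) <- net$labels
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  if (!is.null(net$band) || !is.null(net$window))
    jsonlite::write_json(list(band = net$band, window = net$window),
                         paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA, null = "null")
  invisible(path)
}

#' Read and write recordings
#'
#' Recordings are stored as a delimited matrix (one row per contact, first
#' column the contact label) plus a JSON sidecar `<path>.json` holding the
#' sampling rate.
#'
#' @param path Path to the recording CSV.
#' @return [read_recording()]: a [recording()]. [write_recording()]:
#'   `path`, invisibly.
#' @export
read_recording <- function(path) {
  df <- utils::read.csv(path, header = FALSE, stringsAsFactors = FALSE)
  labels <- as.character(df[[1]])
  samples <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(samples) <- "double"
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  recording(samples, fs = meta$fs, labels = labels)
}

#' @rdname read_recording
#' @param rec A [recording()] to write.
#' @export
write_recording <- function(rec, path) {
  df <- data.frame(label = rec$labels,
                   apply(rec$samples, 2, function(x) sprintf("%.17g", x)))
  utils::write.table(df, path, sep = ",", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(fs = rec$fs), paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Analysis configuration
#'
#' Collects the tunable parameters of the pipeline with their defaults:
#' band (high gamma, 95-105 Hz), 1-s windows, peri-ictal offsets
#' (-10, -5, 0, +5, +10 s), removal fractions (0.2, 0.4, 0.6, 0.8), 1000
#' iterations, filter settings (5-115 Hz elliptic bandpass, 60 Hz notch),
#' AR order 1, optional density thresholding, and the family-wise alpha.
#' Configs round-trip losslessly through YAML (JSON accepted on read).
#'
#' @param ... Overrides of the default fields.
#' @return A named list of class `analysis_config`.
#' @export
analysis_config <- function(...) {
  cfg <- list(band = band_spec("high_gamma"),
              window_len = 1,
              offsets = c(-10, -5, 0, 5, 10),
              fractions = c(0.2, 0.4, 0.6, 0.8),
              n_iter = 1000,
              seed = 0,
              density = NULL,
              filter = list(lo = 5, hi = 115, notch = 60),
              ar_order = 1,
              region_size = 4,
              alpha = 0.05)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop("unknown config field: ", unknown[1])
  cfg[names(over)] <- over
  structure(cfg, class = "analysis_config")
}

#' @rdname analysis_config
#' @param path Path to a YAML (or JSON) config file.
#' @export
read_config <- function(path) {
  raw <- tryCatch(yaml::read_yaml(path),
                  error = function(e)
                    jsonlite::read_json(path, simplifyVector = TRUE))
  do.call(analysis_config, raw)
}

#' @rdname analysis_config
#' @param cfg An `analysis_config` to write.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

config_hash <- function(cfg) {
  # stable short fingerprint for provenance stamping of artifacts
  s <- jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA)
  sum(utf8ToInt(as.character(s)) * seq_len(nchar(s))) %% 100000000L
}
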