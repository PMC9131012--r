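#' EEG recording container
#'
#' Bundles a channels x samples amplitude matrix (microvolts) with its
#' sampling rate, channel labels, optional 3-D electrode positions on the
#' unit sphere, and the list of contiguous artifact-free runs ("segments").
#' A recording with no artifact annotations has a single segment covering
#' all samples.
#'
#' Segments are stored as a two-column integer matrix with 1-based
#' inclusive `start` and exclusive `end` columns, so a segment covers
#' samples `start:(end - 1)`. Segments must be disjoint, sorted and within
#' `[1, n_samples + 1]`.
#'
#' @param data numeric matrix, channels x samples, microvolts.
#' @param fs sampling rate in Hz.
#' @param channels character vector of channel labels; defaults to
#'   `"E01" ...`.
#' @param positions optional n_channels x 3 matrix of unit-norm electrode
#'   coordinates.
#' @param segments optional integer matrix (`start`, `end` columns); default
#'   one segment spanning the whole recording.
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, fs, channels = NULL, positions = NULL,
                          segments = NULL) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  nch <- nrow(data)
  ns <- ncol(data)
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("`fs` must be a positive scalar sampling rate")
  if (is.null(channels)) channels <- sprintf("E%02d", seq_len(nch))
  if (length(channels) != nch)
    stop("structural error: channel label count (", length(channels),
         ") does not match data rows (", nch, ")")
  if (!is.null(positions)) {
    positions <- as.matrix(positions)
    if (nrow(positions) != nch || ncol(positions) != 3L)
      stop("structural error: `positions` must be n_channels x 3")
    nrm <- sqrt(rowSums(positions^2))
    if (any(abs(nrm - 1) > 1e-6))
      stop("`positions` rows must have unit norm (tolerance 1e-6)")
    dimnames(positions) <- NULL
  }
  if (is.null(segments)) segments <- cbind(start = 1L, end = ns + 1L)
  segments <- matrix(as.integer(as.matrix(segments)), ncol = 2L,
                     dimnames = list(NULL, c("start", "end")))
  validate_segments(segments, ns)
  structure(list(data = data, fs = fs, channels = as.character(channels),
                 positions = positions, segments = segments),
            class = "eeg_recording")
}

validate_segments <- function(segments, n_samples) {
  if (nrow(segments) == 0L) stop("at least one segment is required")
  if (any(segments[, "start"] < 1L) || any(segments[, "end"] > n_samples + 1L))
    stop("segment bounds outside [1, n_samples + 1]")
  if (any(segments[, "end"] <= segments[, "start"]))
    stop("segments must be non-empty (end > start)")
  if (nrow(segments) > 1L) {
    o <- order(segments[, "start"])
    s <- segments[o, , drop = FALSE]
    if (any(s[-1L, "start"] < s[-nrow(s), "end"]))
      stop("segments must be disjoint and sorted")
  }
  invisible(segments)
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s), %d segment(s)\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs,
              nrow(x$segments)))
  invisible(x)
}

#' @export
dim.eeg_recording <- function(x) dim(x$data)

n_samples <- function(rec) ncol(rec$data)
n_channels <- function(rec) nrow(rec$data)

#' Sample indices covered by each segment of a recording
#' @param rec an `eeg_recording`.
#' @return list of integer vectors, one per segment.
#' @keywords internal
segment_indices <- function(rec) {
  lapply(seq_len(nrow(rec$segments)), function(i)
    seq.int(rec$segments[i, "start"], rec$segments[i, "end"] - 1L))
}

#' Synthetic electrode montage on the upper unit hemisphere
#'
#' Generates a quasi-uniform Fibonacci-lattice layout of `n` electrodes on
#' the upper half of the unit sphere (a synthetic stand-in for a 10-10
#' cap layout; labels are `"E01" ...`, not anatomical names).
#'
#' @param n number of electrodes.
#' @return list with `positions` (n x 3 unit vectors) and `labels`.
#' @export
synthetic_montage <- function(n) {
  stopifnot(n >= 2)
  i <- seq_len(n) - 0.5
  # z in (0, 1): upper hemisphere only, golden-angle azimuth
  z <- i / n
  phi <- pi * (1 + sqrt(5)) * i
  r <- sqrt(1 - z^2)
  pos <- cbind(r * cos(phi), r * sin(phi), z)
  list(positions = pos, labels = sprintf("E%02d", seq_len(n)))
}

#' Average-reference a recording
#'
#' Subtracts, at every sample, the instantaneous mean across channels, so
#' each column of the result sums to zero. Standard common-average
#' reference applied before microstate analysis.
#'
#' @param rec an `eeg_recording`.
#' @return the re-referenced `eeg_recording`.
#' @export
rereference_average <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (n_channels(rec) < 2L)
    stop("parameter error: average reference requires >= 2 channels")
  rec$data <- sweep(rec$data, 2L, colMeans(rec$data), `-`)
  rec
}
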