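#' Read an EEG recording from disk
#'
#' Dispatches on file type: the package's internal exchange format (a raw
#' little-endian float64 matrix `<stem>.bin` with a JSON sidecar
#' `<stem>.json` holding sampling rate, channel labels, positions and
#' segment table) or 16-bit EDF (European Data Format). Sampling rate and
#' channel order are preserved from the file.
#'
#' @param path path to the `.json` sidecar (internal format) or `.edf` file.
#' @param format_hint optional `"internal"` or `"edf"`; inferred from the
#'   extension when missing.
#' @return an [eeg_recording()].
#' @export
read_recording <- function(path, format_hint = NULL) {
  if (!file.exists(path)) stop("format error: file does not exist: ", path)
  fmt <- format_hint
  if (is.null(fmt)) {
    ext <- tolower(sub(".*\\.", "", basename(path)))
    fmt <- switch(ext, json = "internal", bin = "internal", edf = "edf",
                  stop("format error: cannot infer format from extension '",
                       ext, "'"))
  }
  switch(fmt,
         internal = read_recording_internal(path),
         edf = read_edf(path),
         stop("format error: unknown format '", fmt, "'"))
}

#' Write a recording in the internal matrix + JSON sidecar format
#'
#' @param rec an [eeg_recording()].
#' @param stem output path stem; `<stem>.bin` and `<stem>.json` are written.
#' @return `stem`, invisibly.
#' @export
write_recording <- function(rec, stem) {
  stopifnot(inherits(rec, "eeg_recording"))
  bin <- paste0(stem, ".bin")
  con <- file(bin, "wb")
  on.exit(close(con))
  writeBin(as.vector(rec$data), con, size = 8L, endian = "little")
  meta <- list(n_channels = nrow(rec$data), n_samples = ncol(rec$data),
               fs = rec$fs, channels = rec$channels,
               positions = if (is.null(rec$positions)) NULL else
                 unname(apply(rec$positions, 1L, as.numeric, simplify = FALSE)),
               segments = unname(apply(rec$segments, 1L, as.integer,
                                       simplify = FALSE)))
  jsonlite::write_json(meta, paste0(stem, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(stem)
}

read_recording_internal <- function(path) {
  stem <- sub("\\.(json|bin)$", "", path)
  meta <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  bin <- paste0(stem, ".bin")
  if (!file.exists(bin)) stop("format error: missing data file ", bin)
  n <- meta$n_channels * meta$n_samples
  con <- file(bin, "rb")
  on.exit(close(con))
  x <- readBin(con, "double", n = n, size = 8L, endian = "little")
  if (length(x) != n) stop("format error: truncated data file ", bin)
  data <- matrix(x, nrow = meta$n_channels, ncol = meta$n_samples)
  if (length(meta$channels) != meta$n_channels)
    stop("structural error: channel label count does not match data")
  as_rows <- function(v, ncol_) {
    if (is.matrix(v)) v else matrix(unlist(v), ncol = ncol_, byrow = TRUE)
  }
  eeg_recording(data, fs = as.numeric(meta$fs), channels = meta$channels,
                positions = if (is.null(meta$positions)) NULL else
                  as_rows(meta$positions, 3L),
                segments = as_rows(meta$segments, 2L))
}

pad_field <- function(x, width) {
  s <- substr(as.character(x), 1L, width)
  formatC(s, width = width, flag = "-")
}

#' Write a recording as 16-bit EDF
#'
#' Minimal EDF writer: one data record per second (the duration is padded
#' to a whole number of seconds with zeros), per-channel physical scaling
#' to the full 16-bit digital range. Positions and segment annotations are
#' not representable in plain EDF and are dropped.
#'
#' @param rec an [eeg_recording()]; `fs` must be a positive integer.
#' @param path output `.edf` path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- rec$fs
  if (fs != round(fs)) stop("EDF writer requires an integer sampling rate")
  nch <- n_channels(rec)
  ns <- n_samples(rec)
  nrec <- ceiling(ns / fs)
  x <- matrix(0, nch, nrec * fs)
  x[, seq_len(ns)] <- rec$data
  pmin_ <- apply(x, 1L, min)
  pmax_ <- apply(x, 1L, max)
  flat <- pmax_ - pmin_ < 1e-12
  pmin_[flat] <- pmin_[flat] - 1
  pmax_[flat] <- pmax_[flat] + 1
  dmin <- -32768L; dmax <- 32767L
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad_field("0", 8), pad_field("X X X X", 80), pad_field("X X X", 80),
    pad_field("01.01.00", 8), pad_field("00.00.00", 8),
    pad_field(256L * (1L + nch), 8), pad_field("", 44),
    pad_field(nrec, 8), pad_field("1", 8), pad_field(nch, 4))
  writeChar(hdr, con, eos = NULL)
  writeChar(paste0(vapply(rec$channels, pad_field, "", width = 16),
                   collapse = ""), con, eos = NULL)
  writeChar(strrep(" ", 80 * nch), con, eos = NULL)   # transducer
  writeChar(paste0(rep(pad_field("uV", 8), nch), collapse = ""), con,
            eos = NULL)
  for (v in list(signif(pmin_, 7), signif(pmax_, 7))) {
    writeChar(paste0(vapply(v, pad_field, "", width = 8), collapse = ""),
              con, eos = NULL)
  }
  for (v in list(rep(dmin, nch), rep(dmax, nch))) {
    writeChar(paste0(vapply(v, pad_field, "", width = 8), collapse = ""),
              con, eos = NULL)
  }
  writeChar(strrep(" ", 80 * nch), con, eos = NULL)   # prefiltering
  writeChar(paste0(rep(pad_field(fs, 8), nch), collapse = ""), con,
            eos = NULL)
  writeChar(strrep(" ", 32 * nch), con, eos = NULL)   # reserved
  scale <- (dmax - dmin) / (pmax_ - pmin_)
  for (r in seq_len(nrec)) {
    idx <- ((r - 1L) * fs + 1L):(r * fs)
    dig <- round((x[, idx, drop = FALSE] - pmin_) * scale + dmin)
    writeBin(as.integer(t(dig)), con, size = 2L, endian = "little")
  }
  invisible(path)
}

#' Read a 16-bit EDF file
#'
#' @param path `.edf` path.
#' @return an [eeg_recording()] (positions `NULL`, one segment).
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(nbytes) {
    r <- readChar(con, nbytes, useBytes = TRUE)
    if (nchar(r, type = "bytes") < nbytes)
      stop("format error: truncated EDF header")
    r
  }
  rd(8 + 80 + 80 + 8 + 8)
  nbytes_hdr <- as.integer(trimws(rd(8)))
  rd(44)
  nrec <- as.integer(trimws(rd(8)))
  dur <- as.numeric(trimws(rd(8)))
  nch <- as.integer(trimws(rd(4)))
  if (is.na(nch) || nch < 1L) stop("format error: bad EDF channel count")
  fld <- function(width) {
    raw <- rd(width * nch)
    trimws(substring(raw, (seq_len(nch) - 1L) * width + 1L,
                     seq_len(nch) * width))
  }
  labels <- fld(16); fld(80); fld(8)
  pmin_ <- as.numeric(fld(8)); pmax_ <- as.numeric(fld(8))
  dmin <- as.numeric(fld(8)); dmax <- as.numeric(fld(8))
  fld(80)
  spr <- as.integer(fld(8))
  fld(32)
  if (256L * (1L + nch) != nbytes_hdr)
    warning("EDF header byte count inconsistent; proceeding")
  if (length(unique(spr)) != 1L)
    stop("format error: heterogeneous sampling rates not supported")
  fs <- spr[1L] / dur
  data <- matrix(0, nch, nrec * spr[1L])
  gain <- (pmax_ - pmin_) / (dmax - dmin)
  for (r in seq_len(nrec)) {
    dig <- readBin(con, "integer", n = nch * spr[1L], size = 2L,
                   endian = "little", signed = TRUE)
    if (length(dig) < nch * spr[1L]) stop("format error: truncated EDF data")
    block <- t(matrix(dig, nrow = spr[1L], ncol = nch))
    data[, ((r - 1L) * spr[1L] + 1L):(r * spr[1L])] <-
      (block - dmin) * gain + pmin_
  }
  eeg_recording(data, fs = fs, channels = labels)
}

#' Read a delimited group-metadata table
#'
#' Expects columns `id` and `group`, optionally `time` (e.g. T0/T1) and
#' `score` (a clinical scale such as the 0-34 lower-extremity Fugl-Meyer
#' motor score). Ids must be unique within each time label and scores, when
#' present, must lie in `[score_range[1], score_range[2]]`.
#'
#' @param path delimited text file (tab or comma separated).
#' @param score_range permissible closed range for `score`.
#' @return a `data.frame`.
#' @export
read_group_table <- function(path, score_range = c(0, 34)) {
  if (!file.exists(path)) stop("format error: file does not exist: ", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  if (!all(c("id", "group") %in% names(tab)))
    stop("structural error: group table needs `id` and `group` columns")
  key <- if ("time" %in% names(tab)) paste(tab$id, tab$time) else tab$id
  if (anyDuplicated(key))
    stop("structural error: duplicated id within a time label")
  if ("score" %in% names(tab)) {
    s <- tab$score[!is.na(tab$score)]
    if (any(s < score_range[1] | s > score_range[2]))
      stop("structural error: score outside [", score_range[1], ", ",
           score_range[2], "]")
  }
  tab
}
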