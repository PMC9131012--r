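#' Back-fit microstate templates to a continuous recording
#'
#' Every sample's scalp map is assigned the label of the template with the
#' highest absolute spatial correlation (not only maps at GFP peaks). The
#' full k x n matrix of absolute spatial correlations is kept alongside
#' the labels. Processing is per artifact-free segment, so labels never
#' bridge artifact boundaries. Zero-variance samples inherit the previous
#' sample's class (the first samples of a segment inherit the first valid
#' class) and get zero correlation entries.
#'
#' @param rec an [eeg_recording()], already band-filtered and
#'   average-referenced.
#' @param templates a [template_set()] on the same channels.
#' @return an object of class `ms_sequence`: `labels` (per-sample template
#'   index, `NA` outside segments), `sc` (k x n absolute spatial
#'   correlations), `segments`, `fs`, `k`, `class_labels`.
#' @export
backfit <- function(rec, templates) {
  stopifnot(inherits(rec, "eeg_recording"),
            inherits(templates, "template_set"))
  if (ncol(templates$maps) != n_channels(rec))
    stop("structural error: template channels do not match recording")
  k <- nrow(templates$maps)
  n <- n_samples(rec)
  labels <- rep(NA_integer_, n)
  sc <- matrix(NA_real_, k, n)
  for (idx in segment_indices(rec)) {
    M <- rec$data[, idx, drop = FALSE]
    M <- sweep(M, 2L, colMeans(M), `-`)
    nrm <- sqrt(colSums(M^2))
    bad <- nrm < 1e-12
    nrm[bad] <- 1
    C <- abs(templates$maps %*% sweep(M, 2L, nrm, `/`))
    C[, bad] <- 0
    lab <- max.col(t(C), ties.method = "first")
    if (any(bad)) {
      lab[bad] <- NA_integer_
      # carry previous class over flat samples; backfill a flat prefix
      lab <- fill_forward(lab)
      lab <- rev(fill_forward(rev(lab)))
      if (anyNA(lab)) lab[is.na(lab)] <- 1L   # fully flat segment
    }
    labels[idx] <- lab
    sc[, idx] <- C
  }
  structure(list(labels = labels, sc = sc, segments = rec$segments,
                 fs = rec$fs, k = k, class_labels = templates$labels),
            class = "ms_sequence")
}

#' Build a microstate sequence from known labels
#'
#' Wraps an existing label vector (e.g. simulator ground truth) in an
#' `ms_sequence` so it can drive class-conditional analyses such as
#' [microstate_plv()]. No spatial-correlation series is attached, so the
#' result cannot be smoothed.
#'
#' @param labels integer class labels per sample.
#' @param fs sampling rate (Hz).
#' @param k number of classes (default `max(labels)`).
#' @param segments segment matrix (default one covering segment).
#' @param class_labels class names.
#' @return an `ms_sequence` without `sc`.
#' @export
ms_sequence_from_labels <- function(labels, fs, k = max(labels),
                                    segments = NULL,
                                    class_labels = as.character(seq_len(k))) {
  if (is.null(segments))
    segments <- cbind(start = 1L, end = length(labels) + 1L)
  structure(list(labels = as.integer(labels), sc = NULL,
                 segments = segments, fs = fs, k = as.integer(k),
                 class_labels = class_labels),
            class = "ms_sequence")
}

fill_forward <- function(x) {
  na <- is.na(x)
  if (!any(na)) return(x)
  idx <- cumsum(!na)
  x[na] <- x[!na][idx[na]]
  x
}

#' Run-length segments of a microstate sequence
#'
#' @param seq an `ms_sequence`.
#' @return data frame with `class`, `start` (1-based, inclusive), `end`
#'   (exclusive), `n` (length in samples), `segment` (recording-segment
#'   index) and `truncated` (`TRUE` for the first and last run of each
#'   recording segment, whose true extent is unknowable).
#' @export
sequence_runs <- function(seq) {
  stopifnot(inherits(seq, "ms_sequence"))
  out <- list()
  for (si in seq_len(nrow(seq$segments))) {
    a <- seq$segments[si, "start"]; b <- seq$segments[si, "end"] - 1L
    l <- seq$labels[a:b]
    r <- rle(l)
    ends <- a - 1L + cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    tr <- rep(FALSE, length(r$lengths))
    tr[1L] <- TRUE
    tr[length(tr)] <- TRUE
    out[[si]] <- data.frame(class = r$values, start = starts,
                            end = ends + 1L, n = r$lengths, segment = si,
                            truncated = tr)
  }
  do.call(rbind, out)
}

#' Temporal smoothing of a microstate sequence
#'
#' Iteratively relabels every run shorter than `min_ms` milliseconds: each
#' of its samples moves to the class with the highest spatial correlation
#' among the classes other than the rejected one. Repeats until no short
#' run remains or the iteration cap is hit, in which case remaining short
#' runs are merged into their longer neighbour (with a warning).
#'
#' @param seq an `ms_sequence` (with `sc` present).
#' @param min_ms minimum segment duration in milliseconds.
#' @param max_iter iteration cap.
#' @return the smoothed `ms_sequence`.
#' @export
smooth_sequence <- function(seq, min_ms = 30, max_iter = 100L) {
  stopifnot(inherits(seq, "ms_sequence"), !is.null(seq$sc))
  if (seq$k < 2L) return(seq)
  for (si in seq_len(nrow(seq$segments))) {
    a <- seq$segments[si, "start"]; b <- seq$segments[si, "end"] - 1L
    l <- seq$labels[a:b]
    sc <- seq$sc[, a:b, drop = FALSE]
    seq$labels[a:b] <- smooth_labels_segment(l, sc, min_ms, seq$fs,
                                             max_iter)
  }
  seq
}

smooth_labels_segment <- function(l, sc, min_ms, fs, max_iter) {
  min_samples_excl <- min_ms * fs / 1000   # run is short iff n < this
  k <- nrow(sc)
  short_of <- function(l) {
    r <- rle(l)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    i <- which(r$lengths < min_samples_excl - 1e-9)
    list(starts = starts[i], ends = ends[i], class = r$values[i],
         all_runs = r, all_starts = starts, all_ends = ends)
  }
  # phase 1: monotone relabelling. A sample in a rejected short run
  # permanently excludes that run's class and moves to its next most
  # likely remaining class; every sample can reject at most k - 1
  # classes, so this terminates.
  avail <- matrix(TRUE, k, length(l))
  for (it in seq_len(max_iter)) {
    s <- short_of(l)
    if (!length(s$starts)) return(l)
    if (length(s$all_runs$lengths) == 1L) return(l)
    progressed <- FALSE
    for (j in seq_along(s$starts)) {
      idx <- s$starts[j]:s$ends[j]
      rejected <- s$class[j]
      ok <- avail[rejected, idx]
      if (!any(ok)) next
      avail[rejected, idx] <- FALSE
      open <- colSums(avail[, idx, drop = FALSE]) > 0
      if (!any(open)) next
      sub <- sc[, idx, drop = FALSE]
      sub[!avail[, idx, drop = FALSE]] <- -Inf
      l[idx[open]] <- max.col(t(sub[, open, drop = FALSE]),
                              ties.method = "first")
      progressed <- TRUE
    }
    if (!progressed) break
  }
  # phase 2: merge any leftover short runs into the longer neighbour
  repeat {
    s <- short_of(l)
    if (!length(s$starts) || length(s$all_runs$lengths) == 1L) break
    j <- which.min(s$ends - s$starts)
    ri <- match(s$starts[j], s$all_starts)
    r <- s$all_runs
    left_n <- if (ri > 1L) r$lengths[ri - 1L] else -1L
    right_n <- if (ri < length(r$lengths)) r$lengths[ri + 1L] else -1L
    neigh <- if (left_n >= right_n) r$values[ri - 1L] else r$values[ri + 1L]
    l[s$starts[j]:s$ends[j]] <- neigh
  }
  l
}

#' Spatial correlation metric between templates and labelled maps
#'
#' `SC[X, Y]` is the mean absolute spatial correlation of template `X`
#' with all maps labelled class `Y` (non-truncated samples). The diagonal
#' measures within-class fit quality; the matrix is not symmetric.
#'
#' @param seq a smoothed `ms_sequence`.
#' @return k x k matrix (rows: templates, columns: classes); columns of
#'   empty classes are `NA`.
#' @export
spatial_correlation_matrix <- function(seq) {
  stopifnot(inherits(seq, "ms_sequence"))
  runs <- sequence_runs(seq)
  keep <- runs[!runs$truncated, , drop = FALSE]
  k <- seq$k
  SC <- matrix(NA_real_, k, k,
               dimnames = list(seq$class_labels, seq$class_labels))
  idx_of <- function(rr) unlist(mapply(seq.int, rr$start, rr$end - 1L,
                                       SIMPLIFY = FALSE))
  for (y in seq_len(k)) {
    rr <- keep[keep$class == y, , drop = FALSE]
    if (!nrow(rr)) next
    SC[, y] <- rowMeans(seq$sc[, idx_of(rr), drop = FALSE])
  }
  SC
}

#' Transition probabilities, observed minus expected
#'
#' Observed `TP[x, y]` is the fraction of transitions out of class `x`
#' that land in class `y`, counted over consecutive non-truncated runs
#' within each segment. Expected `TP[x, y]` is the share of class-`y` run
#' counts among all classes other than `x` (`n_y / sum_{z != x} n_z`).
#' The reported matrix is observed minus expected: zero diagonal, rows
#' summing to zero.
#'
#' @param seq a smoothed `ms_sequence`.
#' @return k x k matrix; rows of classes with no outgoing transition are
#'   `NA`.
#' @export
transition_probabilities <- function(seq) {
  stopifnot(inherits(seq, "ms_sequence"))
  runs <- sequence_runs(seq)
  keep <- runs[!runs$truncated, , drop = FALSE]
  if (nrow(keep) < 2L)
    stop("need at least 2 non-truncated segments for transitions")
  k <- seq$k
  obs <- matrix(0, k, k)
  nruns <- tabulate(keep$class, nbins = k)
  for (si in unique(keep$segment)) {
    cl <- keep$class[keep$segment == si]
    if (length(cl) < 2L) next
    for (i in seq_len(length(cl) - 1L))
      obs[cl[i], cl[i + 1L]] <- obs[cl[i], cl[i + 1L]] + 1L
  }
  out_deg <- rowSums(obs)
  expd <- matrix(0, k, k)
  for (x in seq_len(k)) {
    others <- setdiff(seq_len(k), x)
    tot <- sum(nruns[others])
    if (tot > 0) expd[x, others] <- nruns[others] / tot
  }
  obs_p <- obs / ifelse(out_deg > 0, out_deg, 1)
  tp <- obs_p - expd
  diag(tp) <- 0
  tp[out_deg == 0, ] <- NA_real_
  dimnames(tp) <- list(seq$class_labels, seq$class_labels)
  tp
}

#' Microstate parameter suite for one recording
#'
#' Computes, per microstate class, the global explained variance (%),
#' mean duration (ms), occurrence (1/s), coverage (%), mean interval
#' (ms), and mean GFP (microvolts), plus the spatial-correlation and
#' transition-probability matrices. The first and last run of every
#' artifact-free segment are potentially truncated and are excluded from
#' all per-class aggregation; coverage is renormalised over the remaining
#' samples, so it sums to 100%.
#'
#' @param seq a smoothed `ms_sequence`.
#' @param rec the [eeg_recording()] the sequence was fitted on (for GFP).
#' @return object of class `ms_params`: list with `table` (one row per
#'   class), `sc`, `tp`, and `analysis_time_s`.
#' @export
compute_parameters <- function(seq, rec) {
  stopifnot(inherits(seq, "ms_sequence"), inherits(rec, "eeg_recording"))
  gfp <- global_field_power(rec)$values
  runs <- sequence_runs(seq)
  keep <- runs[!runs$truncated, , drop = FALSE]
  k <- seq$k
  fs <- seq$fs
  total_samples <- sum(keep$n)
  total_time <- total_samples / fs
  if (total_samples == 0L)
    stop("no non-truncated segments; recording too short for parameters")
  keep_idx <- unlist(mapply(seq.int, keep$start, keep$end - 1L,
                            SIMPLIFY = FALSE))
  gfp_keep <- gfp[keep_idx]
  lab_keep <- seq$labels[keep_idx]
  corr_keep <- seq$sc[cbind(lab_keep, keep_idx)]
  gev_den <- sum(gfp_keep^2)
  tab <- data.frame(class = seq$class_labels,
                    gev = NA_real_, mean_duration = NA_real_,
                    occurrence = 0, coverage = 0,
                    mean_interval = NA_real_, mean_gfp = NA_real_,
                    stringsAsFactors = FALSE)
  for (x in seq_len(k)) {
    rr <- keep[keep$class == x, , drop = FALSE]
    in_class <- lab_keep == x
    tab$gev[x] <- if (gev_den > 0)
      100 * sum((gfp_keep[in_class] * corr_keep[in_class])^2) / gev_den
      else NA_real_
    if (nrow(rr)) {
      tab$mean_duration[x] <- mean(rr$n) * 1000 / fs
      tab$occurrence[x] <- nrow(rr) / total_time
      tab$coverage[x] <- 100 * sum(rr$n) / total_samples
      tab$mean_gfp[x] <- mean(gfp_keep[in_class])
      gaps <- numeric(0)
      for (si in unique(rr$segment)) {
        rs <- rr[rr$segment == si, , drop = FALSE]
        if (nrow(rs) > 1L)
          gaps <- c(gaps, (rs$start[-1L] - rs$end[-nrow(rs)]) * 1000 / fs)
      }
      if (length(gaps)) tab$mean_interval[x] <- mean(gaps)
    }
  }
  tp <- tryCatch(transition_probabilities(seq), error = function(e) NULL)
  structure(list(table = tab, sc = spatial_correlation_matrix(seq),
                 tp = tp, analysis_time_s = total_time),
            class = "ms_params")
}

#' @export
print.ms_params <- function(x, ...) {
  cat(sprintf("<ms_params> %.1f s analysed\n", x$analysis_time_s))
  print(x$table, digits = 3)
  invisible(x)
}
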