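legendre_terms <- function(x, n_terms) {
  # list of P_1(x) .. P_n(x) by the three-term recursion, elementwise
  out <- vector("list", n_terms)
  Pm1 <- array(1, dim = dim(x))   # P_0
  P <- x                          # P_1
  out[[1L]] <- P
  if (n_terms > 1L) {
    for (n in 2L:n_terms) {
      Pn <- ((2 * n - 1) * x * P - (n - 1) * Pm1) / n
      out[[n]] <- Pn
      Pm1 <- P
      P <- Pn
    }
  }
  out
}

#' Spherical-spline surface Laplacian (current source density)
#'
#' Estimates the scalp current source density by interpolating each
#' sample's potential map with spherical splines of order `spline_order`
#' and applying the negative surface Laplacian analytically, term by term
#' in the Legendre expansion. The transform is linear in the input; a
#' spatially constant map yields zero output, and a spherical harmonic of
#' degree `n` is an eigenmap with eigenvalue `n(n+1)` (unit-sphere
#' radius).
#'
#' @param rec an [eeg_recording()] with electrode `positions`.
#' @param spline_order spline flexibility `m` (Legendre penalty exponent).
#' @param n_legendre number of Legendre terms in the expansion.
#' @param lambda_reg Tikhonov smoothing added to the spline system.
#' @return the transformed `eeg_recording` (CSD units, per unit-sphere
#'   radius squared).
#' @export
surface_laplacian <- function(rec, spline_order = 4L, n_legendre = 50L,
                              lambda_reg = 1e-5) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (is.null(rec$positions))
    stop("electrode positions are required for the surface Laplacian")
  cosang <- rec$positions %*% t(rec$positions)
  cosang <- pmin(pmax(cosang, -1), 1)
  P <- legendre_terms(cosang, n_legendre)
  nch <- n_channels(rec)
  G <- matrix(0, nch, nch)
  H <- matrix(0, nch, nch)
  for (n in seq_len(n_legendre)) {
    G <- G + (2 * n + 1) / (n * (n + 1))^spline_order * P[[n]]
    H <- H + (2 * n + 1) / (n * (n + 1))^(spline_order - 1) * P[[n]]
  }
  G <- G / (4 * pi)
  H <- H / (4 * pi)
  Gs <- G + diag(lambda_reg, nch)
  Gsinv <- tryCatch(solve(Gs), error = function(e)
    stop("numerical error: degenerate electrode geometry (", e$message, ")"))
  TC <- rowSums(Gsinv)
  sgi <- sum(TC)
  Cp <- Gsinv %*% rec$data              # nch x n
  c0 <- colSums(Cp) / sgi
  Cc <- Cp - outer(TC, c0)
  rec$data <- H %*% Cc
  rec
}

fft_analytic <- function(x) {
  # analytic signal of each column of x via the frequency-domain mask
  m <- nrow(x)
  h <- numeric(m)
  if (m %% 2 == 0) {
    h[c(1L, m / 2 + 1L)] <- 1
    h[2L:(m / 2)] <- 2
  } else {
    h[1L] <- 1
    h[2L:((m + 1L) / 2)] <- 2
  }
  stats::mvfft(stats::mvfft(x) * h, inverse = TRUE) / m
}

#' Instantaneous phase of a band-limited recording
#'
#' Band-filters each artifact-free segment (zero phase), forms the
#' analytic signal per segment by the Hilbert transform, and takes its
#' argument. The first and last `edge_discard` fraction of every segment
#' is masked out of the validity index to protect against filter and
#' Hilbert edge effects (`floor` per side); segments shorter than three
#' cycles of the band's low edge carry no usable narrow-band phase and
#' are dropped with a warning.
#'
#' @param rec an [eeg_recording()] (typically after [surface_laplacian()]).
#' @param band two-element band in Hz (default alpha, 8-12).
#' @param edge_discard fraction masked per side of each segment.
#' @return object of class `phase_series`: `phase` (channels x samples,
#'   radians in `(-pi, pi]`, `NA` where undefined), `valid` (logical per
#'   sample), `fs`, `segments`.
#' @export
analytic_phase <- function(rec, band = c(8, 12), edge_discard = 0.10) {
  stopifnot(inherits(rec, "eeg_recording"),
            edge_discard >= 0, edge_discard < 0.5)
  nyq <- rec$fs / 2
  if (!(band[1L] > 0 && band[1L] < band[2L] && band[2L] < nyq))
    stop("parameter error: band must satisfy 0 < low < high < fs/2")
  flt <- signal::butter(4L, band / nyq, type = "pass")
  n <- n_samples(rec)
  min_len <- ceiling(3 * rec$fs / band[1L])   # three low-edge cycles
  phase <- matrix(NA_real_, n_channels(rec), n)
  valid <- rep(FALSE, n)
  for (idx in segment_indices(rec)) {
    len <- length(idx)
    drop_n <- floor(edge_discard * len)
    if (len < min_len) {
      warning("segment of ", len,
              " samples too short for narrow-band phase; dropped")
      next
    }
    seg <- t(apply(rec$data[, idx, drop = FALSE], 1L, function(ch)
      signal::filtfilt(flt, ch)))
    an <- fft_analytic(t(seg))
    phase[, idx] <- t(Arg(an))
    keep <- idx[(drop_n + 1L):(len - drop_n)]
    valid[keep] <- TRUE
  }
  structure(list(phase = phase, valid = valid, fs = rec$fs,
                 segments = rec$segments),
            class = "phase_series")
}

#' Microstate-specific phase-locking value matrices
#'
#' For every microstate class the valid samples carrying that label are
#' gathered (concatenated across segments — PLV uses only per-sample
#' phase differences, so no spurious jumps arise) and
#' `PLV(i, j) = |mean over those samples of exp(1i * (phi_j - phi_i))|`
#' is computed for all channel pairs. Matrices are exactly symmetric with
#' unit diagonal; classes with fewer than `n_min` valid samples are
#' flagged unreliable.
#'
#' @param phases a `phase_series` from [analytic_phase()].
#' @param seq an `ms_sequence` sample-aligned with `phases` (its labels
#'   may come from a differently filtered copy of the same recording).
#' @param n_min minimum sample count per class before flagging.
#' @return object of class `conn_stack`: `plv` (list of channels x
#'   channels matrices per class), `n` (sample counts), `flagged`.
#' @export
microstate_plv <- function(phases, seq, n_min = 250L) {
  stopifnot(inherits(phases, "phase_series"), inherits(seq, "ms_sequence"))
  if (ncol(phases$phase) != length(seq$labels))
    stop("structural error: phases and labels are not sample-aligned")
  k <- seq$k
  nch <- nrow(phases$phase)
  plv <- vector("list", k)
  nn <- integer(k)
  for (m in seq_len(k)) {
    idx <- which(phases$valid & !is.na(seq$labels) & seq$labels == m)
    nn[m] <- length(idx)
    if (!length(idx)) {
      plv[[m]] <- matrix(NA_real_, nch, nch)
      next
    }
    Z <- exp(1i * phases$phase[, idx, drop = FALSE])
    M <- Mod(Z %*% Conj(t(Z))) / length(idx)
    M <- (M + t(M)) / 2
    diag(M) <- 1
    plv[[m]] <- M
  }
  names(plv) <- seq$class_labels
  structure(list(plv = plv, n = stats::setNames(nn, seq$class_labels),
                 flagged = nn < n_min, class_labels = seq$class_labels),
            class = "conn_stack")
}

#' @export
print.conn_stack <- function(x, ...) {
  cat("<conn_stack> classes:", paste(x$class_labels, collapse = " "),
      "| samples:", paste(x$n, collapse = " "),
      if (any(x$flagged)) "| some classes flagged unreliable" else "", "\n")
  invisible(x)
}
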