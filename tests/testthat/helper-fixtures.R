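# shared fixture builders (all data generated in code)

# k mutually orthogonal zero-mean unit-norm maps on nch channels
orthogonal_maps <- function(nch, k, seed = 1) {
  set.seed(seed)
  M <- matrix(rnorm(nch * (k + 1)), nch)
  M <- sweep(M, 2, colMeans(M))
  Q <- qr.Q(qr(M))
  Q <- sweep(Q, 2, colMeans(Q))            # re-centre
  Q <- qr.Q(qr(Q))[, seq_len(k), drop = FALSE]
  out <- t(Q)
  out <- out - rowMeans(out)
  out / sqrt(rowSums(out^2))
}

# recording whose GFP equals |g|: two channels (g, -g)
recording_with_gfp <- function(g, fs = 250, segments = NULL) {
  eeg_recording(rbind(g, -g), fs = fs, segments = segments)
}

# plain template playback: data = t(maps[labels, ]), optional gain per sample
playback_recording <- function(tpl, labels, fs = 250, gain = NULL) {
  x <- t(tpl$maps[labels, , drop = FALSE])
  if (!is.null(gain)) x <- sweep(x, 2, gain, `*`)
  eeg_recording(x, fs = fs)
}

# symmetric matrix stack with iid N(mu, sd) edges, unit diagonal
random_conn_stack <- function(n_subj, nch, mu = 0, sd = 0.1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  replicate(n_subj, {
    m <- matrix(rnorm(nch * nch, mu, sd), nch)
    m <- (m + t(m)) / 2
    diag(m) <- 1
    m
  }, simplify = FALSE)
}

# per-subject alpha-band PLV matrix from the common-carrier phase model
phase_model_plv <- function(nch, n_samples, kappa) {
  psi <- cumsum(2 * pi * 10 / 250 + rnorm(n_samples, 0, 2 * pi * 0.5 / 250))
  ph <- vapply(seq_len(nch), function(ch) psi + rvonmises(n_samples, kappa),
               numeric(n_samples))
  Z <- exp(1i * t(ph))
  M <- Mod(Z %*% Conj(t(Z))) / n_samples
  M <- (M + t(M)) / 2
  diag(M) <- 1
  M
}

edge_key <- function(e) paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]),
                              sep = "-")
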