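#' Draw from a von Mises distribution centred at zero
#'
#' Best-Fisher rejection sampler, vectorised; `kappa = 0` falls back to the
#' uniform circle and very large concentrations (`kappa > 1400`) to the
#' wrapped-normal limit `N(0, 1/kappa)`.
#'
#' @param n number of draws.
#' @param kappa concentration parameter, `>= 0` (may be `Inf`).
#' @return numeric vector of angles in `(-pi, pi]`.
#' @export
rvonmises <- function(n, kappa) {
  stopifnot(length(kappa) == 1L, kappa >= 0)
  if (n == 0L) return(numeric(0))
  if (is.infinite(kappa)) return(rep(0, n))
  if (kappa == 0) return(stats::runif(n, -pi, pi))
  if (kappa > 1400) return(wrap_angle(stats::rnorm(n, 0, 1 / sqrt(kappa))))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need) > 0L) {
    m <- length(need)
    u1 <- stats::runif(m); u2 <- stats::runif(m); u3 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    if (any(ok)) {
      theta <- sign(u3[ok] - 0.5) * acos(f[ok])
      out[need[ok]] <- theta
      need <- need[!ok]
    }
  }
  wrap_angle(out)
}

#' Wrap angles to (-pi, pi]
#' @param x numeric vector of angles in radians.
#' @return wrapped angles.
#' @export
wrap_angle <- function(x) {
  w <- x %% (2 * pi)
  w[w > pi] <- w[w > pi] - 2 * pi
  w
}

#' Mean resultant length of a von Mises distribution
#'
#' `I1(kappa)/I0(kappa)`; the squared value is the theoretical
#' phase-locking value of two phases sharing a common drive with
#' independent von Mises jitters of this concentration.
#'
#' @param kappa concentration (vectorised; `Inf` gives 1).
#' @return mean resultant length in `[0, 1]`.
#' @export
bessel_ratio <- function(kappa) {
  out <- ifelse(is.infinite(kappa), 1,
                ifelse(kappa == 0, 0,
                       besselI(pmin(kappa, 1e6), 1, expon.scaled = TRUE) /
                         besselI(pmin(kappa, 1e6), 0, expon.scaled = TRUE)))
  out
}

#' Theoretical PLV of a von Mises coupled channel pair
#' @param kappa concentration of the per-channel jitters.
#' @return `(I1(kappa)/I0(kappa))^2`.
#' @export
plv_vonmises <- function(kappa) bessel_ratio(kappa)^2

#' Generate well-separated dipolar scalp templates
#'
#' Each template is the field of a random dipole axis in an idealised
#' spherical head: the cosine of the angle between each electrode position
#' and the axis, then average-referenced (zero mean) and normalised to unit
#' norm. Candidates are retried until all pairwise absolute spatial
#' correlations are `<= 1 - min_separation`. For `min_separation = 1`
#' candidates are orthogonalised exactly (Gram-Schmidt in the
#' zero-mean space).
#'
#' @param n_channels number of electrodes.
#' @param k number of templates (`>= 2`).
#' @param min_separation required separation in `(0, 1]`.
#' @param seed RNG seed.
#' @param positions optional electrode positions; default
#'   [synthetic_montage()].
#' @param max_retries bounded retry budget per template.
#' @return a [template_set()] with integer labels.
#' @export
generate_templates <- function(n_channels, k, min_separation = 0.5,
                               seed = NULL, positions = NULL,
                               max_retries = 500L) {
  stopifnot(k >= 2, min_separation > 0, min_separation <= 1)
  if (k > n_channels - 1L)
    stop("generation error: at most n_channels - 1 zero-mean templates exist")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(positions)) positions <- synthetic_montage(n_channels)$positions
  exact <- min_separation >= 1 - 1e-12
  # whiten the dipole-axis metric: with axes drawn as W u (u uniform on
  # the sphere, W the inverse square root of the demeaned-position Gram
  # matrix) the correlation between two dipole maps equals the plain
  # cosine between their u directions, so separation constraints are
  # geometrically honest even on a hemisphere-only montage
  Pd <- sweep(positions, 2L, colMeans(positions))
  eg <- eigen(crossprod(Pd), symmetric = TRUE)
  W <- eg$vectors %*% diag(1 / sqrt(pmax(eg$values, 1e-12))) %*%
    t(eg$vectors)
  for (attempt in seq_len(30L)) {
  maps <- matrix(0, k, n_channels)
  failed <- FALSE
  for (i in seq_len(k)) {
    ok <- FALSE
    for (try in seq_len(max_retries)) {
      u <- stats::rnorm(3)
      ax <- as.vector(W %*% (u / sqrt(sum(u^2))))
      m <- as.vector(positions %*% ax)
      m <- m - mean(m)
      if (exact && i > 1L) {
        prev <- maps[seq_len(i - 1L), , drop = FALSE]
        m <- m - as.vector(t(prev) %*% (prev %*% m))
        # dipole fields span a 3-D space; beyond it, orthogonalise a
        # random (non-dipolar) map instead
        if (sqrt(sum(m^2)) < 1e-8) {
          m <- stats::rnorm(n_channels)
          m <- m - mean(m)
          m <- m - as.vector(t(prev) %*% (prev %*% m))
        }
        m <- m - mean(m)
      }
      nm <- sqrt(sum(m^2))
      if (nm < 1e-8) next
      m <- m / nm
      if (i == 1L ||
          max(abs(maps[seq_len(i - 1L), , drop = FALSE] %*% m)) <=
            (1 - min_separation) + 1e-12) {
        maps[i, ] <- m
        ok <- TRUE
        break
      }
    }
    if (!ok) {   # greedy dead end: restart the whole set
      failed <- TRUE
      break
    }
  }
  if (!failed) return(template_set(maps, labels = as.character(seq_len(k))))
  }
  # greedy sampling cannot reach tight line packings in 3-D (three
  # near-orthogonal axes leave no room for a fourth at >= 60 degrees);
  # fall back to a randomly rotated icosahedral axis frame, whose six
  # lines are pairwise at |cos| = 1/sqrt(5) ~ 0.447
  if (k <= 6L && (1 - min_separation) >= 1 / sqrt(5) - 1e-9) {
    phi <- (1 + sqrt(5)) / 2
    ico <- rbind(c(0, 1, phi), c(0, 1, -phi), c(1, phi, 0),
                 c(1, -phi, 0), c(phi, 0, 1), c(-phi, 0, 1))
    ico <- ico / sqrt(rowSums(ico^2))
    qrr <- qr(matrix(stats::rnorm(9), 3))
    R <- qr.Q(qrr)
    if (det(R) < 0) R[, 1L] <- -R[, 1L]
    maps <- matrix(0, k, n_channels)
    for (i in seq_len(k)) {
      ax <- as.vector(W %*% (R %*% ico[i, ]))
      m <- as.vector(positions %*% ax)
      m <- m - mean(m)
      maps[i, ] <- m / sqrt(sum(m^2))
    }
    return(template_set(maps, labels = as.character(seq_len(k))))
  }
  stop("generation error: could not reach separation ", min_separation,
       " within the retry budget")
}

#' Configuration for the semi-Markov microstate EEG simulator
#'
#' The defaults emulate the reference eyes-closed resting-state setting:
#' 59 channels at 250 Hz, five quasi-stable topographic states with
#' gamma-distributed dwell times of mean 100 ms (shape 4, scale 25 ms)
#' riding on a 10 Hz alpha carrier at a signal-to-noise ratio of 2.
#'
#' @param n_channels,fs,duration geometry: channel count, sampling rate
#'   (Hz), duration (s).
#' @param k_states number of planted states.
#' @param templates optional [template_set()] of planted maps (generated
#'   dipolar maps when `NULL`).
#' @param min_separation separation for generated templates.
#' @param dwell_shape,dwell_scale_ms gamma dwell-time parameters
#'   (mean = shape * scale, ms).
#' @param transition k x k state transition matrix; rows sum to 1, zero
#'   diagonal. Default uniform over the other states.
#' @param carrier_hz alpha-band carrier frequency.
#' @param carrier_jitter_hz standard deviation of the random-walk frequency
#'   jitter of the common carrier phase.
#' @param snr ratio of state-signal RMS to noise RMS (`> 0`).
#' @param kappa von Mises concentration of per-channel phase jitter around
#'   the common carrier: a scalar, or a k_states x n_channels matrix for
#'   state-specific coupling. `Inf` (default) means all channels ride the
#'   carrier exactly.
#' @param seed RNG seed.
#' @return a validated `simulation_config` list.
#' @export
simulation_config <- function(n_channels = 59L, fs = 250, duration = 60,
                              k_states = 5L, templates = NULL,
                              min_separation = 0.5,
                              dwell_shape = 4, dwell_scale_ms = 25,
                              transition = NULL, carrier_hz = 10,
                              carrier_jitter_hz = 0.5, snr = 2,
                              kappa = Inf, seed = 1L) {
  stopifnot(n_channels >= 2, fs > 0, duration > 0, k_states >= 2,
            dwell_shape > 0, dwell_scale_ms > 0, snr > 0,
            carrier_hz > 0, carrier_hz < fs / 2)
  if (is.null(transition)) {
    transition <- matrix(1 / (k_states - 1), k_states, k_states)
    diag(transition) <- 0
  }
  transition <- as.matrix(transition)
  if (any(dim(transition) != k_states))
    stop("transition matrix must be k_states x k_states")
  if (any(abs(rowSums(transition) - 1) > 1e-9))
    stop("transition rows must sum to 1 (tolerance 1e-9)")
  if (any(abs(diag(transition)) > 1e-12))
    stop("transition diagonal must be zero")
  if (length(kappa) == 1L) {
    kappa <- matrix(kappa, k_states, n_channels)
  } else {
    kappa <- as.matrix(kappa)
    if (nrow(kappa) != k_states || ncol(kappa) != n_channels)
      stop("kappa must be scalar or k_states x n_channels")
  }
  if (any(kappa < 0)) stop("kappa must be >= 0")
  structure(list(n_channels = as.integer(n_channels), fs = fs,
                 duration = duration, k_states = as.integer(k_states),
                 templates = templates, min_separation = min_separation,
                 dwell_shape = dwell_shape, dwell_scale_ms = dwell_scale_ms,
                 transition = transition, carrier_hz = carrier_hz,
                 carrier_jitter_hz = carrier_jitter_hz, snr = snr,
                 kappa = kappa, seed = as.integer(seed)),
            class = "simulation_config")
}

simulate_state_labels <- function(cfg, n) {
  k <- cfg$k_states
  labels <- integer(n)
  state <- sample.int(k, 1L)
  t0 <- 1L
  while (t0 <= n) {
    dwell_ms <- stats::rgamma(1L, shape = cfg$dwell_shape,
                              scale = cfg$dwell_scale_ms)
    len <- max(1L, as.integer(round(dwell_ms / 1000 * cfg$fs)))
    t1 <- min(n, t0 + len - 1L)
    labels[t0:t1] <- state
    state <- sample.int(k, 1L, prob = cfg$transition[state, ])
    t0 <- t1 + 1L
  }
  labels
}

#' Simulate EEG with planted microstate dynamics
#'
#' State labels follow a semi-Markov chain with gamma dwell times; the
#' signal at each sample is the active template scaled by an alpha-band
#' carrier (`sqrt(2) * cos(phase)`), with per-channel von Mises phase
#' jitter when `kappa` is finite; spatially white Gaussian noise is added
#' at the configured SNR (signal RMS / noise RMS).
#'
#' @param cfg a [simulation_config()].
#' @return list with `recording` (an [eeg_recording()] with positions) and
#'   `truth` (per-sample labels, planted [template_set()], kappa matrix,
#'   and per-state theoretical PLV matrices).
#' @export
generate_microstate_eeg <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(cfg$seed)
  mont <- synthetic_montage(cfg$n_channels)
  tpl <- cfg$templates
  if (is.null(tpl)) {
    tpl <- generate_templates(cfg$n_channels, cfg$k_states,
                              min_separation = cfg$min_separation,
                              positions = mont$positions)
  }
  stopifnot(ncol(tpl$maps) == cfg$n_channels,
            nrow(tpl$maps) == cfg$k_states)
  n <- as.integer(round(cfg$duration * cfg$fs))
  labels <- simulate_state_labels(cfg, n)
  dphi <- 2 * pi * cfg$carrier_hz / cfg$fs +
    stats::rnorm(n, 0, 2 * pi * cfg$carrier_jitter_hz / cfg$fs)
  psi <- cumsum(dphi)
  nch <- cfg$n_channels
  phase <- matrix(psi, nch, n, byrow = TRUE)
  if (any(is.finite(cfg$kappa))) {
    for (s in seq_len(cfg$k_states)) {
      at <- which(labels == s)
      if (!length(at)) next
      for (ch in seq_len(nch)) {
        kap <- cfg$kappa[s, ch]
        if (is.finite(kap))
          phase[ch, at] <- phase[ch, at] + rvonmises(length(at), kap)
      }
    }
  }
  amp <- tpl$maps[labels, , drop = FALSE]   # n x nch
  sig <- t(amp) * sqrt(2) * cos(phase)
  rms <- sqrt(mean(sig^2))
  noise <- matrix(stats::rnorm(nch * n, sd = rms / cfg$snr), nch, n)
  data <- (sig + noise) * 20   # microvolt-like scale
  plv_targets <- lapply(seq_len(cfg$k_states), function(s) {
    r <- bessel_ratio(cfg$kappa[s, ])
    m <- outer(r, r)
    diag(m) <- 1
    m
  })
  rec <- eeg_recording(data, fs = cfg$fs, channels = mont$labels,
                       positions = mont$positions)
  list(recording = rec,
       truth = list(labels = labels, templates = tpl, kappa = cfg$kappa,
                    plv_targets = plv_targets))
}

#' Generate a pair of von Mises coupled phase series
#'
#' Both series share a common random-walk carrier phase and receive
#' independent von Mises(0, kappa) jitters, so their theoretical PLV is
#' `(I1(kappa)/I0(kappa))^2` ([plv_vonmises()]).
#'
#' @param n_samples series length.
#' @param kappa jitter concentration (`>= 0`).
#' @param seed RNG seed.
#' @param fs,carrier_hz carrier parameters of the common phase.
#' @return 2 x n matrix of wrapped phases in `(-pi, pi]`.
#' @export
generate_coupled_phases <- function(n_samples, kappa, seed = NULL,
                                    fs = 250, carrier_hz = 10) {
  stopifnot(kappa >= 0)
  if (!is.null(seed)) set.seed(seed)
  psi <- cumsum(2 * pi * carrier_hz / fs +
                  stats::rnorm(n_samples, 0, 2 * pi * 0.5 / fs))
  rbind(wrap_angle(psi + rvonmises(n_samples, kappa)),
        wrap_angle(psi + rvonmises(n_samples, kappa)))
}

#' Simulate a two-group cohort with a planted connectivity effect
#'
#' Group "B" has the von Mises coupling concentration raised by `effect`
#' on every channel incident to the planted edge set, during the
#' designated state; everything else is identical in distribution. With
#' `effect = 0` the groups are exchangeable.
#'
#' @param cfg a [simulation_config()] (shared by all subjects; per-subject
#'   seeds are derived from `seed`).
#' @param n_per_group subjects per group.
#' @param planted_edges 2-column matrix of channel index pairs.
#' @param effect added concentration on planted channels (`>= 0`).
#' @param seed cohort-level seed.
#' @param target_state state carrying the planted effect.
#' @return list with `recordings`, `truth` (per subject), a `groups`
#'   data frame (`id`, `group`), and the planted design.
#' @export
generate_cohort <- function(cfg, n_per_group, planted_edges, effect,
                            seed = 1L, target_state = 1L) {
  stopifnot(inherits(cfg, "simulation_config"), effect >= 0,
            n_per_group >= 2)
  planted_edges <- matrix(as.integer(as.matrix(planted_edges)), ncol = 2L)
  if (any(planted_edges < 1L) || any(planted_edges > cfg$n_channels) ||
      any(planted_edges[, 1L] == planted_edges[, 2L]))
    stop("planted_edges must be valid distinct channel pairs")
  set.seed(seed)
  subj_seeds <- sample.int(.Machine$integer.max - 1L, 2L * n_per_group)
  kappa_b <- cfg$kappa
  planted_channels <- sort(unique(as.vector(planted_edges)))
  base <- kappa_b[target_state, planted_channels]
  kappa_b[target_state, planted_channels] <-
    ifelse(is.finite(base), base + effect, base)
  grp <- rep(c("A", "B"), each = n_per_group)
  ids <- sprintf("S%02d", seq_along(grp))
  recs <- vector("list", length(grp))
  truths <- vector("list", length(grp))
  for (i in seq_along(grp)) {
    cfg_i <- cfg
    cfg_i$seed <- subj_seeds[i]
    if (grp[i] == "B") cfg_i$kappa <- kappa_b
    sim <- generate_microstate_eeg(cfg_i)
    recs[[i]] <- sim$recording
    truths[[i]] <- sim$truth
  }
  names(recs) <- names(truths) <- ids
  list(recordings = recs, truth = truths,
       groups = data.frame(id = ids, group = grp,
                           stringsAsFactors = FALSE),
       planted_edges = planted_edges, effect = effect,
       target_state = as.integer(target_state),
       null_cohort = effect == 0)
}
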