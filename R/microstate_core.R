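#' Set of microstate template maps
#'
#' `k` topographic maps stored as rows of a k x channels matrix; every row
#' is average-referenced (zero mean) and unit norm. Polarity is a
#' non-identifiable gauge: negating any row does not change its meaning,
#' and all comparisons in the package use absolute spatial correlation.
#'
#' @param maps k x channels numeric matrix.
#' @param labels character class labels (e.g. `"A" ... "E"` after ordering).
#' @param gev_train fraction of variance explained on the maps the set was
#'   fitted to, if known.
#' @return an object of class `template_set`.
#' @export
template_set <- function(maps, labels = NULL, gev_train = NA_real_) {
  maps <- as.matrix(maps)
  maps <- maps - rowMeans(maps)
  nrm <- sqrt(rowSums(maps^2))
  if (any(nrm < 1e-12)) stop("template maps must be non-constant")
  maps <- maps / nrm
  if (is.null(labels)) labels <- as.character(seq_len(nrow(maps)))
  stopifnot(length(labels) == nrow(maps))
  structure(list(maps = maps, labels = as.character(labels),
                 gev_train = gev_train),
            class = "template_set")
}

#' @export
print.template_set <- function(x, ...) {
  cat(sprintf("<template_set> k = %d, %d channels, labels: %s",
              nrow(x$maps), ncol(x$maps),
              paste(x$labels, collapse = " ")))
  if (!is.na(x$gev_train)) cat(sprintf(", GEV(train) = %.3f", x$gev_train))
  cat("\n")
  invisible(x)
}

#' Pearson spatial correlation between two scalp maps
#'
#' Correlation across channels of the two average-referenced maps; the
#' microstate convention "ignoring polarity" corresponds to taking the
#' absolute value of this quantity.
#'
#' @param a,b numeric channel vectors.
#' @return correlation in `[-1, 1]`.
#' @export
spatial_correlation <- function(a, b) {
  a <- a - mean(a); b <- b - mean(b)
  den <- sqrt(sum(a^2) * sum(b^2))
  if (den < 1e-300) return(NA_real_)
  sum(a * b) / den
}

# rows of X demeaned and unit-normalised; zero-variance rows -> NA rows
normalize_rows <- function(X) {
  X <- X - rowMeans(X)
  nrm <- sqrt(rowSums(X^2))
  bad <- nrm < 1e-12
  nrm[bad] <- 1
  A <- X / nrm
  A[bad, ] <- NA_real_
  list(A = A, norm = nrm, bad = bad)
}

#' Global field power of a recording
#'
#' Per-sample population standard deviation (divisor `n_channels`) of the
#' channel amplitudes — the instantaneous strength of the scalp field.
#'
#' @param rec an [eeg_recording()].
#' @return an object of class `gfp_series`: list of `values`
#'   (non-negative, one per sample), `fs`, and the recording's `segments`.
#' @export
global_field_power <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (n_channels(rec) < 2L) stop("parameter error: need >= 2 channels")
  mu <- colMeans(rec$data)
  v <- colMeans(rec$data^2) - mu^2
  structure(list(values = sqrt(pmax(v, 0)), fs = rec$fs,
                 segments = rec$segments),
            class = "gfp_series")
}

#' Extract filtered GFP peaks
#'
#' Finds strict interior local maxima of the GFP within each artifact-free
#' segment, removes the `floor(discard_fraction * n)` lowest peaks by GFP
#' value (maps at low field power carry unreliable topographies), and then
#' removes outlier peaks whose GFP exceeds the all-sample GFP mean by more
#' than `sd_multiple` standard deviations of the all-sample GFP. (GFP is a
#' non-negative quantity with a substantial mean, so the outlier guard is
#' centred; a threshold at `sd_multiple * SD` from zero would discard the
#' bulk of genuine peaks.)
#'
#' @param gfp a `gfp_series` from [global_field_power()].
#' @param discard_fraction fraction of lowest peaks to drop, in `[0, 1)`.
#' @param sd_multiple outlier threshold multiplier (`> 0`).
#' @return strictly increasing integer sample indices (possibly empty,
#'   with a warning).
#' @export
extract_gfp_peaks <- function(gfp, discard_fraction = 0.15,
                              sd_multiple = 3) {
  stopifnot(inherits(gfp, "gfp_series"),
            discard_fraction >= 0, discard_fraction < 1, sd_multiple > 0)
  g <- gfp$values
  peaks <- integer(0)
  for (i in seq_len(nrow(gfp$segments))) {
    a <- gfp$segments[i, "start"]; b <- gfp$segments[i, "end"] - 1L
    if (b - a < 2L) next
    idx <- (a + 1L):(b - 1L)
    is_pk <- g[idx] > g[idx - 1L] & g[idx] > g[idx + 1L]
    peaks <- c(peaks, idx[is_pk])
  }
  if (!length(peaks)) {
    warning("no GFP peaks found")
    return(integer(0))
  }
  n_drop <- floor(discard_fraction * length(peaks))
  if (n_drop > 0L) {
    keep <- order(g[peaks])[-seq_len(n_drop)]
    peaks <- sort(peaks[keep])
  }
  thr <- mean(g) + sd_multiple * stats::sd(g)
  peaks <- peaks[g[peaks] <= thr]
  if (!length(peaks)) warning("all GFP peaks filtered out")
  peaks
}

# dominant eigenvector of S (symmetric psd), warm-started power iteration
dominant_eigvec <- function(S, v0 = NULL, tol = 1e-12, max_iter = 200L) {
  p <- ncol(S)
  v <- if (is.null(v0)) S[, which.max(diag(S))] else v0
  nv <- sqrt(sum(v^2))
  if (nv < 1e-300) v <- stats::rnorm(p) else v <- v / nv
  for (i in seq_len(max_iter)) {
    w <- as.vector(S %*% v)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-300) return(v)
    w <- w / nw
    if (1 - abs(sum(w * v)) < tol) return(w)
    v <- w
  }
  v
}

#' Global explained variance of a template assignment
#'
#' `GEV = sum_t (GFP_t * C_t)^2 / sum_t GFP_t^2`, where `C_t` is the
#' spatial correlation between map `t` and its assigned template. The
#' fraction of GFP-weighted topographic variance the templates explain.
#'
#' @param maps n x channels matrix of scalp maps.
#' @param gfp numeric GFP value per map.
#' @param templates a [template_set()].
#' @param labels integer template index per map (`NA` maps are skipped).
#' @return fraction in `[0, 1]`.
#' @export
gev <- function(maps, gfp, templates, labels) {
  stopifnot(inherits(templates, "template_set"),
            nrow(maps) == length(gfp), length(labels) == length(gfp))
  den <- sum(gfp^2)
  if (den < 1e-300) stop("undefined: total GFP is zero")
  nm <- normalize_rows(as.matrix(maps))
  ok <- !nm$bad & !is.na(labels)
  if (!any(ok)) return(0)
  C <- rowSums(nm$A[ok, , drop = FALSE] *
                 templates$maps[labels[ok], , drop = FALSE])
  sum((gfp[ok] * C)^2) / den
}

#' Polarity-invariant modified k-means clustering of scalp maps
#'
#' Each map is assigned to the template with the largest absolute spatial
#' correlation; each template is updated to the dominant eigenvector of
#' its cluster's map covariance (a sign-invariant "mean" direction). The
#' procedure restarts `n_repeats` times from random map initialisations
#' and returns the run with the largest global explained variance.
#'
#' @param maps n x channels matrix of maps (e.g. maps at GFP peaks).
#' @param k number of clusters (`1 <= k <= n`).
#' @param n_repeats random restarts.
#' @param max_iter iterations per restart.
#' @param tol convergence tolerance on GEV change.
#' @param seed RNG seed (restarts consume the stream deterministically).
#' @return a [template_set()] with `gev_train` set; attributes
#'   `assignments` (best-run cluster index per map) and `dispersion`
#'   (within-cluster sum of squared sign-aligned distances, for
#'   model-order selection).
#' @export
modified_kmeans <- function(maps, k, n_repeats = 100L, max_iter = 100L,
                            tol = 1e-8, seed = NULL) {
  maps <- as.matrix(maps)
  n <- nrow(maps)
  if (k > n) stop("parameter error: k (", k, ") exceeds number of maps (",
                  n, ")")
  stopifnot(k >= 1)
  if (!is.null(seed)) set.seed(seed)
  mu <- rowMeans(maps)
  v <- rowMeans(maps^2) - mu^2
  gfp_m <- sqrt(pmax(v, 0))
  nm <- normalize_rows(maps)
  if (any(nm$bad)) stop("constant (zero-variance) maps cannot be clustered")
  A <- nm$A
  den <- sum(gfp_m^2)
  best <- NULL
  for (rep_i in seq_len(n_repeats)) {
    Tm <- A[sample.int(n, k), , drop = FALSE]
    assign_prev <- integer(0)
    for (it in seq_len(max_iter)) {
      C <- A %*% t(Tm)                       # n x k signed correlations
      aC <- abs(C)
      assign <- max.col(aC, ties.method = "first")
      # empty clusters: re-seed from the worst-explained map
      fit <- aC[cbind(seq_len(n), assign)]
      for (j in seq_len(k)) {
        if (!any(assign == j)) {
          w <- which.min(fit)
          assign[w] <- j
          fit[w] <- 1
        }
      }
      for (j in seq_len(k)) {
        Aj <- A[assign == j, , drop = FALSE]
        S <- crossprod(Aj)
        Tm[j, ] <- dominant_eigvec(S, v0 = Tm[j, ])
      }
      if (identical(assign, assign_prev)) break
      assign_prev <- assign
    }
    C <- A %*% t(Tm)
    aC <- abs(C)
    assign <- max.col(aC, ties.method = "first")
    fit <- aC[cbind(seq_len(n), assign)]
    g <- sum((gfp_m * fit)^2) / den
    if (is.null(best) || g > best$gev + 1e-15) {
      best <- list(Tm = Tm, assign = assign, gev = g,
                   W = sum(2 - 2 * fit))
    }
  }
  out <- template_set(best$Tm, gev_train = best$gev)
  attr(out, "assignments") <- best$assign
  attr(out, "dispersion") <- best$W
  out
}

#' Cluster GFP-peak maps over a range of model orders
#'
#' Runs [modified_kmeans()] for every `k` in `ks` (and computes the k = 1
#' dispersion, needed by the Krzanowski-Lai differences) on the same map
#' matrix, optionally subsampled to at most `max_maps` maps.
#'
#' @param maps n x channels matrix of maps.
#' @param ks contiguous integer range of cluster counts (default `2:10`).
#' @param max_maps subsample cap on the number of maps used.
#' @inheritParams modified_kmeans
#' @return object of class `cluster_run`: list with `ks`, `sets`
#'   (templates per k), `gev` and `W` curves (the `W` vector also carries
#'   a leading k = 1 entry), and `n_maps`.
#' @export
cluster_templates <- function(maps, ks = 2:10, n_repeats = 100L,
                              max_iter = 100L, tol = 1e-8, seed = NULL,
                              max_maps = Inf) {
  maps <- as.matrix(maps)
  stopifnot(all(diff(ks) == 1L), min(ks) >= 2L)
  if (!is.null(seed)) set.seed(seed)
  if (nrow(maps) > max_maps)
    maps <- maps[sort(sample.int(nrow(maps), max_maps)), , drop = FALSE]
  # k = 1: dominant eigenvector of the full normalized-map covariance
  nm <- normalize_rows(maps)
  S <- crossprod(nm$A)
  t1 <- dominant_eigvec(S)
  fit1 <- abs(as.vector(nm$A %*% t1))
  W <- c(sum(2 - 2 * fit1))
  sets <- vector("list", length(ks))
  gevs <- numeric(length(ks))
  for (i in seq_along(ks)) {
    sets[[i]] <- modified_kmeans(maps, ks[i], n_repeats = n_repeats,
                                 max_iter = max_iter, tol = tol)
    gevs[i] <- sets[[i]]$gev_train
    W <- c(W, attr(sets[[i]], "dispersion"))
  }
  structure(list(ks = ks, sets = sets, gev = gevs,
                 W = stats::setNames(W, c(1L, ks)), n_maps = nrow(maps)),
            class = "cluster_run")
}

#' Krzanowski-Lai model-order selection
#'
#' From within-cluster dispersion curves `W(k)`,
#' `DIFF(k) = (k-1)^(2/p) W(k-1) - k^(2/p) W(k)` and
#' `KL(k) = |DIFF(k) / DIFF(k+1)|`. Each recording's KL curve is
#' normalised by its own maximum, the normalised curves are averaged
#' across recordings, and the `k` with the largest mean is returned
#' (interior `k` only; ties break to the smallest `k`).
#'
#' @param W numeric vector (one recording) or recordings x k matrix of
#'   dispersions, with column names giving the (contiguous) k values.
#' @param p dimensionality exponent (channel count).
#' @param ks k value of each column when `W` has no names.
#' @return selected `k*` (integer); the mean normalised KL curve is
#'   attached as attribute `"kl"`.
#' @export
select_k_kl <- function(W, p, ks = NULL) {
  if (is.vector(W)) W <- matrix(W, nrow = 1L,
                                dimnames = list(NULL, names(W)))
  if (is.null(ks)) ks <- as.integer(colnames(W))
  stopifnot(length(ks) == ncol(W), all(diff(ks) == 1L))
  if (length(ks) < 3L)
    stop("parameter error: need at least 3 contiguous k values")
  # DIFF defined for columns 2..m, KL for columns 2..(m-1)
  m <- length(ks)
  kk <- matrix(ks, nrow(W), m, byrow = TRUE)
  pen <- kk^(2 / p) * W
  DIFF <- pen[, -m, drop = FALSE] - pen[, -1L, drop = FALSE]  # at ks[2..m]
  KL <- abs(DIFF[, -ncol(DIFF), drop = FALSE] /
              DIFF[, -1L, drop = FALSE])                      # ks[2..m-1]
  KL[!is.finite(KL)] <- 0
  kl_ks <- ks[2:(m - 1L)]
  mx <- apply(KL, 1L, max)
  mx[mx < 1e-300] <- 1
  KLn <- KL / mx
  mean_kl <- colMeans(KLn)
  k_star <- kl_ks[which.max(mean_kl)]   # which.max ties -> first = smallest k
  attr(k_star, "kl") <- stats::setNames(mean_kl, kl_ks)
  k_star
}

#' Group-level microstate templates
#'
#' Concatenates the k* recording-specific templates of every recording
#' (equal contribution per participant) and re-clusters them with the
#' modified k-means into k* group templates.
#'
#' @param per_recording list of [template_set()]s, each with exactly
#'   `k_star` maps; canonicalised by name order when named.
#' @param k_star group-level model order.
#' @param seed RNG seed.
#' @param n_repeats restarts for the re-clustering.
#' @return a [template_set()].
#' @export
group_templates <- function(per_recording, k_star, seed = NULL,
                            n_repeats = 100L) {
  stopifnot(length(per_recording) >= 1L)
  if (!is.null(names(per_recording)))
    per_recording <- per_recording[order(names(per_recording))]
  kk <- vapply(per_recording, function(s) nrow(s$maps), integer(1))
  if (any(kk != k_star))
    stop("parameter error: every recording must provide exactly k* = ",
         k_star, " templates")
  pooled <- do.call(rbind, lapply(per_recording, function(s) s$maps))
  modified_kmeans(pooled, k_star, n_repeats = n_repeats, seed = seed)
}

#' Common microstate templates across two groups
#'
#' Pools the two group-level template sets (2k maps) and clusters them
#' into k common templates with the modified k-means, removing systematic
#' between-group template differences from downstream back-fitting.
#'
#' @param group_a,group_b [template_set()]s with the same k and channels.
#' @param seed RNG seed.
#' @param n_repeats restarts.
#' @return a [template_set()].
#' @export
common_templates <- function(group_a, group_b, seed = NULL,
                             n_repeats = 100L) {
  if (ncol(group_a$maps) != ncol(group_b$maps))
    stop("structural error: channel spaces differ")
  if (nrow(group_a$maps) != nrow(group_b$maps))
    stop("parameter error: both groups must have the same k")
  pooled <- rbind(group_a$maps, group_b$maps)
  modified_kmeans(pooled, nrow(group_a$maps), n_repeats = n_repeats,
                  seed = seed)
}

# exact best one-to-one assignment of rows to columns maximizing sum(S),
# DFS with an upper bound; ties resolved toward earlier column indices
best_assignment <- function(S) {
  k <- nrow(S); r <- ncol(S)
  if (k > 8L) stop("assignment supported for k <= 8")
  best_val <- -Inf
  best_asg <- integer(k)
  rowmax <- apply(S, 1L, max)
  dfs <- function(row, used, val, asg) {
    if (row > k) {
      if (val > best_val + 1e-15) {
        best_val <<- val
        best_asg <<- asg
      }
      return()
    }
    if (val + sum(rowmax[row:k]) <= best_val + 1e-15) return()
    for (j in seq_len(r)) {
      if (!used[j]) {
        used[j] <- TRUE
        asg[row] <- j
        dfs(row + 1L, used, val + S[row, j], asg)
        used[j] <- FALSE
      }
    }
  }
  dfs(1L, logical(r), 0, integer(k))
  best_asg
}

#' Order and label templates against a reference set
#'
#' Finds the one-to-one matching between templates and reference maps that
#' maximises the total absolute spatial correlation (exact assignment),
#' reorders the templates to the reference order, takes labels from the
#' matched reference rows, and flips the sign of each template so it
#' correlates positively with its reference.
#'
#' @param templates a [template_set()] with k maps.
#' @param reference a [template_set()] with `>= k` maps (e.g. canonical
#'   A-E maps, or planted ground-truth maps).
#' @return a relabelled, sign-aligned [template_set()]; the matched
#'   absolute correlations are attached as attribute `"match_corr"`.
#' @export
order_templates <- function(templates, reference) {
  stopifnot(inherits(templates, "template_set"),
            inherits(reference, "template_set"))
  if (ncol(templates$maps) != ncol(reference$maps))
    stop("structural error: channel spaces differ")
  if (nrow(reference$maps) < nrow(templates$maps))
    stop("reference must have at least as many maps as `templates`")
  C <- templates$maps %*% t(reference$maps)   # signed correlations
  asg <- best_assignment(abs(C))
  ord <- order(asg)
  maps <- templates$maps[ord, , drop = FALSE]
  signs <- sign(C[cbind(seq_len(nrow(C)), asg)])[ord]
  signs[signs == 0] <- 1
  maps <- maps * signs
  out <- template_set(maps, labels = reference$labels[sort(asg)],
                      gev_train = templates$gev_train)
  attr(out, "match_corr") <- abs(C[cbind(seq_len(nrow(C)), asg)])[ord]
  out
}
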