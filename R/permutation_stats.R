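#' Design specification for edge-wise permutation testing
#'
#' @param kind `"two_sample"` (shuffle group labels), `"paired"` (random
#'   sign flips of per-subject differences), or `"correlation"` (shuffle
#'   the score order).
#' @param p_thr edge-forming threshold applied to the parametric p map,
#'   in `(0, 1)`.
#' @param n_perm number of permutations (`>= 1`).
#' @param seed RNG seed.
#' @return a `design_spec` list.
#' @export
design_spec <- function(kind = c("two_sample", "paired", "correlation"),
                        p_thr = 0.001, n_perm = 2000L, seed = 1L) {
  kind <- match.arg(kind)
  stopifnot(p_thr > 0, p_thr < 1, n_perm >= 1)
  structure(list(kind = kind, p_thr = p_thr, n_perm = as.integer(n_perm),
                 seed = as.integer(seed)),
            class = "design_spec")
}

# flatten a list / 3D array of symmetric matrices to subjects x edges
stack_to_edges <- function(stack) {
  if (is.array(stack) && length(dim(stack)) == 3L)
    stack <- lapply(seq_len(dim(stack)[3L]), function(i) stack[, , i])
  nch <- nrow(stack[[1L]])
  lt <- which(lower.tri(matrix(0, nch, nch)), arr.ind = TRUE)
  E <- vapply(stack, function(m) m[lower.tri(m)], numeric(nrow(lt)))
  E <- if (nrow(lt) == 1L) matrix(E, ncol = 1L) else t(E)
  list(E = E, pairs = lt[, c(2L, 1L), drop = FALSE], nch = nch)
}

edges_to_matrix <- function(v, pairs, nch) {
  M <- matrix(NA_real_, nch, nch)
  M[cbind(pairs[, 1L], pairs[, 2L])] <- v
  M[cbind(pairs[, 2L], pairs[, 1L])] <- v
  M
}

t_two_sample <- function(E, g1) {
  # pooled-variance t per column; g1 logical group-1 indicator
  n1 <- sum(g1); n2 <- sum(!g1)
  X1 <- E[g1, , drop = FALSE]; X2 <- E[!g1, , drop = FALSE]
  m1 <- colMeans(X1); m2 <- colMeans(X2)
  ss1 <- colSums(X1^2) - n1 * m1^2
  ss2 <- colSums(X2^2) - n2 * m2^2
  sp2 <- (ss1 + ss2) / (n1 + n2 - 2)
  (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
}

t_paired_from_diff <- function(D) {
  n <- nrow(D)
  m <- colMeans(D)
  s2 <- (colSums(D^2) - n * m^2) / (n - 1)
  m / sqrt(s2 / n)
}

r_correlation <- function(E, s) {
  n <- nrow(E)
  sc <- (s - mean(s))
  sd_s <- sqrt(sum(sc^2))
  m <- colMeans(E)
  num <- as.vector(crossprod(E, sc))
  den <- sqrt(colSums(E^2) - n * m^2) * sd_s
  num / den
}

#' Edge-wise statistic and p-value maps
#'
#' Computes, for every channel pair, the pooled-variance two-sample t,
#' the paired t (on per-subject condition differences), or the Pearson r
#' against a covariate, with the corresponding parametric two-sided
#' p-value. Zero-variance edges get `NA` and are excluded from
#' thresholding.
#'
#' @param x list or channels x channels x subjects array of symmetric
#'   connectivity matrices (group 1 / condition 1).
#' @param y second group / condition (two-sample and paired designs).
#' @param design a [design_spec()].
#' @param scores numeric covariate (correlation design).
#' @return list with symmetric `stat` and `p` matrices and `df`.
#' @export
edge_statistics <- function(x, design, y = NULL, scores = NULL) {
  sx <- stack_to_edges(x)
  res <- switch(design$kind,
    two_sample = {
      sy <- stack_to_edges(y)
      if (nrow(sx$E) < 2L || nrow(sy$E) < 2L)
        stop("need >= 2 subjects per group")
      E <- rbind(sx$E, sy$E)
      g1 <- c(rep(TRUE, nrow(sx$E)), rep(FALSE, nrow(sy$E)))
      st <- t_two_sample(E, g1)
      df <- nrow(E) - 2L
      list(st = st, p = 2 * stats::pt(-abs(st), df), df = df)
    },
    paired = {
      sy <- stack_to_edges(y)
      if (nrow(sx$E) != nrow(sy$E)) stop("paired design needs equal n")
      if (nrow(sx$E) < 2L) stop("need >= 2 pairs")
      D <- sx$E - sy$E
      st <- t_paired_from_diff(D)
      df <- nrow(D) - 1L
      list(st = st, p = 2 * stats::pt(-abs(st), df), df = df)
    },
    correlation = {
      if (nrow(sx$E) < 3L) stop("need >= 3 subjects")
      if (length(scores) != nrow(sx$E)) stop("scores length mismatch")
      st <- r_correlation(sx$E, scores)
      df <- nrow(sx$E) - 2L
      tt <- st * sqrt(df / (1 - st^2))
      list(st = st, p = 2 * stats::pt(-abs(tt), df), df = df)
    })
  st <- res$st
  p <- res$p
  bad <- !is.finite(st)
  st[bad] <- NA_real_
  p[bad] <- NA_real_
  list(stat = edges_to_matrix(st, sx$pairs, sx$nch),
       p = edges_to_matrix(p, sx$pairs, sx$nch), df = res$df)
}

# connected components of an undirected edge list via union-find
uf_components <- function(pairs) {
  nodes <- unique(as.vector(pairs))
  parent <- stats::setNames(seq_along(nodes), nodes)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  a <- match(pairs[, 1L], nodes)
  b <- match(pairs[, 2L], nodes)
  for (e in seq_len(nrow(pairs))) {
    ra <- find(a[e]); rb <- find(b[e])
    if (ra != rb) parent[rb] <- ra
  }
  vapply(a, find, integer(1))   # component id per edge
}

components_of_sign <- function(stat_v, pairs, keep, positive) {
  sel <- which(keep & if (positive) stat_v > 0 else stat_v < 0)
  if (!length(sel)) return(list())
  comp <- uf_components(pairs[sel, , drop = FALSE])
  lapply(split(sel, comp), function(ix)
    list(sign = if (positive) 1 else -1,
         edges = pairs[ix, , drop = FALSE],
         size = sum(stat_v[ix])))
}

#' Signed suprathreshold connected components
#'
#' Keeps edges with `p < p_thr`, splits them by the sign of the
#' statistic, and finds connected components on the electrode graph for
#' each sign separately. A component's size is the sum of its edges'
#' statistic values.
#'
#' @param stat,p symmetric statistic and p-value matrices.
#' @param p_thr edge-forming threshold.
#' @return list with `positive` and `negative` component lists; each
#'   component holds `sign`, `edges` (2-column channel-index matrix) and
#'   `size`.
#' @export
signed_components <- function(stat, p, p_thr) {
  stopifnot(all(dim(stat) == dim(p)))
  nch <- nrow(stat)
  lt <- which(lower.tri(stat), arr.ind = TRUE)
  pairs <- lt[, c(2L, 1L), drop = FALSE]
  stat_v <- stat[lower.tri(stat)]
  p_v <- p[lower.tri(p)]
  keep <- !is.na(p_v) & !is.na(stat_v) & p_v < p_thr
  list(positive = unname(components_of_sign(stat_v, pairs, keep, TRUE)),
       negative = unname(components_of_sign(stat_v, pairs, keep, FALSE)))
}

max_component_sizes <- function(stat_v, pairs, keep) {
  pos <- components_of_sign(stat_v, pairs, keep, TRUE)
  neg <- components_of_sign(stat_v, pairs, keep, FALSE)
  c(pos = if (length(pos)) max(vapply(pos, `[[`, 0, "size")) else 0,
    neg = if (length(neg)) min(vapply(neg, `[[`, 0, "size")) else 0)
}

# all permutations of 1..n (n small), for exact enumeration
permutations_all <- function(n) {
  if (n == 1L) return(matrix(1L))
  sub <- permutations_all(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i)
    cbind(i, matrix(setdiff(seq_len(n), i)[sub], nrow(sub)))))
}

#' Signed network-based-statistic permutation test
#'
#' Family-wise-error control for mass-univariate edge tests: edge
#' statistic and p maps are thresholded at `p_thr`, connected components
#' are formed separately for positive and negative edges, and each
#' observed component's size (sum of its statistic values) is referred to
#' the permutation null of the largest same-sign component size. The
#' component p-value is `(2 * #\{|S_null| > |s_obs|\} + 1) / (N + 1)`,
#' clamped at 1. When the permutation space is smaller than `n_perm` it
#' is enumerated exactly instead.
#'
#' @inheritParams edge_statistics
#' @return list of components, each with `sign`, `edges`, `size`,
#'   `p`, plus attributes `null_pos`/`null_neg` (the stored null
#'   distributions) and `n_perm`.
#' @export
nbs_test <- function(x, design, y = NULL, scores = NULL) {
  set.seed(design$seed)
  sx <- stack_to_edges(x)
  pairs <- sx$pairs
  kind <- design$kind
  if (kind %in% c("two_sample", "paired")) {
    sy <- stack_to_edges(y)
  }
  if (kind == "two_sample") {
    E <- rbind(sx$E, sy$E)
    n1 <- nrow(sx$E); n <- nrow(E)
    df <- n - 2L
    tcrit <- stats::qt(1 - design$p_thr / 2, df)
    stat_fun <- function(idx1) {
      g <- rep(FALSE, n); g[idx1] <- TRUE
      t_two_sample(E, g)
    }
    obs_v <- stat_fun(seq_len(n1))
    n_space <- choose(n, n1)
    exact <- n_space <= design$n_perm
    draws <- if (exact) utils::combn(n, n1, simplify = FALSE)
             else replicate(design$n_perm, sample.int(n, n1),
                            simplify = FALSE)
  } else if (kind == "paired") {
    if (nrow(sx$E) != nrow(sy$E)) stop("paired design needs equal n")
    D <- sx$E - sy$E
    n <- nrow(D)
    df <- n - 1L
    tcrit <- stats::qt(1 - design$p_thr / 2, df)
    stat_fun <- function(sgn) t_paired_from_diff(D * sgn)
    obs_v <- stat_fun(rep(1, n))
    n_space <- 2^n
    exact <- n_space <= design$n_perm
    draws <- if (exact) {
      g <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
      lapply(seq_len(nrow(g)), function(i) g[i, ])
    } else replicate(design$n_perm, sample(c(-1, 1), n, replace = TRUE),
                     simplify = FALSE)
  } else {
    n <- nrow(sx$E)
    if (length(scores) != n) stop("scores length mismatch")
    df <- n - 2L
    tc <- stats::qt(1 - design$p_thr / 2, df)
    tcrit <- sqrt(tc^2 / (df + tc^2))   # critical |r|
    stat_fun <- function(ord) r_correlation(sx$E, scores[ord])
    obs_v <- stat_fun(seq_len(n))
    n_space <- factorial(n)
    exact <- is.finite(n_space) && n_space <= design$n_perm
    draws <- if (exact) {
      pm <- permutations_all(n)
      lapply(seq_len(nrow(pm)), function(i) pm[i, ])
    } else replicate(design$n_perm, sample.int(n), simplify = FALSE)
  }
  if (exact)
    message("permutation space (", length(draws),
            ") smaller than n_perm; enumerating exactly")
  keep_obs <- is.finite(obs_v) & abs(obs_v) > tcrit
  obs <- c(components_of_sign(obs_v, pairs, keep_obs, TRUE),
           components_of_sign(obs_v, pairs, keep_obs, FALSE))
  N <- length(draws)
  null_pos <- numeric(N)
  null_neg <- numeric(N)
  for (i in seq_len(N)) {
    v <- stat_fun(draws[[i]])
    keep <- is.finite(v) & abs(v) > tcrit
    mx <- max_component_sizes(v, pairs, keep)
    null_pos[i] <- mx["pos"]
    null_neg[i] <- mx["neg"]
  }
  res <- lapply(obs, function(comp) {
    nullv <- if (comp$sign > 0) null_pos else null_neg
    count <- sum(abs(nullv) > abs(comp$size))
    comp$p <- min(1, (2 * count + 1) / (N + 1))
    class(comp) <- "nbs_component"
    comp
  })
  res <- unname(res[order(vapply(res, `[[`, 0, "p"))])
  attr(res, "null_pos") <- null_pos
  attr(res, "null_neg") <- null_neg
  attr(res, "n_perm") <- N
  res
}

#' Mean connectivity strength within a connected component
#'
#' The scalar subject-level feature "mean FCSCC": the arithmetic mean of
#' a subject's connectivity values over the edges of a component.
#'
#' @param mat symmetric connectivity matrix for one subject (or a
#'   `conn_stack` with `class` naming the matrix to use).
#' @param component an `nbs_component` (or any list with an `edges`
#'   matrix).
#' @param class class label when `mat` is a `conn_stack`.
#' @return scalar mean.
#' @export
mean_fcscc <- function(mat, component, class = NULL) {
  if (inherits(mat, "conn_stack")) {
    stopifnot(!is.null(class))
    mat <- mat$plv[[class]]
  }
  e <- component$edges
  if (is.null(e) || nrow(e) == 0L) stop("empty component")
  if (max(e) > nrow(mat)) stop("component edges exceed channel space")
  mean(mat[e])
}

perm_p_two_sided <- function(null_stats, observed) {
  c_hi <- sum(null_stats > observed)
  c_lo <- sum(null_stats < observed)
  min(1, (2 * min(c_hi, c_lo) + 1) / (length(null_stats) + 1))
}

#' Scalar permutation test (two-sample or paired t)
#'
#' Two-sided permutation p-value on the t statistic, using the smaller
#' tail count: `p = (2 * min(tails) + 1) / (N + 1)`, never zero, with
#' floor `1/(N + 1)`.
#'
#' @param x,y numeric samples (for `paired = TRUE`, matched vectors).
#' @param paired paired design (sign-flip permutations) or two-sample
#'   (label shuffles).
#' @param n_perm permutation count.
#' @param seed RNG seed.
#' @return list with `statistic` (t) and `p.value`.
#' @export
permutation_test_scalar <- function(x, y, paired = FALSE,
                                    n_perm = 100000L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (paired) {
    d <- x - y
    n <- length(d)
    if (stats::sd(d) < 1e-300) {
      warning("constant differences; p = 1")
      return(list(statistic = 0, p.value = 1))
    }
    tobs <- mean(d) / (stats::sd(d) / sqrt(n))
    tnull <- vapply(seq_len(n_perm), function(i) {
      ds <- d * sample(c(-1, 1), n, replace = TRUE)
      mean(ds) / (stats::sd(ds) / sqrt(n))
    }, numeric(1))
    return(list(statistic = tobs, p.value = perm_p_two_sided(tnull, tobs)))
  }
  z <- c(x, y)
  n1 <- length(x); n <- length(z)
  if (stats::sd(z) < 1e-300) {
    warning("constant data; p = 1")
    return(list(statistic = 0, p.value = 1))
  }
  tstat <- function(idx1) {
    g <- rep(FALSE, n); g[idx1] <- TRUE
    t_two_sample(matrix(z, ncol = 1L), g)
  }
  tobs <- tstat(seq_len(n1))
  tnull <- vapply(seq_len(n_perm), function(i) tstat(sample.int(n, n1)),
                  numeric(1))
  list(statistic = tobs, p.value = perm_p_two_sided(tnull, tobs))
}

#' Permutation test for a Pearson correlation
#'
#' Shuffles the order of the scores; the same two-sided smaller-tail
#' p-value convention as [permutation_test_scalar()].
#'
#' @param features,scores numeric vectors (`n >= 3`).
#' @param n_perm permutation count.
#' @param seed RNG seed.
#' @return list with `estimate` (r) and `p.value`.
#' @export
permutation_correlation <- function(features, scores, n_perm = 100000L,
                                    seed = NULL) {
  stopifnot(length(features) == length(scores), length(features) >= 3L)
  if (!is.null(seed)) set.seed(seed)
  if (stats::sd(features) < 1e-300 || stats::sd(scores) < 1e-300)
    stop("undefined correlation: zero-variance input")
  n <- length(features)
  xc <- features - mean(features)
  sc <- scores - mean(scores)
  den <- sqrt(sum(xc^2) * sum(sc^2))
  robs <- sum(xc * sc) / den
  rnull <- vapply(seq_len(n_perm), function(i)
    sum(xc * sc[sample.int(n)]) / den, numeric(1))
  list(estimate = robs, p.value = perm_p_two_sided(rnull, robs))
}

#' Bonferroni-Holm correction
#'
#' Step-down Holm adjustment ([stats::p.adjust()]), order-preserving.
#'
#' @param p numeric p-values in `[0, 1]`.
#' @return adjusted p-values in input order.
#' @export
holm_correction <- function(p) stats::p.adjust(p, method = "holm")

#' Bias-corrected and accelerated bootstrap confidence interval
#'
#' BCa interval (jackknife acceleration) for a paired statistic, by
#' default the Pearson correlation, via `boot::boot.ci`. Falls back to
#' the percentile interval with a warning if the bootstrap distribution
#' degenerates.
#'
#' @param x,y paired numeric vectors (`n >= 5`).
#' @param statistic function of `(x, y)` returning a scalar.
#' @param n_boot bootstrap replicates.
#' @param level confidence level.
#' @param seed RNG seed.
#' @return numeric `c(lo, hi)` with attribute `"estimate"`.
#' @export
bca_bootstrap_ci <- function(x, y, statistic = stats::cor,
                             n_boot = 10000L, level = 0.95, seed = NULL) {
  stopifnot(length(x) == length(y), length(x) >= 5L)
  if (!is.null(seed)) set.seed(seed)
  dat <- data.frame(x = x, y = y)
  bt <- boot::boot(dat, function(d, i) statistic(d$x[i], d$y[i]),
                   R = n_boot)
  ci <- tryCatch({
    b <- boot::boot.ci(bt, conf = level, type = "bca")
    b$bca[1L, 4:5]
  }, error = function(e) {
    warning("BCa degenerate (", conditionMessage(e),
            "); falling back to percentile interval")
    stats::quantile(bt$t, c((1 - level) / 2, 1 - (1 - level) / 2),
                    names = FALSE)
  })
  out <- as.numeric(ci)
  attr(out, "estimate") <- as.numeric(bt$t0)
  out
}

#' Cohen's d from group summary statistics
#'
#' `(mean1 - mean2)` over the pooled standard deviation
#' `sqrt(((n1-1) sd1^2 + (n2-1) sd2^2) / (n1+n2-2))`.
#'
#' @param mean1,sd1,n1,mean2,sd2,n2 group summaries.
#' @return signed effect size d.
#' @export
cohens_d_from_summary <- function(mean1, sd1, n1, mean2, sd2, n2) {
  stopifnot(n1 >= 2, n2 >= 2, sd1 > 0, sd2 > 0)
  sp <- sqrt(((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2))
  (mean1 - mean2) / sp
}

#' Cramer's V for a 2 x 2 contingency table
#'
#' `sqrt(chi^2 / n)` without continuity correction.
#'
#' @param tab 2 x 2 matrix of non-negative counts with positive margins.
#' @return effect size V in `[0, 1]`.
#' @export
cramers_v <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == 2L), all(tab >= 0))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("undefined: zero margin")
  chi2 <- suppressWarnings(
    stats::chisq.test(tab, correct = FALSE)$statistic)
  as.numeric(sqrt(chi2 / sum(tab)))
}
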