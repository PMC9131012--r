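test_that("edge statistics match hand formulas and degrade gracefully", {
  a <- list(matrix(c(0, 1, 1, 0), 2), matrix(c(0, 2, 2, 0), 2))
  b <- list(matrix(c(0, 5, 5, 0), 2), matrix(c(0, 7, 7, 0), 2))
  es <- edge_statistics(a, design_spec("two_sample"), y = b)
  x1 <- c(1, 2); x2 <- c(5, 7)
  sp <- sqrt((var(x1) + var(x2)) / 2)
  t_hand <- (mean(x1) - mean(x2)) / (sp * sqrt(1 / 2 + 1 / 2))
  expect_equal(es$stat[2, 1], t_hand, tolerance = 1e-12)
  expect_equal(es$stat, t(es$stat))
  # identical groups: t = 0, p = 1
  es0 <- edge_statistics(a, design_spec("two_sample"), y = a)
  expect_equal(es0$stat[2, 1], 0)
  expect_equal(es0$p[2, 1], 1)
  # a single shifted edge dominates the map
  set.seed(151)
  A <- random_conn_stack(8, 6)
  B <- random_conn_stack(8, 6)
  B <- lapply(B, function(m) { m[3, 5] <- m[5, 3] <- m[3, 5] + 2; m })
  esb <- edge_statistics(A, design_spec("two_sample"), y = B)
  off <- abs(esb$stat[lower.tri(esb$stat)])
  expect_equal(abs(esb$stat[5, 3]), max(off, na.rm = TRUE))
  # zero-variance edge excluded as NA
  Az <- lapply(A, function(m) { m[1, 2] <- m[2, 1] <- 0.5; m })
  Bz <- lapply(B, function(m) { m[1, 2] <- m[2, 1] <- 0.5; m })
  esz <- edge_statistics(Az, design_spec("two_sample"), y = Bz)
  expect_true(is.na(esz$stat[2, 1]))
  # correlation design against cor.test
  sc <- rnorm(8)
  esc <- edge_statistics(A, design_spec("correlation"), scores = sc)
  v <- vapply(A, function(m) m[4, 2], numeric(1))
  ct <- cor.test(v, sc)
  expect_equal(esc$stat[4, 2], unname(ct$estimate), tolerance = 1e-12)
  expect_equal(esc$p[4, 2], ct$p.value, tolerance = 1e-9)
})

test_that("signed components agree with an igraph oracle", {
  nch <- 12
  st <- matrix(0, nch, nch); pv <- matrix(1, nch, nch)
  put <- function(i, j, v) {
    st[i, j] <<- st[j, i] <<- v
    pv[i, j] <<- pv[j, i] <<- 1e-4
  }
  put(1, 2, 2.0); put(2, 3, 3.0); put(3, 4, 2.5)   # positive path
  put(6, 7, -4.0)                                   # lone negative edge
  put(9, 10, 1.5)                                   # disjoint positive
  sc <- signed_components(st, pv, 0.01)
  expect_length(sc$positive, 2L)
  expect_length(sc$negative, 1L)
  sizes <- sort(vapply(sc$positive, `[[`, 0, "size"))
  expect_equal(sizes, c(1.5, 7.5))
  expect_equal(sc$negative[[1]]$size, -4)
  # no suprathreshold edges: both empty
  none <- signed_components(st, matrix(1, nch, nch), 0.01)
  expect_length(none$positive, 0L)
  expect_length(none$negative, 0L)
  # random maps: component memberships equal igraph's
  set.seed(161)
  for (r in 1:5) {
    stat <- matrix(rnorm(nch * nch), nch); stat <- (stat + t(stat)) / 2
    pr <- matrix(runif(nch * nch), nch); pr <- (pr + t(pr)) / 2
    got <- signed_components(stat, pr, 0.3)
    for (sgn in c("positive", "negative")) {
      comps <- got[[sgn]]
      edges <- do.call(rbind, lapply(comps, `[[`, "edges"))
      if (is.null(edges)) next
      g <- igraph::graph_from_edgelist(
        matrix(as.character(edges), ncol = 2), directed = FALSE)
      expect_equal(length(comps), igraph::components(g)$no)
      tot <- sum(vapply(comps, `[[`, 0, "size"))
      keep <- !is.na(pr) & pr < 0.3 &
        (if (sgn == "positive") stat > 0 else stat < 0)
      expect_equal(tot, sum(stat[keep & lower.tri(stat)]),
                   tolerance = 1e-9)
    }
  }
})

test_that("NBS p-values sit on the grid and hit the formula floor", {
  set.seed(171)
  A <- random_conn_stack(10, 8)
  B <- lapply(random_conn_stack(10, 8), function(m) {
    m[1:3, 1:3] <- m[1:3, 1:3] + 3; diag(m) <- 1; m
  })
  res <- nbs_test(A, design_spec("two_sample", p_thr = 0.01,
                                 n_perm = 2000, seed = 7), y = B)
  expect_gt(length(res), 0)
  top <- res[[1]]
  expect_equal(top$p, 1 / 2001, tolerance = 1e-12)
  ps <- vapply(res, `[[`, 0, "p")
  N <- attr(res, "n_perm")
  on_grid <- vapply(ps, function(p)
    any(abs(p - pmin(1, (2 * (0:N) + 1) / (N + 1))) < 1e-12), logical(1))
  expect_true(all(on_grid))
  expect_true(all(ps > 0))
  # every edge in a component matches the component's sign
  for (comp in res) {
    es <- edge_statistics(A, design_spec("two_sample"), y = B)
    vals <- es$stat[comp$edges]
    expect_true(all(sign(vals) == comp$sign))
  }
})

test_that("small permutation spaces are enumerated exactly", {
  a <- random_conn_stack(3, 4, seed = 181)
  b <- lapply(random_conn_stack(3, 4, seed = 182), function(m) m + 0.5)
  expect_message(
    res <- nbs_test(a, design_spec("two_sample", p_thr = 0.2,
                                   n_perm = 5000, seed = 1), y = b),
    "enumerating exactly")
  expect_equal(attr(res, "n_perm"), choose(6, 3))
  d1 <- random_conn_stack(4, 4, seed = 183)
  d2 <- random_conn_stack(4, 4, seed = 184)
  expect_message(
    resp <- nbs_test(d1, design_spec("paired", p_thr = 0.2,
                                     n_perm = 5000, seed = 1), y = d2),
    "enumerating exactly")
  expect_equal(attr(resp, "n_perm"), 2^4)
})

test_that("mean FCSCC averages connectivity over component edges", {
  m <- matrix(2, 5, 5)
  comp <- list(edges = rbind(c(1, 2), c(2, 3), c(4, 5)), sign = 1)
  expect_equal(mean_fcscc(m, comp), 2)
  m2 <- matrix(0, 5, 5)
  m2[1, 2] <- 0.3; m2[2, 3] <- 0.6; m2[4, 5] <- 0.9
  m2 <- m2 + t(m2)
  expect_equal(mean_fcscc(m2, list(edges = rbind(c(2, 1)))), 0.3)
  expect_equal(mean_fcscc(m2, comp), mean(c(0.3, 0.6, 0.9)))
  expect_error(mean_fcscc(m2, list(edges = NULL)), "empty component")
})

test_that("scalar permutation tests match enumeration and the p floor", {
  # strong separation: no permuted |t| reaches the observed one
  pt <- permutation_test_scalar(101:106, 1:6, n_perm = 2000, seed = 3)
  expect_equal(pt$p.value, 1 / 2001, tolerance = 1e-12)
  # paired, all differences zero
  expect_warning(p0 <- permutation_test_scalar(1:5, 1:5, paired = TRUE,
                                               n_perm = 100),
                 "constant")
  expect_equal(p0$p.value, 1)
  # n = 3 + 3 toy against full label enumeration; the sampled and
  # enumerated formulas agree up to one count on the 21-point exact grid
  x <- c(0.2, 1.1, 2.3); y <- c(0.9, 1.8, 1.4)
  z <- c(x, y)
  tfun <- function(idx) {
    a <- z[idx]; b <- z[-idx]
    (mean(a) - mean(b)) / sqrt((var(a) + var(b)) / 2 * (2 / 3))
  }
  tobs <- tfun(1:3)
  tall <- combn(6, 3, tfun)
  c_lo <- sum(tall < tobs); c_hi <- sum(tall > tobs)
  p_exact <- min(1, (2 * min(c_lo, c_hi) + 1) / (length(tall) + 1))
  pt2 <- permutation_test_scalar(x, y, n_perm = 20000, seed = 5)
  expect_equal(pt2$statistic, tobs, tolerance = 1e-12)
  expect_lt(abs(pt2$p.value - p_exact), 2 / 21)
})

test_that("correlation permutation test: closed form r and null uniformity", {
  pc <- permutation_correlation(1:10, 1:10, n_perm = 2000, seed = 1)
  expect_equal(pc$estimate, 1)
  expect_equal(pc$p.value, 1 / 2001, tolerance = 1e-12)
  # 5-point hand data
  f <- c(1.2, -0.4, 2.5, 0.3, 1.9); s <- c(10, 12, 9, 14, 11)
  pc2 <- permutation_correlation(f, s, n_perm = 500, seed = 2)
  expect_equal(pc2$estimate, cor(f, s), tolerance = 1e-12)
  # null p-values are uniform (KS over repeated independent draws)
  set.seed(31)
  ps <- replicate(60, {
    permutation_correlation(rnorm(50), rnorm(50), n_perm = 499)$p.value
  })
  # p-values live on the attainable grid, so ties are expected
  expect_gt(suppressWarnings(ks.test(ps, "punif")$p.value), 0.01)
  expect_error(permutation_correlation(rep(1, 5), rnorm(5)),
               "zero-variance")
})

test_that("Holm correction is the step-down hand rule", {
  expect_equal(holm_correction(0.2), 0.2)
  expect_equal(holm_correction(c(0.01, 0.04, 0.03)), c(0.03, 0.06, 0.06))
  expect_equal(holm_correction(rep(1, 4)), rep(1, 4))
  set.seed(41)
  p <- runif(7)
  adj <- holm_correction(p)
  # hand step-down with monotonicity enforcement
  o <- order(p)
  hand <- pmin(1, cummax((7:1) * p[o]))[order(o)]
  expect_equal(adj, hand, tolerance = 1e-12)
  expect_true(all(adj >= p))
})

test_that("BCa interval contains the estimate and tracks percentile when symmetric", {
  set.seed(51)
  x <- rnorm(40); y <- 0.5 * x + rnorm(40, sd = 0.8)
  ci <- bca_bootstrap_ci(x, y, n_boot = 4000, seed = 52)
  est <- attr(ci, "estimate")
  expect_equal(est, cor(x, y))
  expect_true(ci[1] < est && est < ci[2])
  # symmetric-by-construction statistic: BCa ~ percentile
  stat_mean_diff <- function(a, b) mean(a) - mean(b)
  set.seed(53)
  a <- rnorm(60); b <- rnorm(60)
  ci_bca <- bca_bootstrap_ci(a, b, statistic = stat_mean_diff,
                             n_boot = 4000, seed = 54)
  set.seed(54)
  bt <- boot::boot(data.frame(x = a, y = b),
                   function(d, i) stat_mean_diff(d$x[i], d$y[i]), R = 4000)
  pct <- quantile(bt$t, c(0.025, 0.975), names = FALSE)
  expect_lt(max(abs(as.numeric(ci_bca) - pct)), 0.05)
})

test_that("summary-statistic effect sizes reproduce the cohort table", {
  expect_equal(round(cohens_d_from_summary(56.7, 12.1, 31,
                                           58.9, 12.0, 23), 2), -0.18)
  expect_equal(cohens_d_from_summary(5, 2, 10, 5, 3, 12), 0)
  expect_equal(cohens_d_from_summary(2, 1, 10, 1, 1, 10), 1)
  expect_equal(round(cramers_v(matrix(c(7, 10, 24, 13), 2)), 2), 0.22)
  expect_equal(round(cramers_v(matrix(c(2, 2, 29, 21), 2)), 2), 0.04)
  expect_equal(cramers_v(matrix(c(10, 20, 5, 10), 2)), 0,
               tolerance = 1e-12)
  expect_error(cramers_v(matrix(c(0, 0, 5, 10), 2)), "zero margin")
})
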