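test_that("GFP equals the per-sample population SD across channels", {
  rec <- eeg_recording(cbind(c(2, 2, 2), c(1, -1, 0)), fs = 100)
  expect_equal(global_field_power(rec)$values[1], 0)
  rec2 <- eeg_recording(matrix(c(1, -1), 2, 1), fs = 100)
  expect_equal(global_field_power(rec2)$values, 1)
  set.seed(21)
  m <- matrix(rnorm(59 * 7), 59)
  oracle <- apply(m, 2, function(x) sqrt(mean((x - mean(x))^2)))
  expect_equal(global_field_power(eeg_recording(m, 250))$values, oracle,
               tolerance = 1e-12)
})

test_that("GFP peak extraction applies discard and outlier rules", {
  # strictly monotone GFP: no interior local maxima
  mono <- recording_with_gfp(seq(0.1, 5, length.out = 200))
  expect_warning(pk <- extract_gfp_peaks(global_field_power(mono)),
                 "no GFP peaks")
  expect_length(pk, 0)
  # sinusoidal GFP: peak count matches a brute-force scan
  fs <- 250
  g <- abs(sin(2 * pi * 10 * seq_len(4 * fs) / fs)) + 0.5
  gfp <- global_field_power(recording_with_gfp(g))
  pk_all <- extract_gfp_peaks(gfp, discard_fraction = 0, sd_multiple = 1e6)
  gv <- gfp$values
  brute <- which(gv[2:(length(gv) - 1)] > gv[1:(length(gv) - 2)] &
                   gv[2:(length(gv) - 1)] > gv[3:length(gv)]) + 1L
  expect_identical(pk_all, brute)
  # floor rule for the 15% discard
  pk15 <- extract_gfp_peaks(gfp, discard_fraction = 0.15,
                            sd_multiple = 1e6)
  expect_identical(length(pk15),
                   length(brute) - as.integer(floor(0.15 * length(brute))))
  expect_true(all(diff(pk15) > 0))
  # a peak far above mean + 3 SD is excluded
  g2 <- g
  g2[500] <- mean(gv) + 10 * sd(gv)
  pk_out <- extract_gfp_peaks(global_field_power(recording_with_gfp(g2)))
  expect_false(500L %in% pk_out)
})

test_that("modified k-means recovers planted maps, ignoring polarity", {
  base <- orthogonal_maps(20, 4, seed = 31)
  set.seed(32)
  X <- base[rep(1:4, each = 100), ] * sample(c(-1, 1), 400, TRUE)
  X <- X + matrix(rnorm(400 * 20, sd = 0.01), 400)
  ts <- modified_kmeans(X, 4, n_repeats = 20, seed = 33)
  M <- abs(ts$maps %*% t(base))
  expect_gte(min(apply(M, 1, max)), 0.999)
  # polarity gauge: negating the whole input changes nothing but signs
  ts_neg <- modified_kmeans(-X, 4, n_repeats = 20, seed = 33)
  agree <- abs(ts$maps %*% t(ts_neg$maps))
  expect_gte(min(apply(agree, 1, max)), 1 - 1e-9)
  expect_equal(ts_neg$gev_train, ts$gev_train, tolerance = 1e-9)
  # k = 1 equals the dominant eigenvector of the map covariance
  # (unequal cluster sizes give the covariance a well-separated top
  # eigenvalue, so the dominant direction is unambiguous)
  set.seed(35)
  X1 <- base[rep(1:4, c(300, 60, 30, 15)), ] * sample(c(-1, 1), 405, TRUE)
  X1 <- X1 + matrix(rnorm(405 * 20, sd = 0.01), 405)
  one <- modified_kmeans(X1, 1, n_repeats = 3, seed = 34)
  A <- X1 - rowMeans(X1)
  A <- A / sqrt(rowSums(A^2))
  ev <- eigen(crossprod(A), symmetric = TRUE)$vectors[, 1]
  expect_gt(abs(sum(one$maps[1, ] * ev)), 1 - 1e-6)
  expect_error(modified_kmeans(X[1:3, ], 4), "parameter error")
})

test_that("GEV matches its closed form on constructed assignments", {
  tpl <- template_set(orthogonal_maps(12, 3, seed = 41))
  labels <- c(1L, 2L, 3L, 1L)
  gain <- c(2, 0.5, 3, 1)
  sign <- c(1, -1, 1, -1)
  maps <- tpl$maps[labels, ] * gain * sign
  gfp <- apply(maps, 1, function(x) sqrt(mean((x - mean(x))^2)))
  expect_equal(gev(maps, gfp, tpl, labels), 1, tolerance = 1e-12)
  # orthogonal maps explain nothing
  other <- orthogonal_maps(12, 3, seed = 42)
  ortho <- other - (other %*% t(tpl$maps)) %*% tpl$maps
  ortho <- ortho - rowMeans(ortho)
  gfp_o <- apply(ortho, 1, function(x) sqrt(mean((x - mean(x))^2)))
  expect_lt(gev(ortho, gfp_o, tpl, c(1L, 2L, 3L)), 1e-20)
  # 3-map hand example against the direct formula
  set.seed(43)
  hmaps <- matrix(rnorm(36), 3)
  hgfp <- apply(hmaps, 1, function(x) sqrt(mean((x - mean(x))^2)))
  hl <- c(2L, 1L, 3L)
  cors <- vapply(1:3, function(i)
    cor(hmaps[i, ], tpl$maps[hl[i], ]), numeric(1))
  direct <- sum((hgfp * cors)^2) / sum(hgfp^2)
  expect_equal(gev(hmaps, hgfp, tpl, hl), direct, tolerance = 1e-12)
  expect_error(gev(hmaps, rep(0, 3), tpl, hl), "undefined")
})

test_that("Krzanowski-Lai selection finds elbows and breaks ties low", {
  ks <- 1:10
  p <- 59
  # sharp elbow at k = 5: fast decay then flat
  W_elbow <- c(100, 60, 35, 20, 4, 3.8, 3.6, 3.4, 3.2, 3.0)
  k_star <- select_k_kl(setNames(W_elbow, ks), p = p)
  expect_identical(as.integer(k_star), 5L)
  # flat KL curve (penalised dispersion in arithmetic progression):
  # no interior maximum dominates, tie breaks to the smallest k
  W_tie <- (200 - 10 * ks) / ks^(2 / p)
  k_tie <- select_k_kl(setNames(W_tie, ks), p = p)
  expect_identical(as.integer(k_tie), 2L)
  expect_equal(unname(attr(k_tie, "kl")), rep(1, 8), tolerance = 1e-9)
  expect_error(select_k_kl(setNames(W_elbow[1:2], 1:2), p = p),
               "parameter error")
})

test_that("group and common templates reduce to their inputs when shared", {
  tpl <- template_set(orthogonal_maps(16, 3, seed = 51))
  per_rec <- list(r1 = tpl, r2 = tpl, r3 = tpl)
  grp <- group_templates(per_rec, 3, seed = 52, n_repeats = 10)
  expect_gte(min(apply(abs(grp$maps %*% t(tpl$maps)), 1, max)), 1 - 1e-9)
  # small perturbations: group templates stay close to the planted maps
  set.seed(53)
  noisy <- lapply(1:6, function(i) {
    template_set(tpl$maps + matrix(rnorm(48, sd = 0.05), 3))
  })
  names(noisy) <- sprintf("r%d", 1:6)
  grp2 <- group_templates(noisy, 3, seed = 54, n_repeats = 10)
  expect_gte(min(apply(abs(grp2$maps %*% t(tpl$maps)), 1, max)), 0.99)
  # order canonicalisation: permuting the named list changes nothing
  grp3 <- group_templates(noisy[c(4, 2, 6, 1, 3, 5)], 3, seed = 54,
                          n_repeats = 10)
  expect_identical(grp2$maps, grp3$maps)
  expect_error(group_templates(list(tpl, template_set(tpl$maps[1:2, ])),
                               3), "parameter error")
  # common templates of identical groups reproduce the group set
  com <- common_templates(grp, grp, seed = 55, n_repeats = 10)
  expect_gte(min(apply(abs(com$maps %*% t(grp$maps)), 1, max)), 1 - 1e-9)
  expect_error(common_templates(grp, template_set(orthogonal_maps(8, 3))),
               "structural")
})

test_that("template ordering recovers permutations and beats greedy", {
  ref <- template_set(orthogonal_maps(14, 4, seed = 61),
                      labels = LETTERS[1:4])
  perm <- c(3L, 1L, 4L, 2L)
  flip <- c(-1, 1, -1, 1)
  shuffled <- template_set(ref$maps[perm, ] * flip)
  ord <- order_templates(shuffled, ref)
  expect_identical(ord$labels, LETTERS[1:4])
  expect_equal(ord$maps, ref$maps, tolerance = 1e-9)
  # crafted 3x3 similarity where greedy row-wise assignment is suboptimal
  S <- rbind(c(0.90, 0.80, 0.10),
             c(0.85, 0.20, 0.10),
             c(0.10, 0.20, 0.15))
  greedy <- numeric(3)
  used <- rep(FALSE, 3)
  for (i in 1:3) {
    j <- which.max(replace(S[i, ], used, -Inf))
    greedy[i] <- j
    used[j] <- TRUE
  }
  perms <- list(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1), c(3,1,2), c(3,2,1))
  vals <- vapply(perms, function(p) sum(S[cbind(1:3, p)]), numeric(1))
  best <- perms[[which.max(vals)]]
  expect_false(identical(best, as.integer(greedy)))   # greedy differs
  expect_identical(microdyn:::best_assignment(S), as.integer(best))
})

test_that("polarity gauge: sign flips change no assignment or GEV", {
  base <- orthogonal_maps(18, 3, seed = 71)
  set.seed(72)
  X <- base[rep(1:3, each = 60), ] + matrix(rnorm(180 * 18, sd = 0.1), 180)
  flips <- sample(c(-1, 1), 180, TRUE)
  a <- modified_kmeans(X, 3, n_repeats = 10, seed = 73)
  b <- modified_kmeans(X * flips, 3, n_repeats = 10, seed = 73)
  expect_identical(attr(a, "assignments"), attr(b, "assignments"))
  expect_equal(a$gev_train, b$gev_train, tolerance = 1e-9)
  expect_equal(attr(a, "dispersion"), attr(b, "dispersion"),
               tolerance = 1e-9)
})
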