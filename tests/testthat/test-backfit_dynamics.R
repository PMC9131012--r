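test_that("backfit reproduces planted labels and ignores polarity", {
  tpl <- template_set(orthogonal_maps(16, 3, seed = 81))
  labels <- rep(c(1L, 2L, 3L, 2L), each = 50)
  set.seed(82)
  gain <- runif(200, 0.5, 2) * sample(c(-1, 1), 200, TRUE)
  rec <- playback_recording(tpl, labels, gain = gain)
  sq <- backfit(rec, tpl)
  expect_identical(sq$labels, labels)
  expect_equal(sq$sc[cbind(labels, seq_along(labels))],
               rep(1, 200), tolerance = 1e-9)
  neg <- rec
  neg$data <- -neg$data
  expect_identical(backfit(neg, tpl)$labels, labels)
  # zero-variance samples inherit the previous class
  rec$data[, 100] <- 0
  sq0 <- backfit(rec, tpl)
  expect_identical(sq0$labels[100], sq0$labels[99])
  expect_equal(sq0$sc[, 100], rep(0, 3))
})

test_that("smoothing removes short runs, is idempotent, leaves long runs", {
  fs <- 250
  tpl <- template_set(orthogonal_maps(12, 3, seed = 91))
  # all runs >= 30 ms: unchanged
  long_lab <- rep(c(1L, 2L, 1L), each = 25)   # 100 ms runs
  rec <- playback_recording(tpl, long_lab, fs = fs)
  sq <- backfit(rec, tpl)
  expect_identical(smooth_sequence(sq)$labels, long_lab)
  # a 20 ms run of class 2 inside class 1 with sc favouring 1 next
  lab <- c(rep(1L, 50), rep(2L, 5), rep(1L, 50))
  sc <- rbind(rep(0.9, 105), rep(0.5, 105), rep(0.1, 105))
  sc[2, 51:55] <- 0.95
  hand <- ms_sequence_from_labels(lab, fs = fs, k = 3)
  hand$sc <- sc
  sm <- smooth_sequence(hand)
  expect_identical(sm$labels, rep(1L, 105))
  expect_identical(nrow(sequence_runs(sm)), 1L)
  # postcondition sweep: 100 random label/sc sequences
  set.seed(92)
  for (i in 1:100) {
    n <- sample(200:400, 1)
    k <- sample(3:5, 1)
    s <- ms_sequence_from_labels(sample.int(k, n, TRUE), fs = fs, k = k)
    s$sc <- matrix(runif(k * n), k)
    out <- smooth_sequence(s)
    runs <- sequence_runs(out)
    if (nrow(runs) > 1L)
      expect_gte(min(runs$n) * 1000 / fs, 30)
    out2 <- smooth_sequence(out)
    expect_identical(out2$labels, out$labels)
  }
})

test_that("parameter suite matches the truncation-aware hand example", {
  fs <- 100
  # 6 s alternating 500 ms A/B: 12 runs, first and last truncated
  lab <- rep(rep(c(1L, 2L), 6), each = 50)
  tpl <- template_set(orthogonal_maps(10, 2, seed = 101))
  rec <- playback_recording(tpl, lab, fs = fs)
  sq <- smooth_sequence(backfit(rec, tpl))
  p <- compute_parameters(sq, rec)
  expect_equal(p$table$mean_duration, c(500, 500))
  expect_equal(p$table$occurrence, c(1, 1))
  expect_equal(p$table$coverage, c(50, 50))
  expect_equal(p$table$mean_interval, c(500, 500))
  expect_equal(p$analysis_time_s, 5)
  expect_equal(sum(p$table$coverage), 100, tolerance = 1e-9)
  # occurrence x duration / 1000 ~ coverage / 100
  expect_equal(p$table$occurrence * p$table$mean_duration / 1000,
               p$table$coverage / 100, tolerance = 1e-9)
  # single interior class: full coverage, no transitions, no interval
  lab1 <- rep(c(1L, 2L, 1L), c(30, 600, 30))
  rec1 <- playback_recording(template_set(orthogonal_maps(10, 2, 102)),
                             lab1, fs = fs)
  sq1 <- backfit(rec1, template_set(orthogonal_maps(10, 2, 102)))
  p1 <- compute_parameters(sq1, rec1)
  expect_equal(p1$table$coverage, c(0, 100))
  expect_true(is.na(p1$table$mean_interval[2]))
  expect_null(p1$tp)
})

test_that("SC matrix has unit diagonal on playback and is asymmetric", {
  tpl <- template_set(orthogonal_maps(14, 3, seed = 111))
  lab <- rep(rep(c(1L, 2L, 3L), 3), each = 40)   # interior runs of each class
  rec <- playback_recording(tpl, lab)
  sq <- backfit(rec, tpl)
  SC <- spatial_correlation_matrix(sq)
  expect_equal(unname(diag(SC)), rep(1, 3), tolerance = 1e-9)
  # crafted asymmetry: class-2 maps are tilted toward template 1,
  # class-1 maps stay pure, so SC[1,2] != SC[2,1]
  mix <- tpl
  data <- t(tpl$maps[lab, ])
  tilt <- lab == 2L
  data[, tilt] <- matrix(0.7 * tpl$maps[2, ] + 0.3 * tpl$maps[1, ],
                         nrow = 14, ncol = sum(tilt))
  rec2 <- eeg_recording(data, fs = 250)
  sq2 <- backfit(rec2, mix)
  sq2$labels <- lab   # keep the crafted classes
  SC2 <- spatial_correlation_matrix(sq2)
  expect_gt(abs(SC2[1, 2] - SC2[2, 1]), 0.05)
})

test_that("transition probabilities are observed minus expected", {
  fs <- 100
  # deterministic cycle 1 -> 2 -> 3 -> 1 ... with 40 ms runs
  lab <- rep(rep(c(1L, 2L, 3L), 7), each = 4)
  sq <- ms_sequence_from_labels(lab, fs = fs, k = 3)
  tp <- transition_probabilities(sq)
  # observed 1 -> 2 is certain; expected = share of class-2 run counts
  # among classes other than 1 (hand formula on the interior runs)
  runs <- sequence_runs(sq)
  keep <- runs[!runs$truncated, ]
  n_cl <- tabulate(keep$class, 3)
  expect_equal(tp[1, 2], 1 - n_cl[2] / (n_cl[2] + n_cl[3]),
               tolerance = 1e-9)
  expect_equal(tp[1, 3], -n_cl[3] / (n_cl[2] + n_cl[3]),
               tolerance = 1e-9)
  expect_equal(unname(rowSums(tp)), rep(0, 3), tolerance = 1e-9)
  expect_equal(unname(diag(tp)), rep(0, 3))
  # two classes only: observed = expected = 1, reported 0
  lab2 <- rep(rep(c(1L, 2L), 6), each = 5)
  tp2 <- transition_probabilities(ms_sequence_from_labels(lab2, fs, k = 2))
  expect_equal(unname(tp2), matrix(0, 2, 2))
  # i.i.d. random runs: entries shrink toward 0
  set.seed(112)
  lab3 <- rep(sample.int(4, 4000, TRUE), each = 3)
  tp3 <- transition_probabilities(ms_sequence_from_labels(lab3, fs, k = 4))
  expect_lt(max(abs(tp3)), 0.08)
  # permutation equivariance of the class labels
  perm <- c(3L, 1L, 4L, 2L)
  tp3p <- transition_probabilities(
    ms_sequence_from_labels(perm[lab3], fs, k = 4))
  expect_equal(unname(tp3p[perm, perm]), unname(tp3), tolerance = 1e-12)
})

test_that("planted dwell statistics survive backfit + smoothing", {
  cfg <- simulation_config(n_channels = 30, duration = 90, snr = 5,
                           seed = 115)
  sim <- generate_microstate_eeg(cfg)
  rec <- rereference_average(bandpass_zero_phase(sim$recording, 1, 20))
  sq <- smooth_sequence(backfit(rec, sim$truth$templates))
  p <- compute_parameters(sq, rec)
  grand_mean <- weighted.mean(p$table$mean_duration, p$table$occurrence)
  expect_lt(abs(grand_mean - 100) / 100, 0.10)
})
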