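# small hand-written trial matrices used in several oracle checks
tm_from_rows <- function(rows) {
  m <- do.call(rbind, rows)
  structure(m, lag_s = (seq_len(ncol(m)) - 1) / 15, bin_s = 1 / 15,
            class = c("strical_trials", "matrix"))
}

test_that("trial binarization marks bins with at least one transient", {
  onsets <- c(100L, 200L, 300L)
  tm <- binarize_trials(onsets, onsets, n_frames = 400L, fs = 15,
                        window_s = 2)
  # one transient exactly at each onset: a column of ones at lag 0
  zero_bin <- which(abs(attr(tm, "lag_s")) < 1e-9)
  expect_equal(unname(unclass(tm)[, zero_bin]), rep(1L, 3))
  expect_equal(sum(tm), 3)
  # empty train gives the zero matrix
  tm0 <- binarize_trials(integer(0), onsets, 400L, window_s = 2)
  expect_equal(sum(tm0), 0)
  # out-of-session trials are dropped and counted
  tm2 <- binarize_trials(onsets, c(onsets, 398L), 400L, window_s = 2)
  expect_equal(attr(tm2, "n_dropped"), 1)
  # occupancy of a homogeneous train: 2-frame bins hold >= 1 transient
  # with probability 1 - (1 - p)^2 for per-frame probability p
  set.seed(41)
  r <- 3 # Hz
  train <- which(runif(150000) < r / 15)
  on2 <- seq(200L, 149000L, by = 300L)
  tmp <- binarize_trials(train, on2, 150000L, window_s = 5, bin_s = 2 / 15)
  expect_lt(abs(mean(tmp) - (1 - (1 - r / 15)^2)), 0.015)
})

test_that("raw JPSTH and shift predictor match exhaustive enumeration", {
  tm1 <- tm_from_rows(list(c(1L, 0L, 0L), c(0L, 1L, 0L), c(0L, 0L, 1L)))
  tm2 <- tm_from_rows(list(c(0L, 1L, 0L), c(0L, 1L, 0L), c(1L, 0L, 0L)))
  raw <- raw_jpsth(tm1, tm2)
  # brute-force enumeration over trials
  brute <- matrix(0, 3, 3)
  for (t in 1:3) brute <- brute + outer(unclass(tm1)[t, ], unclass(tm2)[t, ])
  expect_equal(unname(raw), brute)
  # shift predictor: mean of the two hand-shifted raw matrices
  sp <- shift_predictor(tm1, tm2)
  s1 <- s2 <- matrix(0, 3, 3)
  for (t in 1:3) {
    s1 <- s1 + outer(unclass(tm1)[t, ], unclass(tm2)[c(2, 3, 1)[t], ])
    s2 <- s2 + outer(unclass(tm1)[t, ], unclass(tm2)[c(3, 1, 2)[t], ])
  }
  expect_equal(unname(sp), (s1 + s2) / 2)
  # closed-form oracle: sum over all shifts factorizes through the margins
  cf <- (outer(colSums(unclass(tm1)), colSums(unclass(tm2))) - brute) / 2
  expect_equal(unname(sp), cf)
  # explicit shift-and-average loop on a larger random case
  set.seed(40)
  r1 <- matrix(rbinom(8 * 6, 1, 0.3), 8, 6)
  r2 <- matrix(rbinom(8 * 6, 1, 0.3), 8, 6)
  acc <- matrix(0, 6, 6)
  for (m in 1:7) acc <- acc + crossprod(r1, r2[c((m + 1):8, 1:m), ])
  expect_equal(shift_predictor(r1, r2), acc / 7)
})

test_that("degenerate JPSTH cases behave exactly", {
  # both neurons fire in bin 1 on all trials
  tm1 <- tm_from_rows(rep(list(c(1L, 0L, 0L)), 4))
  raw <- raw_jpsth(tm1, tm1)
  expect_equal(unname(raw), matrix(c(4, 0, 0, 0, 0, 0, 0, 0, 0), 3))
  # identical trials: predictor equals raw exactly (shift invariance)
  expect_equal(shift_predictor(tm1, tm1), unname(raw) * 1.0)
  # silent neuron 2 zeroes everything
  tm0 <- tm_from_rows(rep(list(c(0L, 0L, 0L)), 4))
  expect_equal(sum(raw_jpsth(tm1, tm0)), 0)
  expect_error(raw_jpsth(tm1, tm_from_rows(list(c(1L, 0L)))), "shape")
})

test_that("corrected JPSTH is smoothed raw minus predictor", {
  m <- matrix(0, 9, 9)
  expect_equal(corrected_jpsth(m, m), m)
  # raw = predictor gives exactly zero after smoothing
  r <- matrix(runif(81), 9, 9)
  expect_equal(corrected_jpsth(r, r), m)
  # edge renormalization keeps a constant field exactly constant
  cst <- matrix(0.7, 9, 9)
  expect_equal(corrected_jpsth(cst, matrix(0, 9, 9)), cst)
  # an interior impulse keeps its mass to within the edge renormalization
  d <- matrix(0, 9, 9); d[5, 5] <- 1
  sm <- corrected_jpsth(d, matrix(0, 9, 9))
  expect_equal(sum(sm), 1, tolerance = 0.01)
  expect_lt(max(sm), 1)
})

test_that("normalization divides by the product of PSTH SDs", {
  tm1 <- tm_from_rows(list(c(1L, 0L, 0L), c(1L, 1L, 0L), c(0L, 0L, 1L)))
  tm2 <- tm_from_rows(list(c(0L, 1L, 0L), c(0L, 1L, 1L), c(1L, 0L, 0L)))
  corr <- corrected_jpsth(raw_jpsth(tm1, tm2), shift_predictor(tm1, tm2))
  nr <- normalize_jpsth(corr, tm1, tm2)
  s <- sd(colSums(unclass(tm1))) * sd(colSums(unclass(tm2)))
  expect_equal(nr, corr / s)
  expect_equal(normalize_jpsth(matrix(0, 3, 3), tm1, tm2), matrix(0, 3, 3))
  # a neuron with a flat PSTH cannot be normalized
  tmf <- tm_from_rows(list(c(1L, 1L, 1L), c(0L, 0L, 0L), c(1L, 1L, 1L)))
  expect_error(normalize_jpsth(corr, tmf, tm2), class = "strical_zero_sd")
})

test_that("normalized diagonal peaks are stable under bin-width changes", {
  qt <- quick_trains(n_neurons = 2, n_events = 150, gain = 4, seed = 42)
  p1 <- jpsth_pair(qt$spikes[[1]], qt$spikes[[2]], qt$onsets, qt$n_frames,
                   window_s = 4, bin_s = 1 / 15,
                   smooth_sd_bins = 0)
  p2 <- jpsth_pair(qt$spikes[[1]], qt$spikes[[2]], qt$onsets, qt$n_frames,
                   window_s = 4, bin_s = 2 / 15,
                   smooth_sd_bins = 0)
  # unitless normalization keeps the diagonal magnitude comparable
  m1 <- mean(abs(diag(p1$normalized)))
  m2 <- mean(abs(diag(p2$normalized)))
  expect_lt(abs(log(m1 / m2)), log(4))
})

test_that("population JPSTH averages pairs elementwise", {
  qt <- quick_trains(n_neurons = 3, n_events = 60, gain = 4, seed = 43)
  j12 <- jpsth_pair(qt$spikes[[1]], qt$spikes[[2]], qt$onsets, qt$n_frames)
  j13 <- jpsth_pair(qt$spikes[[1]], qt$spikes[[3]], qt$onsets, qt$n_frames)
  pop1 <- population_jpsth(list(j12))
  expect_equal(pop1$matrix, j12$normalized)
  pop2 <- population_jpsth(list(j12, j12))
  expect_equal(pop2$matrix, j12$normalized)
  pop <- population_jpsth(list(j12, j13))
  expect_equal(pop$matrix, (j12$normalized + j13$normalized) / 2)
  expect_error(population_jpsth(list()), "empty")
})

test_that("independent pairs give a near-zero corrected JPSTH", {
  qt <- quick_trains(n_neurons = 2, n_events = 200, gain = 4,
                     duration_s = 2400, seed = 44)
  j <- jpsth_pair(qt$spikes[[1]], qt$spikes[[2]], qt$onsets, qt$n_frames)
  # mean of the corrected matrix is small relative to the coincidence scale
  expect_lt(abs(mean(j$corrected)), 0.05 * mean(j$predictor))
  # the diagonal's post-event peak stays inside the far-removed band
  pairs <- matrix(c(1, 2), 1)
  da <- diagonal_analysis(qt$spikes, qt$onsets, qt$n_frames, pairs,
                          seed = 45)
  expect_lt(da$post_peak, da$baseline_mean + 4 * da$baseline_sd)
})

test_that("injected zero-lag coupling produces a diagonal ridge", {
  p <- synth_params(duration_s = 2400, n_neurons = 10, frac_responsive = 1,
                    frac_negative = 0, gain_pos = 4,
                    shared_coactivation_p = 0.5, seed = 46)
  onsets <- random_onsets(200, 2400L * 15L, seed = 46)
  tr <- generate_traces(p, onsets, coupled_ids = 1:10)
  pairs <- t(utils::combn(1:10, 2))
  da <- diagonal_analysis(tr$spikes, onsets, 2400L * 15L, pairs, seed = 47)
  expect_gt(da$post_peak, da$baseline_mean + 2 * da$baseline_sd)
  expect_gt(da$post_peak, da$baseline_peak)
})
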