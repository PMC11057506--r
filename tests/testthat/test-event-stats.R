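test_that("event-triggered averages equal hand-computed means", {
  n <- 1500L
  x <- numeric(n)
  onsets <- c(300L, 900L)
  x[onsets] <- 1 # impulse at each onset
  e <- compute_eta(x, onsets, fs = 15, window_s = 5)
  expect_equal(nrow(e), 5 * 15 + 1)
  expect_equal(e$mean[e$lag_s == 0], 1)
  expect_equal(sum(e$mean), 1)
  # two events, arbitrary trace: ETA = elementwise mean of the two windows
  set.seed(9)
  y <- rnorm(n)
  e2 <- compute_eta(y, onsets, fs = 15, window_s = 5)
  lags <- -38:37
  expect_equal(e2$mean, (y[onsets[1] + lags] + y[onsets[2] + lags]) / 2)
  # events too close to the edge are dropped and counted
  e3 <- compute_eta(y, c(onsets, 5L), fs = 15, window_s = 5)
  expect_equal(attr(e3, "n_dropped"), 1)
  expect_error(compute_eta(y, 2L), "no usable events")
})

test_that("ETA of shuffled events on stationary noise is flat within SEM", {
  set.seed(10)
  x <- rnorm(30000)
  onsets <- sort(sample(100:29900, 150))
  e <- compute_eta(x, onsets, fs = 15, window_s = 5)
  expect_true(mean(abs(e$mean) < 3 * e$sem) > 0.95)
})

test_that("PSTHs count transients in 67 ms bins", {
  onsets <- c(200L, 400L, 600L)
  train <- onsets # one transient exactly at each onset
  p <- compute_psth(train, onsets, fs = 15, window_s = 5)
  expect_equal(p$count[p$lag_s == 0], 3)
  expect_equal(sum(p$count), 3)
  # doubling the trial count doubles counts but not the rate profile
  p2 <- compute_psth(train, rep(onsets, 2), fs = 15, window_s = 5)
  expect_equal(p2$count, 2 * p$count)
  expect_equal(p2$rate, p$rate)
  # homogeneous train gives a flat PSTH within Poisson error
  set.seed(11)
  tr <- which(runif(30000) < 0.02)
  ph <- compute_psth(tr, sort(sample(100:29800, 80)), fs = 15, window_s = 5)
  expect_lt(max(abs(ph$count - mean(ph$count))), 5 * sqrt(mean(ph$count)))
})

test_that("bootstrap flags strong responders and spares null neurons", {
  qt <- quick_trains(n_neurons = 2, n_events = 100, gain = 4, seed = 13)
  b <- bootstrap_significance(qt$traces[, 1], qt$onsets, n_null = 1000,
                              seed = 14)
  expect_lt(b$p_value, 0.05)
  expect_true(b$significant)
  expect_equal(tidy(b)$p_value, b$p_value)
  # null neuron
  pnull <- synth_params(duration_s = 1800, n_neurons = 1,
                        frac_responsive = 0, seed = 15)
  trn <- generate_traces(pnull, qt$onsets)
  bn <- bootstrap_significance(trn$traces[, 1], qt$onsets, n_null = 1000,
                               seed = 16)
  expect_gt(bn$p_value, 0.05)
  # degenerate constant trace
  bd <- bootstrap_significance(rep(1, 27000), qt$onsets, n_null = 10,
                               seed = 17)
  expect_equal(bd$p_value, 1)
  expect_true(bd$degenerate)
})

test_that("bootstrap p-values are reproducible and respect the add-one rule", {
  qt <- quick_trains(n_neurons = 1, n_events = 60, gain = 1, seed = 18)
  b1 <- bootstrap_significance(qt$traces[, 1], qt$onsets, n_null = 200,
                               seed = 19)
  b2 <- bootstrap_significance(qt$traces[, 1], qt$onsets, n_null = 200,
                               seed = 19)
  expect_identical(b1$p_value, b2$p_value)
  expect_equal(b1$p_value,
               (1 + sum(b1$null_areas >= b1$observed)) / (1 + 200))
  expect_gte(b1$p_value, 1 / 201)
})

test_that("modulation labels compare the 1 s pre and post means", {
  lag_s <- (-38:37) / 15
  step_up <- list(lag_s = lag_s, mean = as.numeric(lag_s > 0))
  expect_equal(classify_modulation(step_up), "positive")
  step_down <- list(lag_s = lag_s, mean = as.numeric(lag_s <= 0))
  expect_equal(classify_modulation(step_down), "negative")
  # time reversal flips the label
  rev_up <- list(lag_s = lag_s, mean = rev(step_up$mean))
  expect_equal(classify_modulation(rev_up), "negative")
  expect_warning(
    lab <- classify_modulation(list(lag_s = lag_s, mean = rep(1, 76))),
    "tie")
  expect_equal(lab, "positive")
})

test_that("suppressed responders are labeled negative from their ETAs", {
  p <- synth_params(duration_s = 3600, n_neurons = 30, frac_responsive = 1,
                    frac_negative = 1, gain_neg = 0.05, base_rate_hz = 0.4,
                    seed = 20)
  onsets <- spaced_onsets(150, 3600 * 15)
  tr <- generate_traces(p, onsets)
  labs <- vapply(seq_len(30), function(j) {
    classify_modulation(compute_eta(tr$traces[, j], onsets))
  }, character(1))
  expect_gte(mean(labs == "negative"), 0.9)
})

test_that("response reliability counts events with a transient in 1 s", {
  onsets <- seq(100L, by = 100L, length.out = 100L)
  train <- onsets[1:50] + 5L # transient after exactly 50 of 100 events
  expect_equal(response_reliability(train, onsets), 0.5)
  expect_equal(response_reliability(onsets + 3L, onsets), 1)
  # invariant to event reordering
  expect_equal(response_reliability(train, sample(onsets)), 0.5)
  # boundary: a transient exactly at the onset frame does not count,
  # 15 frames after it does
  expect_equal(response_reliability(onsets[1], onsets[1]), 0)
  expect_equal(response_reliability(onsets[1] + 15L, onsets[1]), 1)
})

test_that("per-event recruitment is the active fraction in 1.5 s", {
  onsets <- c(100L, 300L)
  trains <- list(integer(0), integer(0), integer(0))
  r0 <- population_recruitment(trains, onsets)
  expect_equal(r0$fraction_active, c(0, 0))
  trains_all <- list(onsets + 2L, onsets + 10L, onsets + 20L)
  r1 <- population_recruitment(trains_all, onsets)
  expect_equal(r1$fraction_active, c(1, 1))
  # 1.5 s spans 22 frames at 15 fps (floor)
  expect_equal(population_recruitment(list(100L + 22L), 100L)$fraction_active, 1)
  expect_equal(population_recruitment(list(100L + 23L), 100L)$fraction_active, 0)
  # independent responders at per-event probability q
  set.seed(22)
  q <- 0.3
  onsets2 <- seq(100L, by = 50L, length.out = 200L)
  trains2 <- lapply(1:60, function(j) {
    hit <- runif(200) < q
    sort(onsets2[hit] + sample(1:22, sum(hit), replace = TRUE))
  })
  r2 <- population_recruitment(trains2, onsets2)
  expect_lt(abs(mean(r2$fraction_active) - q), 0.05)
})

test_that("independence expectation gives 6% for the printed marginals", {
  out <- expected_overlap_independent(c(0.22, 0.27))
  expect_equal(out$all_sessions, 0.0594)
  expect_equal(round(100 * out$all_sessions), 6)
  expect_equal(expected_overlap_independent(c(0, 0.5))$all_sessions, 0)
  expect_equal(expected_overlap_independent(c(1, 1))$all_sessions, 1)
  # k-session profile is a probability distribution with the right mass
  prof <- expected_overlap_independent(c(0.2, 0.3, 0.4))$profile
  expect_equal(sum(prof$prob), 1)
  expect_equal(prof$prob[prof$n_sessions == 3], 0.2 * 0.3 * 0.4)
  expect_error(expected_overlap_independent(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("session overlap fractions partition the registered cells", {
  reg <- tibble::tibble(responsive_a = c(TRUE, TRUE, FALSE, FALSE),
                        responsive_b = c(TRUE, FALSE, TRUE, FALSE))
  ov <- session_overlap(reg)
  expect_equal(ov$fraction, rep(0.25, 4))
  expect_equal(sum(ov$n), 4)
  # disjoint responsive sets
  reg2 <- tibble::tibble(responsive_a = c(TRUE, FALSE),
                         responsive_b = c(FALSE, TRUE))
  expect_equal(ov2 <- session_overlap(reg2)$fraction[3], 0)
  # identical sets of size k over n cells give both = k/n
  reg3 <- tibble::tibble(responsive_a = rep(c(TRUE, FALSE), c(3, 7)),
                         responsive_b = rep(c(TRUE, FALSE), c(3, 7)))
  expect_equal(session_overlap(reg3)$fraction[3], 0.3)
  expect_error(session_overlap(reg[0, ]), "empty")
})

test_that("registration filter applies both acceptance criteria strictly", {
  reg <- tibble::tibble(
    cell = 1:4,
    p_same = c(0.9, 0.4, 0.9, 0.51),
    centroid_distance_um = c(10, 10, 14, 13.9))
  kept <- filter_registration(reg)
  expect_equal(kept$cell, c(1L, 4L))
  expect_error(filter_registration(tibble::tibble(p_same = 1)), "columns")
})

test_that("split-half consistency detects stable responders", {
  qt <- quick_trains(n_neurons = 1, n_events = 160, gain = 8,
                     base_rate_hz = 0.15, seed = 23)
  sh <- split_half_consistency(qt$traces[, 1], qt$onsets, scheme = "odd_even",
                               n_null = 500, seed = 24)
  expect_equal(sh$split, c("odd", "even"))
  expect_true(all(sh$significant))
  expect_true(attr(sh, "both"))
  # relabeling trial order permutes splits but not the full-session result
  b_full <- bootstrap_significance(qt$traces[, 1], qt$onsets, n_null = 500,
                                   seed = 25)
  b_perm <- bootstrap_significance(qt$traces[, 1], rev(qt$onsets),
                                   n_null = 500, seed = 25)
  expect_equal(b_full$p_value, b_perm$p_value)
  expect_error(split_half_consistency(qt$traces[, 1], qt$onsets[1:4]),
               "at least 8")
})

test_that("the 1.5 IQR rule flags extremes on both sides", {
  expect_equal(which(flag_outliers(c(1:9, 100))), 10L)
  expect_false(any(flag_outliers(rep(2, 10))))
  x <- c(-50, seq(10, 20, length.out = 9))
  expect_equal(which(flag_outliers(x)), 1L)
  expect_error(flag_outliers(c(1, 2)), "at least 4")
})
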