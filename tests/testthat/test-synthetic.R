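test_that("synth_params validates its invariants", {
  expect_s3_class(synth_params(), "strical_synth_params")
  expect_error(synth_params(frac_responsive = 1.2), "\\[0, 1\\]")
  expect_error(synth_params(tau_s = -1), "> 0")
  expect_error(synth_params(duration_s = 100.03), "integer frame count")
})

test_that("generators are deterministic under a fixed seed", {
  k1 <- generate_kinematics(duration_s = 120, n_bouts = 5, seed = 3)
  k2 <- generate_kinematics(duration_s = 120, n_bouts = 5, seed = 3)
  expect_identical(k1, k2)
  p <- synth_params(duration_s = 120, n_neurons = 3, seed = 4)
  t1 <- generate_traces(p, c(300L, 900L))
  t2 <- generate_traces(p, c(300L, 900L))
  expect_identical(t1$traces, t2$traces)
  e1 <- generate_conditioning_session(seed = 5)
  e2 <- generate_conditioning_session(seed = 5)
  expect_identical(e1, e2)
  f1 <- generate_footprints(20, seed = 6)
  expect_identical(f1, generate_footprints(20, seed = 6))
})

test_that("generated BA histogram is bimodal at the requested modes", {
  kin <- generate_kinematics(duration_s = 900, n_bouts = 60, rest_g = 0.02,
                             move_g = 0.10, seed = 8)
  h <- hist(kin$record$ba_g, breaks = 60, plot = FALSE)
  d <- h$density
  # local maxima of the raw histogram
  peaks <- which(diff(sign(diff(d))) == -2) + 1
  modes <- h$mids[peaks[order(d[peaks], decreasing = TRUE)][1:2]]
  expect_true(min(abs(sort(modes) - 0.02)) < 0.01)
  expect_true(max(sort(modes)) > 0.08 && max(sort(modes)) < 0.12)
  # axis decomposition preserves the norm exactly
  r <- kin$record
  expect_equal(sqrt(r$ap_g^2 + r$ml_g^2 + r$dv_g^2), r$ba_g)
})

test_that("generate_kinematics rejects non-positive mode separation", {
  expect_error(generate_kinematics(duration_s = 120, rest_g = 0.1,
                                   move_g = 0.05),
               "must exceed")
  expect_error(generate_kinematics(duration_s = 30), ">= 60")
})

test_that("a single noiseless transient reproduces the decay kernel exactly", {
  # force exactly one transient via the coupling mechanism: one event,
  # coupling probability 1, negligible spontaneous rate, zero noise
  p <- synth_params(duration_s = 60, fs = 15, n_neurons = 1, noise_sd = 0,
                    tau_s = 0.6, base_rate_hz = 1e-12, frac_responsive = 0,
                    amp_mean = 0.7, amp_sd = 0, shared_coactivation_p = 1,
                    seed = 2)
  tr <- generate_traces(p, 100L, coupled_ids = 1L)
  sp <- tr$spikes[[1]]
  expect_length(sp, 1)
  x <- tr$traces[, 1]
  expect_true(all(x[seq_len(sp - 1)] == 0))
  expect_equal(x[sp], 0.7) # instantaneous (1-frame) rise to full amplitude
  post <- 0:30
  expect_equal(x[sp + post], 0.7 * exp(-post / (0.6 * 15)), tolerance = 1e-12)
})

test_that("transient counts match the Poisson expectation", {
  p <- synth_params(duration_s = 1800, n_neurons = 100, frac_responsive = 0,
                    base_rate_hz = 0.05, seed = 11)
  tr <- generate_traces(p, integer(0))
  counts <- lengths(tr$spikes)
  # total count within 3 SD of 0.05 * 1800 per neuron
  lambda <- 0.05 * 1800
  expect_true(all(abs(counts - lambda) < 3 * sqrt(lambda) + 3))
  # chi-square goodness of fit of the per-neuron counts against Poisson(lambda)
  brk <- c(-0.5, lambda + sqrt(lambda) * c(-2, -1, 0, 1, 2) + 0.5, Inf)
  obs <- as.numeric(table(cut(counts, brk)))
  expd <- diff(stats::ppois(brk, lambda))
  chi <- suppressWarnings(stats::chisq.test(obs, p = expd, rescale.p = TRUE))
  expect_gt(chi$p.value, 0.01)
})

test_that("post-event transient rate reflects the positive gain", {
  p <- synth_params(duration_s = 3600, n_neurons = 30, frac_responsive = 1,
                    frac_negative = 0, gain_pos = 4, base_rate_hz = 0.1,
                    seed = 12)
  onsets <- spaced_onsets(100, 3600 * 15)
  tr <- generate_traces(p, onsets)
  post <- pre <- 0
  for (sp in tr$spikes) {
    for (f in onsets) {
      post <- post + sum(sp > f & sp <= f + 15)
      pre <- pre + sum(sp > f - 15 & sp <= f)
    }
  }
  ratio <- post / pre
  expect_true(abs(ratio - 4) < 4 * 3 * sqrt(1 / post + 1 / pre))
})

test_that("gain validation rejects inconsistent modulation requests", {
  expect_error(
    make_ground_truth(synth_params(gain_neg = 1.5, frac_negative = 0.5)),
    "gain_neg")
  expect_error(
    make_ground_truth(synth_params(gain_pos = 0.5, frac_negative = 0)),
    "gain_pos")
})

test_that("conditioning sessions have the paradigm's structure", {
  ev <- generate_conditioning_session(seed = 3)
  cues <- ev[ev$type %in% c("cs_plus", "cs_minus"), ]
  expect_equal(nrow(cues), 42)
  expect_true(all(cues$duration_s == 10))
  expect_equal(sum(cues$type == "cs_plus"), 21)
  # pseudo-random: at most 3 consecutive same-cue trials
  expect_lte(max(rle(cues$type[order(cues$trial)])$lengths), 3)
  # rewards follow CS+ only
  expect_equal(sum(ev$type == "reward"), 21)
  # extinction mode emits no rewards
  ext <- generate_conditioning_session(extinction = TRUE, seed = 3)
  expect_equal(sum(ext$type == "reward"), 0)
  expect_error(generate_conditioning_session(n_trials = 7), "even")
})

test_that("footprints respect field bounds and minimum separation", {
  cen <- generate_footprints(100, min_sep_um = 15, seed = 4)
  expect_true(all(cen$x_um >= 0 & cen$x_um <= 600))
  expect_true(all(cen$y_um >= 0 & cen$y_um <= 900))
  d <- stats::dist(cbind(cen$x_um, cen$y_um))
  expect_true(min(d) >= 15)
  expect_error(generate_footprints(100, fov_um = c(20, 20), min_sep_um = 15,
                                   max_tries = 50),
               "cannot place")
})

test_that("neuropil field correlation falls with distance", {
  cen <- tibble::tibble(x_um = c(0, 50, 400), y_um = c(0, 0, 0))
  np <- generate_neuropil_traces(cen, 3000, fov_um = c(500, 100),
                                 corr_len_um = 200, seed = 5)
  expect_gt(cor(np[, 1], np[, 2]), cor(np[, 1], np[, 3]))
})

test_that("independent recruitment draws overlap at the product rate", {
  p <- synth_params(n_neurons = 4000, frac_responsive = 0.22, seed = 6)
  g1 <- make_ground_truth(p, seed = 61)
  p2 <- synth_params(n_neurons = 4000, frac_responsive = 0.27, seed = 6)
  g2 <- make_ground_truth(p2, seed = 62)
  both <- mean(g1$responsive & g2$responsive)
  se <- sqrt(0.0594 * (1 - 0.0594) / 4000)
  expect_lt(abs(both - 0.22 * 0.27), 3 * se)
})
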