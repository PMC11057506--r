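# shared in-code fixtures for the test suite

# a disc ROI mask of given radius centered in a square image
disc_mask <- function(radius_px, size_px = 4 * radius_px + 21) {
  m <- matrix(FALSE, size_px, size_px)
  c0 <- (size_px + 1) / 2
  m[(col(m) - c0)^2 + (row(m) - c0)^2 <= radius_px^2] <- TRUE
  m
}

# evenly spaced event onsets inside a session
spaced_onsets <- function(n_events, n_frames, margin = 200L) {
  as.integer(round(seq(margin, n_frames - margin, length.out = n_events)))
}

# irregularly spaced onsets with a minimum gap, as in real behavior;
# regular spacing would make circular-shift nulls degenerate
random_onsets <- function(n_events, n_frames, min_gap = 60L, margin = 200L,
                          seed = 1) {
  withr::with_seed(seed, {
    slots <- sort(sample.int(n_frames - 2L * margin - n_events * min_gap,
                             n_events))
    as.integer(margin + slots + min_gap * (seq_len(n_events) - 1L))
  })
}

# a quick modulated-session bundle of spike trains (ground-truth transient
# frames), for event-stats and JPSTH tests
quick_trains <- function(n_neurons = 10, n_events = 100, gain = 4,
                         duration_s = 1800, base_rate_hz = 0.1, seed = 1) {
  p <- synth_params(duration_s = duration_s, n_neurons = n_neurons,
                    frac_responsive = as.numeric(gain > 1), frac_negative = 0,
                    gain_pos = max(gain, 2), base_rate_hz = base_rate_hz,
                    seed = seed)
  onsets <- random_onsets(n_events, as.integer(duration_s * 15), seed = seed)
  tr <- generate_traces(p, onsets)
  list(params = p, onsets = onsets, traces = tr$traces, spikes = tr$spikes,
       ground_truth = tr$ground_truth, n_frames = as.integer(duration_s * 15))
}
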