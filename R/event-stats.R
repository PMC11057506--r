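# window convention: an ETA/PSTH of span `window_s` has
# pre = ceiling(window_s * fs / 2) frames before the onset and
# post = window_s * fs - pre frames after, i.e. window_s * fs + 1 samples.
eta_lags <- function(window_s, fs) {
  total <- as.integer(round(window_s * fs))
  pre <- as.integer(ceiling(total / 2))
  (-pre):(total - pre)
}

# events whose full window lies inside [1, n_frames]
usable_events <- function(onset_frames, lags, n_frames) {
  onset_frames[onset_frames + lags[1] >= 1 &
                 onset_frames + lags[length(lags)] <= n_frames]
}

#' Event-triggered average of a continuous trace
#'
#' Averages the trace across repetitions of a behavioral event, in a window
#' of total span `window_s` seconds around each onset (5 or 10 s windows are
#' the common choices). Events whose window extends beyond the session are
#' dropped and counted.
#'
#' @param trace Numeric per-frame trace (dF/F or acceleration).
#' @param onset_frames Integer event-onset frames (1-based).
#' @param fs Frame rate (frames/s).
#' @param window_s Total window span (s), centered on the onset.
#' @return A tibble of class `strical_eta` with `lag_s`, `mean`, `sem`,
#'   and attributes `n_events`, `n_dropped`, `fs`, `window_s`.
#' @export
compute_eta <- function(trace, onset_frames, fs = 15, window_s = 5) {
  lags <- eta_lags(window_s, fs)
  ev <- usable_events(onset_frames, lags, length(trace))
  dropped <- length(onset_frames) - length(ev)
  if (!length(ev)) abort("no usable events after edge handling.")
  idx <- outer(ev, lags, "+")
  m <- matrix(trace[idx], length(ev), length(lags))
  out <- tibble(
    lag_s = lags / fs,
    mean = colMeans(m),
    sem = apply(m, 2, sd) / sqrt(length(ev))
  )
  class(out) <- c("strical_eta", class(out))
  attr(out, "n_events") <- length(ev)
  attr(out, "n_dropped") <- dropped
  attr(out, "fs") <- fs
  attr(out, "window_s") <- window_s
  out
}

#' Peristimulus time histogram of detected transients
#'
#' Counts detected calcium transients in fixed-width bins (one 67 ms frame
#' by default) around event onsets, pooled across trials. For a population
#' PSTH pass a list of per-neuron transient-frame vectors; counts are then
#' also pooled across neurons.
#'
#' @param trains Integer vector of transient frames for one neuron, or a
#'   list of such vectors for a population.
#' @param onset_frames Integer event-onset frames.
#' @param fs Frame rate.
#' @param window_s Total window span (s).
#' @param bin_s Bin width (s); the default is one frame (about 67 ms).
#' @return A tibble with `lag_s` (bin start relative to onset), `count`, and
#'   `rate` (events per second per trial, and per neuron if a list was
#'   given); attributes `n_events`, `n_trains`, `bin_s`.
#' @export
compute_psth <- function(trains, onset_frames, fs = 15, window_s = 5,
                         bin_s = 1 / fs) {
  if (!is.list(trains)) trains <- list(trains)
  lags <- eta_lags(window_s, fs)
  bin_frames <- max(1L, as.integer(round(bin_s * fs)))
  n_bins <- length(lags) %/% bin_frames
  if (!length(onset_frames)) abort("no events.")
  counts <- numeric(n_bins)
  for (tr in trains) {
    if (!length(tr)) next
    for (f in onset_frames) {
      rel <- tr - f - lags[1] # 0-based offset into the window
      rel <- rel[rel >= 0 & rel < n_bins * bin_frames]
      if (length(rel)) {
        b <- rel %/% bin_frames
        tb <- tabulate(b + 1L, n_bins)
        counts <- counts + tb
      }
    }
  }
  out <- tibble(
    lag_s = (lags[1] + bin_frames * (seq_len(n_bins) - 1L)) / fs,
    count = counts,
    rate = counts / (length(onset_frames) * length(trains) * bin_frames / fs)
  )
  attr(out, "n_events") <- length(onset_frames)
  attr(out, "n_trains") <- length(trains)
  attr(out, "bin_s") <- bin_frames / fs
  out
}

# the bootstrap area statistic: area between the ETA and its
# `q`-quantile threshold line over the single longest supra-threshold run
eta_area_statistic <- function(eta_mean, q = 0.85) {
  thr <- quantile(eta_mean, q, names = FALSE)
  above <- eta_mean > thr
  if (!any(above)) {
    return(list(area = 0, run = integer(0), threshold = thr))
  }
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  best <- runs[which.max(r$lengths[runs])]
  run <- starts[best]:ends[best]
  list(area = sum(eta_mean[run] - thr), run = run, threshold = thr)
}

#' Circular-shift bootstrap test of event-locked modulation
#'
#' Tests whether a neuron significantly modulates its signal around a
#' behavioral event. The observed statistic is computed from the ETA: the
#' ETA's 85th-percentile value is taken as a threshold, the single longest
#' run of consecutive frames above the threshold is found, and the area
#' between the ETA and the threshold line over that run is the statistic.
#' The null distribution is built by circularly shifting the full-session
#' trace by a uniformly random number of frames, recomputing the ETA around
#' the same event times, and recomputing the statistic, 2,000 (or 5,000)
#' times. The p-value uses the add-one estimator
#' `p = (1 + #(null >= observed)) / (1 + n_null)`.
#'
#' An optional two-sided variant additionally scores the area below the
#' matching low quantile and takes the larger of the two areas as the
#' statistic; it is off by default.
#'
#' @param trace Full-session numeric trace.
#' @param onset_frames Integer event-onset frames.
#' @param fs Frame rate.
#' @param window_s ETA window span (s).
#' @param n_null Number of circular shifts (2000 or 5000 typical).
#' @param alpha Significance level.
#' @param threshold_q Quantile defining the threshold line (0.85).
#' @param two_sided If `TRUE`, also test downward excursions.
#' @param seed Integer seed for the random shifts.
#' @return A list of class `strical_bootstrap`: `observed`, `null_areas`,
#'   `p_value`, `significant`, `threshold`, `run_lags` (frames of the
#'   longest run, relative to onset), `eta`, `n_events`, `degenerate`.
#' @export
bootstrap_significance <- function(trace, onset_frames, fs = 15, window_s = 5,
                                   n_null = 2000, alpha = 0.05,
                                   threshold_q = 0.85, two_sided = FALSE,
                                   seed = 1L) {
  n <- length(trace)
  lags <- eta_lags(window_s, fs)
  if (n <= 4 * length(lags)) abort("session too short for the ETA window.")
  ev <- usable_events(onset_frames, lags, n)
  if (!length(ev)) abort("no usable events after edge handling.")
  idx0 <- outer(ev, lags, "+") # index matrix for the unshifted ETA
  eta_obs <- colMeans(matrix(trace[idx0], length(ev), length(lags)))
  stat_fun <- function(em) {
    s <- eta_area_statistic(em, threshold_q)
    if (!two_sided) return(s)
    s2 <- eta_area_statistic(-em, 1 - (1 - threshold_q))
    if (s2$area > s$area) {
      s2$threshold <- -s2$threshold
      return(s2)
    }
    s
  }
  obs <- stat_fun(eta_obs)
  degenerate <- sd(eta_obs) == 0
  if (degenerate) {
    return(structure(
      list(observed = 0, null_areas = numeric(0), p_value = 1,
           significant = FALSE, threshold = obs$threshold,
           run_lags = integer(0), eta = eta_obs, lag_s = lags / fs,
           n_events = length(ev), degenerate = TRUE),
      class = "strical_bootstrap"
    ))
  }
  # circularly shifting the trace by s and reading at the original event
  # frames equals reading the original trace at indices shifted by -s
  null_areas <- with_seed(seed, {
    shifts <- sample.int(n - 1L, n_null, replace = TRUE)
    idx0m1 <- idx0 - 1L # 0-based, shifted with %% n
    vapply(shifts, function(s) {
      em <- colMeans(matrix(trace[((idx0m1 - s) %% n) + 1L],
                            nrow(idx0), ncol(idx0)))
      stat_fun(em)$area
    }, numeric(1))
  })
  p <- (1 + sum(null_areas >= obs$area)) / (1 + n_null)
  structure(
    list(observed = obs$area, null_areas = null_areas, p_value = p,
         significant = p < alpha, threshold = obs$threshold,
         run_lags = lags[obs$run], eta = eta_obs, lag_s = lags / fs,
         n_events = length(ev), degenerate = FALSE),
    class = "strical_bootstrap"
  )
}

#' @export
print.strical_bootstrap <- function(x, ...) {
  cat(sprintf(
    "circular-shift bootstrap: area = %.3g, p = %.4g (%s; %d events, %d shuffles)\n",
    x$observed, x$p_value, if (x$significant) "significant" else "n.s.",
    x$n_events, length(x$null_areas)))
  invisible(x)
}

#' Classify a significant response as positively or negatively modulated
#'
#' Compares the mean of the ETA over the 1 s immediately after event onset
#' with the mean over the 1 s immediately before. A larger post-onset mean
#' gives a positive label, otherwise negative. An exact tie is labeled
#' positive with a warning.
#'
#' @param eta A `strical_eta` (from [compute_eta()]) or a list/tibble with
#'   `lag_s` and `mean`.
#' @return `"positive"` or `"negative"`.
#' @export
classify_modulation <- function(eta) {
  lag_s <- eta$lag_s
  m <- eta$mean
  if (min(lag_s) > -1 + 1e-9 || max(lag_s) < 1 - 1e-9) {
    abort("ETA must span at least 1 s on each side of the onset.")
  }
  post <- mean(m[lag_s > 0 & lag_s <= 1])
  pre <- mean(m[lag_s >= -1 & lag_s < 0])
  if (post == pre) {
    warn("pre/post means tie exactly; labeling positive.")
    return("positive")
  }
  if (post > pre) "positive" else "negative"
}

#' Within-session response reliability of a positively modulated neuron
#'
#' The fraction of behavioral events after which the neuron produced at
#' least one detected calcium transient within a 1 s window following the
#' event onset. The analysis is meant for neurons already labeled as
#' significantly positively modulated for this event type.
#'
#' @param train Integer transient frames for the neuron.
#' @param onset_frames Integer event-onset frames.
#' @param fs Frame rate.
#' @param window_s Post-onset window (s).
#' @return A fraction in [0, 1].
#' @export
response_reliability <- function(train, onset_frames, fs = 15, window_s = 1) {
  if (!length(onset_frames)) abort("no events.")
  w <- as.integer(floor(window_s * fs))
  hit <- vapply(onset_frames, function(f)
    any(train > f & train <= f + w), logical(1))
  mean(hit)
}

#' Per-event population recruitment
#'
#' For each repetition of a behavioral event, the fraction of the imaged
#' neurons that produced at least one calcium transient in a 1.5 s window
#' following the event onset.
#'
#' @param trains List of per-neuron transient-frame vectors.
#' @param onset_frames Integer event-onset frames.
#' @param fs Frame rate.
#' @param window_s Post-onset window (s); 1.5 s spans 22 frames at 15
#'   frames/s (floor).
#' @return A tibble with `event`, `onset_frame`, `fraction_active`.
#' @export
population_recruitment <- function(trains, onset_frames, fs = 15,
                                   window_s = 1.5) {
  if (!length(trains)) abort("no neurons.")
  w <- as.integer(floor(window_s * fs))
  frac <- vapply(onset_frames, function(f) {
    mean(vapply(trains, function(tr) any(tr > f & tr <= f + w), logical(1)))
  }, numeric(1))
  tibble(event = seq_along(onset_frames),
         onset_frame = as.integer(onset_frames),
         fraction_active = frac)
}

#' Expected cross-session overlap under independent recruitment
#'
#' If neurons are recruited independently in each session with per-session
#' responsive probabilities `p`, the expected fraction responsive in every
#' session is `prod(p)` (e.g. 22% and 27% marginals give 5.94%, i.e. 6% to
#' the nearest percent). The full profile — probability of being significant
#' in exactly j of the k sessions — is the Poisson-binomial distribution of
#' the per-session indicators.
#'
#' @param p Numeric vector of per-session responsive probabilities (each in
#'   [0, 1]); length k >= 1.
#' @return A list with `all_sessions` (= `prod(p)`) and `profile`, a tibble
#'   with `n_sessions` (j = 0..k) and `prob`.
#' @export
expected_overlap_independent <- function(p) {
  if (any(p < 0 | p > 1)) abort("probabilities must be in [0, 1].")
  # Poisson-binomial by polynomial convolution
  poly <- 1
  for (pi in p) poly <- stats::convolve(poly, rev(c(1 - pi, pi)), type = "open")
  poly <- pmax(poly, 0)
  list(
    all_sessions = prod(p),
    profile = tibble(n_sessions = seq_along(poly) - 1L, prob = poly)
  )
}

#' Observed overlap of responsive neurons across two sessions
#'
#' Over the cells registered in both sessions, the fractions responsive in
#' the first only, the second only, both, or neither, optionally compared
#' with the independent-recruitment expectation for the "both" category.
#'
#' @param registry A data frame with one row per registered cell and logical
#'   columns `responsive_a` and `responsive_b`.
#' @return A tibble with `category` (`a_only`, `b_only`, `both`, `neither`),
#'   `n`, `fraction`; the independence expectation `prod(marginals)` is in
#'   attribute `expected_both`.
#' @export
session_overlap <- function(registry) {
  registry <- as_tibble(registry)
  if (!nrow(registry)) abort("empty registry.")
  if (!all(c("responsive_a", "responsive_b") %in% names(registry))) {
    abort("`registry` needs logical columns responsive_a, responsive_b.")
  }
  a <- registry$responsive_a
  b <- registry$responsive_b
  n <- nrow(registry)
  out <- tibble(
    category = c("a_only", "b_only", "both", "neither"),
    n = c(sum(a & !b), sum(!a & b), sum(a & b), sum(!a & !b))
  )
  out$fraction <- out$n / n
  attr(out, "expected_both") <- mean(a) * mean(b)
  out
}

#' Filter a cross-session cell-registration table
#'
#' Keeps a registered cell only if the registration confidence `p_same`
#' exceeds 0.5 and the centroid distance across sessions is strictly below
#' 14 micrometers.
#'
#' @param registry A data frame with numeric columns `p_same` and
#'   `centroid_distance_um`.
#' @param p_same_min Minimum (exclusive) registration probability.
#' @param max_distance_um Maximum (exclusive) centroid distance (um).
#' @return The accepted rows as a tibble.
#' @export
filter_registration <- function(registry, p_same_min = 0.5,
                                max_distance_um = 14) {
  registry <- as_tibble(registry)
  if (!all(c("p_same", "centroid_distance_um") %in% names(registry))) {
    abort("`registry` needs columns p_same and centroid_distance_um.")
  }
  registry[registry$p_same > p_same_min &
             registry$centroid_distance_um < max_distance_um, ]
}

#' Split-half consistency of event-locked significance
#'
#' Runs the circular-shift bootstrap separately on two halves of the trials
#' (odd/even trial indices, or first/last halves) and reports each half's
#' significance, for assessing within-session consistency of recruitment.
#'
#' @param trace Full-session trace.
#' @param onset_frames Integer event-onset frames (trial order).
#' @param scheme `"odd_even"` or `"first_last"`.
#' @param ... Passed to [bootstrap_significance()] (fs, window_s, n_null,
#'   alpha, seed, ...).
#' @return A tibble with one row per split: `split`, `n_events`, `p_value`,
#'   `significant`; attribute `both` is `TRUE` when both halves are
#'   significant.
#' @export
split_half_consistency <- function(trace, onset_frames,
                                   scheme = c("odd_even", "first_last"),
                                   ...) {
  scheme <- match.arg(scheme)
  n <- length(onset_frames)
  if (n < 8) abort("need at least 8 trials for a split-half analysis.")
  idx <- seq_len(n)
  halves <- if (scheme == "odd_even") {
    list(idx[idx %% 2 == 1], idx[idx %% 2 == 0])
  } else {
    list(idx[idx <= n / 2], idx[idx > n / 2])
  }
  names(halves) <- if (scheme == "odd_even") c("odd", "even") else
    c("first", "last")
  res <- purrr::imap(halves, function(h, nm) {
    b <- bootstrap_significance(trace, onset_frames[h], ...)
    tibble(split = nm, n_events = b$n_events, p_value = b$p_value,
           significant = b$significant)
  })
  out <- dplyr::bind_rows(res)
  attr(out, "both") <- all(out$significant)
  out
}

#' Flag outliers by the 1.5-IQR rule
#'
#' A value is an outlier if it lies more than 1.5 interquartile ranges above
#' the upper quartile or below the lower quartile.
#'
#' @param values Numeric vector (at least 4 values).
#' @return Logical vector of flags.
#' @export
flag_outliers <- function(values) {
  if (length(values) < 4) abort("need at least 4 values.")
  q <- quantile(values, c(0.25, 0.75), names = FALSE, na.rm = TRUE)
  iqr <- q[2] - q[1]
  values > q[2] + 1.5 * iqr | values < q[1] - 1.5 * iqr
}
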