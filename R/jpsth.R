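# Joint peristimulus time histograms with shift-predictor correction.
# Bins are one 67 ms imaging frame wide by default; at that width a bin can
# hold at most one detected transient, so trial matrices are 0/1 indicators.

#' Binarize a transient train into a trial x bin indicator matrix
#'
#' Each repetition of the behavioral event is one trial. A bin is 1 when
#' the neuron produced at least one detected transient in that bin of that
#' trial. Trials whose window extends past the session are dropped (with a
#' message in the `n_dropped` attribute).
#'
#' @param train Integer transient frames for one neuron.
#' @param onset_frames Integer event-onset frames (>= 2 usable).
#' @param n_frames Session length in frames.
#' @param fs Frame rate.
#' @param window_s Total window span (s) centered on the onset.
#' @param bin_s Bin width (s); default one frame (about 67 ms).
#' @return An object of class `strical_trials`: an integer 0/1 matrix
#'   (trials x bins) with attributes `lag_s` (bin start lags), `bin_s`,
#'   `fs`, `onset_frames`, `n_dropped`.
#' @export
binarize_trials <- function(train, onset_frames, n_frames, fs = 15,
                            window_s = 5, bin_s = 1 / fs) {
  lags <- eta_lags(window_s, fs)
  bin_frames <- max(1L, as.integer(round(bin_s * fs)))
  n_bins <- length(lags) %/% bin_frames
  ev <- usable_events(onset_frames, lags, n_frames)
  n_dropped <- length(onset_frames) - length(ev)
  if (length(ev) < 2) abort("need at least 2 usable trials.")
  tm <- matrix(0L, length(ev), n_bins)
  for (t in seq_along(ev)) {
    rel <- train - ev[t] - lags[1]
    rel <- rel[rel >= 0 & rel < n_bins * bin_frames]
    if (length(rel)) tm[t, unique(rel %/% bin_frames) + 1L] <- 1L
  }
  structure(tm,
            lag_s = (lags[1] + bin_frames * (seq_len(n_bins) - 1L)) / fs,
            bin_s = bin_frames / fs, fs = fs, onset_frames = ev,
            n_dropped = n_dropped, class = c("strical_trials", "matrix"))
}

#' Raw JPSTH of a neuron pair
#'
#' Entry (t1, t2) is the number of trials in which neuron 1 produced a
#' transient in bin t1 and neuron 2 produced a transient in bin t2.
#'
#' @param tm1,tm2 Trial matrices from [binarize_trials()], with equal trial
#'   counts and windows.
#' @return A bins x bins numeric matrix.
#' @export
raw_jpsth <- function(tm1, tm2) {
  if (!all(dim(tm1) == dim(tm2))) abort("trial matrices differ in shape.")
  crossprod(unclass(tm1), unclass(tm2))
}

#' Shift-predictor JPSTH of a neuron pair
#'
#' The JPSTH expected from trial-shuffled data: trial n of neuron 1 is
#' paired with trial n + m of neuron 2 (circularly), the raw JPSTH is
#' computed for each nonzero shift m = 1..N-1, and the matrices are
#' averaged. Subtracting the predictor removes correlation explained by
#' common event-locked rate modulation.
#'
#' @inheritParams raw_jpsth
#' @return A bins x bins numeric matrix.
#' @details Summing the raw JPSTH over all N circular shifts (including the
#'   identity) factorizes exactly into the outer product of the two
#'   neurons' per-bin trial counts, so the average over the N-1 nonzero
#'   shifts is computed in closed form as
#'   `(outer(colSums(tm1), colSums(tm2)) - raw) / (N - 1)`; this equals the
#'   explicit shift-and-average loop bin for bin.
#' @export
shift_predictor <- function(tm1, tm2) {
  if (!all(dim(tm1) == dim(tm2))) abort("trial matrices differ in shape.")
  n <- nrow(tm1)
  if (n < 2) abort("need at least 2 trials.")
  m1 <- unclass(tm1); m2 <- unclass(tm2)
  (outer(colSums(m1), colSums(m2)) - crossprod(m1, m2)) / (n - 1)
}

# 2-D Gaussian smoothing, separable, kernel truncated at 3 SD,
# renormalized at the edges so the effective kernel always sums to 1
gauss_smooth_2d <- function(m, sd_bins = 1) {
  if (sd_bins <= 0) return(m)
  half <- as.integer(ceiling(3 * sd_bins))
  k <- dnorm(-half:half, sd = sd_bins)
  smooth_1d <- function(v) {
    n <- length(v)
    out <- numeric(n)
    for (i in seq_len(n)) {
      lo <- max(1L, i - half); hi <- min(n, i + half)
      w <- k[(lo - i + half + 1L):(hi - i + half + 1L)]
      out[i] <- sum(v[lo:hi] * w) / sum(w)
    }
    out
  }
  m <- apply(m, 2, smooth_1d)
  t(apply(m, 1, smooth_1d))
}

#' Corrected JPSTH
#'
#' Subtracts the shift predictor bin by bin from the raw JPSTH and smooths
#' the difference with a two-dimensional Gaussian window with a 1-bin SD
#' (kernel truncated at 3 SD, renormalized at the matrix edges).
#'
#' @param raw,predictor Matrices of equal shape.
#' @param smooth_sd_bins Gaussian SD in bins (0 disables smoothing).
#' @return The corrected matrix.
#' @export
corrected_jpsth <- function(raw, predictor, smooth_sd_bins = 1) {
  if (!all(dim(raw) == dim(predictor))) abort("matrices differ in shape.")
  gauss_smooth_2d(raw - predictor, smooth_sd_bins)
}

#' Normalize a corrected JPSTH by the SDs of the pair's PSTHs
#'
#' Divides the corrected JPSTH by the product of the standard deviations of
#' the two neurons' PSTH curves, making the matrix unitless so its values
#' do not depend on the bin width. An alternative classical normalization
#' by the per-bin across-trial SDs of the two trial matrices is available
#' behind `per_bin = TRUE` for sensitivity analyses.
#'
#' @param corrected Corrected JPSTH matrix.
#' @param tm1,tm2 The pair's trial matrices (PSTHs are their per-bin counts).
#' @param per_bin If `TRUE`, normalize entry (t1, t2) by
#'   `sd(tm1[, t1]) * sd(tm2[, t2])` instead of the scalar PSTH SDs.
#' @return The normalized matrix.
#' @section Errors: A zero PSTH SD (a neuron with no transient-count
#'   variation across bins) signals class `strical_zero_sd`; such pairs are
#'   excluded upstream.
#' @export
normalize_jpsth <- function(corrected, tm1, tm2, per_bin = FALSE) {
  if (per_bin) {
    s1 <- apply(unclass(tm1), 2, sd)
    s2 <- apply(unclass(tm2), 2, sd)
    den <- outer(s1, s2)
    if (any(den == 0)) abort("zero per-bin SD.", class = "strical_zero_sd")
    return(corrected / den)
  }
  psth1 <- colSums(unclass(tm1))
  psth2 <- colSums(unclass(tm2))
  s <- sd(psth1) * sd(psth2)
  if (s == 0) abort("zero PSTH SD for this pair.", class = "strical_zero_sd")
  corrected / s
}

#' Full JPSTH of one pair of transient trains
#'
#' Convenience wrapper producing the raw, shift-predictor, corrected and
#' normalized matrices for one neuron pair around one event type.
#'
#' @param train1,train2 Integer transient frames of the two neurons.
#' @param onset_frames Integer event onsets.
#' @param n_frames Session length in frames.
#' @param fs Frame rate.
#' @param window_s Window span (s).
#' @param bin_s Bin width (s).
#' @param smooth_sd_bins Gaussian smoothing SD (bins).
#' @param per_bin Normalization variant, see [normalize_jpsth()].
#' @return A list of class `strical_jpsth` with `raw`, `predictor`,
#'   `corrected`, `normalized`, `lag_s`, `n_trials`, `bin_s`.
#' @export
jpsth_pair <- function(train1, train2, onset_frames, n_frames, fs = 15,
                       window_s = 5, bin_s = 1 / fs, smooth_sd_bins = 1,
                       per_bin = FALSE) {
  tm1 <- binarize_trials(train1, onset_frames, n_frames, fs, window_s, bin_s)
  tm2 <- binarize_trials(train2, onset_frames, n_frames, fs, window_s, bin_s)
  raw <- raw_jpsth(tm1, tm2)
  pred <- shift_predictor(tm1, tm2)
  corr <- corrected_jpsth(raw, pred, smooth_sd_bins)
  norm <- normalize_jpsth(corr, tm1, tm2, per_bin = per_bin)
  structure(
    list(raw = raw, predictor = pred, corrected = corr, normalized = norm,
         lag_s = attr(tm1, "lag_s"), n_trials = nrow(tm1),
         bin_s = attr(tm1, "bin_s")),
    class = "strical_jpsth"
  )
}

#' Population JPSTH
#'
#' Elementwise mean of the normalized corrected JPSTHs of a set of pairs
#' (all pairs, or a modulation-defined subgroup such as positively
#' modulated pairs only).
#'
#' @param jpsths A list of `strical_jpsth` objects (or of normalized
#'   matrices) sharing the same window and bin width.
#' @return A list of class `strical_pop_jpsth` with `matrix`, `lag_s`,
#'   `n_pairs`.
#' @export
population_jpsth <- function(jpsths) {
  if (!length(jpsths)) abort("empty pair list.")
  mats <- lapply(jpsths, function(j)
    if (inherits(j, "strical_jpsth")) j$normalized else j)
  lag_s <- if (inherits(jpsths[[1]], "strical_jpsth")) jpsths[[1]]$lag_s else
    attr(jpsths[[1]], "lag_s")
  acc <- Reduce(`+`, mats) / length(mats)
  structure(list(matrix = acc, lag_s = lag_s, n_pairs = length(mats)),
            class = "strical_pop_jpsth")
}

#' Diagonal statistics of a population JPSTH
#'
#' The diagonal of the population JPSTH tracks zero-lag noise correlation
#' over time relative to the event. Random fluctuations are gauged from a
#' baseline JPSTH computed around surrogate events displaced by a random
#' shift of at least `far_shift_s` from the real ones, over a
#' `baseline_window_s` window: the baseline band is the mean +/- SD of that
#' diagonal. The statistics compared across sessions are the maximal
#' diagonal value in the 0.5 s window preceding the onset (baseline peak)
#' and in the 1.5 s window immediately following it (post peak).
#'
#' @param trains List of per-neuron transient-frame vectors.
#' @param onset_frames Integer event onsets.
#' @param n_frames Session length in frames.
#' @param pairs Two-column matrix or data frame of neuron index pairs to
#'   include.
#' @param fs Frame rate.
#' @param window_s JPSTH window span (s).
#' @param far_shift_s Minimum displacement of the surrogate events (s).
#' @param baseline_window_s Span of the far-removed window (s).
#' @param n_baseline_shifts Number of independent random displacements whose
#'   diagonals are pooled for the band estimate; a single 10 s placement
#'   gives a noisy SD, so several are averaged.
#' @param pre_peak_s Pre-onset peak window (s).
#' @param post_peak_s Post-onset peak window (s).
#' @param seed Integer seed for the random displacement.
#' @param ... Passed to [jpsth_pair()] (bin_s, smoothing, normalization).
#' @return A list of class `strical_diag_stats` with `diagonal` (tibble
#'   `lag_s`, `value`), `baseline_mean`, `baseline_sd`, `baseline_peak`,
#'   `post_peak`, `population` (the `strical_pop_jpsth`), `n_pairs`.
#' @export
diagonal_analysis <- function(trains, onset_frames, n_frames, pairs,
                              fs = 15, window_s = 5, far_shift_s = 20,
                              baseline_window_s = 10, pre_peak_s = 0.5,
                              post_peak_s = 1.5, n_baseline_shifts = 5,
                              seed = 1L, ...) {
  pairs <- as.matrix(pairs)
  if (n_frames <= 2 * far_shift_s * fs) {
    abort("session too short for the far-removed baseline window.")
  }
  # surrogate events: the same times displaced by random circular shifts of
  # at least far_shift_s; several placements are pooled for the band
  shifts <- with_seed(seed, {
    lo <- as.integer(far_shift_s * fs)
    sample(lo:(n_frames - lo), n_baseline_shifts, replace = TRUE)
  })
  event_js <- list()
  base_diags <- list()
  for (k in seq_len(nrow(pairs))) {
    t1 <- trains[[pairs[k, 1]]]
    t2 <- trains[[pairs[k, 2]]]
    j <- tryCatch(
      jpsth_pair(t1, t2, onset_frames, n_frames, fs = fs,
                 window_s = window_s, ...),
      strical_zero_sd = function(e) NULL
    )
    if (is.null(j)) next
    # the baseline matrix is normalized by the same per-pair denominator as
    # the event-aligned matrix so both are on one scale
    tm1e <- binarize_trials(t1, onset_frames, n_frames, fs, window_s)
    tm2e <- binarize_trials(t2, onset_frames, n_frames, fs, window_s)
    denom <- sd(colSums(unclass(tm1e))) * sd(colSums(unclass(tm2e)))
    bd <- lapply(seq_along(shifts), function(si) {
      surrogate <- ((as.integer(onset_frames) - 1L + shifts[si]) %%
                      n_frames) + 1L
      tm1b <- binarize_trials(t1, surrogate, n_frames, fs,
                              baseline_window_s)
      tm2b <- binarize_trials(t2, surrogate, n_frames, fs,
                              baseline_window_s)
      diag(corrected_jpsth(raw_jpsth(tm1b, tm2b),
                           shift_predictor(tm1b, tm2b))) / denom
    })
    event_js[[length(event_js) + 1L]] <- j
    base_diags[[length(base_diags) + 1L]] <- bd
  }
  if (!length(event_js)) abort("no usable pairs.")
  pop <- population_jpsth(event_js)
  # average over pairs within each placement, pool placements
  base_diag <- unlist(lapply(seq_len(n_baseline_shifts), function(si) {
    Reduce(`+`, lapply(base_diags, `[[`, si)) / length(base_diags)
  }))
  d <- diag(pop$matrix)
  lag <- pop$lag_s
  pre_idx <- lag >= -pre_peak_s & lag < 0
  post_idx <- lag >= 0 & lag < post_peak_s
  structure(
    list(
      diagonal = tibble(lag_s = lag, value = d),
      baseline_mean = mean(base_diag),
      baseline_sd = sd(base_diag),
      baseline_peak = max(d[pre_idx]),
      post_peak = max(d[post_idx]),
      population = pop,
      n_pairs = pop$n_pairs
    ),
    class = "strical_diag_stats"
  )
}

#' @export
print.strical_diag_stats <- function(x, ...) {
  cat(sprintf(
    "JPSTH diagonal: post peak %.3g vs baseline peak %.3g (band %.3g +/- %.3g, %d pairs)\n",
    x$post_peak, x$baseline_peak, x$baseline_mean, x$baseline_sd, x$n_pairs))
  invisible(x)
}
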