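#' Total body acceleration from a 3-axis accelerometer table
#'
#' Computes the total body acceleration (BA) as the elementwise Euclidean norm
#' of the anterio-posterior, mediolateral and dorsoventral head-acceleration
#' axes, in units of g.
#'
#' @param rec A data frame with numeric columns `ap_g`, `ml_g`, `dv_g` (and
#'   typically `time_s`), one row per accelerometer sample.
#' @return The input as a tibble with an added `ba_g` column.
#' @examples
#' rec <- tibble::tibble(time_s = 0, ap_g = 3, ml_g = 4, dv_g = 0)
#' total_body_acceleration(rec)$ba_g # 5
#' @export
total_body_acceleration <- function(rec) {
  rec <- as_tibble(rec)
  need <- c("ap_g", "ml_g", "dv_g")
  if (!all(need %in% names(rec))) {
    abort("`rec` must have columns ap_g, ml_g, dv_g.")
  }
  ns <- vapply(rec[need], length, integer(1))
  if (length(unique(ns)) != 1) abort("axis columns must have equal length.")
  rec$ba_g <- sqrt(rec$ap_g^2 + rec$ml_g^2 + rec$dv_g^2)
  rec
}

#' Movement/rest threshold from the bimodal BA histogram
#'
#' The distribution of total body acceleration in a session with both rest and
#' movement is bimodal: a sharp rest mode and a broader movement mode. The
#' movement threshold is the middle point between the two histogram peaks.
#' Peaks are located on a smoothed 100-bin histogram; the two highest local
#' maxima separated by at least `min_peak_sep` bins are taken as the modes.
#'
#' @param ba Numeric vector of total body acceleration values (g).
#' @param bins Number of histogram bins over the observed range.
#' @param smooth_bins Width (bins) of the moving-average smoother.
#' @param min_peak_sep Minimum separation (bins) between the two peaks.
#' @return An object of class `strical_threshold`: a list with `threshold`
#'   (g), `peaks_g` (the two mode locations), and `histogram` (a tibble with
#'   `mid_g`, `count`, `smoothed`) for audit.
#' @section Errors: Signals a condition of class `strical_bimodality_error`
#'   when fewer than two peaks are found; the caller may then supply a manual
#'   threshold to [segment_movement()].
#' @export
find_movement_threshold <- function(ba, bins = 100, smooth_bins = 5,
                                    min_peak_sep = 5) {
  ba <- as.numeric(ba)
  if (length(ba) < bins) abort("too few samples for a histogram.")
  h <- graphics::hist(ba, breaks = seq(min(ba), max(ba), length.out = bins + 1),
                      plot = FALSE)
  counts <- h$counts
  k <- rep(1 / smooth_bins, smooth_bins)
  sm <- as.numeric(stats::filter(counts, k, sides = 2))
  sm[is.na(sm)] <- 0
  # local maxima of the smoothed histogram (strict on the left, >= right)
  n <- length(sm)
  is_max <- c(FALSE, sm[2:(n - 1)] > sm[1:(n - 2)] &
                sm[2:(n - 1)] >= sm[3:n], FALSE)
  cand <- which(is_max)
  cand <- cand[order(sm[cand], decreasing = TRUE)]
  peaks <- integer(0)
  for (i in cand) {
    if (all(abs(i - peaks) >= min_peak_sep)) peaks <- c(peaks, i)
    if (length(peaks) == 2) break
  }
  # two genuine modes must be separated by a valley: the smoothed histogram
  # between them must drop below half the height of the lower peak
  if (length(peaks) == 2) {
    between <- (min(peaks) + 1):(max(peaks) - 1)
    if (!length(between) ||
        min(sm[between]) >= 0.5 * min(sm[peaks])) {
      peaks <- peaks[1]
    }
  }
  if (length(peaks) < 2) {
    abort("BA histogram is not bimodal; supply a manual threshold.",
          class = "strical_bimodality_error")
  }
  peaks_g <- sort(h$mids[peaks])
  structure(
    list(
      threshold = mean(peaks_g),
      peaks_g = peaks_g,
      histogram = tibble(mid_g = h$mids, count = counts, smoothed = sm)
    ),
    class = "strical_threshold"
  )
}

#' @export
print.strical_threshold <- function(x, ...) {
  cat(sprintf("movement threshold: %.4f g (modes at %.4f and %.4f g)\n",
              x$threshold, x$peaks_g[1], x$peaks_g[2]))
  invisible(x)
}

#' Segment movement bouts from a BA trace
#'
#' Frames with BA above the threshold are movement frames; frames below are
#' rest. Contiguous supra-threshold runs form movement bouts, with onset the
#' first supra-threshold frame and offset the last. Minimum bout length is
#' one frame.
#'
#' @param ba Numeric BA trace in g, one value per frame.
#' @param threshold Threshold in g (a number or a `strical_threshold`).
#' @param fs Frame rate (frames/s).
#' @return A tibble with one row per bout: `bout`, `onset_frame`,
#'   `offset_frame` (1-based, inclusive), `onset_s`, `offset_s`,
#'   `duration_s`. The threshold is stored in the `threshold` attribute and
#'   the per-frame movement state in the `moving` attribute.
#' @export
segment_movement <- function(ba, threshold, fs = 15) {
  if (inherits(threshold, "strical_threshold")) threshold <- threshold$threshold
  check_scalar(threshold, "threshold", positive = TRUE)
  moving <- ba > threshold
  r <- rle(moving)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  out <- tibble(
    bout = seq_len(sum(keep)),
    onset_frame = starts[keep],
    offset_frame = ends[keep]
  )
  out$onset_s <- frame_to_time(out$onset_frame, fs)
  out$offset_s <- frame_to_time(out$offset_frame, fs)
  out$duration_s <- (out$offset_frame - out$onset_frame + 1L) / fs
  attr(out, "threshold") <- threshold
  attr(out, "moving") <- moving
  out
}

#' Classify movement onsets by acceleration-change amplitude
#'
#' For each onset, the amplitude of the acceleration change is the maximal BA
#' value in a 2 s window following the onset minus the BA value at the onset.
#' Amplitudes are divided into session quartiles: quartile 1 events are
#' "small" and quartile 4 events "large" acceleration changes. The same
#' procedure applies to cue-presentation onsets.
#'
#' @param ba Numeric BA trace (g) at the imaging frame rate.
#' @param onset_frames Integer vector of onset frames (1-based).
#' @param fs Frame rate (frames/s).
#' @param window_s Post-onset window (s) searched for the maximum.
#' @return A tibble with `onset_frame`, `amplitude_g` and `quartile`
#'   (integer 1-4). Onsets whose window extends past the end of the session
#'   are dropped with a warning. Amplitudes on a quartile boundary are
#'   assigned to the lower quartile.
#' @export
classify_accel_change <- function(ba, onset_frames, fs = 15, window_s = 2) {
  w <- as.integer(round(window_s * fs))
  n <- length(ba)
  ok <- onset_frames + w <= n & onset_frames >= 1
  if (any(!ok)) {
    warn(sprintf("%d onset(s) dropped: %g s window exceeds session end.",
                 sum(!ok), window_s))
  }
  onset_frames <- onset_frames[ok]
  if (length(onset_frames) < 4) {
    abort("need at least 4 usable onsets to assign quartiles.")
  }
  amp <- vapply(onset_frames, function(f) {
    max(ba[f:(f + w)]) - ba[f]
  }, numeric(1))
  qs <- quantile(amp, c(0.25, 0.5, 0.75), names = FALSE)
  # boundary values fall in the lower quartile (<= on each boundary)
  quartile <- 1L + (amp > qs[1]) + (amp > qs[2]) + (amp > qs[3])
  tibble(onset_frame = as.integer(onset_frames),
         amplitude_g = amp, quartile = as.integer(quartile))
}
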