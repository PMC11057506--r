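#' Rest windows for pairwise-correlation analysis
#'
#' For every rest interval (between a movement offset and the next movement
#' onset, or the session end) lasting at least `min_rest_s`, emits one
#' window of `window_s` seconds starting `delay_s` after the preceding
#' movement termination.
#'
#' @param bouts Movement-bout tibble from [segment_movement()] (columns
#'   `onset_frame`, `offset_frame`).
#' @param n_frames Session length in frames.
#' @param fs Frame rate.
#' @param min_rest_s Minimum rest duration (s) for an interval to qualify.
#' @param delay_s Delay after movement offset before the window starts (s).
#' @param window_s Window length (s).
#' @return A tibble with `start_frame`, `end_frame` (inclusive), `start_s`,
#'   `end_s`; possibly empty.
#' @export
rest_windows <- function(bouts, n_frames, fs = 15, min_rest_s = 2.5,
                         delay_s = 0.25, window_s = 2) {
  if (!nrow(bouts)) {
    return(tibble(start_frame = integer(0), end_frame = integer(0),
                  start_s = numeric(0), end_s = numeric(0)))
  }
  rest_start <- bouts$offset_frame + 1L
  rest_end <- c(bouts$onset_frame[-1] - 1L, as.integer(n_frames))
  dur_s <- (rest_end - rest_start + 1L) / fs
  keep <- dur_s >= min_rest_s
  start <- rest_start[keep] + as.integer(round(delay_s * fs))
  len <- as.integer(round(window_s * fs))
  end <- start + len - 1L
  ok <- end <= rest_end[keep]
  start <- start[ok]; end <- end[ok]
  tibble(start_frame = start, end_frame = end,
         start_s = frame_to_time(start, fs), end_s = frame_to_time(end, fs))
}

#' Movement-onset windows for pairwise-correlation analysis
#'
#' A window of `window_s` seconds centered on each movement onset. Windows
#' extending beyond the session are dropped.
#'
#' @param onset_frames Integer movement-onset frames.
#' @param n_frames Session length in frames.
#' @param fs Frame rate.
#' @param window_s Total window length (s).
#' @return A tibble as in [rest_windows()].
#' @export
movement_windows <- function(onset_frames, n_frames, fs = 15, window_s = 2) {
  half <- as.integer(round(window_s / 2 * fs))
  start <- as.integer(onset_frames) - half
  end <- as.integer(onset_frames) + half
  ok <- start >= 1 & end <= n_frames
  start <- start[ok]; end <- end[ok]
  tibble(start_frame = start, end_frame = end,
         start_s = frame_to_time(start, fs), end_s = frame_to_time(end, fs))
}

#' Cue-presentation windows for pairwise-correlation analysis
#'
#' A window of `window_s` seconds starting at each cue onset.
#'
#' @inheritParams movement_windows
#' @return A tibble as in [rest_windows()].
#' @export
cue_windows <- function(onset_frames, n_frames, fs = 15, window_s = 2) {
  len <- as.integer(round(window_s * fs))
  start <- as.integer(onset_frames)
  end <- start + len - 1L
  ok <- start >= 1 & end <= n_frames
  start <- start[ok]; end <- end[ok]
  tibble(start_frame = start, end_frame = end,
         start_s = frame_to_time(start, fs), end_s = frame_to_time(end, fs))
}

#' Window-averaged pairwise signal correlations
#'
#' For each pair of neurons, computes the Pearson correlation between their
#' traces within each window and averages across windows, yielding one
#' correlation per pair. Windows in which either trace is constant have an
#' undefined correlation; they are skipped and counted. Pairs for which all
#' windows were skipped are omitted (with a warning).
#'
#' @param traces Frames x neurons numeric matrix.
#' @param windows Window tibble (from [rest_windows()],
#'   [movement_windows()] or [cue_windows()]).
#' @param centroids Optional tibble with `x_um`, `y_um` per neuron; when
#'   given, a `distance_um` column is attached per pair.
#' @return A tibble with `i`, `j` (neuron indices, i < j), `r` (mean
#'   correlation), `n_windows`, `n_skipped`, and optionally `distance_um`.
#' @export
pairwise_correlation <- function(traces, windows, centroids = NULL) {
  if (ncol(traces) < 2) abort("need at least 2 neurons.")
  if (!nrow(windows)) abort("need at least 1 window.")
  n <- ncol(traces)
  rs <- vector("list", nrow(windows))
  for (w in seq_len(nrow(windows))) {
    seg <- traces[windows$start_frame[w]:windows$end_frame[w], , drop = FALSE]
    cw <- suppressWarnings(cor(seg))
    rs[[w]] <- cw[upper.tri(cw)]
  }
  rmat <- do.call(cbind, rs) # pairs x windows
  n_ok <- rowSums(!is.na(rmat))
  rbar <- rowMeans(rmat, na.rm = TRUE)
  ij <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  out <- tibble(i = ij[, 1], j = ij[, 2], r = rbar,
                n_windows = n_ok, n_skipped = nrow(windows) - n_ok)
  if (any(n_ok == 0)) {
    warn(sprintf("%d pair(s) omitted: correlation undefined in every window.",
                 sum(n_ok == 0)))
    out <- out[n_ok > 0, ]
  }
  if (!is.null(centroids)) {
    d <- as.matrix(stats::dist(cbind(centroids$x_um, centroids$y_um)))
    out$distance_um <- d[cbind(out$i, out$j)]
  }
  out
}

#' Distance-binned correlation curve and linear regression
#'
#' Bins pairwise correlations by the distance between the neuron centers
#' (10 um bins, half-open `[lo, hi)`), represents each non-empty bin by the
#' single unweighted mean correlation of its pairs, and fits an ordinary
#' least-squares line of mean correlation on bin-center distance.
#'
#' @param pairs A tibble with `distance_um` and `r` per pair (e.g. from
#'   [pairwise_correlation()] with centroids).
#' @param bin_um Bin width (um).
#' @return A list of class `strical_distance_fit` with `curve` (tibble
#'   `bin_lo`, `bin_hi`, `bin_center_um`, `mean_r`, `n_pairs`), `fit` (the
#'   `lm` object), and `stats` (tibble `slope_per_um`, `intercept`,
#'   `r_squared`, `adj_r_squared`, `p_value`, `n_bins`).
#' @export
bin_and_regress <- function(pairs, bin_um = 10) {
  if (!all(c("distance_um", "r") %in% names(pairs))) {
    abort("`pairs` needs columns distance_um and r.")
  }
  lo <- floor(pairs$distance_um / bin_um) * bin_um
  curve <- pairs |>
    dplyr::mutate(bin_lo = lo) |>
    dplyr::group_by(.data$bin_lo) |>
    dplyr::summarise(mean_r = mean(.data$r), n_pairs = dplyr::n(),
                     .groups = "drop") |>
    dplyr::mutate(bin_hi = .data$bin_lo + bin_um,
                  bin_center_um = .data$bin_lo + bin_um / 2) |>
    dplyr::select("bin_lo", "bin_hi", "bin_center_um", "mean_r", "n_pairs") |>
    dplyr::arrange(.data$bin_lo)
  if (nrow(curve) < 3) abort("need at least 3 non-empty distance bins.")
  fit <- lm(mean_r ~ bin_center_um, data = curve)
  sm <- summary(fit)
  stats <- tibble(
    slope_per_um = unname(coef(fit)[2]),
    intercept = unname(coef(fit)[1]),
    r_squared = sm$r.squared,
    adj_r_squared = sm$adj.r.squared,
    p_value = sm$coefficients[2, 4],
    n_bins = nrow(curve)
  )
  structure(list(curve = curve, fit = fit, stats = stats),
            class = "strical_distance_fit")
}

#' @export
print.strical_distance_fit <- function(x, ...) {
  s <- x$stats
  cat(sprintf(
    "correlation vs distance: slope = %.3g /um, R2 = %.3g, p = %.3g (%d bins)\n",
    s$slope_per_um, s$r_squared, s$p_value, s$n_bins))
  invisible(x)
}

#' Distance profile of annulus (neuropil) correlations
#'
#' Applies the same distance binning to annulus-annulus pairwise
#' correlations, computed over the full session (or supplied windows), to
#' expose the spatial correlation of the neuropil background.
#'
#' @param annulus_traces Frames x annuli matrix of annular dF/F (or raw)
#'   traces.
#' @param centroids Tibble with `x_um`, `y_um` per annulus.
#' @param windows Optional window tibble; default is one window spanning
#'   the whole session.
#' @param bin_um Distance bin width (um).
#' @return A `strical_distance_fit` (curve + regression).
#' @export
annulus_correlation_profile <- function(annulus_traces, centroids,
                                        windows = NULL, bin_um = 10) {
  if (is.null(windows)) {
    n <- nrow(annulus_traces)
    windows <- tibble(start_frame = 1L, end_frame = as.integer(n),
                      start_s = 0, end_s = (n - 1) / 15)
  }
  pairs <- pairwise_correlation(annulus_traces, windows, centroids)
  bin_and_regress(pairs, bin_um = bin_um)
}
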