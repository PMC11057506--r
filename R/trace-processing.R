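#' Equal-area annulus (neuropil ring) around a somatic ROI
#'
#' For a somatic ROI mask, builds a ring of pixels with the same area as the
#' ROI. The inner radius is the distance from the ROI's center of mass to
#' the border pixel farthest from it, plus `gap_px` pixels; the outer radius
#' is the solution of the equal-area equation
#' `pi * (r_out^2 - r_in^2) = area(ROI)`. Rasterization selects, among the
#' pixels at distance at least the inner radius from the center of mass, the
#' `area(ROI)` pixels closest to it, so the discrete ring area matches the
#' ROI area (within ties).
#'
#' @param mask Logical matrix (rows = y, cols = x): the somatic ROI.
#' @param gap_px Gap between the farthest ROI border point and the ring
#'   (pixels).
#' @return A list of class `strical_annulus` with `mask` (logical matrix),
#'   `inner_radius_px`, `outer_radius_px` (the analytic real-valued
#'   solution), `area_px`, and `com` (center of mass, c(x, y) in pixels).
#' @section Errors: Errors if the analytic ring extends past the image
#'   border (the ROI is too close to the edge for an unclipped ring).
#' @export
make_annulus <- function(mask, gap_px = 5) {
  if (!is.logical(mask) || !is.matrix(mask)) abort("`mask` must be a logical matrix.")
  area <- sum(mask)
  if (area == 0) abort("ROI mask is empty.")
  idx <- which(mask, arr.ind = TRUE) # (row = y, col = x)
  com <- c(x = mean(idx[, 2]), y = mean(idx[, 1]))
  # border pixels: ROI pixels with at least one 4-neighbor outside the ROI
  pad <- rbind(FALSE, cbind(FALSE, mask, FALSE), FALSE)
  core <- pad[2:(nrow(mask) + 1), 2:(ncol(mask) + 1)]
  nb <- pad[1:nrow(mask), 2:(ncol(mask) + 1)] &
    pad[3:(nrow(mask) + 2), 2:(ncol(mask) + 1)] &
    pad[2:(nrow(mask) + 1), 1:ncol(mask)] &
    pad[2:(nrow(mask) + 1), 3:(ncol(mask) + 2)]
  border <- core & !nb
  bidx <- which(border, arr.ind = TRUE)
  r_max <- max(sqrt((bidx[, 2] - com["x"])^2 + (bidx[, 1] - com["y"])^2))
  r_in <- r_max + gap_px
  r_out <- sqrt(r_in^2 + area / pi)
  if (com["x"] - r_out < 0.5 || com["x"] + r_out > ncol(mask) + 0.5 ||
      com["y"] - r_out < 0.5 || com["y"] + r_out > nrow(mask) + 0.5) {
    abort(sprintf(
      "annulus (outer radius %.1f px) is clipped by the image border.", r_out))
  }
  yy <- matrix(seq_len(nrow(mask)), nrow(mask), ncol(mask))
  xx <- matrix(rep(seq_len(ncol(mask)), each = nrow(mask)), nrow(mask))
  d <- sqrt((xx - com["x"])^2 + (yy - com["y"])^2)
  cand <- which(d >= r_in)
  cand <- cand[order(d[cand])][seq_len(min(area, length(cand)))]
  if (length(cand) < area) abort("not enough pixels for the ring.")
  ring <- matrix(FALSE, nrow(mask), ncol(mask))
  ring[cand] <- TRUE
  structure(
    list(mask = ring, inner_radius_px = unname(r_in),
         outer_radius_px = unname(r_out), area_px = sum(ring), com = com),
    class = "strical_annulus"
  )
}

#' Mean fluorescence trace over a pixel mask
#'
#' @param movie Array (y, x, frames).
#' @param mask Logical matrix matching the movie's spatial dimensions.
#' @return Numeric vector: the per-frame mean over the masked pixels.
#' @export
extract_trace <- function(movie, mask) {
  if (!all(dim(mask) == dim(movie)[1:2])) abort("mask does not match movie.")
  if (!any(mask)) abort("mask is empty.")
  flat <- matrix(movie, prod(dim(movie)[1:2]), dim(movie)[3])
  colMeans(flat[as.vector(mask), , drop = FALSE])
}

#' dF/F with a sliding-minimum baseline
#'
#' The baseline F0 is the minimal averaged fluorescence across 2 s windows
#' placed at 1 s steps throughout the recording (so consecutive windows
#' overlap by 1 s); a final window anchored at the end of the trace is
#' included so the whole recording is covered. dF/F = (F - F0) / F0.
#'
#' @param f Numeric raw fluorescence trace (one neuron), or a frames x
#'   neurons matrix (each column processed independently).
#' @param fs Frame rate (frames/s).
#' @param window_s Baseline averaging window (s).
#' @param step_s Window step (s).
#' @return For a vector input, a numeric dF/F vector with the baseline in
#'   attribute `f0`; for a matrix, a matrix of the same shape with an `f0`
#'   vector attribute.
#' @export
compute_dff <- function(f, fs = 15, window_s = 2, step_s = 1) {
  if (is.matrix(f)) {
    out <- apply(f, 2, compute_dff, fs = fs, window_s = window_s,
                 step_s = step_s)
    attr(out, "f0") <- apply(f, 2, function(col)
      attr(compute_dff(col, fs, window_s, step_s), "f0"))
    return(out)
  }
  L <- as.integer(round(window_s * fs))
  step <- as.integer(round(step_s * fs))
  n <- length(f)
  if (n < L) abort("trace shorter than the baseline window.")
  starts <- unique(c(seq(1L, n - L + 1L, by = step), n - L + 1L))
  csum <- c(0, cumsum(f))
  means <- (csum[starts + L] - csum[starts]) / L
  f0 <- min(means)
  if (f0 <= 0) abort("non-positive baseline F0; dF/F undefined.")
  structure((f - f0) / f0, f0 = f0)
}

#' Subtract the annular trace from its somatic trace
#'
#' Used for the soma-versus-neuropil decay-kinetics analysis: the raw
#' fluorescence of the annulus is subtracted from the raw somatic trace
#' before dF/F extraction.
#'
#' @param soma,annulus Equal-length numeric raw traces.
#' @return The elementwise difference.
#' @export
subtract_annulus <- function(soma, annulus) {
  if (length(soma) != length(annulus)) abort("traces differ in length.")
  soma - annulus
}

#' Detect calcium transients in a dF/F trace
#'
#' Peaks are strict local maxima (plateaus contribute their first frame)
#' whose height exceeds both `sd_mult` standard deviations of the trace and
#' the absolute value of the largest negative deflection in the signal.
#'
#' @param dff Numeric dF/F trace.
#' @param sd_mult SD multiplier for the detection threshold.
#' @return A tibble with `frame` and `amplitude`, with the detection SD and
#'   threshold in attributes `sd` and `threshold`. A constant trace yields
#'   an empty train with a warning.
#' @export
detect_events <- function(dff, sd_mult = 2) {
  n <- length(dff)
  s <- sd(dff)
  if (is.na(s) || s == 0) {
    warn("constant trace: no events detectable.")
    out <- tibble(frame = integer(0), amplitude = numeric(0))
    attr(out, "sd") <- s %||% NA_real_
    attr(out, "threshold") <- NA_real_
    return(out)
  }
  thr <- max(sd_mult * s, if (min(dff) < 0) abs(min(dff)) else 0)
  if (n < 3) {
    pk <- integer(0)
  } else {
    mid <- 2:(n - 1)
    pk <- mid[dff[mid] > dff[mid - 1] & dff[mid] >= dff[mid + 1]]
  }
  pk <- pk[dff[pk] > thr]
  out <- tibble(frame = as.integer(pk), amplitude = dff[pk])
  attr(out, "sd") <- s
  attr(out, "threshold") <- thr
  out
}

#' Fit an exponential decay to a triggered-average transient
#'
#' Least-squares fit of `a * exp(-t / tau) + b` from the peak of the average
#' onward, over at most `fit_window_s` seconds.
#'
#' @param avg Numeric triggered-average trace.
#' @param fs Frame rate (frames/s).
#' @param fit_window_s Post-peak window used for the fit (s).
#' @return A list of class `strical_decay_fit` with `tau_s`, `a`, `b`,
#'   `residual` (RMS), `fitted`, and `t_s` (times relative to the peak).
#' @section Errors: A flat input or a non-converging fit signals a
#'   condition of class `strical_fit_error`.
#' @export
fit_decay <- function(avg, fs = 15, fit_window_s = 3) {
  peak <- which.max(avg)
  last <- min(length(avg), peak + as.integer(round(fit_window_s * fs)))
  y <- avg[peak:last]
  if (length(y) < as.integer(fs) + 1L) {
    abort("need at least 1 s of samples after the peak.",
          class = "strical_fit_error")
  }
  if (sd(y) == 0) {
    abort("flat input: decay fit is degenerate.", class = "strical_fit_error")
  }
  t <- (seq_along(y) - 1) / fs
  b0 <- min(y)
  a0 <- max(y[1] - b0, 1e-6)
  below <- which(y - b0 < a0 / exp(1))
  tau0 <- if (length(below)) max(t[below[1]], 1 / fs) else max(t) / 2
  fit <- tryCatch(
    nls(y ~ a * exp(-t / tau) + b,
        start = list(a = a0, tau = tau0, b = b0),
        lower = c(a = 1e-9, tau = 1e-3, b = -Inf),
        algorithm = "port",
        control = stats::nls.control(maxiter = 200, warnOnly = FALSE)),
    error = function(e) {
      abort(paste0("decay fit did not converge: ", conditionMessage(e)),
            class = "strical_fit_error")
    }
  )
  cf <- coef(fit)
  structure(
    list(tau_s = unname(cf["tau"]), a = unname(cf["a"]), b = unname(cf["b"]),
         residual = sqrt(mean(resid(fit)^2)), fitted = predict(fit), t_s = t),
    class = "strical_decay_fit"
  )
}

#' @export
print.strical_decay_fit <- function(x, ...) {
  cat(sprintf("exponential decay fit: tau = %.3f s, a = %.3f, b = %.3f (rms %.2g)\n",
              x$tau_s, x$a, x$b, x$residual))
  invisible(x)
}

#' Soma- and annulus-triggered averages around somatic transients
#'
#' Averages the somatic and the annular dF/F signals in a fixed window
#' around the detected somatic transient peaks. The pair of averages feeds
#' [fit_decay()] per soma-annulus pair; fits are then pooled across pairs.
#'
#' @param soma_dff,annulus_dff Equal-length dF/F traces.
#' @param peak_frames Integer frames of the detected somatic transients.
#' @param fs Frame rate.
#' @param pre_s,post_s Window before/after each peak (s).
#' @return A list with `lag_s`, `soma` and `annulus` average traces, and
#'   `n_events` (peaks fully inside the session).
#' @export
soma_annulus_eta <- function(soma_dff, annulus_dff, peak_frames, fs = 15,
                             pre_s = 1, post_s = 3) {
  if (length(soma_dff) != length(annulus_dff)) abort("traces differ in length.")
  if (!length(peak_frames)) abort("no somatic events.")
  pre <- as.integer(round(pre_s * fs))
  post <- as.integer(round(post_s * fs))
  n <- length(soma_dff)
  ok <- peak_frames - pre >= 1 & peak_frames + post <= n
  peak_frames <- peak_frames[ok]
  if (!length(peak_frames)) abort("no somatic events fully inside the session.")
  lags <- -pre:post
  idx <- outer(peak_frames, lags, "+")
  list(
    lag_s = lags / fs,
    soma = colMeans(matrix(soma_dff[idx], nrow(idx), ncol(idx))),
    annulus = colMeans(matrix(annulus_dff[idx], nrow(idx), ncol(idx))),
    n_events = length(peak_frames)
  )
}
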