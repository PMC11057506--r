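#' Parameters for the synthetic-session generator
#'
#' Bundles and validates all knobs of the synthetic sessions used to validate
#' the pipeline: session geometry, transient statistics, event-locked rate
#' modulation, trace noise, and the spatial structure of the field of view
#' and its neuropil background.
#'
#' @param seed Integer seed; every generator draws from it deterministically.
#' @param duration_s Session length in seconds.
#' @param fs Imaging frame rate (frames/s).
#' @param n_neurons Number of simulated neurons.
#' @param frac_responsive Fraction of neurons whose transient rate is
#'   modulated in the 1 s window following behavioral events.
#' @param frac_negative Fraction of responsive neurons that are negatively
#'   modulated (rate suppression), the remainder being positively modulated.
#' @param base_rate_hz Transient rate at rest (Hz).
#' @param gain_pos Multiplicative rate gain in the 1 s post-event window for
#'   positively modulated neurons (> 1).
#' @param gain_neg Rate gain for negatively modulated neurons (in [0, 1)).
#' @param tau_s Decay time constant of the transient kernel (s).
#' @param amp_mean,amp_sd Transient amplitude distribution (dF/F units);
#'   amplitudes are truncated at zero.
#' @param noise_sd Additive Gaussian trace noise SD (dF/F units).
#' @param fov_um Field of view (width, height) in micrometers.
#' @param pixel_um Pixel size in micrometers.
#' @param neuropil_corr_len_um Spatial correlation length of the neuropil
#'   background field (um).
#' @param shared_coactivation_p Probability that a coupled group of neurons
#'   fires jointly (zero-lag) on a given trial.
#' @return A validated list of class `strical_synth_params`.
#' @export
synth_params <- function(seed = 1L,
                         duration_s = 1800,
                         fs = 15,
                         n_neurons = 50,
                         frac_responsive = 0.3,
                         frac_negative = 0.22,
                         base_rate_hz = 0.1,
                         gain_pos = 4,
                         gain_neg = 0.2,
                         tau_s = 0.6,
                         amp_mean = 0.5,
                         amp_sd = 0.1,
                         noise_sd = 0.05,
                         fov_um = c(600, 900),
                         pixel_um = 1.2,
                         neuropil_corr_len_um = 200,
                         shared_coactivation_p = 0) {
  p <- list(seed = as.integer(seed), duration_s = duration_s, fs = fs,
            n_neurons = as.integer(n_neurons),
            frac_responsive = frac_responsive, frac_negative = frac_negative,
            base_rate_hz = base_rate_hz, gain_pos = gain_pos,
            gain_neg = gain_neg, tau_s = tau_s, amp_mean = amp_mean,
            amp_sd = amp_sd, noise_sd = noise_sd, fov_um = fov_um,
            pixel_um = pixel_um, neuropil_corr_len_um = neuropil_corr_len_um,
            shared_coactivation_p = shared_coactivation_p)
  for (f in c("frac_responsive", "frac_negative", "shared_coactivation_p")) {
    if (p[[f]] < 0 || p[[f]] > 1) abort(sprintf("`%s` must be in [0, 1].", f))
  }
  for (f in c("duration_s", "fs", "base_rate_hz", "tau_s", "amp_mean",
              "pixel_um", "neuropil_corr_len_um")) {
    check_scalar(p[[f]], f, positive = TRUE)
  }
  if (p$noise_sd < 0 || p$amp_sd < 0) abort("noise_sd and amp_sd must be >= 0.")
  if (abs(p$fs * p$duration_s - round(p$fs * p$duration_s)) > 1e-9) {
    abort("fs * duration_s must be an integer frame count.")
  }
  structure(p, class = "strical_synth_params")
}

#' Generate synthetic head-accelerometer kinematics with known bouts
#'
#' Emulates the bimodal structure of total body acceleration in a freely
#' moving mouse: a sharp rest mode and a broader movement mode occupied
#' during discrete movement bouts. The BA profile is generated first; the
#' three axes are then obtained by multiplying each BA sample by a random
#' 3-D unit vector, so the Euclidean norm of the axes reproduces the BA
#' profile exactly.
#'
#' @param duration_s Session length (s); at least 60.
#' @param fs Frame rate (frames/s).
#' @param n_bouts Number of movement bouts.
#' @param bout_dur_s Bout duration (s): a single value or a vector recycled
#'   across bouts.
#' @param rest_g,move_g Rest and movement BA modes (g); separation must be
#'   positive.
#' @param rest_sd_g,move_sd_g Within-mode SDs (g). Movement samples are
#'   clipped from below and rest samples from above at the mode midpoint
#'   margins so bouts remain contiguous supra-threshold runs.
#' @param min_gap_s Minimum rest gap between bouts (s).
#' @param seed Integer seed.
#' @return A list with `record` (tibble `time_s`, `ap_g`, `ml_g`, `dv_g`,
#'   `ba_g`) and `bouts` (tibble of ground-truth `onset_frame`,
#'   `offset_frame`, in frames at `fs`).
#' @export
generate_kinematics <- function(duration_s = 1800, fs = 15, n_bouts = 40,
                                bout_dur_s = 3, rest_g = 0.018,
                                move_g = 0.099, rest_sd_g = 0.006,
                                move_sd_g = 0.015, min_gap_s = 4, seed = 1L) {
  if (duration_s < 60) abort("duration_s must be >= 60 s.")
  if (move_g <= rest_g) abort("movement mode must exceed rest mode.")
  n <- as.integer(round(duration_s * fs))
  # truncated normal by resampling: keeps each mode's histogram smooth while
  # guaranteeing rest and movement samples never cross the modes' midpoint,
  # so ground-truth bouts equal the supra-threshold runs the segmenter finds
  rtrunc <- function(n, mean, sd, lower = -Inf, upper = Inf) {
    x <- rnorm(n, mean, sd)
    bad <- which(x < lower | x > upper)
    while (length(bad)) {
      x[bad] <- rnorm(length(bad), mean, sd)
      bad <- bad[x[bad] < lower | x[bad] > upper]
    }
    x
  }
  with_seed(seed, {
    mid <- (rest_g + move_g) / 2
    sep <- move_g - rest_g
    ba <- rtrunc(n, rest_g, rest_sd_g, lower = 1e-4,
                 upper = mid - 0.2 * sep)
    bouts <- tibble(onset_frame = integer(0), offset_frame = integer(0))
    if (n_bouts > 0) {
      durs <- as.integer(round(rep_len(bout_dur_s, n_bouts) * fs))
      gap <- as.integer(round(min_gap_s * fs))
      slack <- n - sum(durs) - (n_bouts + 1L) * gap
      if (slack < 0) abort("bouts do not fit in the session.")
      extra <- runif(n_bouts + 1L)
      extra <- floor(slack * extra / sum(extra))
      onsets <- integer(n_bouts)
      pos <- 1L
      for (i in seq_len(n_bouts)) {
        pos <- pos + gap + extra[i]
        onsets[i] <- pos
        pos <- pos + durs[i]
      }
      offsets <- onsets + durs - 1L
      for (i in seq_len(n_bouts)) {
        idx <- onsets[i]:offsets[i]
        ba[idx] <- rtrunc(length(idx), move_g, move_sd_g,
                          lower = mid + 0.2 * sep)
      }
      bouts <- tibble(onset_frame = onsets, offset_frame = offsets)
    }
    u <- matrix(rnorm(3 * n), ncol = 3)
    u <- u / sqrt(rowSums(u^2))
    record <- tibble(
      time_s = frame_to_time(seq_len(n), fs),
      ap_g = abs(u[, 1]) * ba, ml_g = abs(u[, 2]) * ba, dv_g = abs(u[, 3]) * ba
    )
    record$ba_g <- sqrt(record$ap_g^2 + record$ml_g^2 + record$dv_g^2)
    list(record = record, bouts = bouts)
  })
}

#' Draw a ground-truth recruitment for a synthetic session
#'
#' Randomly assigns neurons as responsive or not, and responsive neurons as
#' positively or negatively modulated, per the fractions in `params`.
#' Independent draws across sessions model stochastic session-to-session
#' recruitment.
#'
#' @param params A [synth_params()] object.
#' @param seed Integer seed (defaults to `params$seed`).
#' @return A tibble with one row per neuron: `neuron`, `responsive`
#'   (logical), `sign` (+1, -1, or NA for non-responsive), `gain`.
#' @export
make_ground_truth <- function(params, seed = params$seed) {
  if (params$frac_responsive > 0 && params$gain_pos <= 1 &&
      params$frac_negative < 1) {
    abort("gain_pos must be > 1 when positively modulated neurons are requested.")
  }
  if (params$frac_responsive > 0 && params$frac_negative > 0 &&
      params$gain_neg >= 1) {
    abort("gain_neg must be < 1 when negatively modulated neurons are requested.")
  }
  with_seed(seed, {
    n <- params$n_neurons
    responsive <- runif(n) < params$frac_responsive
    negative <- responsive & (runif(n) < params$frac_negative)
    tibble(
      neuron = seq_len(n),
      responsive = responsive,
      sign = ifelse(!responsive, NA_real_, ifelse(negative, -1, 1)),
      gain = ifelse(!responsive, 1,
                    ifelse(negative, params$gain_neg, params$gain_pos))
    )
  })
}

#' Generate synthetic dF/F traces with event-locked rate modulation
#'
#' Each neuron's transient times form an inhomogeneous Bernoulli-per-frame
#' (Poisson-like) train: the per-frame probability is `base_rate_hz / fs`,
#' multiplied by the neuron's gain inside the 1 s window following each
#' event onset (responsive neurons only). Transients are convolved with an
#' instantaneous-rise, exponential-decay kernel (rise time one frame, well
#' below the GCaMP6f frame period) and Gaussian noise is added. Optionally a
#' coupled group of neurons receives a shared, zero-lag extra transient on a
#' random subset of trials, injecting trial-by-trial noise correlation.
#'
#' @param params A [synth_params()] object.
#' @param onset_frames Integer vector of behavioral event onset frames.
#' @param ground_truth Output of [make_ground_truth()].
#' @param coupled_ids Integer vector of neurons subject to shared
#'   coactivation (requires `params$shared_coactivation_p > 0` to matter).
#' @param coupling_events Indices into `onset_frames` of the trials on which
#'   coupling may occur (default all).
#' @param seed Integer seed (defaults to `params$seed`).
#' @return A list with `traces` (frames x neurons matrix of dF/F), `spikes`
#'   (list of transient-onset frame vectors per neuron), `amplitudes`
#'   (matching amplitude lists) and `ground_truth`.
#' @export
generate_traces <- function(params, onset_frames, ground_truth = NULL,
                            coupled_ids = integer(0),
                            coupling_events = seq_along(onset_frames),
                            seed = params$seed) {
  n_frames <- as.integer(round(params$duration_s * params$fs))
  if (length(onset_frames) && max(onset_frames) > n_frames) {
    abort("event times must fall within the session duration.")
  }
  if (is.null(ground_truth)) ground_truth <- make_ground_truth(params, seed)
  fs <- params$fs
  win <- as.integer(round(1 * fs)) # modulated window: 1 s post-onset
  with_seed(seed + 1L, {
    # per-frame gain profile shared by all responsive neurons
    in_win <- rep(FALSE, n_frames)
    for (f in onset_frames) {
      idx <- (f + 1L):min(f + win, n_frames)
      in_win[idx] <- TRUE
    }
    p_base <- params$base_rate_hz / fs
    klen <- as.integer(ceiling(6 * params$tau_s * fs))
    kern <- exp(-(0:klen) / (params$tau_s * fs))
    # shared coactivation: per selected trial, one shared latency
    coact <- integer(0)
    if (length(coupled_ids) && params$shared_coactivation_p > 0) {
      sel <- coupling_events[runif(length(coupling_events)) <
                               params$shared_coactivation_p]
      lat <- sample.int(as.integer(round(0.5 * fs)), length(sel), replace = TRUE)
      coact <- pmin(onset_frames[sel] + lat, n_frames)
    }
    traces <- matrix(0, n_frames, params$n_neurons)
    spikes <- vector("list", params$n_neurons)
    amplitudes <- vector("list", params$n_neurons)
    for (j in seq_len(params$n_neurons)) {
      g <- ground_truth$gain[j]
      p <- rep(p_base, n_frames)
      if (isTRUE(ground_truth$responsive[j])) p[in_win] <- p_base * g
      sp <- which(runif(n_frames) < p)
      if (j %in% coupled_ids && length(coact)) {
        sp <- sort(unique(c(sp, coact)))
      }
      amp <- pmax(rnorm(length(sp), params$amp_mean, params$amp_sd), 0)
      tr <- numeric(n_frames)
      for (i in seq_along(sp)) {
        idx <- sp[i]:min(sp[i] + klen, n_frames)
        tr[idx] <- tr[idx] + amp[i] * kern[seq_along(idx)]
      }
      if (params$noise_sd > 0) tr <- tr + rnorm(n_frames, 0, params$noise_sd)
      traces[, j] <- tr
      spikes[[j]] <- sp
      amplitudes[[j]] <- amp
    }
    list(traces = traces, spikes = spikes, amplitudes = amplitudes,
         ground_truth = ground_truth)
  })
}

#' Generate a pseudo-random conditioning session event table
#'
#' Builds the event structure of an operant conditioning session: `n_trials`
#' randomly spaced trials, each presenting a 10 s auditory cue (CS+ or CS-)
#' in pseudo-random order. The cue order is a balanced shuffle constrained to
#' at most `max_run` consecutive same-cue trials. In rewarded mode each CS+
#' is followed by a reward event at `reward_latency_s`; extinction mode emits
#' no rewards.
#'
#' @param n_trials Number of trials (even, for a balanced CS+/CS- split).
#' @param cue_s Cue duration (s).
#' @param iti_mean_s Mean inter-trial interval (s), typically 30 or 60; ITIs
#'   are drawn uniformly on (0.5, 1.5) times the mean.
#' @param fs Frame rate used for the `onset_frame` column.
#' @param extinction If `TRUE`, no reward events are emitted.
#' @param reward_latency_s Latency from CS+ onset to reward (s).
#' @param max_run Maximum number of consecutive same-cue trials.
#' @param seed Integer seed.
#' @return A tibble of events with columns `type` (`"cs_plus"`, `"cs_minus"`,
#'   `"reward"`), `onset_s`, `onset_frame`, `duration_s`, `trial`,
#'   `rewarded`.
#' @export
generate_conditioning_session <- function(n_trials = 42, cue_s = 10,
                                          iti_mean_s = 30, fs = 15,
                                          extinction = FALSE,
                                          reward_latency_s = 2,
                                          max_run = 3, seed = 1L) {
  if (n_trials %% 2 != 0) abort("n_trials must be even for a balanced split.")
  with_seed(seed, {
    types <- rep(c("cs_plus", "cs_minus"), n_trials / 2)
    repeat {
      order <- sample(types)
      if (max(rle(order)$lengths) <= max_run) break
    }
    iti <- runif(n_trials, 0.5 * iti_mean_s, 1.5 * iti_mean_s)
    onsets <- cumsum(iti + c(0, rep(cue_s, n_trials - 1)))
    cues <- tibble(
      type = order, onset_s = onsets,
      onset_frame = time_to_frame(onsets, fs),
      duration_s = cue_s, trial = seq_len(n_trials),
      rewarded = !extinction & order == "cs_plus"
    )
    out <- cues
    if (!extinction) {
      rewarded <- cues[cues$rewarded, ]
      if (nrow(rewarded)) {
        rw <- rewarded
        rw$type <- "reward"
        rw$onset_s <- rw$onset_s + reward_latency_s
        rw$onset_frame <- time_to_frame(rw$onset_s, fs)
        rw$duration_s <- 0
        out <- dplyr::bind_rows(cues, rw)
      }
    }
    dplyr::arrange(out, .data$onset_s)
  })
}

#' Place neuron centroids in the field of view with a minimum separation
#'
#' Centroids are drawn uniformly over the field of view (default 600 x 900
#' um) with a hard minimum pairwise separation, by rejection sampling.
#'
#' @param n_neurons Number of neurons to place.
#' @param fov_um Field of view (width, height) in micrometers.
#' @param min_sep_um Minimum pairwise centroid distance (um).
#' @param seed Integer seed.
#' @param max_tries Attempts per neuron before declaring packing impossible.
#' @return A tibble with `neuron`, `x_um`, `y_um`.
#' @export
generate_footprints <- function(n_neurons, fov_um = c(600, 900),
                                min_sep_um = 15, seed = 1L,
                                max_tries = 5000) {
  with_seed(seed, {
    xs <- numeric(0); ys <- numeric(0)
    for (i in seq_len(n_neurons)) {
      placed <- FALSE
      for (k in seq_len(max_tries)) {
        x <- runif(1, 0, fov_um[1]); y <- runif(1, 0, fov_um[2])
        if (!length(xs) || min(sqrt((xs - x)^2 + (ys - y)^2)) >= min_sep_um) {
          xs <- c(xs, x); ys <- c(ys, y); placed <- TRUE; break
        }
      }
      if (!placed) abort("cannot place neurons at the requested separation.")
    }
    tibble(neuron = seq_len(n_neurons), x_um = xs, y_um = ys)
  })
}

# internal: low-rank spatially correlated field
# returns list(basis = n_points x n_bumps weights, centers)
field_basis <- function(points_um, fov_um, corr_len_um, n_bumps) {
  cx <- runif(n_bumps, -corr_len_um, fov_um[1] + corr_len_um)
  cy <- runif(n_bumps, -corr_len_um, fov_um[2] + corr_len_um)
  d2 <- outer(points_um[, 1], cx, "-")^2 + outer(points_um[, 2], cy, "-")^2
  exp(-d2 / (2 * corr_len_um^2))
}

# internal: one-pole lowpass with time constant tau_s
lowpass <- function(x, tau_s, fs) {
  a <- exp(-1 / (tau_s * fs))
  as.numeric(stats::filter((1 - a) * x, a, method = "recursive"))
}

#' Generate a small synthetic movie patch with neuropil background
#'
#' Renders a synthetic one-photon movie: disc-shaped somatic footprints times
#' their dF/F traces, plus a spatially correlated neuropil background field,
#' plus shot-like pixel noise. The background has two components, both with
#' slower kinetics than the somatic transients: (i) a Gaussian-bump random
#' field with correlation length `neuropil_corr_len_um` and slow temporal
#' noise, and (ii) a wide low-pass-filtered "bleed" of each soma's own
#' transient train, which gives annular signals event-locked but slower
#' kinetics than their somata.
#'
#' @param centroids Tibble from [generate_footprints()] (um coordinates);
#'   must fit inside `nx * pixel_um` by `ny * pixel_um`.
#' @param traces Frames x neurons dF/F matrix (e.g. from
#'   [generate_traces()]).
#' @param params A [synth_params()] object (supplies `pixel_um`,
#'   `neuropil_corr_len_um`, `fs`).
#' @param nx,ny Movie size in pixels (at most 256 each).
#' @param pixel_um Movie pixel size (um); may be coarser than
#'   `params$pixel_um` to cover a wide field with few pixels.
#' @param soma_radius_px Somatic footprint disc radius (pixels).
#' @param bg_amp Amplitude of the random background field (0 disables it).
#' @param bleed_amp Amplitude of the slow somatic bleed component.
#' @param bleed_tau_s Time constant of the bleed low-pass filter (s).
#' @param bleed_len_um Spatial extent (Gaussian SD, um) of the bleed.
#' @param shot_sd SD of additive pixel noise.
#' @param n_bumps Number of background bumps (default scales with area).
#' @param seed Integer seed.
#' @return A list with `movie` (array ny x nx x frames), `masks` (list of
#'   logical ny x nx somatic masks), `background_at_centroids` (frames x
#'   neurons matrix of the total background sampled at each centroid), and
#'   `pixel_um`.
#' @export
generate_movie_patch <- function(centroids, traces, params,
                                 nx = 128, ny = 128,
                                 pixel_um = params$pixel_um,
                                 soma_radius_px = 3,
                                 bg_amp = 0.3, bleed_amp = 0.3,
                                 bleed_tau_s = 1, bleed_len_um = 40,
                                 shot_sd = 0.02, n_bumps = NULL,
                                 seed = 1L) {
  if (nx > 256 || ny > 256) abort("movie patch is limited to 256 x 256 px.")
  n_frames <- nrow(traces)
  n_neurons <- ncol(traces)
  fov <- c(nx * pixel_um, ny * pixel_um)
  if (any(centroids$x_um > fov[1]) || any(centroids$y_um > fov[2])) {
    abort("centroids fall outside the movie patch.")
  }
  L <- params$neuropil_corr_len_um
  if (is.null(n_bumps)) n_bumps <- max(10L, ceiling(3 * prod(fov) / L^2))
  with_seed(seed, {
    px <- (seq_len(nx) - 0.5) * pixel_um
    py <- (seq_len(ny) - 0.5) * pixel_um
    pts <- cbind(rep(px, each = ny), rep(py, nx)) # (y fastest) matches array fill
    # somatic footprints
    masks <- vector("list", n_neurons)
    for (j in seq_len(n_neurons)) {
      cxp <- centroids$x_um[j] / pixel_um
      cyp <- centroids$y_um[j] / pixel_um
      xx <- matrix(rep(seq_len(nx), each = ny), ny, nx)
      yy <- matrix(rep(seq_len(ny), nx), ny, nx)
      masks[[j]] <- (xx - 0.5 - cxp)^2 + (yy - 0.5 - cyp)^2 <= soma_radius_px^2
    }
    # background: random bumps with slow time courses
    n_px <- nx * ny
    bg_pix <- matrix(0, n_frames, 0)
    B <- matrix(0, n_px, 0)
    if (bg_amp > 0) {
      B <- field_basis(pts, fov, L, n_bumps)
      bcourse <- matrix(rnorm(n_frames * n_bumps), n_frames, n_bumps)
      bcourse <- apply(bcourse, 2, lowpass, tau_s = bleed_tau_s, fs = params$fs)
      bg_pix <- bg_amp * bcourse
    }
    # somatic bleed: wide gaussian around each soma, lowpassed trace
    Bs <- matrix(0, n_px, 0)
    bl_course <- matrix(0, n_frames, 0)
    if (bleed_amp > 0) {
      d2 <- outer(pts[, 1], centroids$x_um, "-")^2 +
        outer(pts[, 2], centroids$y_um, "-")^2
      Bs <- exp(-d2 / (2 * bleed_len_um^2))
      bl_course <- bleed_amp *
        apply(traces, 2, lowpass, tau_s = bleed_tau_s, fs = params$fs)
    }
    movie <- array(0, dim = c(ny, nx, n_frames))
    flat <- matrix(0, n_px, n_frames)
    for (j in seq_len(n_neurons)) {
      flat[as.vector(masks[[j]]), ] <-
        flat[as.vector(masks[[j]]), ] +
        matrix(traces[, j], sum(masks[[j]]), n_frames, byrow = TRUE)
    }
    if (ncol(bg_pix)) flat <- flat + B %*% t(bg_pix)
    if (ncol(bl_course)) flat <- flat + Bs %*% t(bl_course)
    if (shot_sd > 0) flat <- flat + matrix(rnorm(length(flat), 0, shot_sd),
                                           n_px, n_frames)
    movie[] <- flat
    # background sampled at the rendered pixel under each centroid,
    # with the somatic signal removed
    cpts <- cbind(centroids$x_um, centroids$y_um)
    pix_i <- pmin(pmax(ceiling(cpts[, 2] / pixel_um), 1), ny)
    pix_j <- pmin(pmax(ceiling(cpts[, 1] / pixel_um), 1), nx)
    lin <- (pix_j - 1L) * ny + pix_i
    bg_flat <- flat
    for (j in seq_len(n_neurons)) {
      bg_flat[as.vector(masks[[j]]), ] <-
        bg_flat[as.vector(masks[[j]]), ] -
        matrix(traces[, j], sum(masks[[j]]), n_frames, byrow = TRUE)
    }
    bg_at <- t(bg_flat[lin, , drop = FALSE])
    list(movie = movie, masks = masks, background_at_centroids = bg_at,
         pixel_um = pixel_um)
  })
}

#' Generate spatially correlated neuropil time courses at given points
#'
#' Evaluates the same Gaussian-bump background field used by
#' [generate_movie_patch()] directly at a set of positions (e.g. annulus
#' centers), without rendering pixels. Nearby points share bump weights, so
#' their time courses are correlated with spatial correlation length
#' `corr_len_um`.
#'
#' @param centroids Tibble with `x_um`, `y_um`.
#' @param n_frames Number of frames.
#' @param fov_um Field extent (um).
#' @param corr_len_um Spatial correlation length (um).
#' @param tau_s Temporal smoothing constant of the bump time courses (s).
#' @param fs Frame rate.
#' @param n_bumps Number of bumps (default scales with area).
#' @param seed Integer seed.
#' @return A frames x points matrix of background time courses.
#' @export
generate_neuropil_traces <- function(centroids, n_frames,
                                     fov_um = c(600, 900),
                                     corr_len_um = 200, tau_s = 2, fs = 15,
                                     n_bumps = NULL, seed = 1L) {
  if (is.null(n_bumps)) {
    n_bumps <- max(20L, ceiling(3 * prod(fov_um) / corr_len_um^2))
  }
  with_seed(seed, {
    B <- field_basis(cbind(centroids$x_um, centroids$y_um), fov_um,
                     corr_len_um, n_bumps)
    bcourse <- matrix(rnorm(n_frames * n_bumps), n_frames, n_bumps)
    bcourse <- apply(bcourse, 2, lowpass, tau_s = tau_s, fs = fs)
    bcourse %*% t(B)
  })
}

#' Generate traces with a prescribed correlation-distance profile
#'
#' Draws multivariate-normal traces whose pairwise correlation is a given
#' function of the pairwise centroid distance, for testing the distance-
#' binned correlation analysis. If the target correlation matrix is not
#' positive semi-definite it is projected onto the PSD cone by eigenvalue
#' clipping, and the realized (post-projection) correlations are returned
#' alongside the traces.
#'
#' @param centroids Tibble with `x_um`, `y_um`.
#' @param n_frames Number of frames.
#' @param corr_fun Function of distance (um) returning target correlation.
#' @param seed Integer seed.
#' @return A list with `traces` (frames x neurons), `target` and `realized`
#'   correlation matrices.
#' @export
generate_correlated_traces <- function(centroids, n_frames, corr_fun,
                                       seed = 1L) {
  n <- nrow(centroids)
  d <- as.matrix(stats::dist(cbind(centroids$x_um, centroids$y_um)))
  target <- corr_fun(d)
  diag(target) <- 1
  e <- eigen(target, symmetric = TRUE)
  vals <- pmax(e$values, 1e-8)
  A <- e$vectors %*% diag(sqrt(vals))
  realized <- e$vectors %*% diag(vals) %*% t(e$vectors)
  # renormalize to unit variance so realized is a correlation matrix
  s <- sqrt(diag(realized))
  realized <- realized / outer(s, s)
  A <- A / s
  with_seed(seed, {
    Z <- matrix(rnorm(n_frames * n), n_frames, n)
    list(traces = Z %*% t(A), target = target, realized = realized)
  })
}
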