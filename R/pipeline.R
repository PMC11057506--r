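#' Subset a behavioral event table
#'
#' Filters an event table by any combination of event type, reward flag,
#' acceleration-change quartile, trial-ordinal range, first/last n trials,
#' and odd/even trial parity — the event subsets the downstream analyses
#' compare (CS+ vs CS-, rewarded vs unrewarded, quartile 1 vs 4, first 10
#' trials, odd vs even trials). Ordinal filters (`first_n`, `last_n`,
#' `ordinal`, `parity`) apply to the row order after the value filters.
#'
#' @param events Event tibble (e.g. from
#'   [generate_conditioning_session()]): any columns among `type`,
#'   `rewarded`, `quartile` are used when the matching filter is given.
#' @param type Keep events of this type (character).
#' @param rewarded Keep events with this reward flag (logical).
#' @param quartile Keep events with these quartile labels (integer).
#' @param ordinal Length-2 integer range of ordinal positions to keep.
#' @param first_n,last_n Keep the first/last n events.
#' @param parity `"odd"` or `"even"` ordinal positions.
#' @return The filtered tibble (possibly empty, with a warning).
#' @export
subset_events <- function(events, type = NULL, rewarded = NULL,
                          quartile = NULL, ordinal = NULL, first_n = NULL,
                          last_n = NULL, parity = NULL) {
  ev <- as_tibble(events)
  if (!is.null(type)) ev <- ev[ev$type %in% type, ]
  if (!is.null(rewarded)) ev <- ev[ev$rewarded %in% rewarded, ]
  if (!is.null(quartile)) ev <- ev[ev$quartile %in% quartile, ]
  pos <- seq_len(nrow(ev))
  keep <- rep(TRUE, nrow(ev))
  if (!is.null(ordinal)) keep <- keep & pos >= ordinal[1] & pos <= ordinal[2]
  if (!is.null(first_n)) keep <- keep & pos <= first_n
  if (!is.null(last_n)) keep <- keep & pos > nrow(ev) - last_n
  if (!is.null(parity)) {
    parity <- match.arg(parity, c("odd", "even"))
    keep <- keep & (pos %% 2 == if (parity == "odd") 1 else 0)
  }
  out <- ev[keep, ]
  if (!nrow(out)) warn("event subset is empty.")
  out
}

#' Generate a complete synthetic free-movement session
#'
#' Bundles the generators into one session with ground truth: kinematics
#' with known bouts, a recruitment draw, dF/F traces with event-locked
#' modulation at the true movement onsets, and centroids.
#'
#' @param params A [synth_params()] object.
#' @param n_bouts,bout_dur_s Passed to [generate_kinematics()].
#' @param ... Further arguments to [generate_traces()] (coupling etc.).
#' @return A list with `record`, `bouts`, `traces`, `spikes`,
#'   `ground_truth`, `centroids`, `events` (movement-onset tibble), and
#'   `params`.
#' @export
generate_session <- function(params, n_bouts = 40, bout_dur_s = 3, ...) {
  kin <- generate_kinematics(duration_s = params$duration_s, fs = params$fs,
                             n_bouts = n_bouts, bout_dur_s = bout_dur_s,
                             seed = params$seed)
  gt <- make_ground_truth(params)
  tr <- generate_traces(params, kin$bouts$onset_frame, gt, ...)
  cen <- generate_footprints(params$n_neurons, fov_um = params$fov_um,
                             seed = params$seed + 2L)
  events <- tibble(
    type = "movement_onset",
    onset_frame = kin$bouts$onset_frame,
    onset_s = frame_to_time(kin$bouts$onset_frame, params$fs)
  )
  list(record = kin$record, bouts = kin$bouts, traces = tr$traces,
       spikes = tr$spikes, ground_truth = tr$ground_truth,
       centroids = cen, events = events, params = params)
}

#' Run the full analysis pipeline on a synthetic session
#'
#' Orchestrates the stages end-to-end on a generated session: kinematics
#' (threshold, bout segmentation, acceleration-change quartiles), trace
#' processing (transient detection), event statistics (bootstrap
#' significance, modulation labels, reliability, per-event recruitment),
#' pairwise correlations in rest and movement windows with distance
#' regression, and the positively modulated population JPSTH with diagonal
#' statistics. Results are returned as tidy tibbles and, when `out_dir` is
#' given, written as delimited tables together with a machine-readable run
#' manifest (all parameters, seeds and package version); identical config
#' and seed reproduce identical tables.
#'
#' @param config A named list: `synth` (arguments for [synth_params()]),
#'   `n_bouts`, `bout_dur_s`, `n_null`, `alpha`, `window_s`, and logical
#'   stage toggles `do_correlations`, `do_jpsth`. A path to a YAML file
#'   with these keys is also accepted.
#' @param out_dir Optional output directory for result tables.
#' @return A list of tibbles: `bouts`, `quartiles`, `neurons` (per-neuron
#'   p, label, reliability), `recruitment`, `correlations` (per-state
#'   regression stats), `jpsth_diagonal`, plus `manifest`.
#' @export
run_pipeline <- function(config = list(), out_dir = NULL) {
  if (is.character(config)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      abort("reading YAML configs requires the yaml package.")
    }
    config <- yaml::yaml.load_file(config)
  }
  cfg <- utils::modifyList(list(
    synth = list(), n_bouts = 40, bout_dur_s = 3, n_null = 500,
    alpha = 0.05, window_s = 5, do_correlations = TRUE, do_jpsth = TRUE
  ), config)
  params <- do.call(synth_params, cfg$synth)
  if (cfg$alpha < 0 || cfg$alpha > 1) abort("alpha must be in [0, 1].")
  ses <- generate_session(params, n_bouts = cfg$n_bouts,
                          bout_dur_s = cfg$bout_dur_s)
  n_frames <- nrow(ses$traces)
  fs <- params$fs

  thr <- find_movement_threshold(ses$record$ba_g)
  bouts <- segment_movement(ses$record$ba_g, thr, fs)
  quart <- classify_accel_change(ses$record$ba_g, bouts$onset_frame, fs)
  onsets <- bouts$onset_frame

  seeds <- derive_seeds(params$seed + 10L, params$n_neurons)
  neurons <- purrr::map_dfr(seq_len(params$n_neurons), function(j) {
    b <- bootstrap_significance(ses$traces[, j], onsets, fs = fs,
                                window_s = cfg$window_s, n_null = cfg$n_null,
                                alpha = cfg$alpha, seed = seeds[j])
    label <- if (b$significant) {
      classify_modulation(list(lag_s = b$lag_s, mean = b$eta))
    } else "nonsignificant"
    ev <- detect_events(ses$traces[, j])
    rel <- if (label == "positive") {
      response_reliability(ev$frame, onsets, fs)
    } else NA_real_
    tibble(neuron = j, p_value = b$p_value, significant = b$significant,
           label = label, reliability = rel,
           true_responsive = ses$ground_truth$responsive[j],
           true_sign = ses$ground_truth$sign[j])
  })
  trains <- lapply(seq_len(params$n_neurons),
                   function(j) detect_events(ses$traces[, j])$frame)
  recruit <- population_recruitment(trains, onsets, fs)

  correlations <- NULL
  if (isTRUE(cfg$do_correlations)) {
    rw <- rest_windows(bouts, n_frames, fs)
    mw <- movement_windows(onsets, n_frames, fs)
    correlations <- purrr::map_dfr(
      list(rest = rw, movement = mw),
      function(w) {
        if (nrow(w) < 1) return(tibble())
        pr <- pairwise_correlation(ses$traces, w, ses$centroids)
        fit <- tryCatch(bin_and_regress(pr), error = function(e) NULL)
        if (is.null(fit)) tibble(mean_r = mean(pr$r)) else
          dplyr::bind_cols(tibble(mean_r = mean(pr$r)), fit$stats)
      },
      .id = "state"
    )
  }

  jd <- NULL
  if (isTRUE(cfg$do_jpsth)) {
    pos <- neurons$neuron[neurons$label == "positive"]
    if (length(pos) >= 2) {
      prs <- t(utils::combn(pos, 2))
      jd_obj <- tryCatch(
        diagonal_analysis(trains, onsets, n_frames, prs, fs = fs,
                          window_s = cfg$window_s,
                          seed = params$seed + 20L),
        error = function(e) NULL
      )
      if (!is.null(jd_obj)) {
        jd <- jd_obj$diagonal
        attr(jd, "stats") <- tibble(
          baseline_mean = jd_obj$baseline_mean,
          baseline_sd = jd_obj$baseline_sd,
          baseline_peak = jd_obj$baseline_peak,
          post_peak = jd_obj$post_peak, n_pairs = jd_obj$n_pairs)
      }
    }
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("strical")),
    config = cfg, seed = params$seed,
    threshold_g = thr$threshold, n_bouts_detected = nrow(bouts)
  )
  out <- list(bouts = bouts, quartiles = quart, neurons = neurons,
              recruitment = recruit, correlations = correlations,
              jpsth_diagonal = jd, manifest = manifest)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in c("bouts", "quartiles", "neurons", "recruitment",
                 "correlations", "jpsth_diagonal")) {
      if (!is.null(out[[nm]]) && nrow(out[[nm]])) {
        utils::write.csv(out[[nm]], file.path(out_dir, paste0(nm, ".csv")),
                         row.names = FALSE)
      }
    }
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(out)
}
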