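#' Default experiment configuration
#'
#' The study conditions of the synthetic experiment: 8 stimulus durations
#' from 75 to 600 ms, 15 participants, 120 epochs per condition, the default
#' simulator, preprocessing, detection and dipole-fit settings, and a master
#' seed from which every stage seed is derived.
#'
#' @param ... name-value overrides.
#' @return a named list (`experiment_config`).
#' @export
default_experiment_config <- function(...) {
  cfg <- list(
    durations_ms = seq(75, 600, by = 75),
    n_participants = 15,
    sim = default_sim_config(),
    behavior = list(theta_ms = 84, slope_ms = 4),
    preprocess = list(threshold_ft_cm = 3000, min_epochs = 100,
                      band_hz = c(1, 75), notch_hz = 60,
                      baseline_ms = c(-100, 0)),
    detect = list(search_ms = c(60, 160), window_halfwidth_ms = 20, k_sd = 4),
    fit_duration_ms = 600,      # dipole fits run on this condition
    use_detected_transitions = FALSE,
    n_sites = 102,
    master_seed = 1)
  over <- list(...)
  cfg[names(over)] <- over
  cfg
}

#' Derive a stage seed from the master seed
#'
#' Stable splitting rule: the stage name, participant and condition are
#' hashed (31-based polynomial over the label bytes, modulo 2^31 - 1) and
#' mixed with the master seed, so adding conditions or participants never
#' perturbs the seeds of existing ones.
#'
#' @param master_seed integer master seed.
#' @param stage stage label.
#' @param participant participant id (integer or label).
#' @param condition condition label.
#' @return an integer seed in 1 .. 2^31 - 2.
#' @export
stage_seed <- function(master_seed, stage, participant = 0, condition = "") {
  s <- sprintf("%s|%s|%s", stage, participant, condition)
  h <- 0
  for (c in utf8ToInt(s)) h <- (h * 31 + c) %% 2147483647
  h <- (h + as.numeric(master_seed) * 48271) %% 2147483647
  as.integer(h %% 2147483645 + 1)
}

#' Run the full synthetic experiment
#'
#' For every simulated participant and stimulus duration: synthesize and
#' time-stretch the stimulus, simulate the MEG epoch set, preprocess (reject,
#' average, filter, baseline), and detect/count the significant M100
#' components per hemisphere. Dipole fits are computed on the
#' `fit_duration_ms` condition for each participant, and the statistical
#' report (Spearman correlations, Wilcoxon tests against the longest
#' condition, pairwise component discriminant tests) is assembled from the
#' tables. Deterministic given `cfg$master_seed`.
#'
#' @param cfg configuration from [default_experiment_config()].
#' @param progress print one line per participant (default FALSE).
#' @return an `experiment_report`: list with `behavior`, `detections`,
#'   `fits`, `stats`, `config`.
#' @export
run_experiment <- function(cfg = default_experiment_config(), progress = FALSE) {
  array <- default_sensor_array(n_sites = cfg$n_sites)
  stims <- generate_stimulus_set(cfg$durations_ms)
  behavior <- simulate_behavior(cfg$durations_ms, cfg$n_participants,
                                cfg$behavior$theta_ms, cfg$behavior$slope_ms,
                                seed = stage_seed(cfg$master_seed, "behavior"))
  detections <- NULL
  fits <- NULL
  for (pid in seq_len(cfg$n_participants)) {
    for (d in cfg$durations_ms) {
      stim <- stims[[as.character(d)]]
      onsets_ms <- if (cfg$use_detected_transitions) {
        a <- d / max(cfg$durations_ms)
        tr <- dynamic_measure(cepstral_analysis(stim, frame_ms = 25 * a,
                                                hop_ms = 5 * a))
        c(0, 1000 * find_transitions(tr, 3, min_separation_ms = 30 * a))
      } else 1000 * stim$syllable_onsets
      ep <- simulate_epochs(stim, array, cfg$sim,
                            seed = stage_seed(cfg$master_seed, "epochs", pid, d),
                            stimulus_id = sprintf("dur%03d", d))
      ev <- suppressWarnings(preprocess_epochs(
        ep, cfg$preprocess$threshold_ft_cm, cfg$preprocess$min_epochs,
        cfg$preprocess$band_hz, cfg$preprocess$notch_hz,
        cfg$preprocess$baseline_ms))
      dc <- detect_counts(ev, array, onsets_ms,
                          search_ms = cfg$detect$search_ms,
                          window_halfwidth_ms = cfg$detect$window_halfwidth_ms,
                          k_sd = cfg$detect$k_sd)
      detections <- rbind(detections, data.frame(
        participant_id = pid, duration_ms = d,
        n_left = dc$left$n_significant, n_right = dc$right$n_significant,
        n_significant = dc$n_combined,
        n_epochs_averaged = ev$n_epochs_averaged))
      if (d == cfg$fit_duration_ms) {
        for (h in c("left", "right")) {
          fh <- fit_all_components(ev, array, dc[[h]]$components, h)
          if (nrow(fh) > 0) fh$participant_id <- pid
          fits <- rbind(fits, fh)
        }
      }
    }
    if (progress)
      message(sprintf("participant %d/%d done", pid, cfg$n_participants))
  }
  stats <- analysis_report(behavior, detections, fits)
  structure(list(behavior = behavior, detections = detections, fits = fits,
                 stats = stats, config = cfg),
            class = "experiment_report")
}

#' @export
print.experiment_report <- function(x, ...) {
  cat(sprintf("<experiment_report> %d participants x %d conditions\n",
              x$config$n_participants, length(x$config$durations_ms)))
  agg <- stats::aggregate(cbind(perceived = x$behavior$perceived_count),
                          by = list(duration_ms = x$behavior$duration_ms), FUN = mean)
  agg$n_m100 <- stats::aggregate(x$detections$n_significant,
                                 by = list(x$detections$duration_ms), FUN = mean)$x
  print(agg, row.names = FALSE)
  if (!is.null(x$stats$correlations)) {
    cat("correlations (pooled pairs):\n")
    print(x$stats$correlations, row.names = FALSE)
  }
  invisible(x)
}
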