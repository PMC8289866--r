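#' Pipeline configuration
#'
#' Bundles every tunable of the analysis chain. The defaults are the
#' parameters the detectors were calibrated with: spike threshold 6x the
#' median-based noise sd, propagation ratio 0.3 over a +-2 ms CCG with a
#' 0.5 ms moving window, coupling window 0.5--10 ms with a 3 ms peak window
#' and criteria v1--v6 = 0.1, 0.57, 1, 5, 2.7, 0.25.
#'
#' @param k_threshold Spike-detection threshold multiplier.
#' @param ratio_threshold Propagation ratio threshold.
#' @param propagation_window,moving_window,bin_width Propagation CCG
#'   parameters (ms).
#' @param criteria A [coupling_criteria()] object.
#' @param co_occurrence_window Anchor co-occurrence window (ms).
#' @param ks_draws Random draws per coupled-vs-random KS comparison.
#' @param shuffle_reps ISI-shuffle repetitions per coupling.
#' @param seed Integer seed for all stochastic stages.
#' @return A list of class `axo_pipeline_config`.
#' @export
pipeline_config <- function(k_threshold = 6, ratio_threshold = 0.3,
                            propagation_window = c(-2, 2),
                            moving_window = 0.5, bin_width = 0.05,
                            criteria = coupling_criteria(),
                            co_occurrence_window = 2,
                            ks_draws = 100, shuffle_reps = 20, seed = 1) {
  structure(list(
    k_threshold = k_threshold, ratio_threshold = ratio_threshold,
    propagation_window = propagation_window, moving_window = moving_window,
    bin_width = bin_width, criteria = criteria,
    co_occurrence_window = co_occurrence_window,
    ks_draws = ks_draws, shuffle_reps = shuffle_reps, seed = seed),
    class = "axo_pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Spike table in; propagation signals, couplings, validation report and
#' connectivity graph out. Every stage's output is written to `out_dir`
#' together with provenance (parameters, seed, package version), and a rerun
#' with the same inputs and seed is identical.
#'
#' Stages: [detect_propagation_signals()] ->
#' [assign_signal_spike_times()] -> [detect_all_couplings()] -> per accepted
#' electrode-target coupling, [coupled_vs_random_amplitude_test()] and
#' [shuffle_control()] -> [build_graph()].
#'
#' @param rec An [mea_recording()] or the path of a spike-table CSV.
#' @param out_dir Output directory (created if missing); `NULL` skips
#'   writing.
#' @param config A [pipeline_config()].
#' @param condition_label Condition label attached to the graph.
#' @return A list with `signals`, `couplings`, `validation`, `graph`
#'   (invisibly if `out_dir` is given).
#' @export
run_pipeline <- function(rec, out_dir = NULL, config = pipeline_config(),
                         condition_label = "") {
  if (is.character(rec)) {
    rec <- read_spike_table(rec)
  }
  signals <- detect_propagation_signals(
    rec, ratio_threshold = config$ratio_threshold,
    window = config$propagation_window,
    moving_window = config$moving_window, bin_width = config$bin_width)
  signals <- assign_signal_spike_times(
    signals, rec, co_occurrence_window = config$co_occurrence_window)
  couplings <- detect_all_couplings(signals, rec, criteria = config$criteria)
  validation <- validate_couplings(couplings, rec, ks_draws = config$ks_draws,
                                   shuffle_reps = config$shuffle_reps,
                                   seed = config$seed,
                                   signals = signals,
                                   window = config$criteria$window)
  graph <- build_graph(couplings, signals, condition_label = condition_label)
  result <- list(signals = signals, couplings = couplings,
                 validation = validation, graph = graph)
  if (!is.null(out_dir)) {
    write_pipeline_outputs(result, rec, config, out_dir)
    return(invisible(result))
  }
  result
}

#' Validate accepted couplings
#'
#' Runs the two controls on each accepted coupling: for electrode targets,
#' the coupled-versus-random amplitude KS comparison; for all targets, the
#' ISI-shuffle chance-coupling control.
#'
#' @param couplings An `axo_couplings` log.
#' @param rec The recording.
#' @param signals The `axo_signals` the couplings refer to.
#' @param ks_draws,shuffle_reps,seed,window See [pipeline_config()].
#' @return A tibble with one row per accepted coupling: KS summary (median
#'   p over draws) and shuffle summary (original vs mean shuffled ratio).
#' @export
validate_couplings <- function(couplings, rec, signals, ks_draws = 100,
                               shuffle_reps = 20, seed = 1,
                               window = c(0.5, 10)) {
  acc <- couplings[couplings$accepted, , drop = FALSE]
  trains <- spike_trains(rec)
  purrr::map_dfr(seq_len(nrow(acc)), function(i) {
    row <- acc[i, ]
    ref_times <- signals$spike_times[[match(row$reference_id, signals$signal_id)]]
    if (row$target_type == "electrode") {
      tr <- trains[[row$target_id]]
      camps <- coupled_spike_amplitudes(row, tr)
      ks <- coupled_vs_random_amplitude_test(camps, tr$amplitudes,
                                             n_draws = ks_draws,
                                             seed = seed + i)
      target_times <- tr$times
      ks_median_p <- stats::median(ks$p_value)
    } else {
      target_times <- signals$spike_times[[match(row$target_id, signals$signal_id)]]
      ks_median_p <- NA_real_
    }
    sh <- shuffle_control(ref_times, target_times, n_reps = shuffle_reps,
                          seed = seed + i, window = window)
    tibble::tibble(
      reference_id = row$reference_id, target_id = row$target_id,
      target_type = row$target_type,
      ks_median_p = ks_median_p,
      original_ratio = sh$original_ratio,
      shuffled_ratio_mean = mean(sh$shuffled_ratios),
      shuffle_reduction = 1 - mean(sh$shuffled_ratios) /
        max(sh$original_ratio, .Machine$double.eps))
  })
}

write_pipeline_outputs <- function(result, rec, config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sig <- result$signals
  sig_json <- purrr::map(seq_len(nrow(sig)), function(i) {
    list(signal_id = sig$signal_id[i], origin = sig$origin[i],
         anchor_first = sig$anchor_first[i],
         anchor_second = sig$anchor_second[i],
         n_spikes = sig$n_spikes[i],
         electrodes = sig$electrodes[[i]])
  })
  jsonlite::write_json(sig_json, file.path(out_dir, "signals.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  sig_times <- purrr::map_dfr(seq_len(nrow(sig)), function(i) {
    tibble::tibble(signal_id = sig$signal_id[i],
                   time_s = sig$spike_times[[i]])
  })
  readr::write_csv(sig_times, file.path(out_dir, "signal_times.csv"))
  readr::write_csv(dplyr::select(result$couplings, -"coupled_idx"),
                   file.path(out_dir, "couplings.csv"))
  jsonlite::write_json(result$validation, file.path(out_dir, "validation.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  write_graph_csv(result$graph, file.path(out_dir, "graph.csv"))
  write_graphml(result$graph, file.path(out_dir, "graph.graphml"))
  info <- list(
    package = "axocouple",
    version = as.character(utils::packageVersion("axocouple")),
    seed = config$seed,
    n_spikes = nrow(rec), duration_s = rec_duration(rec),
    parameters = list(
      k_threshold = config$k_threshold,
      ratio_threshold = config$ratio_threshold,
      propagation_window_ms = config$propagation_window,
      moving_window_ms = config$moving_window,
      bin_width_ms = config$bin_width,
      criteria = unclass(config$criteria),
      co_occurrence_window_ms = config$co_occurrence_window,
      ks_draws = config$ks_draws, shuffle_reps = config$shuffle_reps))
  jsonlite::write_json(info, file.path(out_dir, "run_info.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
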