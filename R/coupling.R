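#' Coupling acceptance criteria
#'
#' The thresholds used to accept a short-latency (putatively synaptic)
#' coupling from a one-sided CCG. With `n` the number of reference signal
#' spikes, `n1` the total CCG counts and `n2` the largest sum of counts in
#' any `peak_window` ms moving window:
#'
#' * `v1`: minimum coupling ratio, `n1/n > v1` (default 0.1);
#' * `v2`: minimum peak-concentration ratio, `n2/n1 > v2` (default 0.57);
#' * `v3`, `v4`: the mean latency of the peak-window spikes must lie in
#'   `[v3, v4]` ms (defaults 1 and 5 — the latency range typical of
#'   excitatory coupling between neighbouring neurons);
#' * `v5`: the standard deviation of all CCG deltas must be below `v5` ms
#'   (default 2.7), filtering electrodes contaminated by multiple neurons;
#' * `v6`: verification-flag threshold (default 0.25) — for single-electrode
#'   targets, if the CV of `abs(amplitude)` over all spikes on the electrode
#'   exceeds `v6`, the electrode likely records several units and the
#'   coupling is flagged for manual review.
#'
#' @param v1,v2,v3,v4,v5,v6 Thresholds as described above.
#' @param window One-sided CCG window in ms (default `c(0.5, 10)`).
#' @param peak_window Moving peak window in ms (default 3).
#' @param bin_width CCG bin width in ms (default 0.05).
#' @return A list of class `axo_criteria`.
#' @export
coupling_criteria <- function(v1 = 0.1, v2 = 0.57, v3 = 1, v4 = 5,
                              v5 = 2.7, v6 = 0.25,
                              window = c(0.5, 10), peak_window = 3,
                              bin_width = 0.05) {
  if (!(v1 > 0 && v1 <= 1)) abort("v1 must be in (0, 1]")
  if (!(v2 > 0 && v2 <= 1)) abort("v2 must be in (0, 1]")
  if (!(v3 < v4)) abort("v3 must be below v4")
  if (!(v5 > 0)) abort("v5 must be positive")
  structure(list(v1 = v1, v2 = v2, v3 = v3, v4 = v4, v5 = v5, v6 = v6,
                 window = window, peak_window = peak_window,
                 bin_width = bin_width),
            class = "axo_criteria")
}

#' Evaluate one candidate coupling
#'
#' Applies the acceptance criteria (see [coupling_criteria()]) to a
#' one-sided CCG. The coupling probability is the ratio of spikes in the CCG
#' peak (`n2`) over the number of reference signal spikes (`n`); latency
#' mean/sd are computed from the peak-window deltas.
#'
#' @param ccg An `axo_ccg` from [coupling_ccg()].
#' @param criteria A [coupling_criteria()] object.
#' @param target_amplitudes Amplitudes (µV, signed or absolute) of *all*
#'   spikes on the target electrode, used for the `v6` verification flag;
#'   leave `NULL` for signal targets.
#' @return A one-row tibble (class `axo_couplings`) with columns
#'   `reference_id`, `target_id`, `target_type`, `accepted`, `reason`,
#'   `coupling_probability`, `mean_latency_ms`, `sd_latency_ms`,
#'   `n_coupled`, `n_ref`, `n1`, `flag` and list-column `coupled_idx`
#'   (indices of peak-window spikes into the target train).
#' @export
evaluate_coupling <- function(ccg, criteria = coupling_criteria(),
                              target_amplitudes = NULL) {
  stopifnot(inherits(ccg, "axo_ccg"))
  n <- ccg$n_ref
  n1 <- sum(ccg$counts)
  target_type <- if (is.null(target_amplitudes)) "signal" else "electrode"
  flag <- 0L
  if (!is.null(target_amplitudes) && length(target_amplitudes) >= 2) {
    a <- abs(target_amplitudes)
    if (mean(a) > 0 && stats::sd(a) / mean(a) > criteria$v6) flag <- 1L
  }
  res <- function(accepted, reason, prob = NA_real_, mlat = NA_real_,
                  slat = NA_real_, n2 = NA_integer_, idx = integer()) {
    out <- tibble::tibble(
      reference_id = ccg$reference_id, target_id = ccg$target_id,
      target_type = target_type, accepted = accepted, reason = reason,
      coupling_probability = prob, mean_latency_ms = mlat,
      sd_latency_ms = slat, n_coupled = n2, n_ref = n, n1 = n1,
      flag = flag, coupled_idx = list(idx))
    class(out) <- unique(c("axo_couplings", class(out)))
    out
  }
  if (n == 0) {
    return(res(FALSE, "no reference spikes"))
  }
  # peak-window summary is computed even for rejected candidates, so the
  # rejection log still reports the (sub-threshold) probability and latency
  wb <- max(1L, as.integer(round(criteria$peak_window / ccg$bin_width)))
  mw <- moving_window_max(ccg$counts, wb)
  n2 <- as.integer(mw$max)
  win_lo <- ccg$breaks[mw$start_bin]
  win_hi <- ccg$breaks[min(mw$start_bin + wb, length(ccg$breaks))]
  inside <- ccg$deltas > win_lo & ccg$deltas <= win_hi
  peak_deltas <- ccg$deltas[inside]
  idx <- sort(unique(ccg$target_idx[inside]))
  mlat <- if (length(peak_deltas) > 0) mean(peak_deltas) else NA_real_
  slat <- if (length(peak_deltas) >= 2) stats::sd(peak_deltas) else NA_real_
  prob <- n2 / n
  if (n1 / n <= criteria$v1) {
    return(res(FALSE, sprintf("coupling ratio n1/n = %.3f <= v1", n1 / n),
               prob, mlat, slat, n2, idx))
  }
  if (n2 / n1 <= criteria$v2) {
    return(res(FALSE, sprintf("peak concentration n2/n1 = %.3f <= v2", n2 / n1),
               prob, mlat, slat, n2, idx))
  }
  if (mlat < criteria$v3 || mlat > criteria$v4) {
    return(res(FALSE, sprintf("mean latency %.2f ms outside [v3, v4]", mlat),
               prob, mlat, slat, n2, idx))
  }
  sd_all <- if (length(ccg$deltas) >= 2) stats::sd(ccg$deltas) else 0
  if (!(sd_all < criteria$v5)) {
    return(res(FALSE, sprintf("latency sd %.2f ms >= v5", sd_all),
               prob, mlat, slat, n2, idx))
  }
  res(TRUE, "accepted", prob, mlat, slat, n2, idx)
}

#' Detect all couplings in a recording
#'
#' Uses every propagation signal's spike times as reference events and
#' evaluates a one-sided CCG against every other signal and every electrode
#' not belonging to the reference signal's own cohort. Returns the full
#' evaluation log; accepted couplings have `accepted == TRUE`, rejected
#' candidates carry the first criterion that failed in `reason`.
#'
#' @param signals An `axo_signals` object with assigned spike times
#'   (see [assign_signal_spike_times()]).
#' @param rec The [mea_recording()].
#' @param criteria A [coupling_criteria()] object.
#' @param min_target_spikes Electrode targets with fewer spikes are skipped
#'   (default 1, i.e. any active electrode).
#' @return An `axo_couplings` tibble (see [evaluate_coupling()]).
#' @export
detect_all_couplings <- function(signals, rec,
                                 criteria = coupling_criteria(),
                                 min_target_spikes = 1) {
  trains <- spike_trains(rec)
  rows <- list()
  for (i in seq_len(nrow(signals))) {
    ref_times <- signals$spike_times[[i]]
    ref_id <- signals$signal_id[i]
    if (length(ref_times) == 0) next
    own <- signals$electrodes[[i]]$electrode
    for (j in seq_len(nrow(signals))) {
      if (i == j) next
      ccg <- coupling_ccg(ref_times, signals$spike_times[[j]],
                          window = criteria$window,
                          bin_width = criteria$bin_width,
                          reference_id = ref_id,
                          target_id = signals$signal_id[j])
      rows[[length(rows) + 1]] <- evaluate_coupling(ccg, criteria)
    }
    for (el in setdiff(names(trains), own)) {
      if (length(trains[[el]]$times) < min_target_spikes) next
      ccg <- coupling_ccg(ref_times, trains[[el]]$times,
                          window = criteria$window,
                          bin_width = criteria$bin_width,
                          reference_id = ref_id, target_id = el)
      rows[[length(rows) + 1]] <- evaluate_coupling(
        ccg, criteria, target_amplitudes = trains[[el]]$amplitudes)
    }
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- evaluate_coupling(coupling_ccg(numeric(), numeric()))[0, ]
  }
  class(out) <- unique(c("axo_couplings", class(out)))
  out
}

#' Amplitudes of the coupled spikes
#'
#' Extracts the absolute amplitudes of the peak-window (coupled) spikes of
#' an electrode-target coupling, for downstream KS comparison against the
#' electrode's full amplitude distribution.
#'
#' @param coupling A single row of an `axo_couplings` tibble with
#'   `target_type == "electrode"`.
#' @param target The target electrode's spike train: a tibble with
#'   `amplitude_uV` (ordered by time) or the list form from
#'   [spike_trains()].
#' @return Numeric vector of absolute amplitudes (µV).
#' @export
coupled_spike_amplitudes <- function(coupling, target) {
  if (nrow(coupling) != 1) abort("pass exactly one coupling row")
  if (coupling$target_type != "electrode") {
    abort("coupled spike amplitudes apply only to electrode targets")
  }
  amps <- if (is.data.frame(target)) target$amplitude_uV else target$amplitudes
  idx <- coupling$coupled_idx[[1]]
  abs(amps[idx])
}

#' Stimulation-referenced coupling
#'
#' Evaluates coupling using external stimulation onset times as the
#' reference events. Latency is measured from stimulation onset; target
#' spikes inside the post-stimulus blanking period (during which no usable
#' voltage exists) are masked.
#'
#' @param stim_times Stimulation onset times in seconds.
#' @param target Target spike train (numeric times or tibble with `time_s`).
#' @param criteria A [coupling_criteria()] object.
#' @param blanking_ms Blanking period in ms (default 1.5).
#' @param target_amplitudes Optional amplitudes for the `v6` flag.
#' @param stim_id,target_id Identifiers.
#' @return A one-row `axo_couplings` tibble.
#' @export
stimulation_coupling <- function(stim_times, target,
                                 criteria = coupling_criteria(),
                                 blanking_ms = 1.5,
                                 target_amplitudes = NULL,
                                 stim_id = "stim", target_id = NA_character_) {
  ccg <- coupling_ccg(stim_times, target, window = criteria$window,
                      bin_width = criteria$bin_width,
                      blanking_ms = blanking_ms,
                      reference_id = stim_id, target_id = target_id)
  evaluate_coupling(ccg, criteria, target_amplitudes = target_amplitudes)
}

#' Upstream (presynaptic) input probabilities
#'
#' The reverse-direction analysis: for a postsynaptic propagation signal,
#' the probability that each candidate input fired shortly *before* its
#' spikes. Unlike the forward coupling probability, this uses at-least-one
#' counting: probability = (number of postsynaptic spikes with >= 1
#' candidate spike in the window) / (number of postsynaptic spikes). The
#' default window is 0.5--10 ms before the postsynaptic spike (a 9.5 ms
#' window).
#'
#' @param post_times Postsynaptic signal spike times in seconds.
#' @param candidates Named list of candidate spike-time vectors (signals or
#'   single electrodes).
#' @param window Window in ms relative to the postsynaptic spike
#'   (default `c(-10, -0.5)`).
#' @return A tibble with one row per candidate: `candidate`, `probability`,
#'   `mean_latency_ms` (mean lead time of candidate spikes in the window),
#'   `n_post`.
#' @export
upstream_inputs <- function(post_times, candidates, window = c(-10, -0.5)) {
  post_times <- event_times(post_times)
  if (length(post_times) == 0) abort("no postsynaptic spikes")
  if (is.null(names(candidates))) {
    names(candidates) <- paste0("input", seq_along(candidates))
  }
  purrr::imap_dfr(candidates, function(cand, id) {
    p <- window_pairs(post_times, event_times(cand), window[1], window[2])
    hit <- unique(p$ref_idx)
    tibble::tibble(
      candidate = id,
      probability = length(hit) / length(post_times),
      mean_latency_ms = if (length(p$delta_ms) > 0) mean(-p$delta_ms) else NA_real_,
      n_post = length(post_times))
  })
}

#' @export
glance.axo_couplings <- function(x, ...) {
  acc <- x[x$accepted, , drop = FALSE]
  tibble::tibble(
    n_evaluated = nrow(x), n_accepted = nrow(acc),
    n_flagged = sum(acc$flag == 1),
    mean_probability = if (nrow(acc)) mean(acc$coupling_probability) else NA_real_,
    mean_latency_ms = if (nrow(acc)) mean(acc$mean_latency_ms) else NA_real_)
}

#' @export
autoplot.axo_couplings <- function(object, ...) {
  acc <- object[object$accepted, , drop = FALSE]
  ggplot2::ggplot(acc, ggplot2::aes(x = .data$mean_latency_ms,
                                    y = .data$coupling_probability)) +
    ggplot2::geom_point(ggplot2::aes(colour = factor(.data$flag)), ...) +
    ggplot2::labs(x = "mean latency (ms)", y = "coupling probability",
                  colour = "flag") +
    ggplot2::lims(y = c(0, 1)) +
    ggplot2::theme_minimal()
}
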