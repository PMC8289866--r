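#' Raw voltage recordings
#'
#' Container for multi-channel extracellular voltage. Channels are named
#' numeric vectors (µV) sampled at a common rate; the default acquisition
#' rate for the arrays modelled here is 20 kHz.
#'
#' @param channels Named list of equal-length numeric vectors (µV), one per
#'   electrode.
#' @param sampling_rate Sampling rate in Hz.
#' @param electrode_map Optional [electrode_map()]; channel names must be a
#'   subset of its labels when given.
#'
#' @return An object of class `axo_voltage` with elements `channels`,
#'   `sampling_rate`, `n_samples`, `duration`, `electrode_map`.
#' @export
voltage_recording <- function(channels, sampling_rate = 20000,
                              electrode_map = NULL) {
  if (sampling_rate <= 0) abort("sampling_rate must be positive")
  if (length(channels) == 0) abort("at least one channel is required")
  if (is.null(names(channels)) || any(names(channels) == "")) {
    abort("channels must be a named list (electrode labels)")
  }
  lens <- lengths(channels)
  if (length(unique(lens)) != 1) {
    abort("all channels must have identical length")
  }
  if (!is.null(electrode_map)) {
    unknown <- setdiff(names(channels), electrode_map$electrode)
    if (length(unknown) > 0) {
      abort(paste0("channel name(s) not in electrode map: ",
                   paste(unknown, collapse = ", ")))
    }
  }
  structure(
    list(channels = channels, sampling_rate = sampling_rate,
         n_samples = lens[[1]], duration = lens[[1]] / sampling_rate,
         electrode_map = electrode_map),
    class = "axo_voltage"
  )
}

#' @export
print.axo_voltage <- function(x, ...) {
  cat(sprintf("<voltage recording: %d channels, %.3g s @ %g Hz>\n",
              length(x$channels), x$duration, x$sampling_rate))
  invisible(x)
}

#' Zero-phase Butterworth bandpass filter
#'
#' Applies a Butterworth bandpass (default 2nd order, 200--4000 Hz, the
#' standard extracellular spike band) to every channel, forward--backward
#' (zero phase) so that detected spike times are not shifted by filter delay.
#'
#' @param vrec An [voltage_recording()].
#' @param low,high Cutoff frequencies in Hz.
#' @param order Filter order (the order of the underlying low/high sections;
#'   applied twice by the forward--backward pass).
#' @return A filtered `axo_voltage` of identical shape.
#' @export
bandpass_filter <- function(vrec, low = 200, high = 4000, order = 2) {
  stopifnot(inherits(vrec, "axo_voltage"))
  nyq <- vrec$sampling_rate / 2
  if (!(low > 0 && low < high)) abort("need 0 < low < high")
  if (high >= nyq) abort("high cutoff must be below the Nyquist frequency")
  if (order < 1) abort("order must be >= 1")
  bf <- signal::butter(order, c(low, high) / nyq, type = "pass")
  vrec$channels <- lapply(vrec$channels, function(v) {
    as.numeric(signal::filtfilt(bf, v))
  })
  vrec
}

#' Threshold spike detection on filtered voltage
#'
#' Detects negative voltage deflections channel by channel. The noise scale
#' is estimated robustly as `median(abs(v)) / 0.6745` (the median-based
#' estimator commonly used for extracellular recordings, insensitive to the
#' spikes themselves); a spike is recorded at every local negative minimum
#' below `-k * sigma`, with amplitude equal to the minimum sample value and
#' time equal to the minimum's sample time. Detections closer than
#' `dead_time` to a previously kept detection on the same channel are
#' suppressed (earlier detection wins), preventing double counting of
#' multiphasic waveforms.
#'
#' @param vrec A bandpass-filtered [voltage_recording()].
#' @param k Threshold multiplier (default 6).
#' @param dead_time Minimum separation between detections in seconds
#'   (default 1 ms).
#' @return An [mea_recording()] spike table.
#' @export
detect_spikes <- function(vrec, k = 6, dead_time = 1e-3) {
  stopifnot(inherits(vrec, "axo_voltage"))
  if (k <= 0) abort("k must be positive")
  if (dead_time < 0) abort("dead_time must be >= 0")
  fs <- vrec$sampling_rate
  out <- purrr::imap(vrec$channels, function(v, el) {
    n <- length(v)
    if (n < 3) {
      return(NULL)
    }
    sigma <- stats::median(abs(v)) / 0.6745
    thr <- -k * sigma
    mid <- v[2:(n - 1)]
    cand <- which(mid < thr & mid < v[1:(n - 2)] & mid <= v[3:n]) + 1L
    if (length(cand) == 0) {
      return(NULL)
    }
    if (dead_time > 0 && length(cand) > 1) {
      keep <- logical(length(cand))
      last <- -Inf
      gap <- dead_time * fs
      for (i in seq_along(cand)) {
        if (cand[i] - last >= gap) {
          keep[i] <- TRUE
          last <- cand[i]
        }
      }
      cand <- cand[keep]
    }
    tibble::tibble(electrode = el, time_s = (cand - 1) / fs,
                   amplitude_uV = v[cand])
  })
  spikes <- dplyr::bind_rows(out)
  if (nrow(spikes) == 0) {
    spikes <- tibble::tibble(electrode = character(), time_s = numeric(),
                             amplitude_uV = numeric())
  }
  map <- vrec$electrode_map
  if (is.null(map)) {
    map <- electrode_map(names(vrec$channels),
                         x = seq_along(vrec$channels), y = rep(0, length(vrec$channels)))
  }
  mea_recording(spikes, duration = vrec$duration, electrode_map = map)
}
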