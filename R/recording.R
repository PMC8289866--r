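#' Spike-table recordings
#'
#' The atomic data structure of the package is a spike table: one row per
#' detected extracellular action potential (eAP), with the electrode it was
#' detected on, its time in seconds and its negative-peak amplitude in µV.
#' `mea_recording()` validates a spike table and attaches the recording
#' duration, electrode map and free-form condition metadata as attributes.
#'
#' Amplitudes are stored signed (negative deflections); all amplitude
#' distribution comparisons in the package use `abs(amplitude_uV)`.
#'
#' @param spikes A data frame with columns `electrode` (character),
#'   `time_s` (numeric, seconds) and `amplitude_uV` (numeric, negative).
#' @param duration Recording duration in seconds. If `NULL`, the last spike
#'   time (rounded up to the next second) is used.
#' @param electrode_map An [electrode_map()]; defaults to the 120-electrode
#'   array.
#' @param metadata Named list of free-form condition labels (e.g. drug,
#'   temperature).
#'
#' @return A tibble of class `axo_recording`, sorted by electrode and time,
#'   with attributes `duration`, `electrode_map` and `metadata`.
#' @export
#' @examples
#' rec <- mea_recording(
#'   tibble::tibble(
#'     electrode = c("A4", "A4", "B4"),
#'     time_s = c(0.5, 1.2, 0.8),
#'     amplitude_uV = c(-40, -38, -25)
#'   ),
#'   duration = 2
#' )
mea_recording <- function(spikes, duration = NULL,
                          electrode_map = default_electrode_map(),
                          metadata = list()) {
  spikes <- tibble::as_tibble(spikes)
  required <- c("electrode", "time_s", "amplitude_uV")
  missing_cols <- setdiff(required, names(spikes))
  if (length(missing_cols) > 0) {
    abort(paste0("spike table is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  spikes$electrode <- as.character(spikes$electrode)
  validate_spike_table(spikes, electrode_map)
  if (is.null(duration)) {
    duration <- if (nrow(spikes) == 0) 0 else ceiling(max(spikes$time_s))
  }
  if (nrow(spikes) > 0 && max(spikes$time_s) > duration) {
    abort("spike times exceed the stated recording duration")
  }
  spikes <- dplyr::arrange(spikes, .data$electrode, .data$time_s)
  attr(spikes, "duration") <- duration
  attr(spikes, "electrode_map") <- electrode_map
  attr(spikes, "metadata") <- metadata
  class(spikes) <- unique(c("axo_recording", class(spikes)))
  spikes
}

#' Validate a spike table
#'
#' Checks electrode labels against the map, strict monotonicity of times per
#' electrode, and negativity of amplitudes. Errors name the offending rows.
#'
#' @inheritParams mea_recording
#' @return Invisibly, `spikes`.
#' @export
validate_spike_table <- function(spikes, electrode_map = default_electrode_map()) {
  if (nrow(spikes) == 0) {
    return(invisible(spikes))
  }
  unknown <- !spikes$electrode %in% electrode_map$electrode
  if (any(unknown)) {
    abort(paste0("unknown electrode label(s) at row(s) ",
                 paste(utils::head(which(unknown), 5), collapse = ", "),
                 ": ", paste(unique(spikes$electrode[unknown]), collapse = ", ")))
  }
  if (any(!is.finite(spikes$time_s)) || any(spikes$time_s < 0)) {
    abort("spike times must be finite and non-negative")
  }
  bad_amp <- spikes$amplitude_uV >= 0
  if (any(bad_amp)) {
    abort(paste0("amplitudes must be negative (negative-peak µV); offending row(s): ",
                 paste(utils::head(which(bad_amp), 5), collapse = ", ")))
  }
  ord <- order(spikes$electrode, spikes$time_s)
  sorted <- spikes[ord, ]
  same_el <- sorted$electrode[-1] == sorted$electrode[-nrow(sorted)]
  dt <- diff(sorted$time_s)
  dup <- same_el & dt <= 0
  if (any(dup)) {
    abort(paste0("spike times must be strictly increasing per electrode; ",
                 "duplicate time on electrode ",
                 sorted$electrode[which(dup)[1] + 1]))
  }
  # monotonicity within the original row order, so CSV input errors point at rows
  by_el <- split(seq_len(nrow(spikes)), spikes$electrode)
  for (rows in by_el) {
    t <- spikes$time_s[rows]
    bad <- which(diff(t) <= 0)
    if (length(bad) > 0) {
      abort(paste0("non-monotone spike times on electrode ",
                   spikes$electrode[rows[1]], " at input row ",
                   rows[bad[1] + 1]))
    }
  }
  invisible(spikes)
}

#' @export
print.axo_recording <- function(x, ...) {
  cat(sprintf("<MEA recording: %d spikes on %d electrodes, %.4g s>\n",
              nrow(x), dplyr::n_distinct(x$electrode), rec_duration(x)))
  NextMethod()
}

#' Recording accessors
#'
#' @param rec An `axo_recording`.
#' @return `rec_duration()`: duration in seconds; `rec_map()`: the electrode
#'   map; `spike_trains()`: a named list (one entry per active electrode) of
#'   lists with elements `times` and `amplitudes`.
#' @export
rec_duration <- function(rec) {
  d <- attr(rec, "duration")
  if (is.null(d)) {
    d <- if (nrow(rec) == 0) 0 else max(rec$time_s)
  }
  d
}

#' @rdname rec_duration
#' @export
rec_map <- function(rec) {
  m <- attr(rec, "electrode_map")
  if (is.null(m)) default_electrode_map() else m
}

#' @rdname rec_duration
#' @export
spike_trains <- function(rec) {
  if (nrow(rec) == 0) {
    return(list())
  }
  idx <- split(seq_len(nrow(rec)), rec$electrode)
  lapply(idx, function(i) {
    o <- i[order(rec$time_s[i])]
    list(times = rec$time_s[o], amplitudes = rec$amplitude_uV[o])
  })
}

#' Read and write spike tables (CSV)
#'
#' The on-disk format is a plain CSV with columns
#' `electrode,time_s,amplitude_uV`, preceded by `#`-comment header lines
#' carrying the recording duration and metadata, so that write-then-read
#' round-trips the recording exactly (to printed precision).
#'
#' @param path File path.
#' @param electrode_map Electrode map used for validation on read.
#' @return `read_spike_table()` returns an [mea_recording()].
#' @export
read_spike_table <- function(path, electrode_map = default_electrode_map()) {
  header <- character()
  con <- file(path, "r")
  on.exit(close(con))
  repeat {
    line <- readLines(con, n = 1)
    if (length(line) == 0 || !startsWith(line, "#")) break
    header <- c(header, line)
  }
  duration <- NULL
  metadata <- list()
  for (h in header) {
    h <- sub("^#\\s*", "", h)
    if (grepl("^duration_s:", h)) {
      duration <- as.numeric(sub("^duration_s:\\s*", "", h))
    } else if (grepl("^meta\\.", h)) {
      key <- sub("^meta\\.([^:]+):.*$", "\\1", h)
      metadata[[key]] <- sub("^meta\\.[^:]+:\\s*", "", h)
    }
  }
  spikes <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                            col_types = readr::cols(
                              electrode = readr::col_character(),
                              time_s = readr::col_double(),
                              amplitude_uV = readr::col_double()
                            ))
  mea_recording(spikes, duration = duration, electrode_map = electrode_map,
                metadata = metadata)
}

#' @rdname read_spike_table
#' @param rec An `axo_recording` (or plain spike table).
#' @export
write_spike_table <- function(rec, path) {
  duration <- rec_duration(rec)
  meta <- attr(rec, "metadata")
  lines <- sprintf("# duration_s: %.10g", duration)
  if (length(meta) > 0) {
    lines <- c(lines, sprintf("# meta.%s: %s", names(meta),
                              vapply(meta, as.character, character(1))))
  }
  writeLines(lines, path)
  readr::write_csv(tibble::tibble(electrode = rec$electrode,
                                  time_s = rec$time_s,
                                  amplitude_uV = rec$amplitude_uV),
                   path, append = TRUE, col_names = TRUE)
  invisible(path)
}
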