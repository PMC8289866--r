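#' Detect propagation signals
#'
#' A propagation signal is a cohort of electrodes that detect the same
#' axon's action potential in a fixed order with fixed sub-millisecond
#' delays; its spikes are thereby self-classified as coming from one neuron,
#' without spike sorting. Detection: every electrode is used in turn as a
#' reference; a +-2 ms cross-correlogram is computed against every other
#' electrode, and targets whose [propagation_ratio()] exceeds
#' `ratio_threshold` (strictly) are collected with their delays. If every
#' such target lags the reference (all delays non-negative), the reference
#' is the cohort origin and a signal is emitted. Signals detected from
#' different reference electrodes that describe the same cohort (>= 2 shared
#' electrodes with delays agreeing within `merge_tol_ms` after offsetting)
#' are merged, keeping the variant with the most electrodes and the earliest
#' origin.
#'
#' Jitter can make a genuinely simultaneous cohort-mate measure an
#' epsilon-negative delay; delays down to `-bin_width/2` are therefore
#' treated as non-negative and clamped to zero.
#'
#' @param rec An [mea_recording()] spike table.
#' @param ratio_threshold Minimum propagation ratio (strict; default 0.3).
#' @param window CCG window in ms (default `c(-2, 2)`).
#' @param moving_window Sliding-window length in ms (default 0.5).
#' @param bin_width CCG bin width in ms (default 0.05).
#' @param min_electrodes Minimum cohort size including the origin (default 2).
#' @param min_ref_spikes Electrodes with fewer spikes than this are not used
#'   as references or cohort members (default 5): the count ratio is
#'   meaningless on nearly empty trains.
#' @param merge_tol_ms Delay agreement tolerance used when merging duplicate
#'   cohorts (default 0.2 ms).
#'
#' @return An object of class `axo_signals`: a tibble with one row per
#'   signal — `signal_id`, `origin`, `anchor_first`, `anchor_second`,
#'   `n_electrodes`, `n_spikes`, plus list-columns `electrodes` (tibbles of
#'   `electrode`, `delay_ms`, `n_cooccur`) and `spike_times` (filled by
#'   [assign_signal_spike_times()]).
#' @export
detect_propagation_signals <- function(rec, ratio_threshold = 0.3,
                                       window = c(-2, 2), moving_window = 0.5,
                                       bin_width = 0.05, min_electrodes = 2,
                                       min_ref_spikes = 5,
                                       merge_tol_ms = 0.2) {
  trains <- spike_trains(rec)
  trains <- trains[vapply(trains, function(tr) length(tr$times), 0L) >= min_ref_spikes]
  electrodes <- names(trains)
  neg_tol <- bin_width / 2
  raw <- list()
  for (ei in electrodes) {
    ref <- trains[[ei]]$times
    cohort <- list()
    all_nonneg <- TRUE
    for (ej in electrodes) {
      if (ej == ei) next
      ccg <- pairwise_ccg(ref, trains[[ej]]$times, window = window,
                          bin_width = bin_width,
                          reference_id = ei, target_id = ej)
      pr <- propagation_ratio(ccg, moving_window)
      if (pr$ratio > ratio_threshold) {
        if (pr$delay_ms < -neg_tol) {
          all_nonneg <- FALSE
          break
        }
        cohort[[length(cohort) + 1]] <- tibble::tibble(
          electrode = ej, delay_ms = max(0, pr$delay_ms),
          n_cooccur = pr$n_win)
      }
    }
    if (!all_nonneg || length(cohort) < min_electrodes - 1) next
    members <- dplyr::bind_rows(
      tibble::tibble(electrode = ei, delay_ms = 0,
                     n_cooccur = length(ref)),
      dplyr::bind_rows(cohort)
    )
    members <- dplyr::arrange(members, .data$delay_ms, .data$electrode)
    raw[[length(raw) + 1]] <- members
  }
  raw <- merge_duplicate_cohorts(raw, merge_tol_ms)
  rows <- purrr::map(raw, function(members) {
    origin <- members$electrode[1]
    n_per_el <- vapply(members$electrode,
                       function(el) length(trains[[el]]$times), 0L)
    others <- members$electrode[-1]
    anchor_second <- others[which.max(n_per_el[-1])]
    tibble::tibble(
      signal_id = origin,
      origin = origin,
      anchor_first = origin,
      anchor_second = anchor_second,
      n_electrodes = nrow(members),
      n_spikes = NA_integer_,
      electrodes = list(members),
      spike_times = list(numeric())
    )
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble::tibble(
      signal_id = character(), origin = character(),
      anchor_first = character(), anchor_second = character(),
      n_electrodes = integer(), n_spikes = integer(),
      electrodes = list(), spike_times = list())
  }
  class(out) <- unique(c("axo_signals", class(out)))
  out
}

# delay-profile agreement between two cohorts on their shared electrodes
cohorts_match <- function(a, b, tol_ms = 0.2, min_shared = 2) {
  shared <- intersect(a$electrode, b$electrode)
  if (length(shared) < min_shared) {
    return(list(match = FALSE))
  }
  da <- a$delay_ms[match(shared, a$electrode)]
  db <- b$delay_ms[match(shared, b$electrode)]
  offset <- mean(da - db)
  list(match = all(abs((da - db) - offset) <= tol_ms), offset = offset)
}

merge_duplicate_cohorts <- function(raw, tol_ms) {
  if (length(raw) <= 1) {
    return(raw)
  }
  keep <- rep(TRUE, length(raw))
  for (i in seq_along(raw)) {
    if (!keep[i]) next
    for (j in seq_along(raw)) {
      if (i == j || !keep[j]) next
      m <- cohorts_match(raw[[i]], raw[[j]], tol_ms)
      if (!m$match) next
      # prefer the larger cohort; on ties, the earlier origin
      # (offset > 0 means i's origin fires later in shared time)
      drop_i <- if (nrow(raw[[i]]) != nrow(raw[[j]])) {
        nrow(raw[[i]]) < nrow(raw[[j]])
      } else {
        m$offset > 0
      }
      if (drop_i) {
        keep[i] <- FALSE
        break
      } else {
        keep[j] <- FALSE
      }
    }
  }
  raw[keep]
}

#' Assign spike times to propagation signals
#'
#' Each signal's spike times are computed from its two anchor electrodes:
#' the earliest electrode of the cohort and the electrode with the most
#' spikes among the rest. Spikes on the two anchors occurring in quick
#' succession (within `co_occurrence_window` ms, matched greedily one-to-one
#' in time order) form co-occurrences; the signal spike time is the mean of
#' the two spike times. Unmatched spikes are dropped. A signal whose anchors
#' share no co-occurrences is retained with empty spike times and a warning.
#'
#' @param signals An `axo_signals` object.
#' @param rec The [mea_recording()] the signals were detected in.
#' @param co_occurrence_window Matching window in ms (default 2).
#' @return `signals` with `spike_times` and `n_spikes` filled in.
#' @export
assign_signal_spike_times <- function(signals, rec, co_occurrence_window = 2) {
  trains <- spike_trains(rec)
  for (i in seq_len(nrow(signals))) {
    e1 <- signals$anchor_first[i]
    ex <- signals$anchor_second[i]
    t1 <- if (e1 %in% names(trains)) trains[[e1]]$times else numeric()
    tx <- if (ex %in% names(trains)) trains[[ex]]$times else numeric()
    times <- cooccurrence_times(t1, tx, co_occurrence_window)
    if (length(times) == 0) {
      warn(sprintf("signal %s: anchors %s/%s share no co-occurrences",
                   signals$signal_id[i], e1, ex))
    }
    signals$spike_times[[i]] <- times
    signals$n_spikes[i] <- length(times)
  }
  signals
}

# greedy one-to-one matching of anchor spikes; returns mean times of matches
cooccurrence_times <- function(t1, tx, window_ms = 2) {
  if (length(t1) == 0 || length(tx) == 0) {
    return(numeric())
  }
  w <- window_ms * 1e-3
  used_until <- 0L # tx indices <= used_until are consumed
  out <- numeric(length(t1))
  n_out <- 0L
  nx <- length(tx)
  for (t in t1) {
    lo <- findInterval(t - w, tx) + 1L       # first tx >= t - w
    hi <- findInterval(t + w, tx)            # last tx <= t + w
    lo <- max(lo, used_until + 1L)
    if (lo > hi || lo > nx) next
    cand <- lo:hi
    j <- cand[which.min(abs(tx[cand] - t))]
    used_until <- j
    n_out <- n_out + 1L
    out[n_out] <- (t + tx[j]) / 2
  }
  sort(out[seq_len(n_out)])
}

#' @export
print.axo_signals <- function(x, ...) {
  cat(sprintf("<%d propagation signal(s)>\n", nrow(x)))
  NextMethod()
}

#' @export
tidy.axo_signals <- function(x, ...) {
  if (nrow(x) == 0) {
    return(tibble::tibble(signal_id = character(), electrode = character(),
                          delay_ms = numeric(), n_cooccur = integer()))
  }
  dplyr::select(
    tidyr::unnest(tibble::as_tibble(x)[, c("signal_id", "electrodes")],
                  "electrodes"),
    "signal_id", "electrode", "delay_ms", "n_cooccur")
}

#' @export
glance.axo_signals <- function(x, ...) {
  tibble::tibble(
    n_signals = nrow(x),
    n_electrodes_total = sum(x$n_electrodes),
    n_spikes_total = sum(x$n_spikes, na.rm = TRUE)
  )
}
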