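#' Cross-correlograms between event series and spike trains
#'
#' A cross-correlogram (CCG) collects, for every reference event, the time
#' differences `delta = t_target - t_ref` (in ms) of all target spikes inside
#' a window, and bins them. The raw deltas are retained alongside the binned
#' counts so that latency statistics and per-spike amplitude lookups stay
#' exact. Window membership uses the half-open convention `(lo, hi]`.
#'
#' `pairwise_ccg()` is the symmetric-window form used for propagation
#' detection (default +-2 ms); `coupling_ccg()` is the one-sided form used
#' for synaptic-coupling detection (default 0.5--10 ms after the reference),
#' optionally masking a post-stimulus blanking period.
#'
#' @param ref Reference event times: a numeric vector (seconds) or a spike
#'   train tibble with a `time_s` column.
#' @param target Target spike train: numeric vector (seconds) or tibble with
#'   `time_s`.
#' @param window Length-2 numeric window in ms relative to reference events.
#' @param bin_width Bin width in ms (default 0.05 ms, one sample at 20 kHz).
#' @param reference_id,target_id Identifiers carried into the result.
#'
#' @return An object of class `axo_ccg`: a list with `reference_id`,
#'   `target_id`, `window`, `bin_width`, `breaks`, `counts`, `deltas` (ms),
#'   `target_idx` (index of the target spike behind each delta), `ref_idx`,
#'   and `n_ref`.
#' @export
#' @examples
#' ccg <- pairwise_ccg(c(0, 1, 2), c(0.0003, 1.0003, 2.0003))
#' sum(ccg$counts) # 3, all deltas 0.3 ms
pairwise_ccg <- function(ref, target, window = c(-2, 2), bin_width = 0.05,
                         reference_id = NA_character_, target_id = NA_character_) {
  new_ccg(event_times(ref), event_times(target), window, bin_width,
          reference_id, target_id)
}

#' @rdname pairwise_ccg
#' @param blanking_ms If not `NULL`, target spikes with delta below this
#'   value (ms) are excluded — the analysis analogue of the post-stimulation
#'   blanking period during which no voltage data exist.
#' @export
coupling_ccg <- function(ref, target, window = c(0.5, 10), bin_width = 0.05,
                         blanking_ms = NULL,
                         reference_id = NA_character_, target_id = NA_character_) {
  if (window[1] < 0) abort("coupling CCG window must be one-sided (after the reference)")
  ccg <- new_ccg(event_times(ref), event_times(target), window, bin_width,
                 reference_id, target_id)
  if (!is.null(blanking_ms) && blanking_ms > window[1]) {
    keep <- ccg$deltas >= blanking_ms
    ccg$deltas <- ccg$deltas[keep]
    ccg$target_idx <- ccg$target_idx[keep]
    ccg$ref_idx <- ccg$ref_idx[keep]
    ccg$counts <- bin_deltas(ccg$deltas, ccg$breaks)
  }
  ccg
}

event_times <- function(x) {
  if (is.data.frame(x)) {
    if (!"time_s" %in% names(x)) abort("spike table must have a time_s column")
    return(as.numeric(x$time_s))
  }
  as.numeric(x)
}

# all (ref, target) pairs with t_target - t_ref in (lo, hi] ms
window_pairs <- function(ref, target, lo_ms, hi_ms) {
  if (length(ref) == 0 || length(target) == 0) {
    return(list(ref_idx = integer(), target_idx = integer(), delta_ms = numeric()))
  }
  lo <- lo_ms * 1e-3
  hi <- hi_ms * 1e-3
  i0 <- findInterval(ref + lo, target)           # targets <= ref + lo excluded
  i1 <- findInterval(ref + hi, target)           # targets <= ref + hi included
  n <- i1 - i0
  pos <- n > 0
  if (!any(pos)) {
    return(list(ref_idx = integer(), target_idx = integer(), delta_ms = numeric()))
  }
  tgt_idx <- sequence(n[pos], from = i0[pos] + 1L)
  ref_idx <- rep.int(which(pos), n[pos])
  delta <- (target[tgt_idx] - ref[ref_idx]) * 1e3
  list(ref_idx = ref_idx, target_idx = tgt_idx, delta_ms = delta)
}

bin_deltas <- function(deltas, breaks) {
  nb <- length(breaks) - 1L
  if (length(deltas) == 0) {
    return(integer(nb))
  }
  lo <- breaks[1]
  bw <- breaks[2] - breaks[1]
  idx <- pmin.int(pmax.int(ceiling((deltas - lo) / bw), 1L), nb)
  tabulate(idx, nb)
}

new_ccg <- function(ref, target, window, bin_width, reference_id, target_id) {
  if (length(window) != 2 || window[1] >= window[2]) {
    abort("window must be an ordered length-2 vector (ms)")
  }
  if (bin_width <= 0) abort("bin_width must be positive")
  nb <- as.integer(ceiling((window[2] - window[1]) / bin_width - 1e-9))
  breaks <- window[1] + bin_width * (0:nb)
  breaks[nb + 1] <- window[2]
  p <- window_pairs(ref, target, window[1], window[2])
  structure(
    list(reference_id = reference_id, target_id = target_id,
         window = window, bin_width = bin_width, breaks = breaks,
         counts = bin_deltas(p$delta_ms, breaks),
         deltas = p$delta_ms, target_idx = p$target_idx, ref_idx = p$ref_idx,
         n_ref = length(ref)),
    class = "axo_ccg"
  )
}

#' @export
print.axo_ccg <- function(x, ...) {
  cat(sprintf("<CCG %s -> %s: window (%g, %g] ms, %d counts over %d reference events>\n",
              x$reference_id, x$target_id, x$window[1], x$window[2],
              sum(x$counts), x$n_ref))
  invisible(x)
}

#' @export
tidy.axo_ccg <- function(x, ...) {
  nb <- length(x$counts)
  tibble::tibble(
    bin_lo = x$breaks[seq_len(nb)],
    bin_hi = x$breaks[seq_len(nb) + 1],
    bin_mid = (x$breaks[seq_len(nb)] + x$breaks[seq_len(nb) + 1]) / 2,
    count = x$counts
  )
}

#' @export
autoplot.axo_ccg <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$bin_mid, y = .data$count)) +
    ggplot2::geom_col(width = object$bin_width, fill = "grey30") +
    ggplot2::labs(
      x = "latency relative to reference (ms)", y = "count",
      title = sprintf("CCG %s → %s", object$reference_id, object$target_id)
    ) +
    ggplot2::theme_minimal()
}

# rolling sum over wb consecutive bins; returns max value and first-bin index
moving_window_max <- function(counts, wb) {
  nb <- length(counts)
  wb <- min(wb, nb)
  cs <- c(0, cumsum(counts))
  sums <- cs[(wb + 1):(nb + 1)] - cs[1:(nb - wb + 1)]
  i <- which.max(sums) # first maximum on ties
  list(max = sums[i], start_bin = i, n_windows = nb - wb + 1)
}

#' Propagation ratio of a pairwise CCG
#'
#' Computes `n_win / n_all`, where `n_win` is the largest sum of counts in
#' any `moving_window` ms sliding window (slid one bin at a time) and
#' `n_all` is the number of spikes on the reference electrode. A ratio above
#' 0.3 indicates a consistent spike-time delay between the electrodes —
#' the signature of axonal propagation. The delay is the count-weighted mean
#' of the raw deltas inside the maximizing window.
#'
#' @param ccg An `axo_ccg` from [pairwise_ccg()].
#' @param moving_window Sliding window length in ms (default 0.5).
#' @return A list with `ratio`, `delay_ms`, `n_win`, `n_all` and the
#'   maximizing window bounds `win_lo`, `win_hi` (ms).
#' @export
propagation_ratio <- function(ccg, moving_window = 0.5) {
  stopifnot(inherits(ccg, "axo_ccg"))
  span <- ccg$window[2] - ccg$window[1]
  if (moving_window <= 0 || moving_window > span + 1e-9) {
    abort("moving_window must be positive and no longer than the CCG window")
  }
  if (ccg$n_ref == 0 || sum(ccg$counts) == 0) {
    return(list(ratio = 0, delay_ms = NA_real_, n_win = 0L, n_all = ccg$n_ref,
                win_lo = NA_real_, win_hi = NA_real_))
  }
  wb <- max(1L, as.integer(round(moving_window / ccg$bin_width)))
  mw <- moving_window_max(ccg$counts, wb)
  win_lo <- ccg$breaks[mw$start_bin]
  win_hi <- ccg$breaks[min(mw$start_bin + wb, length(ccg$breaks))]
  inside <- ccg$deltas > win_lo & ccg$deltas <= win_hi
  list(ratio = mw$max / ccg$n_ref,
       delay_ms = mean(ccg$deltas[inside]),
       n_win = as.integer(mw$max), n_all = ccg$n_ref,
       win_lo = win_lo, win_hi = win_hi)
}

#' Latency summary statistics
#'
#' Mean, sample standard deviation and coefficient of variation (CV =
#' sd/mean) of a set of latencies. A low CV (~0.08) is the signature of
#' axonal propagation; coupled (putatively synaptic) latencies have CVs an
#' order of magnitude higher (~0.5).
#'
#' @param deltas Numeric latencies in ms (n >= 2).
#' @return A one-row tibble with `mean_ms`, `sd_ms`, `cv`, `n`.
#' @export
#' @examples
#' latency_stats(c(1, 3)) # mean 2, sd sqrt(2), cv ~0.707
latency_stats <- function(deltas) {
  n <- length(deltas)
  if (n < 2) abort("latency CV is undefined for fewer than 2 latencies")
  m <- mean(deltas)
  s <- stats::sd(deltas)
  tibble::tibble(mean_ms = m, sd_ms = s,
                 cv = if (m == 0) NA_real_ else s / m, n = n)
}
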