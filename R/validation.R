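#' Two-sample Kolmogorov--Smirnov comparison
#'
#' Two-sided two-sample KS statistic with asymptotic p-value, as used to
#' test whether coupled spikes could have been drawn at random from an
#' electrode's full amplitude distribution.
#'
#' @param a,b Numeric samples (n >= 1 each).
#' @param label Optional comparison label.
#' @return One-row tibble: `statistic`, `p_value`, `n_a`, `n_b`, `label`.
#' @export
ks_two_sample <- function(a, b, label = NA_character_) {
  if (length(a) == 0 || length(b) == 0) abort("both samples must be non-empty")
  kt <- suppressWarnings(stats::ks.test(a, b, alternative = "two.sided",
                                        exact = FALSE))
  tibble::tibble(statistic = unname(kt$statistic),
                 p_value = unname(kt$p.value),
                 n_a = length(a), n_b = length(b), label = label)
}

#' Coupled-versus-random amplitude comparisons
#'
#' Draws `n_draws` random subsets (without replacement) of the electrode's
#' full amplitude set, each the size of the coupled set, and KS-compares
#' each draw with the coupled amplitudes. If the coupled spikes come from a
#' single neuron on a multi-unit (multimodal) electrode, every comparison
#' should reject; on a genuinely single-unit (unimodal) electrode they
#' should not. `mode = "random-vs-random"` instead compares two independent
#' random draws per repetition — the null control in which ~95% of
#' comparisons should exceed a 5% significance threshold.
#'
#' @param coupled_amps Absolute amplitudes of the coupled spikes.
#' @param all_amps Absolute amplitudes of all spikes on the electrode.
#' @param n_draws Number of random draws.
#' @param seed Integer seed.
#' @param mode `"coupled-vs-random"` or `"random-vs-random"`.
#' @return A tibble of [ks_two_sample()] rows, one per draw.
#' @export
coupled_vs_random_amplitude_test <- function(coupled_amps, all_amps,
                                             n_draws = 100, seed = 1,
                                             mode = c("coupled-vs-random",
                                                      "random-vs-random")) {
  mode <- match.arg(mode)
  m <- length(coupled_amps)
  if (m > length(all_amps)) {
    abort("coupled set cannot be larger than the full amplitude set")
  }
  if (n_draws == 0) {
    return(ks_two_sample(0, 0)[0, ])
  }
  coupled_amps <- abs(coupled_amps)
  all_amps <- abs(all_amps)
  withr::with_seed(seed, {
    purrr::map_dfr(seq_len(n_draws), function(i) {
      if (mode == "coupled-vs-random") {
        ks_two_sample(coupled_amps, sample(all_amps, m), label = mode)
      } else {
        ks_two_sample(sample(all_amps, m), sample(all_amps, m), label = mode)
      }
    })
  })
}

#' ISI-preserving spike-time shuffle
#'
#' Builds a surrogate spike train by randomly permuting the original
#' inter-spike intervals and cumulating them from the first spike time. The
#' ISI multiset (and hence the overall firing pattern, count, first spike
#' and total span) is preserved exactly while fine timing relative to other
#' trains is destroyed. Amplitudes, if present, keep their original order:
#' the control concerns timing only.
#'
#' @param train A numeric vector of spike times (s) or a tibble with
#'   `time_s` (and optionally `amplitude_uV`).
#' @param seed Integer seed.
#' @return Same type as `train`, with shuffled times. Trains with fewer
#'   than 2 spikes are returned unchanged.
#' @export
isi_shuffle <- function(train, seed = 1) {
  times <- event_times(train)
  if (length(times) < 2) {
    return(train)
  }
  new_times <- withr::with_seed(seed, {
    isi <- diff(times)
    times[1] + cumsum(c(0, isi[sample.int(length(isi))]))
  })
  if (is.data.frame(train)) {
    train$time_s <- new_times
    train
  } else {
    new_times
  }
}

#' Chance-coupling ratio
#'
#' The ratio of the number of target spikes that fall within the window
#' (default 0.5--10 ms) after *any* reference spike — each target spike
#' counted once — over the number of reference spikes. Unlike a probability
#' this ratio can exceed 1.
#'
#' @param ref_times Reference spike times (s).
#' @param target Target spike train (times or tibble).
#' @param window Window in ms (default `c(0.5, 10)`).
#' @return A single number.
#' @export
chance_coupling_ratio <- function(ref_times, target, window = c(0.5, 10)) {
  ref_times <- event_times(ref_times)
  if (length(ref_times) == 0) abort("no reference spikes")
  p <- window_pairs(ref_times, event_times(target), window[1], window[2])
  length(unique(p$target_idx)) / length(ref_times)
}

#' Shuffle control for a detected coupling
#'
#' Compares the observed [chance_coupling_ratio()] of a reference/target
#' pair with its distribution over `n_reps` ISI-shuffled surrogates of the
#' target train. A genuine coupling collapses under shuffling (the observed
#' ratio far exceeds every surrogate); chance associations do not.
#'
#' @param ref_times Reference (propagation-signal) spike times in seconds.
#' @param target Target spike train (times or tibble).
#' @param n_reps Number of shuffle repetitions.
#' @param seed Integer seed (repetition r uses sub-seed `seed + r`).
#' @param window Window in ms.
#' @return An object of class `axo_shuffle`: list with `original_ratio`,
#'   `shuffled_ratios`, `n_reps`, `seed`.
#' @export
shuffle_control <- function(ref_times, target, n_reps = 20, seed = 1,
                            window = c(0.5, 10)) {
  ref_times <- event_times(ref_times)
  target_times <- event_times(target)
  original <- chance_coupling_ratio(ref_times, target_times, window)
  shuffled <- vapply(seq_len(n_reps), function(r) {
    chance_coupling_ratio(ref_times, isi_shuffle(target_times, seed = seed + r),
                          window)
  }, numeric(1))
  structure(list(original_ratio = original, shuffled_ratios = shuffled,
                 n_reps = n_reps, seed = seed),
            class = "axo_shuffle")
}

#' @export
print.axo_shuffle <- function(x, ...) {
  cat(sprintf("<shuffle control: original ratio %.4f, shuffled %.4f +- %.4f (n = %d)>\n",
              x$original_ratio, mean(x$shuffled_ratios),
              stats::sd(x$shuffled_ratios), x$n_reps))
  invisible(x)
}

#' @export
tidy.axo_shuffle <- function(x, ...) {
  tibble::tibble(rep = seq_len(x$n_reps), shuffled_ratio = x$shuffled_ratios,
                 original_ratio = x$original_ratio)
}

#' @export
autoplot.axo_shuffle <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$shuffled_ratio)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey60") +
    ggplot2::geom_vline(xintercept = object$original_ratio,
                        colour = "red", linetype = 2) +
    ggplot2::labs(x = "chance-coupling ratio",
                  subtitle = "red: observed; grey: ISI-shuffled surrogates") +
    ggplot2::theme_minimal()
}
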