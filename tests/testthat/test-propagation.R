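# Propagation-signal detection and spike-time assignment.

# recording with one planted axon crossing three electrodes
axon_recording <- function(n = 500, delays_ms = c(0, 0.3, 0.6),
                           jitter = 0.02, duration = 300, seed = 1,
                           electrodes = c("A4", "B4", "C4")) {
  withr::with_seed(seed, {
    base <- sort(runif(n, 1, duration - 1))
    rows <- purrr::map2_dfr(electrodes, delays_ms, function(el, d) {
      tibble::tibble(electrode = el,
                     time_s = base + d * 1e-3 + rnorm(n, 0, jitter * 1e-3),
                     amplitude_uV = rnorm(n, -45, 4))
    })
  })
  rows <- dplyr::arrange(rows, electrode, time_s)
  mea_recording(rows, duration = duration)
}

test_that("a planted three-electrode axon is recovered exactly once", {
  rec <- axon_recording(seed = 2)
  sig <- detect_propagation_signals(rec)
  expect_equal(nrow(sig), 1)
  cohort <- sig$electrodes[[1]]
  expect_equal(cohort$electrode, c("A4", "B4", "C4"))
  expect_true(all(diff(cohort$delay_ms) > 0))
  expect_equal(cohort$delay_ms, c(0, 0.3, 0.6), tolerance = 0.05)
})

test_that("independent Poisson electrodes never form a signal", {
  for (seed in 1:20) {
    withr::with_seed(seed, {
      spikes <- dplyr::bind_rows(
        tibble::tibble(electrode = "A4", time_s = sort(runif(300, 0, 300)),
                       amplitude_uV = -40),
        tibble::tibble(electrode = "B4", time_s = sort(runif(300, 0, 300)),
                       amplitude_uV = -40))
    })
    rec <- mea_recording(spikes, duration = 300)
    expect_equal(nrow(detect_propagation_signals(rec)), 0)
  }
})

test_that("a single active electrode yields no signal", {
  rec <- mea_recording(
    tibble::tibble(electrode = "A4", time_s = sort(runif(50, 0, 60)),
                   amplitude_uV = -40), duration = 60)
  expect_equal(nrow(detect_propagation_signals(rec)), 0)
})

test_that("zero-delay cohorts are merged to a single signal", {
  withr::with_seed(4, {
    base <- sort(runif(400, 1, 299))
  })
  spikes <- dplyr::bind_rows(
    tibble::tibble(electrode = "A4", time_s = base, amplitude_uV = -40),
    tibble::tibble(electrode = "B4", time_s = base + 1e-5, amplitude_uV = -42))
  rec <- mea_recording(spikes, duration = 300)
  sig <- detect_propagation_signals(rec)
  expect_equal(nrow(sig), 1)
})

test_that("emitted signals always satisfy sorted non-negative delays", {
  sim <- simulate_recording(simulation_config(duration = 120, n_units = 3,
                                              seed = 6))
  sig <- detect_propagation_signals(sim$recording)
  for (i in seq_len(nrow(sig))) {
    d <- sig$electrodes[[i]]$delay_ms
    expect_true(all(d >= 0))
    expect_true(!is.unsorted(d))
    expect_equal(d[1], 0)
  }
})

test_that("anchor co-occurrence averaging matches the arithmetic mean", {
  spikes <- dplyr::bind_rows(
    tibble::tibble(electrode = "A4", time_s = c(1.0, 2.0), amplitude_uV = -40),
    tibble::tibble(electrode = "B4", time_s = c(1.0003, 2.0003),
                   amplitude_uV = -42))
  rec <- mea_recording(spikes, duration = 3)
  sig <- tibble::tibble(
    signal_id = "A4", origin = "A4", anchor_first = "A4", anchor_second = "B4",
    n_electrodes = 2L, n_spikes = NA_integer_,
    electrodes = list(tibble::tibble(electrode = c("A4", "B4"),
                                     delay_ms = c(0, 0.3), n_cooccur = 2L)),
    spike_times = list(numeric()))
  class(sig) <- c("axo_signals", class(sig))
  out <- assign_signal_spike_times(sig, rec)
  expect_equal(out$spike_times[[1]], c(1.00015, 2.00015), tolerance = 1e-9)

  # silent second anchor: empty times with a warning
  rec2 <- mea_recording(spikes[1:2, ], duration = 3)
  expect_warning(out2 <- assign_signal_spike_times(sig, rec2),
                 "no co-occurrences")
  expect_equal(out2$n_spikes[1], 0L)
})

test_that("co-occurrence matching is one-to-one and greedy in time order", {
  # two e1 spikes compete for one ex spike: the earlier one wins
  t1 <- c(1.0000, 1.0010)
  tx <- c(1.0005)
  expect_equal(axocouple:::cooccurrence_times(t1, tx, 2),
               (1.0000 + 1.0005) / 2)
})

test_that("assigned signal latencies reproduce the propagation regime", {
  # 1000 co-occurrences at 0.305 ms mean inter-anchor latency with 0.024 ms
  # latency sd (per-electrode jitter 0.024/sqrt(2)): CV ~ 0.08
  rec <- axon_recording(n = 1000, delays_ms = c(0, 0.305),
                        jitter = 0.024 / sqrt(2), duration = 600, seed = 11,
                        electrodes = c("H6", "D6"))
  sig <- assign_signal_spike_times(detect_propagation_signals(rec), rec)
  expect_equal(sig$n_spikes[1], 1000)
  tr <- spike_trains(rec)
  # latency distribution of the co-occurring spikes (tight window so stray
  # chance coincidences from unrelated spikes do not enter the statistics)
  p <- axocouple:::window_pairs(tr$H6$times, tr$D6$times, 0, 0.6)
  stats <- latency_stats(p$delta_ms)
  expect_lt(abs(stats$mean_ms - 0.305), 0.01)
  expect_lt(abs(stats$cv - 0.078), 0.03)
})
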