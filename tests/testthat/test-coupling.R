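# Short-latency coupling detection: the one-sided CCG, the v1-v6
# acceptance criteria, and the reverse (presynaptic-input) analysis.

test_that("coupling CCG applies the one-sided 0.5-10 ms window", {
  expect_equal(sum(coupling_ccg(1.0, 1.0024)$counts), 1)
  expect_equal(coupling_ccg(1.0, 1.0024)$deltas, 2.4, tolerance = 1e-9)
  expect_equal(sum(coupling_ccg(1.0, 1.0002)$counts), 0) # 0.2 ms < 0.5 ms
  expect_equal(sum(coupling_ccg(numeric(), c(1, 2))$counts), 0)
})

test_that("one-sided CCG counts match the coincidence expectation and oracle", {
  withr::with_seed(14, {
    ref <- sort(runif(400, 0, 200))
    target <- sort(runif(600, 0, 200))
  })
  ccg <- coupling_ccg(ref, target)
  oracle <- brute_force_ccg(ref, target, 0.5, 10)
  expect_equal(sum(ccg$counts), length(oracle))
  expected <- length(ref) * (600 / 200) * 9.5e-3
  expect_lt(abs(sum(ccg$counts) - expected), 3 * sqrt(expected))
})

test_that("blanking masks early post-stimulus spikes", {
  ccg <- coupling_ccg(1.0, c(1.0008, 1.003), blanking_ms = 1.5)
  expect_equal(ccg$deltas, 3, tolerance = 1e-9)
})

test_that("evaluate_coupling enforces each criterion and reports the failure", {
  # v1: 500 refs but only 10 counts -> ratio 0.02
  withr::with_seed(3, {
    ref <- sort(runif(500, 0, 500))
  })
  target <- sort(ref[1:10] + 3e-3)
  out <- evaluate_coupling(coupling_ccg(ref, target))
  expect_false(out$accepted)
  expect_match(out$reason, "v1")

  # mean latency above v4
  withr::with_seed(4, {
    target2 <- sort(ref + rnorm(500, 8e-3, 3e-4))
  })
  out2 <- evaluate_coupling(coupling_ccg(ref, target2))
  expect_false(out2$accepted)
  expect_match(out2$reason, "v3, v4")

  # no reference spikes
  out3 <- evaluate_coupling(coupling_ccg(numeric(), c(1, 2)))
  expect_match(out3$reason, "no reference spikes")

  # rejected candidates still report their sub-threshold probability
  expect_false(is.na(out$coupling_probability))
})

test_that("planted couplings are recovered with accurate probability and latency", {
  errs <- purrr::map_dfr(1:10, function(seed) {
    pair <- make_coupled_pair(p = 0.4, mu = 2.5, sd = 0.8, seed = seed)
    out <- evaluate_coupling(coupling_ccg(pair$ref, pair$target))
    tibble::tibble(accepted = out$accepted,
                   p_err = out$coupling_probability - 0.4,
                   lat_err = out$mean_latency_ms - 2.5)
  })
  expect_true(all(errs$accepted))
  expect_lt(mean(abs(errs$p_err)), 0.05)
  expect_lt(mean(abs(errs$lat_err)), 0.2)
})

test_that("accepted couplings satisfy the criteria when re-checked independently", {
  crit <- coupling_criteria()
  for (seed in 1:5) {
    pair <- make_coupled_pair(p = 0.5, seed = 100 + seed)
    out <- evaluate_coupling(coupling_ccg(pair$ref, pair$target), crit)
    if (!out$accepted) next
    deltas <- brute_force_ccg(pair$ref, pair$target, 0.5, 10)
    n1 <- length(deltas)
    expect_gt(n1 / length(pair$ref), crit$v1)
    # brute-force peak: max count over 3 ms windows anchored on bin edges
    starts <- seq(0.5, 10 - 3, by = crit$bin_width)
    n2 <- max(vapply(starts, function(s) {
      sum(deltas > s & deltas <= s + 3)
    }, numeric(1)))
    expect_equal(out$n_coupled, as.integer(n2))
    expect_gt(n2 / n1, crit$v2)
    expect_gte(out$mean_latency_ms, crit$v3)
    expect_lte(out$mean_latency_ms, crit$v4)
    expect_lt(sd(deltas), crit$v5)
  }
})

test_that("recovered probability degrades monotonically with planted probability", {
  grid <- c(0.05, 0.2, 0.5, 0.8)
  p_hat <- vapply(grid, function(p) {
    mean(vapply(1:3, function(s) {
      pair <- make_coupled_pair(p = p, seed = 200 + round(100 * p) + s)
      out <- evaluate_coupling(coupling_ccg(pair$ref, pair$target))
      out$coupling_probability
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(p_hat) > 0))
  # below v1 the coupling must be rejected
  pair <- make_coupled_pair(p = 0.05, seed = 999)
  expect_false(evaluate_coupling(coupling_ccg(pair$ref, pair$target))$accepted)
})

test_that("detect_all_couplings finds exactly the planted connections", {
  cfg <- simulation_config(
    duration = 300, n_units = 3,
    couplings = tibble::tibble(pre = c(1, 1), post = c(2, 3),
                               probability = c(0.5, 0.3),
                               latency_mean_ms = 2.5, latency_sd_ms = 0.4),
    background_rate_hz = 0, seed = 8)
  sim <- simulate_recording(cfg)
  sig <- assign_signal_spike_times(detect_propagation_signals(sim$recording),
                                   sim$recording)
  cp <- detect_all_couplings(sig, sim$recording)
  sc <- score_recovery(sim$truth, sig, cp)
  expect_equal(sc$coupling_precision, 1)
  expect_equal(sc$coupling_recall, 1)
  ss <- dplyr::filter(cp, accepted, target_type == "signal")
  expect_equal(nrow(ss), 2)
})

test_that("a lone signal with no other activity yields an empty coupling set", {
  cfg <- simulation_config(duration = 120, n_units = 1,
                           background_rate_hz = 0, seed = 9)
  sim <- simulate_recording(cfg)
  sig <- assign_signal_spike_times(detect_propagation_signals(sim$recording),
                                   sim$recording)
  cp <- detect_all_couplings(sig, sim$recording)
  expect_equal(sum(cp$accepted), 0)
})

test_that("coupled_spike_amplitudes extracts the peak-window spikes", {
  cp <- evaluate_coupling(coupling_ccg(c(1, 2), c(1.003, 1.5, 2.0031),
                                       reference_id = "s1", target_id = "E5"),
                          target_amplitudes = c(-40, -20, -42))
  amps <- coupled_spike_amplitudes(cp, list(amplitudes = c(-40, -20, -42)))
  expect_equal(sort(amps), c(40, 42))

  cp_sig <- evaluate_coupling(coupling_ccg(c(1, 2), c(1.003, 2.0031)))
  expect_error(coupled_spike_amplitudes(cp_sig, list(amplitudes = -40)),
               "electrode targets")
})

test_that("the v6 flag marks multi-unit electrodes by amplitude CV", {
  withr::with_seed(10, {
    uni <- rnorm(500, -40, 3)
    bi <- c(rnorm(250, -45, 3), rnorm(250, -20, 2))
  })
  ref <- seq(1, 100, by = 0.5)
  target <- ref + 2.5e-3
  flag_uni <- evaluate_coupling(coupling_ccg(ref, target),
                                target_amplitudes = uni)$flag
  flag_bi <- evaluate_coupling(coupling_ccg(ref, target),
                               target_amplitudes = bi)$flag
  expect_equal(flag_uni, 0L)
  expect_equal(flag_bi, 1L)
})

test_that("stimulation-referenced coupling reproduces a probability from counts", {
  stim <- seq(1, 500, by = 1) # 500 stimulation events
  withr::with_seed(12, {
    coupled <- sort(sample(stim, 393)) + rnorm(393, 5.93e-3, 3e-4)
  })
  out <- stimulation_coupling(stim, sort(coupled), blanking_ms = 1.5)
  expect_equal(out$n_ref, 500)
  expect_equal(out$n_coupled, 393L)
  expect_equal(round(out$coupling_probability, 2), 0.79)
})

test_that("upstream input probabilities use at-least-one counting", {
  post <- c(1, 2, 3)
  up <- upstream_inputs(post, list(a = post - 2e-3, b = numeric()))
  expect_equal(up$probability[up$candidate == "a"], 1)
  expect_equal(up$probability[up$candidate == "b"], 0)
  expect_equal(up$mean_latency_ms[up$candidate == "a"], 2, tolerance = 1e-9)
  expect_error(upstream_inputs(numeric(), list(a = 1)), "no postsynaptic")

  # planted presynaptic driver at p = 0.3 plus independent firing,
  # checked against a per-post-spike brute-force count
  withr::with_seed(13, {
    cand <- sort(runif(600, 0, 300))
    driven <- cand[runif(600) < 0.3] + 3e-3
    post2 <- sort(c(driven, runif(200, 0, 300)))
  })
  up2 <- upstream_inputs(post2, list(drv = cand))
  brute <- mean(vapply(post2, function(t) {
    any(cand >= t - 10e-3 & cand <= t - 0.5e-3)
  }, logical(1)))
  expect_equal(up2$probability, brute, tolerance = 1e-12)
})
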