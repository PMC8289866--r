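# Independent brute-force oracles used to check the vectorised implementations.

# all-pairs double loop: counts of t_target - t_ref in (lo, hi] ms, plus the
# raw deltas, computed without findInterval
brute_force_ccg <- function(ref, target, lo_ms, hi_ms) {
  deltas <- numeric()
  for (r in ref) {
    for (t in target) {
      d <- (t - r) * 1e3
      if (d > lo_ms && d <= hi_ms) deltas <- c(deltas, d)
    }
  }
  deltas
}

brute_force_bins <- function(deltas, breaks) {
  nb <- length(breaks) - 1
  counts <- integer(nb)
  for (d in deltas) {
    for (b in seq_len(nb)) {
      if (d > breaks[b] && d <= breaks[b + 1]) {
        counts[b] <- counts[b] + 1L
        break
      }
      # first bin is closed below by the window itself
      if (b == 1 && d == breaks[1]) break
    }
  }
  counts
}

# max |ECDF_a - ECDF_b| evaluated at every sample point
brute_force_ks_d <- function(a, b) {
  pts <- sort(unique(c(a, b)))
  max(abs(vapply(pts, function(x) mean(a <= x) - mean(b <= x), numeric(1))))
}

rand_train <- function(n, duration = 10, seed = NULL) {
  gen <- function() sort(runif(n, 0, duration))
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

# Poisson train plus a coupled follower: each ref spike triggers a target
# spike with probability p at latency N(mu, sd) ms
make_coupled_pair <- function(rate = 2, duration = 300, p = 0.4, mu = 2.5,
                              sd = 0.5, target_rate = 1, seed = 1) {
  withr::with_seed(seed, {
    ref <- sort(runif(rpois(1, rate * duration), 0, duration))
    fired <- runif(length(ref)) < p
    trig <- ref[fired] + pmax(rnorm(sum(fired), mu, sd), 0.1) * 1e-3
    target <- sort(c(trig, runif(rpois(1, target_rate * duration), 0, duration)))
    list(ref = ref, target = target, n_triggered = sum(fired))
  })
}
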