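# Connectivity graphs over propagation signals and cross-condition diffs.

fake_signals <- function(ids, delay0 = 0) {
  rows <- purrr::imap(ids, function(id, k) {
    tibble::tibble(
      signal_id = id, origin = id, anchor_first = id,
      anchor_second = paste0(id, "b"), n_electrodes = 2L, n_spikes = 100L,
      electrodes = list(tibble::tibble(
        electrode = c(id, paste0(id, "x")),
        delay_ms = c(0, 0.3 + delay0), n_cooccur = 100L)),
      spike_times = list(seq(1, 10, length.out = 5)))
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("axo_signals", class(out))
  out
}

fake_couplings <- function(from, to, prob = 0.5) {
  out <- tibble::tibble(
    reference_id = from, target_id = to, target_type = "signal",
    accepted = TRUE, reason = "accepted",
    coupling_probability = rep_len(prob, length(from)),
    mean_latency_ms = 2.5, sd_latency_ms = 0.5,
    n_coupled = 50L, n_ref = 100L, n1 = 55L, flag = 0L,
    coupled_idx = replicate(length(from), integer(), simplify = FALSE))
  class(out) <- c("axo_couplings", class(out))
  out
}

test_that("graphs keep isolated nodes and count recurrent pairs as two edges", {
  sigs <- fake_signals(paste0("s", 1:10))
  # 29 couplings among 8 of the 10 signals
  withr::with_seed(19, {
    pool <- paste0("s", 1:8)
    pairs <- expand.grid(from = pool, to = pool, stringsAsFactors = FALSE)
    pairs <- pairs[pairs$from != pairs$to, ]
    pick <- pairs[sample(nrow(pairs), 29), ]
  })
  g <- build_graph(fake_couplings(pick$from, pick$to), sigs, "control")
  expect_equal(igraph::vcount(g$graph), 10)
  expect_equal(igraph::ecount(g$graph), 29)

  g0 <- build_graph(fake_couplings(character(), character()), sigs)
  expect_equal(igraph::ecount(g0$graph), 0)
  expect_equal(igraph::vcount(g0$graph), 10)

  g2 <- build_graph(fake_couplings(c("s1", "s2"), c("s2", "s1")), sigs)
  expect_equal(igraph::ecount(g2$graph), 2)
  expect_equal(glance(g2)$n_recurrent_pairs, 1L)

  expect_error(build_graph(fake_couplings("s1", "zz"), sigs), "unknown signal")
})

test_that("graph diff partitions edges into retained, lost and gained", {
  sigs <- fake_signals(c("x", "y", "z"))
  ga <- build_graph(fake_couplings(c("x", "y", "x"), c("y", "z", "z")), sigs, "A")
  gb <- build_graph(fake_couplings("x", "y"), sigs, "B")
  d <- diff_graphs(ga, gb)
  expect_equal(nrow(d$retained), 1)
  expect_equal(paste(d$retained$source, d$retained$target), "x y")
  expect_equal(nrow(d$lost), 2)
  expect_equal(nrow(d$gained), 0)
  # partition exactness
  expect_equal(nrow(d$retained) + nrow(d$lost), igraph::ecount(ga$graph))

  d0 <- diff_graphs(ga, ga)
  expect_equal(nrow(d0$lost), 0)
  expect_equal(nrow(d0$gained), 0)
})

test_that("edge partition is disjoint and exhaustive on random graphs", {
  sigs <- fake_signals(paste0("n", 1:6))
  for (seed in 1:10) {
    withr::with_seed(seed, {
      all_pairs <- expand.grid(f = sigs$signal_id, t = sigs$signal_id,
                               stringsAsFactors = FALSE)
      all_pairs <- all_pairs[all_pairs$f != all_pairs$t, ]
      ea <- all_pairs[runif(nrow(all_pairs)) < 0.3, ]
      eb <- all_pairs[runif(nrow(all_pairs)) < 0.3, ]
    })
    ga <- build_graph(fake_couplings(ea$f, ea$t), sigs, "A")
    gb <- build_graph(fake_couplings(eb$f, eb$t), sigs, "B")
    d <- diff_graphs(ga, gb)
    key <- function(df) paste(df$source, df$target)
    expect_equal(length(intersect(key(d$retained), key(d$lost))), 0)
    expect_equal(length(intersect(key(d$retained), key(d$gained))), 0)
    expect_equal(nrow(d$retained) + nrow(d$lost), nrow(ea))
    expect_equal(nrow(d$retained) + nrow(d$gained), nrow(eb))
  }
})

test_that("condition-degraded couplings below v1 appear as lost edges", {
  sigs <- fake_signals(c("a", "b", "c"))
  probs <- c(0.4, 0.15, 0.12)
  ctrl <- fake_couplings(c("a", "a", "b"), c("b", "c", "c"), probs)
  degraded <- ctrl
  degraded$coupling_probability <- probs / 2
  degraded$accepted <- degraded$coupling_probability > 0.1 # v1 re-applied
  ga <- build_graph(ctrl, sigs, "control")
  gb <- build_graph(degraded, sigs, "treated")
  d <- diff_graphs(ga, gb)
  lostkey <- paste(d$lost$source, d$lost$target)
  expect_setequal(lostkey, c("a c", "b c")) # exactly those with p/2 < 0.1
})

test_that("signal matching across recordings tolerates a delay offset", {
  a <- fake_signals(c("p", "q"))
  b <- fake_signals(c("p", "r"))
  # same cohorts -> p matches p; r's cohort electrodes differ -> new node
  m <- match_signals(a, b)
  expect_equal(m$a_id[m$b_id == "p"], "p")
  expect_true(is.na(m$a_id[m$b_id == "r"]))

  # ambiguity: two a-signals with identical cohorts
  a2 <- fake_signals(c("p", "q"))
  a2$electrodes[[2]] <- a2$electrodes[[1]]
  expect_error(match_signals(a2, fake_signals("p")), "ambiguous")
})

test_that("graphs round-trip through the edge-list CSV", {
  sigs <- fake_signals(c("x", "y", "z"))
  g <- build_graph(fake_couplings(c("x", "y"), c("y", "z"), c(0.4, 0.2)),
                   sigs, "control")
  path <- withr::local_tempfile(fileext = ".csv")
  write_graph_csv(g, path)
  back <- read_graph_csv(path, signals = sigs, condition_label = "control")
  expect_equal(tidy(back), tidy(g))
  expect_equal(igraph::vcount(back$graph), 3)

  gml <- withr::local_tempfile(fileext = ".graphml")
  write_graphml(g, gml)
  reread <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::ecount(reread), 2)
})
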