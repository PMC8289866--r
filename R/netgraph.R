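#' Connectivity graph over propagation signals
#'
#' Builds the directed graph whose nodes are propagation-signal neurons and
#' whose edges are accepted signal-to-signal couplings, annotated with
#' coupling probability and mean latency. Isolated signals are retained as
#' nodes; recurrent pairs (A->B and B->A) are two distinct edges.
#'
#' @param couplings An `axo_couplings` tibble; only rows with
#'   `accepted == TRUE` and `target_type == "signal"` become edges.
#' @param signals An `axo_signals` object supplying the node set.
#' @param condition_label Free-text condition label (e.g. `"control"`).
#' @return An object of class `axo_graph`: list with `graph` (igraph),
#'   `condition_label`, `signals`.
#' @export
build_graph <- function(couplings, signals, condition_label = "") {
  edges <- couplings[couplings$accepted & couplings$target_type == "signal", ,
                     drop = FALSE]
  unknown <- setdiff(c(edges$reference_id, edges$target_id), signals$signal_id)
  if (length(unknown) > 0) {
    abort(paste0("coupling references unknown signal(s): ",
                 paste(unknown, collapse = ", ")))
  }
  if (any(edges$reference_id == edges$target_id)) {
    abort("self-coupling of a signal to itself is not a valid edge")
  }
  edge_df <- data.frame(
    from = edges$reference_id, to = edges$target_id,
    probability = edges$coupling_probability,
    latency_ms = edges$mean_latency_ms)
  g <- igraph::graph_from_data_frame(
    edge_df, directed = TRUE,
    vertices = data.frame(name = signals$signal_id))
  structure(list(graph = g, condition_label = condition_label,
                 signals = signals),
            class = "axo_graph")
}

#' @export
print.axo_graph <- function(x, ...) {
  cat(sprintf("<connectivity graph '%s': %d nodes, %d edges>\n",
              x$condition_label, igraph::vcount(x$graph),
              igraph::ecount(x$graph)))
  invisible(x)
}

#' @export
tidy.axo_graph <- function(x, ...) {
  tibble::as_tibble(igraph::as_data_frame(x$graph, what = "edges")) |>
    dplyr::rename(source = "from", target = "to")
}

#' @export
glance.axo_graph <- function(x, ...) {
  el <- igraph::as_data_frame(x$graph, what = "edges")
  recurrent <- sum(paste(el$from, el$to) %in% paste(el$to, el$from)) / 2
  tibble::tibble(
    condition = x$condition_label,
    n_nodes = igraph::vcount(x$graph),
    n_edges = igraph::ecount(x$graph),
    n_participating = sum(igraph::degree(x$graph) > 0),
    n_recurrent_pairs = as.integer(recurrent))
}

#' @export
plot.axo_graph <- function(x, ...) {
  igraph::plot.igraph(x$graph, edge.arrow.size = 0.4,
                      vertex.color = "grey85", vertex.label.cex = 0.8,
                      main = x$condition_label, ...)
}

#' Match propagation signals across recordings
#'
#' Signals recorded from the same culture under different conditions are
#' identified as the same neuron when their electrode cohorts share at least
#' `min_shared` electrodes with delay profiles agreeing within `tol_ms`
#' after removing a constant offset. Unmatched signals are new nodes. An
#' ambiguous match (one signal matching several) is an error listing the
#' candidates.
#'
#' @param a,b `axo_signals` from the two recordings.
#' @param tol_ms Delay agreement tolerance in ms (default 0.2).
#' @param min_shared Minimum shared electrodes (default 2).
#' @return A tibble with `b_id` and the matching `a_id` (`NA` when new).
#' @export
match_signals <- function(a, b, tol_ms = 0.2, min_shared = 2) {
  purrr::map_dfr(seq_len(nrow(b)), function(j) {
    hits <- character()
    for (i in seq_len(nrow(a))) {
      m <- cohorts_match(a$electrodes[[i]], b$electrodes[[j]], tol_ms, min_shared)
      if (m$match) hits <- c(hits, a$signal_id[i])
    }
    if (length(hits) > 1) {
      abort(paste0("ambiguous match for signal ", b$signal_id[j],
                   ": candidates ", paste(hits, collapse = ", ")))
    }
    tibble::tibble(b_id = b$signal_id[j],
                   a_id = if (length(hits) == 1) hits else NA_character_)
  })
}

#' Compare connectivity graphs across conditions
#'
#' Partitions the union of the two edge sets into edges retained in both,
#' edges lost from condition A and edges gained in condition B, after
#' matching node identities across conditions with [match_signals()].
#'
#' @param a,b `axo_graph` objects for the two conditions.
#' @param matching Optional precomputed [match_signals()] tibble; by default
#'   it is computed from the graphs' signal sets.
#' @return An object of class `axo_graphdiff`: list of tibbles `retained`,
#'   `lost`, `gained` (columns `source`, `target` in A's node namespace
#'   where matched) plus the `matching`.
#' @export
diff_graphs <- function(a, b, matching = NULL) {
  if (is.null(matching)) {
    matching <- match_signals(a$signals, b$signals)
  }
  rename_b <- function(id) {
    hit <- matching$a_id[match(id, matching$b_id)]
    ifelse(is.na(hit), paste0(id, "@", b$condition_label), hit)
  }
  ea <- tidy(a)
  eb <- tidy(b)
  key_a <- paste(ea$source, ea$target, sep = "->")
  eb$source <- rename_b(eb$source)
  eb$target <- rename_b(eb$target)
  key_b <- paste(eb$source, eb$target, sep = "->")
  structure(list(
    retained = ea[key_a %in% key_b, c("source", "target")],
    lost = ea[!key_a %in% key_b, c("source", "target")],
    gained = eb[!key_b %in% key_a, c("source", "target")],
    matching = matching,
    condition_a = a$condition_label, condition_b = b$condition_label),
    class = "axo_graphdiff")
}

#' @export
print.axo_graphdiff <- function(x, ...) {
  cat(sprintf("<graph diff %s vs %s: %d retained, %d lost, %d gained>\n",
              x$condition_a, x$condition_b,
              nrow(x$retained), nrow(x$lost), nrow(x$gained)))
  invisible(x)
}

#' @export
glance.axo_graphdiff <- function(x, ...) {
  tibble::tibble(n_retained = nrow(x$retained), n_lost = nrow(x$lost),
                 n_gained = nrow(x$gained))
}

#' Graph import/export
#'
#' Edge-list CSV (`source,target,probability,latency_ms`) and GraphML
#' round-trips of a connectivity graph.
#'
#' @param graph An `axo_graph`.
#' @param path Output path.
#' @export
write_graph_csv <- function(graph, path) {
  readr::write_csv(tidy(graph), path)
  invisible(path)
}

#' @rdname write_graph_csv
#' @param signals Signal set for the node namespace (defaults to the nodes
#'   present in the file).
#' @param condition_label Condition label for the reconstructed graph.
#' @export
read_graph_csv <- function(path, signals = NULL, condition_label = "") {
  el <- readr::read_csv(path, show_col_types = FALSE)
  node_ids <- if (is.null(signals)) {
    unique(c(el$source, el$target))
  } else {
    signals$signal_id
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = el$source, to = el$target,
               probability = el$probability, latency_ms = el$latency_ms),
    directed = TRUE, vertices = data.frame(name = node_ids))
  structure(list(graph = g, condition_label = condition_label,
                 signals = signals),
            class = "axo_graph")
}

#' @rdname write_graph_csv
#' @export
write_graphml <- function(graph, path) {
  igraph::write_graph(graph$graph, path, format = "graphml")
  invisible(path)
}
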