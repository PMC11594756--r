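#' Restrict a recording to spikes inside burst spans
#'
#' Functional-connectivity profiles are computed on spikes inside detected
#' burst spans — by default only large bursts, which carry the network-level
#' structure that cross-correlation methods resolve best. Burst spans are
#' closed intervals (their endpoints are spikes).
#'
#' @param s a [spike_train_set()].
#' @param bursts result of [detect_network_bursts()] on `s`.
#' @param size_class `"large"`, `"small"`, or `"all"` bursts.
#' @return A [spike_train_set()] containing only the in-span spikes.
#' @export
restrict_to_bursts <- function(s, bursts, size_class = c("large", "all", "small")) {
  stopifnot(inherits(s, "spike_train_set"), inherits(bursts, "network_bursts"))
  size_class <- match.arg(size_class)
  b <- if (size_class == "all") bursts else bursts[bursts$size_class == size_class, , drop = FALSE]
  b <- b[order(b$start_s), , drop = FALSE]
  spk <- lapply(s$spikes, function(t) {
    if (!length(t) || nrow(b) == 0L) return(numeric(0))
    fi <- findInterval(t, b$start_s - 1e-12)
    t[fi >= 1L & t <= b$end_s[pmax(fi, 1L)] + 1e-12]
  })
  spike_train_set(spk, s$duration_s, electrode_ids = s$electrode_ids,
                  group_label = s$meta$group_label, div = s$meta$div,
                  recording_id = s$meta$recording_id, notes = s$meta$notes)
}

# Cumulative delay-synchrony counts for one ordered pair, on millisecond
# spike vectors. counts[k] = number of target spikes having at least one
# source spike strictly earlier by a delay d in (0, k] ms, k = 1..K.
# Each target spike is counted once per window length (via its minimal
# positive delay to the preceding source spike).
.sync_counts <- function(src_ms, tgt_ms, K) {
  counts <- integer(K)
  if (!length(src_ms) || !length(tgt_ms)) return(counts)
  idx <- findInterval(tgt_ms - 0.005, src_ms)   # last source strictly before target
  ok <- idx >= 1L
  d <- tgt_ms[ok] - src_ms[idx[ok]]
  k <- ceiling(d - 1e-9)
  k <- k[k >= 1L & k <= K]
  if (length(k)) counts <- cumsum(tabulate(k, nbins = K))
  counts
}

#' Delay-synchrony profile for one ordered electrode pair
#'
#' For the ordered pair (source `m` -> target `n`), examines `max_delay_ms`
#' cumulative windows of increasing duration (1, 2, ..., `max_delay_ms` ms).
#' `counts[k]` is the number of target spikes preceded by at least one source
#' spike with a delay in `(0, k]` ms; `ratios[k]` divides by the total number
#' of spikes on the target electrode (within the burst restriction). The
#' connection score is the ratio at the largest window (the maximum over
#' windows, since counts are cumulative), and `best_delay_ms` is the
#' half-rise delay: the smallest `k` at which `counts[k]` reaches half of
#' `counts[max_delay_ms]`.
#'
#' @param s a [spike_train_set()].
#' @param bursts result of [detect_network_bursts()] on `s`; profiles are
#'   computed on in-burst spikes only (see `restrict`).
#' @param m,n source and target electrode ids (`m != n`).
#' @param max_delay_ms number of 1 ms delay windows (default 50).
#' @param restrict which spikes enter the profile: spikes inside large-burst
#'   spans (default), inside any burst span, or all spikes.
#' @return A list of class `pair_sync_profile` with elements `m`, `n`,
#'   `counts`, `ratios`, `n_target_spikes`, `score`, `best_delay_ms`.
#' @export
pair_sync_profile <- function(s, bursts, m, n, max_delay_ms = 50L,
                              restrict = c("large", "all", "none")) {
  restrict <- match.arg(restrict)
  if (identical(m, n)) stop("source and target electrodes must differ")
  if (!all(c(m, n) %in% s$electrode_ids)) stop("unknown electrode id")
  r <- if (restrict == "none") s else restrict_to_bursts(s, bursts, size_class = restrict)
  .pair_profile(.to_ms(r$spikes[[m]]), .to_ms(r$spikes[[n]]),
                as.character(m), as.character(n), as.integer(max_delay_ms))
}

.pair_profile <- function(src_ms, tgt_ms, m, n, K) {
  counts <- .sync_counts(src_ms, tgt_ms, K)
  n_tgt <- length(tgt_ms)
  ratios <- if (n_tgt) counts / n_tgt else rep(0, K)
  total <- counts[K]
  structure(list(
    m = m, n = n,
    counts = counts,
    ratios = ratios,
    n_target_spikes = n_tgt,
    score = if (n_tgt) ratios[K] else 0,
    best_delay_ms = if (total > 0L) which(counts >= 0.5 * total)[1L] else NA_integer_),
    class = "pair_sync_profile")
}

#' Delay-synchrony profiles for all ordered electrode pairs
#'
#' @inheritParams pair_sync_profile
#' @return Data frame with one row per ordered pair: `m`, `n`, `score`,
#'   `best_delay_ms`, `n_target_spikes`, and a `counts` list-column.
#' @export
pair_sync_profiles <- function(s, bursts, max_delay_ms = 50L,
                               restrict = c("large", "all", "none")) {
  restrict <- match.arg(restrict)
  r <- if (restrict == "none") s else restrict_to_bursts(s, bursts, size_class = restrict)
  ids <- s$electrode_ids
  trains <- lapply(r$spikes, .to_ms)
  K <- as.integer(max_delay_ms)
  nel <- length(ids)
  res <- vector("list", nel * (nel - 1L))
  pos <- 0L
  for (i in seq_len(nel)) {
    for (j in seq_len(nel)) {
      if (i == j) next
      pos <- pos + 1L
      res[[pos]] <- .pair_profile(trains[[i]], trains[[j]], ids[i], ids[j], K)
    }
  }
  out <- data.frame(
    m = vapply(res, `[[`, character(1), "m"),
    n = vapply(res, `[[`, character(1), "n"),
    score = vapply(res, `[[`, numeric(1), "score"),
    best_delay_ms = vapply(res, function(p) as.integer(p$best_delay_ms), integer(1)),
    n_target_spikes = vapply(res, `[[`, integer(1), "n_target_spikes"),
    stringsAsFactors = FALSE)
  out$counts <- lapply(res, `[[`, "counts")
  out
}

#' Rank electrode pairs by connection strength
#'
#' Sorts profiles by descending score with a deterministic tie-break:
#' smaller half-rise delay first, then lexicographic (source, target) ids.
#' The resulting order is invariant to the input ordering.
#'
#' @param profiles data frame from [pair_sync_profiles()] (columns `m`, `n`,
#'   `score`, `best_delay_ms` required).
#' @return The same data frame sorted, with a `rank` column prepended.
#' @export
rank_pairs <- function(profiles) {
  stopifnot(all(c("m", "n", "score", "best_delay_ms") %in% names(profiles)))
  delay <- ifelse(is.na(profiles$best_delay_ms), Inf, profiles$best_delay_ms)
  ord <- order(-profiles$score, delay, profiles$m, profiles$n, method = "radix")
  out <- profiles[ord, , drop = FALSE]
  rownames(out) <- NULL
  cbind(rank = seq_len(nrow(out)), out)
}

#' Build the directed functional-connectivity graph
#'
#' Selects the strongest `top_fraction` (default 5%) of ranked pairs with a
#' positive score — `ceiling(top_fraction * P)` edges, where `P` is the
#' number of positive-score ordered pairs; zero-score pairs are never
#' selected — and builds a directed graph whose nodes are the electrodes
#' incident to a selected edge. Edge attributes carry the half-rise delay
#' and the score; node degree counts incident edges in both directions.
#'
#' @param ranked output of [rank_pairs()].
#' @param top_fraction fraction of positive-score pairs to keep.
#' @return An object of class `connectivity_graph`: a list with the
#'   [igraph][igraph::graph_from_data_frame] `graph`, the selected `edges`
#'   data frame, a `nodes` data frame (`electrode`, `degree`), and
#'   `n_candidates` (the number of positive-score pairs).
#' @export
build_connectivity_graph <- function(ranked, top_fraction = 0.05) {
  stopifnot(is.data.frame(ranked), top_fraction > 0, top_fraction <= 1)
  pos <- ranked[ranked$score > 0, , drop = FALSE]
  P <- nrow(pos)
  if (P == 0L) {
    g <- igraph::make_empty_graph(n = 0, directed = TRUE)
    return(structure(list(graph = g,
                          edges = data.frame(m = character(0), n = character(0),
                                             delay_ms = integer(0), score = numeric(0)),
                          nodes = data.frame(electrode = character(0), degree = integer(0)),
                          n_candidates = 0L, top_fraction = top_fraction),
                     class = "connectivity_graph"))
  }
  n_sel <- as.integer(ceiling(top_fraction * P))
  sel <- pos[seq_len(n_sel), , drop = FALSE]
  edges <- data.frame(m = sel$m, n = sel$n,
                      delay_ms = sel$best_delay_ms, score = sel$score,
                      stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(
    stats::setNames(edges, c("from", "to", "delay_ms", "score")),
    directed = TRUE)
  deg <- igraph::degree(g, mode = "all")
  nodes <- data.frame(electrode = names(deg), degree = as.integer(deg),
                      stringsAsFactors = FALSE)
  rownames(nodes) <- NULL
  structure(list(graph = g, edges = edges, nodes = nodes,
                 n_candidates = P, top_fraction = top_fraction),
            class = "connectivity_graph")
}

#' @export
print.connectivity_graph <- function(x, ...) {
  cat(sprintf("connectivity_graph: %d nodes, %d edges (top %.0f%% of %d positive pairs)\n",
              nrow(x$nodes), nrow(x$edges), 100 * x$top_fraction, x$n_candidates))
  invisible(x)
}

#' Hub and diameter metrics of a connectivity graph
#'
#' Hubs are nodes whose degree reaches the `hub_quantile` quantile of the
#' nonzero node degrees and is at least 2. The hub coefficient is the mean
#' degree over hub nodes (`NA` when there are none). The diameter is the
#' longest finite shortest-path length (in edges) on the underlying
#' undirected graph; 0 for graphs with fewer than two nodes.
#'
#' @param cg a [build_connectivity_graph()] result.
#' @param hub_quantile degree quantile defining hubs (default 0.90).
#' @return List with `hubs` (electrode ids), `n_hubs`, `hub_coefficient`,
#'   `diameter`, and the `degree_threshold` used.
#' @export
hub_metrics <- function(cg, hub_quantile = 0.90) {
  stopifnot(inherits(cg, "connectivity_graph"))
  deg <- cg$nodes$degree
  if (!length(deg)) {
    return(list(hubs = character(0), n_hubs = 0L, hub_coefficient = NA_real_,
                diameter = 0, degree_threshold = NA_real_))
  }
  thr <- as.numeric(stats::quantile(deg[deg > 0], hub_quantile, names = FALSE))
  is_hub <- deg >= thr & deg >= 2L
  hubs <- cg$nodes$electrode[is_hub]
  diam <- if (nrow(cg$nodes) < 2L) 0 else {
    und <- igraph::as_undirected(cg$graph, mode = "collapse")
    as.numeric(igraph::diameter(und, weights = NA, unconnected = TRUE))
  }
  list(hubs = hubs,
       n_hubs = length(hubs),
       hub_coefficient = if (length(hubs)) mean(deg[is_hub]) else NA_real_,
       diameter = diam,
       degree_threshold = thr)
}

#' Export a connectivity graph
#'
#' Writes the directed graph as GraphML plus edge-list and node-table CSVs.
#'
#' @param cg a [build_connectivity_graph()] result.
#' @param basename output path prefix; writes `<basename>.graphml`,
#'   `<basename>_edges.csv`, `<basename>_nodes.csv`.
#' @param hub_quantile passed to [hub_metrics()] to flag hub nodes in the
#'   node table.
#' @return Character vector of the written paths, invisibly.
#' @export
write_connectivity <- function(cg, basename, hub_quantile = 0.90) {
  stopifnot(inherits(cg, "connectivity_graph"))
  paths <- paste0(basename, c(".graphml", "_edges.csv", "_nodes.csv"))
  igraph::write_graph(cg$graph, paths[1], format = "graphml")
  utils::write.csv(stats::setNames(cg$edges, c("source", "target", "delay_ms", "score")),
                   paths[2], row.names = FALSE)
  hm <- hub_metrics(cg, hub_quantile)
  nodes <- cg$nodes
  nodes$is_hub <- nodes$electrode %in% hm$hubs
  utils::write.csv(nodes, paths[3], row.names = FALSE)
  invisible(paths)
}

#' Score recovery of a planted edge set
#'
#' Compares the selected edge set of a connectivity graph against a planted
#' (ground-truth) edge list: precision and recall on the directed edge set,
#' and the fraction of true-positive edges whose recovered delay lies within
#' `delay_tol_ms` of the planted delay.
#'
#' @param cg a [build_connectivity_graph()] result.
#' @param planted data frame with columns `source`, `target`, `delay_ms`.
#' @param delay_tol_ms delay agreement tolerance in ms (default 2).
#' @return List with `precision`, `recall`, `n_true_positive`, and
#'   `delay_within_tol` (fraction of true positives; `NA` if none).
#' @export
evaluate_edge_recovery <- function(cg, planted, delay_tol_ms = 2) {
  stopifnot(inherits(cg, "connectivity_graph"),
            all(c("source", "target", "delay_ms") %in% names(planted)))
  sel_key <- paste(cg$edges$m, cg$edges$n, sep = "->")
  true_key <- paste(planted$source, planted$target, sep = "->")
  tp <- sel_key %in% true_key
  n_tp <- sum(tp)
  delay_ok <- if (n_tp) {
    planted_delay <- planted$delay_ms[match(sel_key[tp], true_key)]
    mean(abs(cg$edges$delay_ms[tp] - planted_delay) <= delay_tol_ms + 1e-9)
  } else NA_real_
  list(precision = if (nrow(cg$edges)) n_tp / nrow(cg$edges) else NA_real_,
       recall = if (length(true_key)) n_tp / length(unique(true_key)) else NA_real_,
       n_true_positive = n_tp,
       delay_within_tol = delay_ok)
}
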