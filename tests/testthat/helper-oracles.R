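# Independent brute-force oracles used to check the package implementations.
# These deliberately use naive quadratic scans and explicit loops, sharing no
# code with the package internals.

# Exhaustive window-scan network-burst oracle: tests every window anchored at
# each spike (half-open [t, t+w) at 0.01 ms resolution), marks windows with
# >= min_spikes spikes from >= min_electrodes distinct electrodes, merges
# overlapping/abutting qualifying windows, and reports each merged run as a
# burst spanning first to last covered spike.
oracle_detect_bursts <- function(s, window_ms = 50, min_spikes = 4,
                                 min_electrodes = 4, large_threshold = 100) {
  df <- as.data.frame(s)
  empty <- data.frame(start_s = numeric(0), end_s = numeric(0),
                      total_spikes = integer(0), n_electrodes = integer(0),
                      peak_rate = integer(0), size_class = character(0))
  if (!nrow(df)) return(empty)
  ord <- order(df$time_s, match(df$electrode_id, s$electrode_ids))
  t_s <- df$time_s[ord]
  tm <- round(t_s * 1000, 2)
  el <- df$electrode_id[ord]
  n <- length(tm)
  in_window <- function(anchor) which(tm >= anchor - 1e-9 & tm - anchor < window_ms - 0.005)
  qual <- vapply(seq_len(n), function(i) {
    iw <- in_window(tm[i])
    length(iw) >= min_spikes && length(unique(el[iw])) >= min_electrodes
  }, logical(1))
  if (!any(qual)) return(empty)
  qs <- tm[qual]
  spans <- list()
  cs <- qs[1]; ce <- qs[1] + window_ms
  for (q in qs[-1]) {
    if (q <= ce + 1e-9) {
      ce <- max(ce, q + window_ms)
    } else {
      spans[[length(spans) + 1L]] <- c(cs, ce)
      cs <- q; ce <- q + window_ms
    }
  }
  spans[[length(spans) + 1L]] <- c(cs, ce)
  rows <- lapply(spans, function(sp) {
    idx <- which(tm >= sp[1] - 1e-9 & tm < sp[2] - 0.005)
    tb <- tm[idx]
    peak <- max(vapply(seq_along(tb), function(j) {
      sum(tb >= tb[j] - 1e-9 & tb - tb[j] < window_ms - 0.005)
    }, numeric(1)))
    data.frame(start_s = t_s[idx[1]], end_s = t_s[idx[length(idx)]],
               total_spikes = length(idx),
               n_electrodes = length(unique(el[idx])),
               peak_rate = as.integer(peak),
               size_class = if (peak > large_threshold) "large" else "small")
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Nested-loop delay-synchrony oracle: counts[k] = number of target spikes
# with at least one source spike strictly earlier (at 0.01 ms resolution)
# by a delay of at most k ms.
oracle_sync_counts <- function(src_ms, tgt_ms, K = 50) {
  counts <- integer(K)
  for (k in seq_len(K)) {
    c_k <- 0L
    for (t in tgt_ms) {
      if (any(src_ms < t - 0.005 & t - src_ms <= k + 1e-9)) c_k <- c_k + 1L
    }
    counts[k] <- c_k
  }
  counts
}

# Brute-force all-pairs-shortest-path diameter of an undirected graph given
# as an edge data frame (columns m, n): repeated BFS, longest finite path.
oracle_diameter <- function(edges) {
  nodes <- unique(c(edges$m, edges$n))
  if (length(nodes) < 2L) return(0)
  adj <- lapply(stats::setNames(nodes, nodes), function(v) {
    unique(c(edges$n[edges$m == v], edges$m[edges$n == v]))
  })
  best <- 0
  for (src in nodes) {
    dist <- stats::setNames(rep(Inf, length(nodes)), nodes)
    dist[src] <- 0
    frontier <- src
    while (length(frontier)) {
      nxt <- character(0)
      for (v in frontier) {
        for (u in adj[[v]]) {
          if (!is.finite(dist[u])) {
            dist[u] <- dist[v] + 1
            nxt <- c(nxt, u)
          }
        }
      }
      frontier <- nxt
    }
    finite <- dist[is.finite(dist)]
    best <- max(best, max(finite))
  }
  best
}

# Closed-form Kruskal-Wallis H with tie correction, from the rank-sum
# formula, independent of stats::kruskal.test.
oracle_kw_H <- function(values, groups) {
  N <- length(values)
  r <- rank(values)
  g <- split(r, groups)
  H <- 12 / (N * (N + 1)) * sum(vapply(g, function(ri) sum(ri)^2 / length(ri),
                                       numeric(1))) - 3 * (N + 1)
  ties <- table(values)
  H / (1 - sum(ties^3 - ties) / (N^3 - N))
}

# Random bursty spike recording: a mixture of uniform background spikes and
# clustered spikes around a few burst centres, deduplicated per electrode at
# the 0.1 ms data-model resolution.
random_bursty_set <- function(seed, n_electrodes = 8, n_spikes = 300,
                              duration_s = 5, n_clusters = 3,
                              cluster_sd_ms = 15) {
  set.seed(seed)
  ids <- paste0("e", seq_len(n_electrodes))
  n_bg <- ceiling(n_spikes * 0.4)
  n_cl <- n_spikes - n_bg
  centres <- runif(n_clusters, 0.1 * duration_s, 0.9 * duration_s)
  t <- c(runif(n_bg, 0, duration_s),
         rnorm(n_cl, sample(centres, n_cl, replace = TRUE), cluster_sd_ms / 1000))
  t <- pmin(pmax(t, 0), duration_s)
  el <- sample(ids, length(t), replace = TRUE)
  spk <- lapply(stats::setNames(ids, ids), function(id) {
    ti <- sort(t[el == id])
    while (length(ti) > 1L && any(diff(ti) < 1e-4)) {
      ti <- ti[c(TRUE, diff(ti) >= 1e-4)]
    }
    ti
  })
  spike_train_set(spk, duration_s, electrode_ids = ids)
}

# Random in-burst-like spike train in milliseconds (sorted, 0.01 ms grid,
# 0.1 ms minimum separation).
random_train_ms <- function(seed, n, span_ms = 500) {
  set.seed(seed)
  t <- sort(round(runif(n, 0, span_ms), 2))
  while (length(t) > 1L && any(diff(t) < 0.1 - 1e-9)) {
    t <- t[c(TRUE, diff(t) >= 0.1 - 1e-9)]
  }
  t
}

expect_bursts_match_oracle <- function(s, params = burst_detection_params()) {
  got <- detect_network_bursts(s, params)
  want <- oracle_detect_bursts(s, params$window_ms, params$min_spikes,
                               params$min_electrodes, params$large_threshold)
  expect_equal(nrow(got), nrow(want))
  if (nrow(want)) {
    expect_equal(got$start_s, want$start_s, tolerance = 1e-9)
    expect_equal(got$end_s, want$end_s, tolerance = 1e-9)
    expect_equal(got$total_spikes, want$total_spikes)
    expect_equal(got$n_electrodes, want$n_electrodes)
    expect_equal(got$peak_rate, want$peak_rate)
    expect_equal(got$size_class, want$size_class)
  }
  invisible(got)
}
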