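#' Network-burst detection parameters
#'
#' A network burst is an event in which at least `min_spikes` spikes from at
#' least `min_electrodes` distinct electrodes fall within a `window_ms`
#' window (defaults: 4 spikes from 4 different electrodes within 50 ms).
#' Bursts whose peak spike count per `window_ms` exceeds `large_threshold`
#' are classified as large, the rest as small; the boundary itself
#' (exactly `large_threshold` spikes) is small.
#'
#' @param window_ms detection window in milliseconds.
#' @param min_spikes minimum spikes within one window.
#' @param min_electrodes minimum distinct electrodes contributing to one
#'   window. Set to 2 for the weaker reading of the distinct-electrode rule.
#' @param large_threshold small/large class boundary in spikes per window.
#' @return A list of class `burst_detection_params`.
#' @export
burst_detection_params <- function(window_ms = 50, min_spikes = 4L,
                                   min_electrodes = 4L, large_threshold = 100L) {
  if (!is.numeric(window_ms) || window_ms <= 0) stop("window_ms must be > 0")
  if (min_spikes < 1) stop("min_spikes must be >= 1")
  if (min_electrodes < 1) stop("min_electrodes must be >= 1")
  if (large_threshold < min_spikes) stop("large_threshold must be >= min_spikes")
  structure(list(window_ms = as.numeric(window_ms),
                 min_spikes = as.integer(min_spikes),
                 min_electrodes = as.integer(min_electrodes),
                 large_threshold = as.integer(large_threshold)),
            class = "burst_detection_params")
}

.empty_bursts <- function(params) {
  structure(
    data.frame(start_s = numeric(0), end_s = numeric(0),
               duration_ms = numeric(0), total_spikes = integer(0),
               n_electrodes = integer(0), peak_rate = integer(0),
               size_class = character(0), stringsAsFactors = FALSE),
    per_electrode_counts = list(),
    params = params,
    class = c("network_bursts", "data.frame"))
}

#' Detect network bursts
#'
#' Slides a `window_ms` window anchored at every spike over the pooled
#' recording. A window qualifies when it contains at least `min_spikes`
#' spikes from at least `min_electrodes` distinct electrodes; overlapping or
#' abutting qualifying windows are merged, and each merged run becomes one
#' burst whose span runs from the first to the last covered spike. Windows
#' are half-open `[t, t + window_ms)` on a 0.01 ms grid.
#'
#' Detection is linear-time via a two-pointer sweep that maintains the
#' per-electrode occupancy of the current window.
#'
#' @param s a [spike_train_set()].
#' @param params a [burst_detection_params()].
#' @return A data frame of class `network_bursts`, ordered by `start_s`, with
#'   columns `start_s`, `end_s`, `duration_ms`, `total_spikes`,
#'   `n_electrodes`, `peak_rate` (maximum spikes in any `window_ms` window
#'   inside the span — the burst amplitude, in spikes per window) and
#'   `size_class` (`"small"`/`"large"`). Per-burst per-electrode spike counts
#'   are attached as the `per_electrode_counts` attribute (list of named
#'   integer vectors). Bursts are disjoint.
#' @export
detect_network_bursts <- function(s, params = burst_detection_params()) {
  stopifnot(inherits(s, "spike_train_set"))
  if (!inherits(params, "burst_detection_params")) {
    stop("`params` must come from burst_detection_params()")
  }
  pool <- .pool_spikes(s)
  n <- pool$n
  if (n == 0L) return(.empty_bursts(params))
  tm <- .to_ms(pool$time_s)
  el <- pool$electrode
  w <- params$window_ms
  nel <- length(s$electrode_ids)

  # Two-pointer sweep: after iteration i the multiset holds spikes i..r,
  # where r is the last spike with time < tm[i] + w (at 0.01 ms resolution).
  occ <- integer(nel)
  distinct <- 0L
  r <- 0L
  qual <- logical(n)
  for (i in seq_len(n)) {
    if (i > 1L) {
      e <- el[i - 1L]
      occ[e] <- occ[e] - 1L
      if (occ[e] == 0L) distinct <- distinct - 1L
    }
    lim <- tm[i] + w - 0.005
    while (r < n && tm[r + 1L] < lim) {
      r <- r + 1L
      e <- el[r]
      if (occ[e] == 0L) distinct <- distinct + 1L
      occ[e] <- occ[e] + 1L
    }
    qual[i] <- (r - i + 1L) >= params$min_spikes && distinct >= params$min_electrodes
  }

  qi <- which(qual)
  if (!length(qi)) return(.empty_bursts(params))
  qs <- tm[qi]
  qe <- qs + w
  # merge overlapping or abutting qualifying windows
  run_end <- cummax(qe)
  new_run <- c(TRUE, qs[-1L] > run_end[-length(run_end)] + 1e-9)
  run <- cumsum(new_run)

  groups <- split(seq_along(qi), run)
  rows <- vector("list", length(groups))
  pec <- vector("list", length(groups))
  for (g in seq_along(groups)) {
    ix <- groups[[g]]
    S <- qs[ix[1L]]
    E <- max(qe[ix])
    idx <- which(tm >= S - 1e-9 & tm < E - 0.005)
    tb <- tm[idx]
    peak <- max(findInterval(tb + w - 0.005, tb) - seq_along(tb) + 1L)
    counts <- tabulate(el[idx], nbins = nel)
    pec[[g]] <- stats::setNames(counts[counts > 0L],
                                s$electrode_ids[counts > 0L])
    rows[[g]] <- data.frame(
      start_s = pool$time_s[idx[1L]],
      end_s = pool$time_s[idx[length(idx)]],
      duration_ms = round(tb[length(tb)] - tb[1L], 2),
      total_spikes = length(idx),
      n_electrodes = sum(counts > 0L),
      peak_rate = peak,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$size_class <- classify_bursts(out$peak_rate, params)
  rownames(out) <- NULL
  structure(out, per_electrode_counts = pec, params = params,
            class = c("network_bursts", "data.frame"))
}

#' Classify burst amplitude into small/large
#'
#' Small bursts contain up to `large_threshold` spikes per window (boundary
#' inclusive), large bursts exceed it.
#'
#' @param peak_rate numeric vector of burst amplitudes (peak spikes per
#'   detection window).
#' @param params a [burst_detection_params()].
#' @return Character vector of `"small"`/`"large"`.
#' @export
classify_bursts <- function(peak_rate, params = burst_detection_params()) {
  ifelse(peak_rate > params$large_threshold, "large", "small")
}

# Indices (into the pooled time vector) of spikes inside any burst span.
.in_burst <- function(time_s, bursts) {
  if (nrow(bursts) == 0L || !length(time_s)) return(logical(length(time_s)))
  fi <- findInterval(time_s, bursts$start_s - 1e-12)
  fi >= 1L & time_s <= bursts$end_s[pmax(fi, 1L)] + 1e-12
}

#' Per-recording burst statistics
#'
#' Computes the five standard activity parameters for one recording: burst
#' rate per class (bursts/min), mean spikes per burst, mean burst duration
#' (ms), mean burst amplitude (peak spikes per detection window), and the
#' percentage of all recorded spikes falling inside any burst span. Per-class
#' means are `NA` (not zero) when the recording has no bursts of that class;
#' `pct_spikes_in_bursts` is `NA` when the recording has no spikes.
#'
#' @param s the [spike_train_set()] the bursts were detected on.
#' @param bursts result of [detect_network_bursts()] on `s`.
#' @return One-row data frame of class `burst_statistics` carrying the
#'   recording metadata and statistics.
#' @export
compute_burst_statistics <- function(s, bursts) {
  stopifnot(inherits(s, "spike_train_set"), inherits(bursts, "network_bursts"))
  total <- n_spikes(s)
  mins <- s$duration_s / 60
  pool <- .pool_spikes(s)
  n_in <- sum(.in_burst(pool$time_s, bursts))
  cls <- bursts$size_class
  stat_for <- function(x, sel) if (any(sel)) mean(x[sel]) else NA_real_
  small <- cls == "small"; large <- cls == "large"
  out <- data.frame(
    recording_id = s$meta$recording_id,
    group = s$meta$group_label,
    div = s$meta$div,
    duration_s = s$duration_s,
    n_spikes_total = total,
    n_bursts = nrow(bursts),
    n_small_per_min = sum(small) / mins,
    n_large_per_min = sum(large) / mins,
    mean_spikes_small = stat_for(bursts$total_spikes, small),
    mean_spikes_large = stat_for(bursts$total_spikes, large),
    mean_duration_small_ms = stat_for(bursts$duration_ms, small),
    mean_duration_large_ms = stat_for(bursts$duration_ms, large),
    mean_amplitude_small = stat_for(bursts$peak_rate, small),
    mean_amplitude_large = stat_for(bursts$peak_rate, large),
    pct_spikes_in_bursts = if (total == 0L) NA_real_ else 100 * n_in / total,
    stringsAsFactors = FALSE)
  class(out) <- c("burst_statistics", "data.frame")
  out
}

#' Minute-by-minute burst statistics
#'
#' Splits the recording with [split_minutes()], detects bursts in every
#' segment independently, and returns one statistics row per minute.
#'
#' @inheritParams detect_network_bursts
#' @return Data frame with a leading `minute` column (1-based).
#' @export
burst_statistics_by_minute <- function(s, params = burst_detection_params()) {
  segs <- split_minutes(s)
  rows <- lapply(seq_along(segs), function(k) {
    st <- compute_burst_statistics(segs[[k]], detect_network_bursts(segs[[k]], params))
    cbind(minute = k, st)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# The statistics columns that get baseline fold-change companions.
.metric_cols <- c("n_small_per_min", "n_large_per_min",
                  "mean_spikes_small", "mean_spikes_large",
                  "mean_duration_small_ms", "mean_duration_large_ms",
                  "mean_amplitude_small", "mean_amplitude_large",
                  "pct_spikes_in_bursts")

#' Longitudinal burst-statistics summary
#'
#' Detects bursts and computes [compute_burst_statistics()] for every
#' recording in a bundle (one row per recording), and appends fold-change
#' columns (`fc_<metric>`) giving each value relative to its group's mean at
#' the baseline DIV. Groups lacking a baseline recording get `NA` fold
#' changes with a warning.
#'
#' @param bundle a [recording_bundle()].
#' @param params a [burst_detection_params()].
#' @param baseline_div baseline day in vitro (default 14).
#' @return Data frame keyed by (group, div, recording_id).
#' @export
longitudinal_summary <- function(bundle, params = burst_detection_params(),
                                 baseline_div = 14L) {
  stopifnot(inherits(bundle, "recording_bundle"))
  rows <- lapply(bundle$design$recording_id, function(id) {
    s <- bundle$recordings[[id]]
    compute_burst_statistics(s, detect_network_bursts(s, params))
  })
  out <- do.call(rbind, rows)
  class(out) <- "data.frame"
  for (m in .metric_cols) out[[paste0("fc_", m)]] <- NA_real_
  for (g in unique(out$group)) {
    base <- out$group == g & out$div == baseline_div
    if (!any(base)) {
      warning("group ", g, " has no DIV", baseline_div,
              " recording; fold changes reported missing")
      next
    }
    sel <- out$group == g
    for (m in .metric_cols) {
      bm <- mean(out[[m]][base], na.rm = TRUE)
      out[[paste0("fc_", m)]][sel] <-
        if (!is.finite(bm) || bm == 0) NA_real_ else out[[m]][sel] / bm
    }
  }
  rownames(out) <- NULL
  out
}
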