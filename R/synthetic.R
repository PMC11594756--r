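#' Standard 60-electrode MEA layout labels
#'
#' Electrode labels of the classic MEA60 grid: an 8 x 8 array without the
#' four corners, named `<column><row>` ("12", "13", ..., "87"). Geometry is
#' metadata only; no computation in this package uses electrode positions.
#'
#' @param n number of electrodes to return (first `n` labels, default all 60).
#' @return Character vector of labels.
#' @export
mea60_layout <- function(n = 60L) {
  grid <- expand.grid(row = 1:8, col = 1:8)
  keep <- !(grid$row %in% c(1, 8) & grid$col %in% c(1, 8))
  labels <- sprintf("%d%d", grid$col[keep], grid$row[keep])
  labels <- labels[order(labels)]
  if (n > length(labels)) {
    labels <- c(labels, sprintf("x%02d", seq_len(n - length(labels))))
  }
  labels[seq_len(n)]
}

#' Default planted connectivity for the synthetic generator
#'
#' Hub-broadcast architecture: every hub electrode projects to every non-hub
#' electrode. All edges converging on one target share that target's
#' transmission delay (delays cycle over `delays_ms` across targets), so the
#' delay structure of each pair is unambiguous.
#'
#' @param electrode_ids all electrode labels.
#' @param hub_electrodes subset acting as burst initiators.
#' @param delays_ms pool of transmission delays cycled across targets.
#' @param transmission_prob per-burst probability that an edge fires its
#'   target.
#' @param jitter_ms standard deviation of Gaussian delay jitter.
#' @return Data frame with columns `source`, `target`, `delay_ms`,
#'   `transmission_prob`, `jitter_ms`.
#' @export
default_planted_edges <- function(electrode_ids, hub_electrodes,
                                  delays_ms = 2:15,
                                  transmission_prob = 0.9,
                                  jitter_ms = 0.5) {
  targets <- setdiff(electrode_ids, hub_electrodes)
  if (!length(targets) || !length(hub_electrodes)) {
    return(data.frame(source = character(0), target = character(0),
                      delay_ms = numeric(0), transmission_prob = numeric(0),
                      jitter_ms = numeric(0)))
  }
  tgt_delay <- rep_len(delays_ms, length(targets))
  out <- expand.grid(source = hub_electrodes, target = targets,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$delay_ms <- tgt_delay[match(out$target, targets)]
  out$transmission_prob <- transmission_prob
  out$jitter_ms <- jitter_ms
  out[order(out$source, out$target, method = "radix"), , drop = FALSE]
}

#' Configuration of the synthetic MEA recording generator
#'
#' The generator emulates a 60-electrode, 10-minute MEA recording of a
#' cultured neuronal network: sparse tonic background spiking plus
#' hub-initiated network bursts that propagate to target electrodes over
#' planted directed edges with millisecond transmission delays. The
#' condition factor `delta` scales burst initiation rate, in-burst spike
#' counts, and transmission probability simultaneously: `delta = 1` emulates
#' an intact culture, `delta < 1` the graded suppression seen under
#' amyloidosis, intermediate values a partially protected (chronically
#' stimulated) culture. Per-parameter overrides remain available through the
#' individual fields.
#'
#' @param n_electrodes number of electrodes (default 60).
#' @param duration_s recording length in seconds (default 600).
#' @param background_rate_hz per-electrode tonic Poisson rate (default 0.15).
#' @param burst_rate_per_min network-burst initiation rate (default 8).
#' @param hub_electrodes initiator electrode ids (default: first 3 of the
#'   layout).
#' @param planted_edges data frame as from [default_planted_edges()].
#' @param spikes_per_electrode_in_burst mean in-burst spike count per
#'   electrode (scalar, or vector over electrodes), default 2.5.
#' @param burst_envelope_ms spread of in-burst spikes within an electrode
#'   (default 60 ms).
#' @param volley_spikes,volley_spread_ms size and spread of the initiator
#'   volley fired by each hub at burst onset (defaults 10 spikes over 1 ms).
#' @param condition_factor delta multiplier described above.
#' @param electrode_ids explicit labels (default [mea60_layout()]).
#' @param group_label,div,recording_id metadata stamped on the output.
#' @param seed RNG seed; identical (config, seed) gives byte-identical
#'   recordings.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_electrodes = 60L,
                             duration_s = 600,
                             background_rate_hz = 0.15,
                             burst_rate_per_min = 8,
                             hub_electrodes = NULL,
                             planted_edges = NULL,
                             spikes_per_electrode_in_burst = 2.5,
                             burst_envelope_ms = 60,
                             volley_spikes = 10L,
                             volley_spread_ms = 1,
                             condition_factor = 1,
                             electrode_ids = NULL,
                             group_label = NA_character_,
                             div = NA_integer_,
                             recording_id = NA_character_,
                             seed = 1L) {
  if (is.null(electrode_ids)) electrode_ids <- mea60_layout(n_electrodes)
  electrode_ids <- as.character(electrode_ids)
  if (length(electrode_ids) != n_electrodes) {
    stop("electrode_ids must have length n_electrodes")
  }
  if (is.null(hub_electrodes)) hub_electrodes <- electrode_ids[seq_len(min(3L, n_electrodes))]
  if (!all(hub_electrodes %in% electrode_ids)) stop("hub_electrodes must be electrode ids")
  if (is.null(planted_edges)) {
    planted_edges <- default_planted_edges(electrode_ids, hub_electrodes)
  }
  if (nrow(planted_edges)) {
    if (!all(c("source", "target", "delay_ms", "transmission_prob", "jitter_ms")
             %in% names(planted_edges))) {
      stop("planted_edges must have columns source, target, delay_ms, transmission_prob, jitter_ms")
    }
    if (!all(planted_edges$source %in% electrode_ids) ||
        !all(planted_edges$target %in% electrode_ids)) {
      stop("planted edge endpoints must be electrode ids")
    }
    if (any(planted_edges$delay_ms < 1 | planted_edges$delay_ms > 50)) {
      stop("planted delays must lie in [1, 50] ms")
    }
    if (any(planted_edges$transmission_prob < 0 | planted_edges$transmission_prob > 1)) {
      stop("transmission probabilities must lie in [0, 1]")
    }
  }
  if (background_rate_hz < 0 || burst_rate_per_min < 0 ||
      any(spikes_per_electrode_in_burst < 0)) {
    stop("rates must be nonnegative")
  }
  if (condition_factor <= 0) stop("condition_factor must be positive")
  spe <- rep_len(spikes_per_electrode_in_burst, n_electrodes)
  structure(list(n_electrodes = as.integer(n_electrodes),
                 duration_s = duration_s,
                 background_rate_hz = background_rate_hz,
                 burst_rate_per_min = burst_rate_per_min,
                 hub_electrodes = as.character(hub_electrodes),
                 planted_edges = planted_edges,
                 spikes_per_electrode_in_burst = spe,
                 burst_envelope_ms = burst_envelope_ms,
                 volley_spikes = as.integer(volley_spikes),
                 volley_spread_ms = volley_spread_ms,
                 condition_factor = condition_factor,
                 electrode_ids = electrode_ids,
                 group_label = group_label,
                 div = div,
                 recording_id = recording_id,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Generate one synthetic MEA recording
#'
#' Draws burst onsets from a Poisson process at `burst_rate_per_min * delta`;
#' at each onset every hub fires a short volley, every planted edge fires its
#' target with probability `transmission_prob * delta` at
#' `onset + delay_ms + N(0, jitter_ms)`, and every electrode adds
#' `Poisson(spikes_per_electrode * delta)` envelope spikes spread uniformly
#' over `burst_envelope_ms`. Homogeneous Poisson background spiking is laid
#' over the whole recording. Per-electrode spike trains are sorted and
#' deduplicated at the 0.1 ms resolution of the data model.
#'
#' @param config a [synthetic_config()].
#' @return List with `recording` (a [spike_train_set()]) and `truth` (list
#'   with `burst_onsets_s`, `planted_edges`, and analytic `expected` means:
#'   burst count, background spikes, in-burst spikes per burst).
#' @export
generate_recording <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  cfg <- config
  .with_seed(cfg$seed, {
    delta <- cfg$condition_factor
    nel <- cfg$n_electrodes
    ids <- cfg$electrode_ids
    dur <- cfg$duration_s
    hubs_idx <- match(cfg$hub_electrodes, ids)
    max_delay <- if (nrow(cfg$planted_edges)) max(cfg$planted_edges$delay_ms) else 0
    margin <- (cfg$burst_envelope_ms + max_delay + 10) / 1000

    n_bursts <- stats::rpois(1L, cfg$burst_rate_per_min * delta * dur / 60)
    onsets <- if (n_bursts > 0) {
      sort(stats::runif(n_bursts, 0, max(dur - margin, 0)))
    } else numeric(0)

    acc <- vector("list", nel)
    for (i in seq_len(nel)) acc[[i]] <- list()
    add <- function(i, t) acc[[i]][[length(acc[[i]]) + 1L]] <<- t

    pe <- cfg$planted_edges
    tgt_idx <- if (nrow(pe)) match(pe$target, ids) else integer(0)
    for (b in seq_along(onsets)) {
      on <- onsets[b]
      if (cfg$volley_spikes > 0L) {
        for (h in hubs_idx) {
          add(h, on + sort(stats::runif(cfg$volley_spikes, 0, cfg$volley_spread_ms)) / 1000)
        }
      }
      if (nrow(pe)) {
        fired <- stats::runif(nrow(pe)) < pmin(1, pe$transmission_prob * delta)
        if (any(fired)) {
          d <- pe$delay_ms[fired] + stats::rnorm(sum(fired), 0, pe$jitter_ms[fired])
          d <- pmax(d, 0.1)
          ti <- tgt_idx[fired]
          tt <- on + d / 1000
          for (q in seq_along(ti)) add(ti[q], tt[q])
        }
      }
      env_counts <- stats::rpois(nel, cfg$spikes_per_electrode_in_burst * delta)
      for (i in which(env_counts > 0L)) {
        add(i, on + stats::runif(env_counts[i], 0, cfg$burst_envelope_ms) / 1000)
      }
    }
    if (cfg$background_rate_hz > 0) {
      bg_counts <- stats::rpois(nel, cfg$background_rate_hz * dur)
      for (i in which(bg_counts > 0L)) add(i, stats::runif(bg_counts[i], 0, dur))
    }

    spikes <- vector("list", nel)
    for (i in seq_len(nel)) {
      t <- sort(as.numeric(unlist(acc[[i]], use.names = FALSE)))
      t <- t[t >= 0 & t <= dur]
      # enforce the 0.1 ms per-electrode resolution of the data model
      while (length(t) > 1L && any(diff(t) < 1e-4)) {
        t <- t[c(TRUE, diff(t) >= 1e-4)]
      }
      spikes[[i]] <- t
    }
    names(spikes) <- ids

    recording <- spike_train_set(spikes, dur, electrode_ids = ids,
                                 group_label = cfg$group_label, div = cfg$div,
                                 recording_id = cfg$recording_id)
    expected <- list(
      n_bursts = cfg$burst_rate_per_min * delta * dur / 60,
      background_spikes = nel * cfg$background_rate_hz * dur,
      in_burst_spikes_per_burst =
        length(hubs_idx) * cfg$volley_spikes +
        (if (nrow(pe)) sum(pmin(1, pe$transmission_prob * delta)) else 0) +
        sum(cfg$spikes_per_electrode_in_burst * delta))
    list(recording = recording,
         truth = list(burst_onsets_s = onsets,
                      planted_edges = pe,
                      expected = expected))
  })
}

#' Default longitudinal condition schedules
#'
#' Condition-factor (delta) trajectories over the recording schedule
#' (DIV14, 15, 17, 19, 21) for the three emulated groups: an intact culture
#' (stationary, delta = 1), graded amyloid suppression down to delta = 0.3
#' ("Ab"), and partial preservation under chronic stimulation down to
#' delta = 0.8 ("Ab+ChR2").
#'
#' @param divs recording days (default `c(14, 15, 17, 19, 21)`).
#' @return Data frame with columns `group`, `div`, `delta`.
#' @export
condition_schedules <- function(divs = c(14L, 15L, 17L, 19L, 21L)) {
  k <- length(divs)
  ramp <- function(final) {
    if (k == 1L) return(final)
    1 + (final - 1) * (seq_len(k) - 1) / (k - 1)
  }
  rbind(
    data.frame(group = "Intact", div = divs, delta = rep(1, k)),
    data.frame(group = "Ab", div = divs, delta = ramp(0.3)),
    data.frame(group = "Ab+ChR2", div = divs, delta = ramp(0.8)))
}

#' Generate a longitudinal recording bundle
#'
#' Generates `replicates` recordings for every (group, DIV) row of a
#' condition schedule. Each recording's seed is derived deterministically
#' from `(master_seed, group, DIV, replicate)` by a 31-based string hash, so
#' the whole bundle is reproducible from the master seed alone.
#'
#' @param schedule data frame with columns `group`, `div`, `delta` (see
#'   [condition_schedules()]).
#' @param base_config a [synthetic_config()] supplying all non-condition
#'   parameters.
#' @param replicates recordings per (group, DIV).
#' @param master_seed master RNG seed.
#' @return List with `bundle` (a [recording_bundle()]) and `truths` (list of
#'   per-recording ground truths, named by recording id).
#' @export
generate_longitudinal <- function(schedule = condition_schedules(),
                                  base_config = synthetic_config(),
                                  replicates = 3L,
                                  master_seed = 1L) {
  stopifnot(all(c("group", "div", "delta") %in% names(schedule)))
  recs <- list()
  truths <- list()
  for (r in seq_len(nrow(schedule))) {
    g <- schedule$group[r]; dv <- schedule$div[r]; delta <- schedule$delta[r]
    for (rep_i in seq_len(replicates)) {
      id <- sprintf("%s_DIV%02d_r%02d", gsub("[^A-Za-z0-9]+", "", g), dv, rep_i)
      cfg <- base_config
      cfg$condition_factor <- delta
      cfg$group_label <- g
      cfg$div <- as.integer(dv)
      cfg$recording_id <- id
      cfg$seed <- .derive_seed(master_seed, g, dv, rep_i)
      out <- generate_recording(cfg)
      recs[[id]] <- out$recording
      truths[[id]] <- out$truth
    }
  }
  divs <- sort(unique(as.integer(schedule$div)))
  list(bundle = recording_bundle(recs, allowed_divs = divs), truths = truths)
}

#' Synthetic configuration for planted-edge recovery studies
#'
#' A generator preset tuned for testing connectivity recovery: all hubs
#' project to every non-hub target with a shared per-target delay, hub
#' volleys are large enough that every burst exceeds the large-burst
#' threshold, and per-target envelope spiking is sparse so target spike
#' trains are dominated by planted transmission.
#'
#' @param seed RNG seed.
#' @param n_electrodes,duration_s as in [synthetic_config()].
#' @param delays_ms pool of per-target delays.
#' @return A [synthetic_config()].
#' @export
recovery_config <- function(seed = 1L, n_electrodes = 60L, duration_s = 600,
                            delays_ms = 3:30) {
  ids <- mea60_layout(n_electrodes)
  hubs <- ids[seq_len(min(3L, n_electrodes))]
  synthetic_config(
    n_electrodes = n_electrodes,
    duration_s = duration_s,
    background_rate_hz = 0.05,
    burst_rate_per_min = 6,
    hub_electrodes = hubs,
    planted_edges = default_planted_edges(ids, hubs, delays_ms = delays_ms,
                                          transmission_prob = 0.9,
                                          jitter_ms = 0.5),
    spikes_per_electrode_in_burst = ifelse(ids %in% hubs, 0, 2),
    burst_envelope_ms = 50,
    volley_spikes = 15L,
    volley_spread_ms = 1,
    electrode_ids = ids,
    recording_id = sprintf("recovery_seed%d", seed),
    seed = seed)
}
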