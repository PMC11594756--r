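#' MEA spike-train recording
#'
#' A `spike_train_set` holds per-electrode spike timestamps (in seconds) for
#' one multielectrode-array (MEA) recording, together with the recording
#' duration and metadata (group label, DIV = days in vitro, recording id).
#' It is the universal input of the analysis pipeline.
#'
#' Invariants enforced at construction:
#' * every spike time `t` satisfies `0 <= t <= duration_s`;
#' * per-electrode times are strictly ascending — two spikes on the same
#'   electrode closer than 0.1 ms are considered duplicates and rejected;
#' * electrode ids are unique.
#'
#' Identical spike times on *different* electrodes are allowed (and expected
#' during network bursts).
#'
#' @param spikes named list of numeric vectors of spike times in seconds, one
#'   element per electrode. Unsorted input is sorted.
#' @param duration_s recording length in seconds (scalar > 0).
#' @param electrode_ids electrode labels; defaults to `names(spikes)`.
#'   Electrodes with no spikes may be listed here with no entry in `spikes`.
#' @param group_label,div,recording_id,notes recording metadata.
#' @return An object of class `spike_train_set`.
#' @seealso [read_spike_table()], [split_minutes()], [detect_network_bursts()]
#' @export
spike_train_set <- function(spikes, duration_s,
                            electrode_ids = NULL,
                            group_label = NA_character_,
                            div = NA_integer_,
                            recording_id = NA_character_,
                            notes = NULL) {
  if (!is.list(spikes)) stop("`spikes` must be a named list of numeric vectors")
  if (!is.numeric(duration_s) || length(duration_s) != 1L || !is.finite(duration_s) ||
      duration_s <= 0) {
    stop("`duration_s` must be a single positive number")
  }
  if (is.null(electrode_ids)) electrode_ids <- names(spikes)
  electrode_ids <- as.character(electrode_ids)
  if (length(electrode_ids) == 0L && length(spikes) > 0L) {
    stop("`spikes` must be named or `electrode_ids` supplied")
  }
  if (anyDuplicated(electrode_ids)) stop("electrode ids must be unique")
  full <- stats::setNames(vector("list", length(electrode_ids)), electrode_ids)
  for (id in electrode_ids) {
    t <- spikes[[id]]
    t <- if (is.null(t)) numeric(0) else sort(as.numeric(t))
    if (length(t)) {
      if (anyNA(t) || any(!is.finite(t))) stop("spike times must be finite")
      if (t[1] < 0) stop("negative spike time on electrode ", id)
      if (t[length(t)] > duration_s + 1e-9) {
        stop("spike time exceeds stated duration on electrode ", id)
      }
      if (length(t) > 1L && any(diff(t) < 5e-5)) {
        stop("duplicate spike times (< 0.1 ms apart) on electrode ", id)
      }
    }
    full[[id]] <- t
  }
  extra <- setdiff(names(spikes), electrode_ids)
  if (length(extra)) stop("spikes given for unknown electrodes: ",
                          paste(extra, collapse = ", "))
  structure(
    list(electrode_ids = electrode_ids,
         spikes = full,
         duration_s = as.numeric(duration_s),
         meta = list(group_label = group_label,
                     div = if (is.na(div)) NA_integer_ else as.integer(div),
                     recording_id = recording_id,
                     notes = notes)),
    class = "spike_train_set")
}

#' @export
print.spike_train_set <- function(x, ...) {
  cat(sprintf("spike_train_set: %d electrodes, %d spikes, %.1f s\n",
              length(x$electrode_ids), n_spikes(x), x$duration_s))
  m <- x$meta
  if (!is.na(m$recording_id) || !is.na(m$group_label) || !is.na(m$div)) {
    cat(sprintf("  id=%s group=%s DIV=%s\n", m$recording_id, m$group_label, m$div))
  }
  invisible(x)
}

#' Total number of spikes in a recording
#' @param s a [spike_train_set()].
#' @return Integer spike count over all electrodes.
#' @export
n_spikes <- function(s) {
  stopifnot(inherits(s, "spike_train_set"))
  sum(lengths(s$spikes))
}

#' @export
as.data.frame.spike_train_set <- function(x, ...) {
  data.frame(
    electrode_id = rep(x$electrode_ids, lengths(x$spikes)),
    time_s = unlist(x$spikes, use.names = FALSE),
    stringsAsFactors = FALSE)
}

# Pool all spikes into time order (ties broken by electrode index) and return
# parallel vectors used by the detection and connectivity code.
.pool_spikes <- function(s) {
  t <- unlist(s$spikes, use.names = FALSE)
  el <- rep(seq_along(s$electrode_ids), lengths(s$spikes))
  if (length(t)) {
    ord <- order(t, el, method = "radix")
    t <- t[ord]; el <- el[ord]
  }
  list(time_s = t, electrode = el, n = length(t))
}

#' Bundle of recordings with a group design
#'
#' Collects several [spike_train_set()] recordings together with the design
#' mapping (group label, DIV) -> recording ids used for longitudinal analysis.
#'
#' @param recordings list of `spike_train_set` objects; each must carry a
#'   `recording_id`, `group_label` and `div` in its metadata.
#' @param allowed_divs DIVs permitted in the design; defaults to the standard
#'   recording schedule (DIV14, 15, then every 48 h to 21). Pass `NULL` to
#'   accept any DIV.
#' @return An object of class `recording_bundle` with elements `recordings`
#'   (named by recording id) and `design` (data frame with columns
#'   `group`, `div`, `recording_id`).
#' @export
recording_bundle <- function(recordings, allowed_divs = c(14L, 15L, 17L, 19L, 21L)) {
  stopifnot(is.list(recordings), length(recordings) > 0L)
  ok <- vapply(recordings, inherits, logical(1), "spike_train_set")
  if (!all(ok)) stop("all elements must be spike_train_set objects")
  ids <- vapply(recordings, function(r) as.character(r$meta$recording_id), character(1))
  if (anyNA(ids) || any(ids == "NA")) stop("every recording needs a recording_id")
  if (anyDuplicated(ids)) stop("recording ids must be unique")
  grp <- vapply(recordings, function(r) as.character(r$meta$group_label), character(1))
  div <- vapply(recordings, function(r) as.integer(r$meta$div), integer(1))
  if (anyNA(grp) || anyNA(div)) stop("every recording needs group_label and div metadata")
  if (!is.null(allowed_divs) && !all(div %in% allowed_divs)) {
    stop("DIV outside the allowed set: ",
         paste(setdiff(div, allowed_divs), collapse = ", "))
  }
  names(recordings) <- ids
  design <- data.frame(group = grp, div = div, recording_id = ids,
                       stringsAsFactors = FALSE)
  design <- design[order(design$group, design$div, design$recording_id,
                         method = "radix"), , drop = FALSE]
  rownames(design) <- NULL
  structure(list(recordings = recordings, design = design),
            class = "recording_bundle")
}

#' @export
print.recording_bundle <- function(x, ...) {
  cat(sprintf("recording_bundle: %d recordings, %d groups, DIVs %s\n",
              nrow(x$design), length(unique(x$design$group)),
              paste(sort(unique(x$design$div)), collapse = ",")))
  invisible(x)
}
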