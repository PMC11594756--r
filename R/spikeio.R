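#' Read a delimited spike table
#'
#' Reads a two-column table of `(electrode_id, time_s)` rows into a
#' [spike_train_set()]. The delimiter is auto-detected from the file
#' extension (`.tsv`/`.txt` = tab, otherwise comma); a header row is detected
#' by a non-numeric second field. Rows need not be sorted — the reader sorts
#' per electrode.
#'
#' Recording metadata (duration, group label, DIV, recording id) is taken
#' from a JSON sidecar `<path>.json` when present; explicit arguments
#' override the sidecar. When no duration is available anywhere it defaults
#' to `max(time) + 1e-3` with a warning.
#'
#' @param path file to read.
#' @param duration_s,group_label,div,recording_id metadata overrides.
#' @param electrode_ids optional full electrode layout (so silent electrodes
#'   are represented); defaults to the electrodes present in the file.
#' @return A [spike_train_set()].
#' @export
read_spike_table <- function(path, duration_s = NULL, group_label = NULL,
                             div = NULL, recording_id = NULL,
                             electrode_ids = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  sidecar <- paste0(path, ".json")
  meta <- if (file.exists(sidecar)) jsonlite::read_json(sidecar) else list()
  if (is.null(duration_s)) duration_s <- meta$duration_s
  if (is.null(group_label)) group_label <- meta$group_label
  if (is.null(div)) div <- meta$div
  if (is.null(recording_id)) recording_id <- meta$recording_id
  if (is.null(electrode_ids) && !is.null(meta$electrode_ids)) {
    electrode_ids <- unlist(meta$electrode_ids)
  }

  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  df <- NULL
  if (length(lines)) {
    first <- strsplit(lines[[1]], sep, fixed = TRUE)[[1]]
    has_header <- length(first) >= 2L && is.na(suppressWarnings(as.numeric(first[[2]])))
    df <- utils::read.table(text = lines, sep = sep, header = has_header,
                            colClasses = c("character", "numeric"),
                            col.names = c("electrode_id", "time_s"),
                            stringsAsFactors = FALSE)
  }
  if (is.null(df) || nrow(df) == 0L) {
    if (is.null(duration_s)) {
      warning("empty spike table and no duration supplied; using 1 s")
      duration_s <- 1
    }
    return(spike_train_set(list(), duration_s,
                           electrode_ids = if (is.null(electrode_ids)) character(0) else electrode_ids,
                           group_label = if (is.null(group_label)) NA_character_ else group_label,
                           div = if (is.null(div)) NA_integer_ else div,
                           recording_id = if (is.null(recording_id)) NA_character_ else recording_id))
  }
  if (any(df$time_s < 0)) stop("negative spike time in ", path)
  if (is.null(duration_s)) {
    duration_s <- max(df$time_s) + 1e-3
    warning("no duration supplied for ", path,
            "; using max(time) + 1 ms = ", format(duration_s))
  }
  if (any(df$time_s > duration_s + 1e-9)) {
    stop("spike time exceeds stated duration in ", path)
  }
  spk <- split(df$time_s, df$electrode_id)
  ids <- if (is.null(electrode_ids)) names(spk) else as.character(electrode_ids)
  spike_train_set(spk, duration_s, electrode_ids = ids,
                  group_label = if (is.null(group_label)) NA_character_ else group_label,
                  div = if (is.null(div)) NA_integer_ else div,
                  recording_id = if (is.null(recording_id)) NA_character_ else recording_id)
}

#' Write a spike table
#'
#' Writes `(electrode_id, time_s)` rows (times formatted at 1 microsecond
#' resolution) plus a JSON metadata sidecar `<path>.json` holding the
#' duration, electrode layout and recording metadata, so that
#' `read_spike_table(write_spike_table(s, path))` reproduces `s`.
#'
#' @param s a [spike_train_set()].
#' @param path output file; extension selects the delimiter as in
#'   [read_spike_table()].
#' @param sidecar write the JSON metadata sidecar (default `TRUE`).
#' @return `path`, invisibly.
#' @export
write_spike_table <- function(s, path, sidecar = TRUE) {
  stopifnot(inherits(s, "spike_train_set"))
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  df <- as.data.frame(s)
  con <- file(path, "w")
  writeLines(paste("electrode_id", "time_s", sep = sep), con)
  if (nrow(df)) {
    writeLines(paste(df$electrode_id, sprintf("%.6f", df$time_s), sep = sep), con)
  }
  close(con)
  if (sidecar) {
    meta <- list(duration_s = s$duration_s,
                 electrode_ids = s$electrode_ids,
                 group_label = s$meta$group_label,
                 div = s$meta$div,
                 recording_id = s$meta$recording_id)
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA, null = "null", na = "null")
  }
  invisible(path)
}

#' Split a recording into minute segments
#'
#' Cuts a recording into `ceiling(duration_s / 60)` segments of 60 s (the
#' last possibly shorter) for minute-by-minute analysis. Segments use
#' half-open windows `[k*60, (k+1)*60)`; a spike exactly at a minute boundary
#' belongs to the following segment. Segment times are re-zeroed. A spike
#' exactly at `duration_s` is kept in the last segment.
#'
#' @param s a [spike_train_set()].
#' @return List of `spike_train_set` segments; each carries the parent
#'   metadata with `recording_id` suffixed by `_minNN`.
#' @export
split_minutes <- function(s) {
  stopifnot(inherits(s, "spike_train_set"))
  n_seg <- max(1L, as.integer(ceiling(s$duration_s / 60 - 1e-9)))
  out <- vector("list", n_seg)
  for (k in seq_len(n_seg)) {
    lo <- (k - 1) * 60
    hi <- min(k * 60, s$duration_s)
    seg_dur <- hi - lo
    spk <- lapply(s$spikes, function(t) {
      sel <- if (k == n_seg) t >= lo & t <= hi else t >= lo & t < hi
      t[sel] - lo
    })
    id <- s$meta$recording_id
    out[[k]] <- spike_train_set(
      spk, seg_dur, electrode_ids = s$electrode_ids,
      group_label = s$meta$group_label, div = s$meta$div,
      recording_id = if (is.na(id)) sprintf("min%02d", k) else sprintf("%s_min%02d", id, k),
      notes = s$meta$notes)
  }
  out
}

#' Write a recording bundle to disk
#'
#' Writes each recording as a spike table (with JSON sidecar) plus a
#' `manifest.json` listing the files and the group design.
#'
#' @param bundle a [recording_bundle()].
#' @param dir output directory (created if needed).
#' @return Path to the manifest, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "recording_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  entries <- lapply(bundle$design$recording_id, function(id) {
    fn <- paste0(id, ".csv")
    write_spike_table(bundle$recordings[[id]], file.path(dir, fn))
    r <- bundle$recordings[[id]]
    list(recording_id = id, file = fn,
         group_label = r$meta$group_label, div = r$meta$div,
         duration_s = r$duration_s)
  })
  manifest <- file.path(dir, "manifest.json")
  jsonlite::write_json(list(recordings = entries), manifest,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Read a recording bundle from a manifest
#'
#' @param manifest path to a `manifest.json` written by [write_bundle()].
#' @param allowed_divs passed to [recording_bundle()].
#' @return A [recording_bundle()].
#' @export
read_bundle <- function(manifest, allowed_divs = c(14L, 15L, 17L, 19L, 21L)) {
  if (!file.exists(manifest)) stop("no such manifest: ", manifest)
  m <- jsonlite::read_json(manifest)
  if (is.null(m$recordings) || !length(m$recordings)) {
    stop("malformed manifest (no `recordings` entry): ", manifest)
  }
  dir <- dirname(manifest)
  recs <- lapply(m$recordings, function(e) {
    for (f in c("recording_id", "file", "group_label", "div")) {
      if (is.null(e[[f]])) {
        stop("malformed manifest entry (missing `", f, "`) in ", manifest)
      }
    }
    p <- file.path(dir, e$file)
    if (!file.exists(p)) stop("manifest references missing file: ", e$file)
    read_spike_table(p, duration_s = e$duration_s,
                     group_label = e$group_label, div = e$div,
                     recording_id = e$recording_id)
  })
  recording_bundle(recs, allowed_divs = allowed_divs)
}
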