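# Reading, repairing and calibrating kymograph tracer output.
#
# Raw tracks arrive in pixel/frame units, one ordered (t_frame, x_pixel) list
# per particle per kymograph. Two on-disk dialects are supported: a long CSV
# (kymograph_id, track_id, t_frame, x_pixel) and a JSON mapping
# kymograph -> track -> list of [t, x] pairs mirroring per-track tracer
# exports. Calibrated tracks are kept in a long data.frame in seconds/um.

RAW_COLS <- c("kymograph_id", "track_id", "t_frame", "x_pixel")
TRACK_COLS <- c("condition", "kymograph_id", "track_id",
                "axon_distance_um", "t_s", "x_um")

#' Imaging calibration
#'
#' Bundles the physical calibration of a kymograph: pixel size, frame
#' interval and axis orientation. `plus_end_right = TRUE` means increasing
#' pixel x points toward microtubule plus ends, so anterograde displacement
#' becomes positive after calibration.
#'
#' The default pixel size of 0.1074 um makes the standard 0.6444 um movement
#' threshold an even 6 pixels; the default frame interval is 156 ms.
#'
#' @param pixel_size_um micrometres per pixel (> 0).
#' @param frame_interval_s seconds per frame (> 0).
#' @param plus_end_right logical; orientation of the plus-end axis.
#' @return An object of class `"dcv_calibration"`.
#' @examples
#' calibration()
#' calibration(pixel_size_um = 0.16, frame_interval_s = 0.1)
#' @export
calibration <- function(pixel_size_um = 0.1074, frame_interval_s = 0.156,
                        plus_end_right = TRUE) {
  check_number(pixel_size_um, "pixel_size_um")
  check_number(frame_interval_s, "frame_interval_s")
  if (!is.logical(plus_end_right) || length(plus_end_right) != 1L ||
      is.na(plus_end_right))
    stop_config("'plus_end_right' must be TRUE or FALSE")
  structure(list(pixel_size_um = pixel_size_um,
                 frame_interval_s = frame_interval_s,
                 plus_end_right = plus_end_right),
            class = "dcv_calibration")
}

#' @export
print.dcv_calibration <- function(x, ...) {
  cat(sprintf("calibration: %.4f um/px, %.3f s/frame, plus ends %s\n",
              x$pixel_size_um, x$frame_interval_s,
              if (x$plus_end_right) "right" else "left"))
  invisible(x)
}

empty_raw_tracks <- function() {
  data.frame(kymograph_id = character(), track_id = character(),
              t_frame = numeric(), x_pixel = numeric(),
              stringsAsFactors = FALSE)
}

#' Read kymograph tracer output
#'
#' Reads per-track (t, x) point lists in pixel/frame units from one of two
#' dialects: `"long_csv"` (columns `kymograph_id, track_id, t_frame,
#' x_pixel`) or `"kymobutler_json"` (a JSON object mapping kymograph id ->
#' track id -> list of `[t, x]` pairs). Points of each track are returned
#' sorted by frame index; values are not modified.
#'
#' @param path path to the input file.
#' @param dialect `"long_csv"` or `"kymobutler_json"`.
#' @return A data.frame with columns `kymograph_id`, `track_id`, `t_frame`,
#'   `x_pixel`, one row per point. An empty (header-only) file yields a
#'   zero-row data.frame.
#' @seealso [deduplicate_timepoints()], [calibrate_tracks()]
#' @export
read_tracks <- function(path, dialect = c("long_csv", "kymobutler_json")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop_config("input file does not exist: %s", path)
  raw <- if (dialect == "long_csv") read_tracks_csv(path) else
    read_tracks_json(path)
  sort_raw_tracks(raw)
}

read_tracks_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  missing <- setdiff(RAW_COLS, names(df))
  if (length(missing))
    stop_config("long_csv format error: missing column(s) %s",
                paste(missing, collapse = ", "))
  extra <- setdiff(names(df), RAW_COLS)
  if (length(extra))
    stop_config("long_csv format error: unexpected column(s) %s",
                paste(extra, collapse = ", "))
  if (nrow(df) == 0L) return(empty_raw_tracks())
  for (col in c("t_frame", "x_pixel")) {
    vals <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(vals) & !is.na(df[[col]]) & nzchar(df[[col]]))
    if (any(is.na(vals)))
      stop_config("parse error in column '%s' at data row %d: '%s'",
                  col, if (length(bad)) bad[1] else which(is.na(vals))[1],
                  df[[col]][if (length(bad)) bad[1] else which(is.na(vals))[1]])
    df[[col]] <- vals
  }
  df
}

read_tracks_json <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (length(obj) == 0L) return(empty_raw_tracks())
  rows <- list()
  for (kid in names(obj)) {
    kymo <- obj[[kid]]
    if (!is.list(kymo))
      stop_config("kymobutler_json format error: kymograph '%s' is not a mapping", kid)
    for (tid in names(kymo)) {
      pts <- kymo[[tid]]
      tt <- vapply(pts, function(p) {
        if (length(p) != 2L || !is.numeric(unlist(p)))
          stop_config("parse error: track '%s' in kymograph '%s' has a malformed [t, x] pair",
                      tid, kid)
        as.numeric(p[[1]])
      }, numeric(1))
      xx <- vapply(pts, function(p) as.numeric(p[[2]]), numeric(1))
      rows[[length(rows) + 1L]] <- data.frame(
        kymograph_id = kid, track_id = tid, t_frame = tt, x_pixel = xx,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(empty_raw_tracks())
  do.call(rbind, rows)
}

sort_raw_tracks <- function(raw) {
  if (nrow(raw) == 0L) return(raw)
  ord <- order(raw$kymograph_id, raw$track_id, raw$t_frame, method = "radix")
  out <- raw[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Average duplicate timepoints within each track
#'
#' A particle cannot occupy two positions at once: where a tracker reports
#' several x positions for the same frame of one track, they are replaced by
#' their arithmetic mean. All other points are untouched, so the operation is
#' idempotent and preserves the set of distinct frame indices.
#'
#' @param raw a raw track data.frame as returned by [read_tracks()].
#' @return The same data.frame with at most one row per
#'   (kymograph, track, frame), sorted by track and frame.
#' @export
deduplicate_timepoints <- function(raw) {
  if (nrow(raw) == 0L) return(raw)
  raw <- sort_raw_tracks(raw)
  key <- paste(track_key(raw), raw$t_frame, sep = "\r")
  if (!anyDuplicated(key)) return(raw)
  x_mean <- tapply(raw$x_pixel, key, mean)
  keep <- !duplicated(key)
  out <- raw[keep, , drop = FALSE]
  out$x_pixel <- as.numeric(x_mean[key[keep]])
  rownames(out) <- NULL
  out
}

#' Convert raw tracks to physical units
#'
#' Converts frame indices to seconds and pixel positions to micrometres,
#' signed so that anterograde displacement is positive (`x_um = x_pixel *
#' pixel_size` when plus ends are to the right, negated otherwise), and
#' attaches condition and optional axon-distance metadata.
#'
#' @param raw deduplicated raw tracks (see [deduplicate_timepoints()]).
#' @param cal a [calibration()] object.
#' @param condition condition / strain label attached to every track.
#' @param axon_distance_um distance of the imaged region from the cell body,
#'   in micrometres. Either a single value (or `NA`), or a named vector keyed
#'   by `kymograph_id`.
#' @return A calibrated track data.frame with columns `condition`,
#'   `kymograph_id`, `track_id`, `axon_distance_um`, `t_s`, `x_um`.
#' @export
calibrate_tracks <- function(raw, cal, condition, axon_distance_um = NA_real_) {
  if (!inherits(cal, "dcv_calibration"))
    stop_config("'cal' must be a calibration() object")
  if (!is.character(condition) || length(condition) != 1L)
    stop_config("'condition' must be a single string")
  if (nrow(raw) > 0L) {
    key <- paste(track_key(raw), raw$t_frame, sep = "\r")
    if (anyDuplicated(key))
      stop_config("raw tracks contain duplicate timepoints; run deduplicate_timepoints() first")
  }
  dist <- if (length(axon_distance_um) > 1L || !is.null(names(axon_distance_um))) {
    unname(axon_distance_um[raw$kymograph_id])
  } else {
    rep(as.numeric(axon_distance_um), nrow(raw))
  }
  sign <- if (cal$plus_end_right) 1 else -1
  out <- data.frame(
    condition = rep(condition, nrow(raw)),
    kymograph_id = raw$kymograph_id,
    track_id = raw$track_id,
    axon_distance_um = as.numeric(dist),
    t_s = raw$t_frame * cal$frame_interval_s,
    x_um = sign * raw$x_pixel * cal$pixel_size_um,
    stringsAsFactors = FALSE)
  if (nrow(out)) out <- out[order_by(out, c("condition", "kymograph_id",
                                            "track_id", "t_s")), ]
  rownames(out) <- NULL
  out
}

write_table <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  out <- df
  # >= 9 significant digits so collections round-trip losslessly
  for (col in names(df)[num]) out[[col]] <- format(df[[col]], digits = 15,
                                                   trim = TRUE,
                                                   scientific = FALSE)
  ok <- tryCatch({
    utils::write.csv(out, path, row.names = FALSE, quote = TRUE, na = "")
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stop_config("cannot write to '%s'", path)
  invisible(path)
}

#' Write and read calibrated track tables
#'
#' Long-format CSV with header `condition, kymograph_id, track_id,
#' axon_distance_um, t_s, x_um`. Numeric values are written with enough
#' significant digits that `read_calibrated_tracks(write_tracks(x))`
#' reproduces `x` exactly; a missing axon distance round-trips as `NA`.
#'
#' @param tracks calibrated track data.frame.
#' @param path output/input CSV path.
#' @return `write_tracks()` returns `path` invisibly;
#'   `read_calibrated_tracks()` returns the track data.frame.
#' @export
write_tracks <- function(tracks, path) {
  stopifnot(all(TRACK_COLS %in% names(tracks)))
  write_table(tracks[TRACK_COLS], path)
}

#' @rdname write_tracks
#' @export
read_calibrated_tracks <- function(path) {
  if (!file.exists(path)) stop_config("input file does not exist: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(condition = "character",
                                       kymograph_id = "character",
                                       track_id = "character"))
  missing <- setdiff(TRACK_COLS, names(df))
  if (length(missing))
    stop_config("tracks CSV missing column(s): %s",
                paste(missing, collapse = ", "))
  for (col in c("axon_distance_um", "t_s", "x_um"))
    df[[col]] <- as.numeric(df[[col]])
  df
}

#' Write and read segment tables
#'
#' Long-format CSV mirroring the segment schema produced by
#' [segment_tracks()]; round-trips losslessly.
#'
#' @param segments segment data.frame from [segment_tracks()].
#' @param path output/input CSV path.
#' @return `write_segments()` returns `path` invisibly; `read_segments()`
#'   returns the segment data.frame.
#' @export
write_segments <- function(segments, path) {
  stopifnot(all(SEGMENT_COLS %in% names(segments)))
  write_table(segments[SEGMENT_COLS], path)
}

#' @rdname write_segments
#' @export
read_segments <- function(path) {
  if (!file.exists(path)) stop_config("input file does not exist: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(condition = "character",
                                       kymograph_id = "character",
                                       track_id = "character",
                                       label = "character"))
  missing <- setdiff(SEGMENT_COLS, names(df))
  if (length(missing))
    stop_config("segments CSV missing column(s): %s",
                paste(missing, collapse = ", "))
  df$i_start <- as.integer(df$i_start)
  df$i_end <- as.integer(df$i_end)
  df$n_points <- as.integer(df$n_points)
  df
}
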