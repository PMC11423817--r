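# Aggregate statistics over segments and tracks: per-direction velocity
# summaries, track motility classification, displacement-within-N-frames
# distributions, combined-origin ensembles and axon-position stratification.

#' Per-direction velocity summary
#'
#' Summarizes velocity-eligible segment speeds per condition and direction,
#' in the usual motility-table layout: n, mean, s.d. (n - 1 denominator),
#' median and maximum of the speed magnitudes.
#'
#' @param segments velocity-eligible segments (see [filter_for_velocity()]).
#' @return A data.frame with one row per condition x direction
#'   (`anterograde` = positive velocities, `retrograde` = negative), columns
#'   `condition`, `direction`, `n_segments`, `mean_speed`, `sd_speed`,
#'   `median_speed`, `max_speed`. Directions absent from a condition get an
#'   `n_segments = 0` row with `NA` statistics. Speeds are in um/s.
#' @export
summarize_velocities <- function(segments) {
  conditions <- sort(unique(segments$condition))
  rows <- list()
  for (cond in conditions) {
    for (dir in c("anterograde", "retrograde")) {
      lab <- if (dir == "anterograde") "A" else "R"
      v <- segments$velocity_um_per_s[segments$condition == cond &
                                        segments$label == lab]
      speeds <- abs(v)
      n <- length(speeds)
      rows[[length(rows) + 1L]] <- data.frame(
        condition = cond, direction = dir, n_segments = n,
        mean_speed = if (n) mean(speeds) else NA_real_,
        sd_speed = if (n > 1L) stats::sd(speeds) else NA_real_,
        median_speed = if (n) stats::median(speeds) else NA_real_,
        max_speed = if (n) max(speeds) else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(condition = character(), direction = character(),
                      n_segments = integer(), mean_speed = numeric(),
                      sd_speed = numeric(), median_speed = numeric(),
                      max_speed = numeric(), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Classify tracks by motility behaviour
#'
#' Uses every segment of a track (no minimum-point filter) to decide which
#' motility states it exhibited, then assigns each track to one of three
#' exclusive categories: `stationary_only` (no moving segment),
#' `moving_no_pause` (moving but never stationary) or `moving_with_pause`
#' (both). These are the categories behind Venn-style track summaries.
#'
#' @param segments full segment data.frame from [segment_tracks()].
#' @return A data.frame with one row per track: `condition`, `kymograph_id`,
#'   `track_id`, `has_antero`, `has_retro`, `has_stationary`, `category`.
#' @seealso [class_fractions()]
#' @export
classify_tracks <- function(segments) {
  if (nrow(segments) == 0L)
    return(data.frame(condition = character(), kymograph_id = character(),
                      track_id = character(), has_antero = logical(),
                      has_retro = logical(), has_stationary = logical(),
                      category = character(), stringsAsFactors = FALSE))
  key <- paste(segments$condition, track_key(segments), sep = "\r")
  first <- !duplicated(key)
  has <- function(lab) tapply(segments$label == lab, key, any)
  idx <- key[first]
  has_a <- as.logical(has("A")[idx])
  has_r <- as.logical(has("R")[idx])
  has_s <- as.logical(has("S")[idx])
  moving <- has_a | has_r
  category <- ifelse(!moving, "stationary_only",
                     ifelse(has_s, "moving_with_pause", "moving_no_pause"))
  out <- data.frame(
    condition = segments$condition[first],
    kymograph_id = segments$kymograph_id[first],
    track_id = segments$track_id[first],
    has_antero = unname(has_a), has_retro = unname(has_r),
    has_stationary = unname(has_s), category = unname(category),
    stringsAsFactors = FALSE)
  out <- out[order_by(out, c("condition", "kymograph_id", "track_id")), ]
  rownames(out) <- NULL
  out
}

#' Per-condition motility fractions
#'
#' Category fractions (summing to 1 per condition) and direction
#' participation: the fraction of tracks with at least one anterograde
#' segment and with at least one retrograde segment.
#'
#' @param classes output of [classify_tracks()].
#' @return A data.frame with one row per condition: `condition`, `n_tracks`,
#'   `frac_stationary_only`, `frac_moving_no_pause`, `frac_moving_with_pause`,
#'   `frac_antero`, `frac_retro`.
#' @export
class_fractions <- function(classes) {
  conditions <- sort(unique(classes$condition))
  rows <- lapply(conditions, function(cond) {
    cl <- classes[classes$condition == cond, , drop = FALSE]
    n <- nrow(cl)
    data.frame(
      condition = cond, n_tracks = n,
      frac_stationary_only = mean(cl$category == "stationary_only"),
      frac_moving_no_pause = mean(cl$category == "moving_no_pause"),
      frac_moving_with_pause = mean(cl$category == "moving_with_pause"),
      frac_antero = mean(cl$has_antero),
      frac_retro = mean(cl$has_retro),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Displacement within a fixed number of frames
#'
#' For every track and every start point with a recorded point exactly `n_frames`
#' later, contributes the absolute displacement `|x[i + N] - x[i]|`. Windows
#' broken by missing frames (gaps) are skipped. All overlapping start indices
#' are used by default; `mode = "per_track_max"` instead reports one value
#' per track, the maximum displacement it reached within the window.
#'
#' @param tracks calibrated track data.frame.
#' @param n_frames window length in frames (N >= 1), conventionally one of
#'   5, 10, 20, 40.
#' @param cal the [calibration()] used (supplies the frame interval for
#'   mapping times back to frame indices).
#' @param mode `"pooled"` (all windows) or `"per_track_max"`.
#' @return A data.frame with columns `condition`, `window_n_frames`,
#'   `value` (um, >= 0). Empty (with a warning) if no track is long enough.
#' @export
displacement_distribution <- function(tracks, n_frames, cal = calibration(),
                                      mode = c("pooled", "per_track_max")) {
  mode <- match.arg(mode)
  check_number(n_frames, "n_frames")
  empty <- data.frame(condition = character(), window_n_frames = integer(),
                      value = numeric(), stringsAsFactors = FALSE)
  if (nrow(tracks) == 0L) return(empty)
  pieces <- lapply(split(tracks, ctrack_key(tracks)), function(tr) {
    tr <- tr[order(tr$t_s), , drop = FALSE]
    frames <- as.integer(round(tr$t_s / cal$frame_interval_s))
    target <- match(frames + as.integer(n_frames), frames)
    ok <- !is.na(target)
    if (!any(ok)) return(NULL)
    vals <- abs(tr$x_um[target[ok]] - tr$x_um[ok])
    if (mode == "per_track_max") vals <- max(vals)
    data.frame(condition = tr$condition[1L],
               window_n_frames = as.integer(n_frames), value = vals,
               stringsAsFactors = FALSE)
  })
  pieces <- pieces[!vapply(pieces, is.null, logical(1))]
  if (!length(pieces)) {
    warning(sprintf("no track has two points %d frames apart", n_frames))
    return(empty)
  }
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

#' Align tracks to a common origin
#'
#' Translates every track to start at (0 s, 0 um), the standard way to
#' overlay all trajectories of a condition in one displacement-versus-time
#' plot. No resampling is performed; net displacement is preserved.
#'
#' @param tracks calibrated track data.frame.
#' @return The same data.frame with `t_s` and `x_um` replaced by
#'   track-relative values.
#' @export
align_tracks_to_origin <- function(tracks) {
  if (nrow(tracks) == 0L) return(tracks)
  key <- ctrack_key(tracks)
  pieces <- lapply(split(tracks, key), function(tr) {
    tr <- tr[order(tr$t_s), , drop = FALSE]
    tr$t_s <- tr$t_s - tr$t_s[1L]
    tr$x_um <- tr$x_um - tr$x_um[1L]
    tr
  })
  out <- do.call(rbind, pieces)
  out <- out[order_by(out, c("condition", "kymograph_id", "track_id", "t_s")), ]
  rownames(out) <- NULL
  out
}

#' Stratify tracks by position along the axon
#'
#' Assigns each track to a half-open distance bin `[lo, hi)` based on its
#' `axon_distance_um` metadata (a value exactly on an interior edge starts
#' the upper bin; the top edge of the last bin is closed). By default four
#' equal-width bins span the observed distance range. Tracks without
#' distance metadata go to an `"unassigned"` group with a warning.
#'
#' @param tracks calibrated track data.frame.
#' @param bin_edges increasing numeric vector of bin edges (um), length
#'   `n_bins + 1`; `NULL` for four equal-width bins over the observed range.
#' @return A data.frame with one row per track: `condition`, `kymograph_id`,
#'   `track_id`, `axon_distance_um`, `bin` (an interval label or
#'   `"unassigned"`), `bin_index` (`NA` for unassigned).
#' @export
stratify_by_axon_position <- function(tracks, bin_edges = NULL) {
  key <- ctrack_key(tracks)
  first <- !duplicated(key)
  per_track <- tracks[first, c("condition", "kymograph_id", "track_id",
                               "axon_distance_um")]
  d <- per_track$axon_distance_um
  if (is.null(bin_edges)) {
    obs <- d[!is.na(d)]
    if (!length(obs)) {
      warning("no axon_distance_um metadata; all tracks unassigned")
      per_track$bin <- "unassigned"
      per_track$bin_index <- NA_integer_
      rownames(per_track) <- NULL
      return(per_track)
    }
    bin_edges <- seq(min(obs), max(obs), length.out = 5L)
    if (min(obs) == max(obs)) bin_edges <- min(obs) + c(0, 1e-9 * 1:4)
  }
  if (any(diff(bin_edges) <= 0))
    stop_config("'bin_edges' must be strictly increasing")
  n_bins <- length(bin_edges) - 1L
  idx <- findInterval(d, bin_edges, rightmost.closed = TRUE)
  idx[!is.na(idx) & (idx < 1L | idx > n_bins)] <- NA_integer_
  if (anyNA(idx) && anyNA(d))
    warning(sprintf("%d track(s) without axon_distance_um assigned to 'unassigned'",
                    sum(is.na(d))))
  labels <- sprintf("[%g,%g)", bin_edges[-length(bin_edges)], bin_edges[-1L])
  per_track$bin <- ifelse(is.na(idx), "unassigned", labels[idx])
  per_track$bin_index <- as.integer(idx)
  rownames(per_track) <- NULL
  per_track
}
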