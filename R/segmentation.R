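# Sliding-window segmentation of calibrated tracks into maximal
# anterograde (A) / retrograde (R) / stationary (S) stretches.
#
# For each point i, the forward window ends at the first point j with
# t[j] - t[i] >= tau_w; the windowed displacement d_i = x[j] - x[i] labels
# the point: A if d_i >= theta, R if d_i <= -theta, S otherwise. Trailing
# points with no complete window inherit the last computed label; tracks
# shorter than one window are labelled from their net displacement.
# Windows are defined in time, so frame gaps (e.g. frames removed during
# image stabilization) are handled without interpolation.

SEGMENT_COLS <- c("condition", "kymograph_id", "track_id", "label",
                  "i_start", "i_end", "t_start_s", "t_end_s",
                  "displacement_um", "duration_s", "n_points",
                  "velocity_um_per_s")

#' Segmentation parameters
#'
#' @param theta movement threshold in micrometres: the windowed displacement
#'   a point must reach to be called moving. Default 0.6444 um (6 px at
#'   0.1074 um/px).
#' @param tau_w sliding-window duration in seconds. Default 2 s (a 13-frame
#'   step at 156 ms/frame). Together with `theta` this sets the minimum
#'   detectable speed `theta / tau_w` = 0.3222 um/s at the defaults.
#' @param min_points minimum number of points for a moving segment to enter
#'   velocity statistics (default 4). Applies to velocity statistics only,
#'   never to classification or coverage.
#' @return An object of class `"dcv_seg_params"`.
#' @export
segmentation_params <- function(theta = 0.6444, tau_w = 2.0, min_points = 4L) {
  check_number(theta, "theta")
  check_number(tau_w, "tau_w")
  check_number(min_points, "min_points")
  if (min_points < 2) stop_config("'min_points' must be >= 2")
  structure(list(theta = theta, tau_w = tau_w,
                 min_points = as.integer(min_points)),
            class = "dcv_seg_params")
}

#' @export
print.dcv_seg_params <- function(x, ...) {
  cat(sprintf(
    "segmentation: theta = %g um, window = %g s, min_points = %d (v_min = %.4f um/s)\n",
    x$theta, x$tau_w, x$min_points, x$theta / x$tau_w))
  invisible(x)
}

#' Label track points as anterograde, retrograde or stationary
#'
#' Applies the sliding-window rule to a single track given as time and
#' position vectors.
#'
#' @param t_s time in seconds, strictly increasing.
#' @param x_um position in micrometres (anterograde positive).
#' @param params a [segmentation_params()] object.
#' @return Character vector of per-point labels in `c("A", "R", "S")`.
#' @export
label_points <- function(t_s, x_um, params = segmentation_params()) {
  n <- length(t_s)
  stopifnot(n >= 1L, length(x_um) == n)
  if (n > 1L && any(diff(t_s) <= 0))
    stop_config("track times must be strictly increasing")
  theta <- params$theta
  tau <- params$tau_w
  lab <- rep(NA_character_, n)
  # j(i): smallest j with t[j] >= t[i] + tau. findInterval gives the largest
  # j with t[j] <= t[i] + tau; promote by one unless that point already
  # closes the window exactly.
  j <- findInterval(t_s + tau, t_s)
  closes <- j >= 1L & (t_s[pmax(j, 1L)] - t_s >= tau)
  j <- ifelse(closes, j, j + 1L)
  valid <- j <= n
  if (any(valid)) {
    jv <- j[valid]
    d <- x_um[jv] - x_um[valid]
    lab[valid] <- ifelse(d >= theta, "A", ifelse(d <= -theta, "R", "S"))
    last <- max(which(valid))
    if (last < n) lab[(last + 1L):n] <- lab[last]
  } else {
    net <- x_um[n] - x_um[1L]
    lab[] <- if (net >= theta) "A" else if (net <= -theta) "R" else "S"
  }
  lab
}

segment_one_track <- function(t_s, x_um, params) {
  labels <- label_points(t_s, x_um, params)
  runs <- rle(labels)
  k <- length(runs$lengths)
  ends_run <- cumsum(runs$lengths)        # last index of each label run
  starts <- c(1L, utils::head(ends_run, -1L) + 1L)
  # the first point of each new run also terminates the previous segment,
  # so displacements telescope to the net track displacement
  i_end <- c(if (k > 1L) starts[-1L] else integer(0), length(labels))
  i_start <- starts
  duration <- t_s[i_end] - t_s[i_start]
  displacement <- x_um[i_end] - x_um[i_start]
  velocity <- ifelse(duration > 0, displacement / duration, NA_real_)
  data.frame(
    label = runs$values,
    i_start = i_start, i_end = i_end,
    t_start_s = t_s[i_start], t_end_s = t_s[i_end],
    displacement_um = displacement, duration_s = duration,
    n_points = i_end - i_start + 1L,
    velocity_um_per_s = velocity,
    stringsAsFactors = FALSE)
}

#' Segment a single calibrated track
#'
#' Maximal runs of identical point labels become segments; adjacent segments
#' share their boundary point, so the sum of segment displacements equals the
#' net track displacement exactly. Velocity is displacement over duration
#' (signed; `NA` for single-point segments).
#'
#' @inheritParams label_points
#' @return A data.frame of segments ordered along the track with columns
#'   `label`, `i_start`, `i_end`, `t_start_s`, `t_end_s`, `displacement_um`,
#'   `duration_s`, `n_points`, `velocity_um_per_s`.
#' @export
segment_track <- function(t_s, x_um, params = segmentation_params()) {
  segment_one_track(t_s, x_um, params)
}

#' Segment every track in a calibrated collection
#'
#' @param tracks calibrated track data.frame (see [calibrate_tracks()]).
#' @param params a [segmentation_params()] object.
#' @return A segment data.frame with identification columns `condition`,
#'   `kymograph_id`, `track_id` plus the per-segment columns of
#'   [segment_track()].
#' @export
segment_tracks <- function(tracks, params = segmentation_params()) {
  empty <- data.frame(condition = character(), kymograph_id = character(),
                      track_id = character(), label = character(),
                      i_start = integer(), i_end = integer(),
                      t_start_s = numeric(), t_end_s = numeric(),
                      displacement_um = numeric(), duration_s = numeric(),
                      n_points = integer(), velocity_um_per_s = numeric(),
                      stringsAsFactors = FALSE)
  if (nrow(tracks) == 0L) return(empty)
  pieces <- lapply(split(tracks, ctrack_key(tracks)), function(tr) {
    tr <- tr[order(tr$t_s), , drop = FALSE]
    seg <- segment_one_track(tr$t_s, tr$x_um, params)
    cbind(data.frame(condition = tr$condition[1L],
                     kymograph_id = tr$kymograph_id[1L],
                     track_id = tr$track_id[1L],
                     stringsAsFactors = FALSE),
          seg)
  })
  out <- do.call(rbind, pieces)
  out <- out[order_by(out, c("condition", "kymograph_id", "track_id",
                             "i_start")), ]
  rownames(out) <- NULL
  out[SEGMENT_COLS]
}

#' Select velocity-eligible segments
#'
#' Keeps moving (anterograde or retrograde) segments with at least
#' `min_points` points; stationary and short segments are excluded from
#' velocity statistics only (classification still sees every segment).
#' The removed fraction of moving segments is reported via `message()` for
#' run QC.
#'
#' @param segments segment data.frame from [segment_tracks()].
#' @param params a [segmentation_params()] object.
#' @param quiet suppress the QC message.
#' @return The velocity-eligible subset of `segments`.
#' @export
filter_for_velocity <- function(segments, params = segmentation_params(),
                                quiet = FALSE) {
  moving <- segments$label != "S"
  keep <- moving & segments$n_points >= params$min_points &
    !is.na(segments$velocity_um_per_s)
  n_mov <- sum(moving)
  if (!quiet && n_mov > 0L) {
    dropped <- n_mov - sum(keep)
    message(sprintf(
      "filter_for_velocity: %d of %d moving segments dropped (%.2f%%) below %d points",
      dropped, n_mov, 100 * dropped / n_mov, params$min_points))
  }
  out <- segments[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
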