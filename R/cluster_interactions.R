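# Stationary DCV cluster detection and moving-track interaction scoring.
#
# Clusters are long-lived stationary accumulations at a fixed axonal
# position. A moving vesicle approaching a cluster can pass through it,
# stop at it, or be shed from it. The geometric rules here make that
# (originally visual) scoring reproducible: every threshold is a parameter
# and is echoed in the summary output.

#' Detect stationary clusters
#'
#' Every stationary segment lasting at least `min_duration_s` contributes
#' cluster evidence at its mean position; evidence in the same kymograph
#' that lies within `merge_tol_um` and overlaps in time is merged
#' transitively (union of temporal extents, duration-weighted mean
#' position).
#'
#' @param tracks calibrated track data.frame.
#' @param segments full segment data.frame from [segment_tracks()].
#' @param min_duration_s minimum stationary duration to count as evidence
#'   (default 30 s).
#' @param merge_tol_um spatial merge tolerance (default 0.3222 um = 3 px at
#'   0.1074 um/px).
#' @return A data.frame of clusters: `cluster_id`, `kymograph_id`,
#'   `x_center_um`, `t_start_s`, `t_end_s`, `n_evidence`,
#'   `source_track_ids` (semicolon-separated).
#' @export
detect_clusters <- function(tracks, segments, min_duration_s = 30,
                            merge_tol_um = 0.3222) {
  check_number(min_duration_s, "min_duration_s")
  check_number(merge_tol_um, "merge_tol_um")
  empty <- data.frame(cluster_id = character(), kymograph_id = character(),
                      x_center_um = numeric(), t_start_s = numeric(),
                      t_end_s = numeric(), n_evidence = integer(),
                      source_track_ids = character(), stringsAsFactors = FALSE)
  ev <- segments[segments$label == "S" &
                   segments$duration_s >= min_duration_s, , drop = FALSE]
  if (nrow(ev) == 0L) return(empty)
  # mean x over the points of each stationary segment
  tr_split <- split(tracks[order(tracks$t_s), ], track_key(tracks[order(tracks$t_s), ]))
  ev$x_center_um <- vapply(seq_len(nrow(ev)), function(i) {
    tr <- tr_split[[paste(ev$kymograph_id[i], ev$track_id[i], sep = "\r")]]
    mean(tr$x_um[ev$i_start[i]:ev$i_end[i]])
  }, numeric(1))

  out <- list()
  for (kid in unique(ev$kymograph_id)) {
    e <- ev[ev$kymograph_id == kid, , drop = FALSE]
    n <- nrow(e)
    parent <- seq_len(n)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    if (n > 1L) {
      ord <- order(e$x_center_um)
      for (ai in seq_len(n - 1L)) for (bi in (ai + 1L):n) {
        a <- ord[ai]; b <- ord[bi]
        if (e$x_center_um[b] - e$x_center_um[a] > merge_tol_um) break
        if (e$t_start_s[a] <= e$t_end_s[b] && e$t_start_s[b] <= e$t_end_s[a]) {
          ra <- find(a); rb <- find(b)
          if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
        }
      }
    }
    roots <- vapply(seq_len(n), find, integer(1))
    for (r in unique(roots)) {
      idx <- which(roots == r)
      wgt <- e$duration_s[idx]
      out[[length(out) + 1L]] <- data.frame(
        kymograph_id = kid,
        x_center_um = sum(e$x_center_um[idx] * wgt) / sum(wgt),
        t_start_s = min(e$t_start_s[idx]),
        t_end_s = max(e$t_end_s[idx]),
        n_evidence = length(idx),
        source_track_ids = paste(sort(unique(e$track_id[idx])),
                                 collapse = ";"),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, out)
  out <- out[order_by(out, c("kymograph_id", "x_center_um")), ]
  out <- cbind(cluster_id = sprintf("C%04d", seq_len(nrow(out))), out,
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Score moving-track interactions with clusters
#'
#' Three event kinds are scored per (track, cluster) geometry:
#' * **pass** - a moving segment whose x extent strictly spans the band
#'   `[x_center - tol, x_center + tol]` while overlapping the cluster in
#'   time. One crossing yields one event; a repeat against the same cluster
#'   requires an intervening stop or direction change (which, with maximal
#'   segments, means a different moving segment).
#' * **stop** - a stationary segment of an otherwise-moving track lying
#'   within `tol` of the cluster centre, adjacent to a moving segment and
#'   overlapping the cluster in time.
#' * **shed** - a track born within `tol` of a live cluster whose first
#'   segment is moving (cluster source tracks themselves are excluded).
#'
#' @param tracks calibrated track data.frame.
#' @param segments full segment data.frame.
#' @param clusters output of [detect_clusters()].
#' @param tol_um spatial tolerance (default 0.3222 um = 3 px).
#' @return A list with `events` (data.frame: `track_id`, `kymograph_id`,
#'   `cluster_id`, `kind`, `t_event_s`, `direction`) and `summary`
#'   (per-direction data.frame: `direction`, `n_moving_tracks`,
#'   `frac_passing`, `frac_stopping`, `n_shed`) plus the tolerance used.
#' @export
score_interactions <- function(tracks, segments, clusters,
                               tol_um = 0.3222) {
  check_number(tol_um, "tol_um")
  ev_cols <- data.frame(track_id = character(), kymograph_id = character(),
                        cluster_id = character(), kind = character(),
                        t_event_s = numeric(), direction = character(),
                        stringsAsFactors = FALSE)
  events <- list()
  tracks <- tracks[order(tracks$t_s), ]
  tr_split <- split(tracks, track_key(tracks))
  seg_split <- split(segments, track_key(segments))

  for (key in names(seg_split)) {
    seg <- seg_split[[key]]
    seg <- seg[order(seg$i_start), , drop = FALSE]
    tr <- tr_split[[key]]
    kid <- seg$kymograph_id[1L]
    cl <- clusters[clusters$kymograph_id == kid, , drop = FALSE]
    if (nrow(cl) == 0L) next
    moving <- seg$label != "S"
    x_start <- tr$x_um[seg$i_start]
    x_end <- tr$x_um[seg$i_end]

    # shed: track born at a live cluster, first segment moving
    if (moving[1L]) {
      t0 <- tr$t_s[1L]; x0 <- tr$x_um[1L]
      born <- which(abs(cl$x_center_um - x0) <= tol_um &
                      cl$t_start_s <= t0 & cl$t_end_s >= t0)
      born <- born[!vapply(born, function(i)
        seg$track_id[1L] %in% strsplit(cl$source_track_ids[i], ";")[[1L]],
        logical(1))]
      if (length(born)) {
        events[[length(events) + 1L]] <- data.frame(
          track_id = seg$track_id[1L], kymograph_id = kid,
          cluster_id = cl$cluster_id[born[1L]], kind = "shed",
          t_event_s = t0, direction = seg$label[1L],
          stringsAsFactors = FALSE)
      }
    }

    for (si in seq_len(nrow(seg))) {
      lo <- min(x_start[si], x_end[si]); hi <- max(x_start[si], x_end[si])
      overlap <- seg$t_start_s[si] <= cl$t_end_s &
        cl$t_start_s <= seg$t_end_s[si]
      if (moving[si]) {
        hit <- which(overlap & lo < cl$x_center_um - tol_um &
                       hi > cl$x_center_um + tol_um)
        for (ci in hit) {
          v <- seg$velocity_um_per_s[si]
          t_cross <- seg$t_start_s[si] +
            (cl$x_center_um[ci] - x_start[si]) / v
          events[[length(events) + 1L]] <- data.frame(
            track_id = seg$track_id[si], kymograph_id = kid,
            cluster_id = cl$cluster_id[ci], kind = "pass",
            t_event_s = t_cross, direction = seg$label[si],
            stringsAsFactors = FALSE)
        }
      } else if (any(moving)) {
        adj_moving <- (si > 1L && moving[si - 1L]) ||
          (si < nrow(seg) && moving[si + 1L])
        if (!adj_moving) next
        x_mean <- mean(tr$x_um[seg$i_start[si]:seg$i_end[si]])
        hit <- which(overlap & abs(cl$x_center_um - x_mean) <= tol_um)
        dir <- if (si > 1L && moving[si - 1L]) seg$label[si - 1L] else
          seg$label[si + 1L]
        for (ci in hit) {
          events[[length(events) + 1L]] <- data.frame(
            track_id = seg$track_id[si], kymograph_id = kid,
            cluster_id = cl$cluster_id[ci], kind = "stop",
            t_event_s = seg$t_start_s[si], direction = dir,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  events <- if (length(events)) do.call(rbind, events) else ev_cols
  rownames(events) <- NULL

  classes <- classify_tracks(segments)
  summary <- do.call(rbind, lapply(c("A", "R"), function(lab) {
    movers <- classes[if (lab == "A") classes$has_antero else
      classes$has_retro, , drop = FALSE]
    mkey <- paste(movers$kymograph_id, movers$track_id, sep = "\r")
    e <- events[events$direction == lab, , drop = FALSE]
    ekey <- paste(e$kymograph_id, e$track_id, sep = "\r")
    data.frame(
      direction = if (lab == "A") "anterograde" else "retrograde",
      n_moving_tracks = nrow(movers),
      frac_passing = if (nrow(movers)) mean(mkey %in% ekey[e$kind == "pass"]) else NA_real_,
      frac_stopping = if (nrow(movers)) mean(mkey %in% ekey[e$kind == "stop"]) else NA_real_,
      n_shed = sum(e$kind == "shed"),
      stringsAsFactors = FALSE)
  }))
  rownames(summary) <- NULL
  list(events = events, summary = summary, tol_um = tol_um)
}
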