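# Cluster detection and pass/stop/shed interaction scoring on
# deterministically planted geometries.

dtf <- 0.156

# noise-free calibrated tracks on one kymograph
stationary_track <- function(id, x, t0 = 0, t1 = 78) {
  tt <- seq(t0, t1, by = dtf)
  make_tracks_df(list(t = tt, x = rep(x, length(tt)), id = id))
}
mover_track <- function(id, x0, v, t0 = 0, t1 = 30) {
  tt <- seq(t0, t1, by = dtf)
  make_tracks_df(list(t = tt, x = x0 + v * (tt - t0), id = id))
}

test_that("stationary evidence becomes clusters and merges within tolerance", {
  tr <- stationary_track("T1", 10)
  seg <- segment_tracks(tr)
  cl <- detect_clusters(tr, seg)
  expect_identical(nrow(cl), 1L)
  expect_equal(cl$x_center_um, 10)
  expect_equal(cl$t_start_s, 0)
  expect_equal(cl$t_end_s, 78)

  # two co-temporal stationary tracks 0.1 um apart merge into one cluster
  tr2 <- rbind(stationary_track("T1", 10), stationary_track("T2", 10.1))
  cl2 <- detect_clusters(tr2, segment_tracks(tr2), merge_tol_um = 0.32)
  expect_identical(nrow(cl2), 1L)
  expect_equal(cl2$x_center_um, 10.05)
  expect_identical(cl2$n_evidence, 2L)

  # beyond the tolerance they stay separate
  tr3 <- rbind(stationary_track("T1", 10), stationary_track("T2", 11))
  expect_identical(nrow(detect_clusters(tr3, segment_tracks(tr3))), 2L)

  # short stationary dwell is not cluster evidence
  short <- stationary_track("T1", 10, 0, 10)
  expect_identical(nrow(detect_clusters(short, segment_tracks(short))), 0L)

  # moving-only kymograph has no clusters
  mv <- mover_track("T1", 0, 1.5)
  expect_identical(nrow(detect_clusters(mv, segment_tracks(mv))), 0L)
})

test_that("pass, stop and shed events are scored with perfect recall on planted geometry", {
  cluster_tr <- stationary_track("C", 20)
  # mover crossing the cluster without stopping -> one pass, no stop
  pass_tr <- mover_track("P1", 10, 2, t0 = 0, t1 = 10)
  # mover that runs, stops exactly at the cluster, then runs on -> stop
  stop_tr <- local({
    ph <- piecewise_track(list(c(2, 7), c(0, 8), c(2, 7)), x0 = 6)
    make_tracks_df(list(t = ph$t, x = ph$x, id = "P2"))
  })
  # track born at the cluster moving retrograde -> shed
  shed_tr <- mover_track("P3", 20, -1.5, t0 = 40, t1 = 50)
  tracks <- rbind(cluster_tr, pass_tr, stop_tr, shed_tr)
  seg <- segment_tracks(tracks)
  cl <- detect_clusters(tracks, seg)
  expect_identical(nrow(cl), 1L)
  sc <- score_interactions(tracks, seg, cl)
  ev <- sc$events

  expect_identical(sort(unique(ev$kind)), c("pass", "shed", "stop"))
  expect_identical(ev$track_id[ev$kind == "pass" & ev$direction == "A"][1], "P1")
  # P2 pauses at x = 20 for 8 s: scored as a stop; neither of its moving
  # segments strictly spans the +/- tol band on its own, so no pass
  expect_true("P2" %in% ev$track_id[ev$kind == "stop"])
  expect_identical(ev$track_id[ev$kind == "shed"], "P3")
  expect_identical(ev$direction[ev$kind == "shed"], "R")
  # no spurious events: every planted event accounted for, nothing else
  expect_identical(nrow(ev[ev$kind == "stop", ]), 1L)
  expect_identical(nrow(ev[ev$kind == "shed", ]), 1L)
  expect_true(all(ev$cluster_id %in% cl$cluster_id))

  s <- sc$summary
  # anterograde movers are P1 (passes) and P2 (stops): half pass, half stop
  expect_equal(s$frac_passing[s$direction == "anterograde"], 0.5)
  expect_equal(s$frac_stopping[s$direction == "anterograde"], 0.5)
  expect_true(all(s$frac_passing <= 1 & s$frac_passing >= 0, na.rm = TRUE))
})

test_that("movers that do not reach a cluster generate no events", {
  tracks <- rbind(stationary_track("C", 60), mover_track("P1", 5, 1, 0, 20))
  seg <- segment_tracks(tracks)
  cl <- detect_clusters(tracks, seg)
  sc <- score_interactions(tracks, seg, cl)
  expect_identical(nrow(sc$events), 0L)
  expect_equal(sc$summary$frac_passing[sc$summary$direction == "anterograde"], 0)
})

test_that("widening the spatial tolerance never loses pass or stop events", {
  set.seed(55)
  tracks <- rbind(
    stationary_track("C1", 15), stationary_track("C2", 35),
    mover_track("P1", 5, 2, 0, 25), mover_track("P2", 45, -1.8, 0, 25))
  seg <- segment_tracks(tracks)
  cl <- detect_clusters(tracks, seg)
  counts <- vapply(c(0.1, 0.3222, 1, 3), function(tol) {
    ev <- score_interactions(tracks, seg, cl, tol_um = tol)$events
    sum(ev$kind %in% c("pass", "stop"))
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("simulated cluster shedding is recovered end to end", {
  # slow planted speeds keep the first observed point of a shed track
  # within one frame step (< tol) of its birth cluster at zero noise
  slow <- velocity_mixture(1, 1.0, 0.15)
  cfg <- simulation_config(n_tracks = 12, seed = 21, noise_sd_um = 0,
                           n_clusters = 3, shed_rate_per_100s = 6,
                           antero_velocity = slow, retro_velocity = slow,
                           class_probs = c(stationary = 0.5, no_pause = 0.5,
                                           with_pause = 0),
                           tracks_per_kymograph = 1000L)
  sim <- simulate_tracks(cfg)
  shed_planted <- sum(vapply(sim$truth$tracks, function(t) isTRUE(t$is_shed),
                             logical(1)))
  expect_gt(shed_planted, 0L)
  tr <- calibrate_tracks(deduplicate_timepoints(sim$tracks), calibration(),
                         "sim")
  seg <- segment_tracks(tr)
  cl <- detect_clusters(tr, seg)
  sc <- score_interactions(tr, seg, cl)
  shed_found <- sc$events[sc$events$kind == "shed", ]
  planted_ids <- vapply(Filter(function(t) isTRUE(t$is_shed),
                               sim$truth$tracks),
                        function(t) t$track_id, character(1))
  # every planted shed track is recovered as a shed event (recall = 1)
  expect_true(all(planted_ids %in% shed_found$track_id))
  # every reported shed event is geometrically valid: the track really is
  # born within tolerance of the referenced cluster while it is live
  firsts <- tr[!duplicated(track_key(tr)), ]
  for (i in seq_len(nrow(shed_found))) {
    f <- firsts[firsts$track_id == shed_found$track_id[i], ]
    c_i <- cl[cl$cluster_id == shed_found$cluster_id[i], ]
    expect_lte(abs(f$x_um - c_i$x_center_um), sc$tol_um)
    expect_lte(c_i$t_start_s, f$t_s)
  }
})
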