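# Velocity summaries, track classification, displacement distributions,
# origin alignment and axon-position stratification.

test_that("velocity summaries are exact sample statistics of speeds", {
  segs <- data.frame(
    condition = "c", kymograph_id = "K1", track_id = "T1",
    label = c("A", "A", "A", "R"), i_start = 1L, i_end = 5L,
    t_start_s = 0, t_end_s = 1, displacement_um = 0, duration_s = 1,
    n_points = 5L, velocity_um_per_s = c(1, 2, 3, -2.5),
    stringsAsFactors = FALSE)
  s <- summarize_velocities(segs)
  a <- s[s$direction == "anterograde", ]
  expect_identical(a$n_segments, 3L)
  expect_equal(a$mean_speed, 2)
  expect_equal(a$sd_speed, 1)
  expect_equal(a$median_speed, 2)
  expect_equal(a$max_speed, 3)
  # retrograde speeds are magnitudes; n = 1 leaves sd undefined
  r <- s[s$direction == "retrograde", ]
  expect_identical(r$n_segments, 1L)
  expect_equal(r$mean_speed, 2.5)
  expect_true(is.na(r$sd_speed))
  expect_true(r$max_speed >= r$median_speed)

  # permutation invariance
  s2 <- summarize_velocities(segs[sample(nrow(segs)), ])
  expect_equal(s2, s)
})

test_that("tracks are classified into the three exclusive categories", {
  mk <- function(id, labels) data.frame(
    condition = "c", kymograph_id = "K1", track_id = id, label = labels,
    i_start = seq_along(labels), i_end = seq_along(labels) + 1L,
    t_start_s = 0, t_end_s = 1, displacement_um = 0, duration_s = 1,
    n_points = 2L, velocity_um_per_s = 0, stringsAsFactors = FALSE)
  segs <- rbind(mk("T1", "S"), mk("T2", c("A", "S", "R")), mk("T3", "A"))
  cl <- classify_tracks(segs)
  expect_identical(cl$category[cl$track_id == "T1"], "stationary_only")
  expect_identical(cl$category[cl$track_id == "T2"], "moving_with_pause")
  expect_true(cl$has_antero[cl$track_id == "T2"] &&
                cl$has_retro[cl$track_id == "T2"])
  expect_identical(cl$category[cl$track_id == "T3"], "moving_no_pause")

  fr <- class_fractions(cl)
  expect_equal(fr$frac_stationary_only + fr$frac_moving_no_pause +
                 fr$frac_moving_with_pause, 1, tolerance = 1e-12)
  expect_equal(fr$frac_antero, 2 / 3)
  expect_equal(fr$frac_retro, 1 / 3)
})

test_that("displacement distributions pool all N-frame windows", {
  cal <- calibration()
  dtf <- cal$frame_interval_s
  t <- (0:19) * dtf
  tracks <- make_tracks_df(list(t = t, x = rep(3, 20)),
                           list(t = t, x = 2 * t))
  d <- displacement_distribution(tracks, 5, cal)
  # stationary track contributes zeros; drift contributes 2 * 5 * dt each
  expect_equal(sort(unique(round(d$value, 9))),
               round(c(0, 2 * 5 * dtf), 9))
  # count obeys the closed form sum(n_points - N)
  expect_identical(nrow(d), 2L * (20L - 5L))

  # track of 6 points has exactly one 5-frame window
  short <- make_tracks_df(list(t = (0:5) * dtf, x = (0:5) * 0.5))
  expect_identical(nrow(displacement_distribution(short, 5, cal)), 1L)
  # windows broken by a missing frame are skipped: frames 0-2 and 4-6
  # give exactly the 0->5 and 1->6 pairs (2->7 has no partner)
  gap <- make_tracks_df(list(t = c(0:2, 4:6) * dtf, x = rep(1, 6)))
  expect_identical(nrow(displacement_distribution(gap, 5, cal)), 2L)
  # N longer than every track -> empty with a warning
  expect_warning(out <- displacement_distribution(short, 50, cal), "frames")
  expect_identical(nrow(out), 0L)

  # per-track maximum mode gives one value per track
  dm <- displacement_distribution(tracks, 5, cal, mode = "per_track_max")
  expect_identical(nrow(dm), 2L)
  expect_equal(max(dm$value), 2 * 5 * dtf)
})

test_that("origin alignment translates tracks without distortion", {
  tracks <- make_tracks_df(list(t = c(3, 3.156, 3.312), x = c(50, 51, 52)),
                           list(t = c(7, 7.156, 7.312), x = c(80, 81, 82)))
  al <- align_tracks_to_origin(tracks)
  firsts <- al[!duplicated(track_key(al <- al[order(al$track_id, al$t_s), ])), ]
  expect_true(all(firsts$t_s == 0) && all(firsts$x_um == 0))
  # two identical shapes at different offsets align identically
  expect_equal(al$x_um[al$track_id == "T01"], al$x_um[al$track_id == "T02"])
  # net displacement preserved
  expect_equal(diff(range(al$x_um[al$track_id == "T01"])),
               diff(range(tracks$x_um[tracks$track_id == "T01"])))
})

test_that("axon-position bins are half-open with edge values going up", {
  tracks <- rbind(
    make_tracks_df(list(t = 0, x = 0, dist = 100, kymo = "K1")),
    make_tracks_df(list(t = 0, x = 0, dist = 300, kymo = "K2")),
    make_tracks_df(list(t = 0, x = 0, dist = 650, kymo = "K3")))
  st <- stratify_by_axon_position(tracks, c(0, 250, 500, 750, 1000))
  expect_identical(st$bin_index, c(1L, 2L, 3L))
  # a distance exactly on an interior edge starts the upper bin
  edge <- make_tracks_df(list(t = 0, x = 0, dist = 250))
  expect_identical(stratify_by_axon_position(edge, c(0, 250, 500))$bin_index,
                   2L)
  # missing metadata -> unassigned with warning
  none <- make_tracks_df(list(t = 0, x = 0))
  expect_warning(u <- stratify_by_axon_position(none), "unassigned")
  expect_identical(u$bin, "unassigned")
})

test_that("classified fractions recover planted class probabilities", {
  # binomial check at simulated n: each category fraction must fall within
  # the exact 99% interval around its planted probability
  sim <- simulate_tracks(sim_preset("wild_type", n_tracks = 600, seed = 11))
  tr <- calibrate_tracks(deduplicate_timepoints(sim$tracks), calibration(),
                         "wt")
  fr <- class_fractions(classify_tracks(segment_tracks(tr)))
  n <- fr$n_tracks
  planted <- c(stationary_only = 0.666, moving_no_pause = 0.215,
               moving_with_pause = 0.119)
  got <- c(fr$frac_stationary_only, fr$frac_moving_no_pause,
           fr$frac_moving_with_pause)
  for (i in 1:3) {
    ci <- stats::qbinom(c(0.005, 0.995), n, planted[i]) / n
    expect_gte(got[i], ci[1])
    expect_lte(got[i], ci[2])
  }
})
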