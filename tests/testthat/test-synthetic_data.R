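# Synthetic transport simulator: determinism, ground-truth consistency,
# preset parameterization and file emission.

test_that("configuration is validated before any sampling", {
  expect_error(simulation_config(n_tracks = -1), "n_tracks")
  expect_error(simulation_config(10, class_probs = c(0.5, 0.5, 0.5)),
               "sum")
  expect_error(simulation_config(10, noise_sd_um = -1), ">= 0")
  expect_error(velocity_mixture(c(0.5, 0.6), c(1, 2), c(0.1, 0.1)), "sum")
  expect_error(velocity_mixture(1, -1, 0.1), "> 0")
  expect_error(simulate_tracks(list()), "simulation_config")
})

test_that("an empty simulation yields empty collections", {
  sim <- simulate_tracks(simulation_config(n_tracks = 0, n_clusters = 0))
  expect_identical(nrow(sim$tracks), 0L)
  expect_identical(length(sim$truth$tracks), 0L)
})

test_that("the same seed reproduces the simulation bit for bit", {
  cfg <- sim_preset("wild_type", n_tracks = 40, seed = 9)
  s1 <- simulate_tracks(cfg)
  s2 <- simulate_tracks(cfg)
  expect_identical(s1$tracks, s2$tracks)
  expect_identical(s1$truth, s2$truth)
  s3 <- simulate_tracks(sim_preset("wild_type", n_tracks = 40, seed = 10))
  expect_false(identical(s1$tracks, s3$tracks))
})

test_that("zero-noise single mover is recovered exactly by segmentation", {
  cfg <- simulation_config(
    n_tracks = 1, seed = 3, noise_sd_um = 0, n_clusters = 0,
    class_probs = c(stationary = 0, no_pause = 1, with_pause = 0),
    p_reversal = 0, mean_run_s = 1e6)   # one run spanning the whole movie
  sim <- simulate_tracks(cfg)
  truth <- sim$truth$tracks[[1]]
  expect_identical(truth$class, "no_pause")
  v_true <- truth$runs$v[1]

  tr <- calibrate_tracks(deduplicate_timepoints(sim$tracks), calibration(),
                         "sim")
  seg <- segment_tracks(tr)
  expect_identical(nrow(seg), 1L)
  expect_identical(seg$label, if (v_true > 0) "A" else "R")
  expect_equal(seg$velocity_um_per_s, v_true, tolerance = 1e-9)
})

test_that("zero-noise run-and-pause tracks match ground truth segment for segment", {
  cfg <- simulation_config(
    n_tracks = 12, seed = 14, noise_sd_um = 0, n_clusters = 0,
    class_probs = c(stationary = 0, no_pause = 0, with_pause = 1),
    p_reversal = 0, mean_run_s = 15, mean_pause_s = 6)
  sim <- simulate_tracks(cfg)
  tr <- calibrate_tracks(deduplicate_timepoints(sim$tracks), calibration(),
                         "sim")
  seg <- segment_tracks(tr)
  p <- segmentation_params()
  n_checked <- 0L
  for (truth in sim$truth$tracks) {
    s <- seg[seg$track_id == truth$track_id & seg$label != "S", ]
    # compare each recovered moving segment that maps to a single planted
    # run (segments that bridge a short undetected pause straddle two runs
    # and are skipped) against that run, within the boundary-smearing
    # bound 2 * v * tau_w / duration
    for (i in seq_len(nrow(s))) {
      core <- c(s$t_start_s[i] + p$tau_w, s$t_end_s[i] - p$tau_w)
      if (core[2] <= core[1]) next
      run <- truth$runs[truth$runs$t0 < core[2] & truth$runs$t1 > core[1], ]
      if (nrow(run) != 1L) next
      bound <- 2 * abs(run$v[1]) * p$tau_w / s$duration_s[i] + 1e-9
      expect_lt(abs(s$velocity_um_per_s[i] - run$v[1]), bound)
      expect_identical(s$label[i], if (run$v[1] > 0) "A" else "R")
      n_checked <- n_checked + 1L
    }
  }
  expect_gt(n_checked, 10L)
})

test_that("planted run speeds respect the lower truncation", {
  sim <- simulate_tracks(sim_preset("unc116_rf", n_tracks = 150, seed = 5))
  runs <- do.call(rbind, lapply(sim$truth$tracks, function(t) t$runs))
  expect_true(all(abs(runs$v) >= 0.35))
})

test_that("strain presets carry the published motility parameters", {
  wt <- sim_preset("wild_type")
  expect_equal(wt$retro_velocity$means, 2.14)
  expect_equal(wt$retro_velocity$sds, 0.77)
  expect_equal(wt$antero_velocity$means, 1.4)
  expect_equal(unname(wt$class_probs),
               c(0.666, 0.215, 0.119))
  # planted anterograde participation = P(moving) * p_antero_start = 12.2%
  expect_equal((1 - wt$class_probs[["stationary"]]) * wt$p_antero_start,
               0.122, tolerance = 1e-9)

  expect_equal(sim_preset("unc116_rf")$antero_velocity$means, 0.67)
  expect_equal(sim_preset("unc116_rf")$retro_velocity$sds, 0.24)
  expect_equal(sim_preset("klc1_null")$retro_velocity$means, 2.38)
  expect_equal(sim_preset("klc2_km11")$antero_velocity$means, 1.2)
  expect_equal(sim_preset("klc2_km11")$retro_velocity$means, 1.66)

  wt3 <- sim_preset("wild_type", antero_components = 3)
  expect_identical(length(wt3$antero_velocity$means), 3L)
  expect_equal(sum(wt3$antero_velocity$weights * wt3$antero_velocity$means),
               1.36, tolerance = 0.05)

  expect_error(sim_preset("mystery"), "wild_type")
})

test_that("emitted files round-trip through both ingest dialects", {
  sim <- simulate_tracks(sim_preset("wild_type", n_tracks = 25, seed = 4))
  out <- tempfile("simout")
  paths <- emit_input_files(sim, out)
  expect_true(all(file.exists(paths)))

  csv <- read_tracks(paths[["tracks_csv"]], "long_csv")
  expect_equal(csv, sim$tracks)
  json <- read_tracks(paths[["tracks_json"]], "kymobutler_json")
  expect_equal(json, sim$tracks)

  truth <- jsonlite::fromJSON(paths[["truth_json"]], simplifyVector = FALSE)
  expect_identical(length(truth$tracks), length(sim$truth$tracks))

  # different seed -> different data, identical schema
  sim2 <- simulate_tracks(sim_preset("wild_type", n_tracks = 25, seed = 5))
  expect_identical(names(sim2$tracks), names(sim$tracks))
  expect_false(identical(sim2$tracks, sim$tracks))
})
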