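# Ground-truthed synthetic kymograph tracks.
#
# The generative model is a run-and-pause state switcher: each track is
# stationary for the whole movie, moves without pausing, or alternates
# exponentially distributed runs and pauses. Run velocities are drawn per
# direction from a Gaussian mixture truncated below at v_min (redraw), so
# every planted run is detectable at the standard segmentation threshold.
# Direction flips with a small probability at run boundaries (reversals are
# rare). Long-lived stationary tracks double as vesicle clusters that shed
# movers. The observed position is the true position plus Gaussian
# localization noise, sampled every frame and emitted in pixel/frame units,
# i.e. exactly the input format consumed by read_tracks().
#
# Class probabilities refer to the *observed* motility phenotype (how a
# scored kymograph track looks), so movers are conditioned - by bounded
# rejection resampling - on their assigned phenotype actually manifesting
# within the recorded window.

#' Mixture specification for run velocities
#'
#' @param weights component weights (sum 1).
#' @param means component mean speeds, um/s (positive magnitudes).
#' @param sds component standard deviations, um/s.
#' @return A validated list with class `"dcv_vel_mix"`.
#' @export
velocity_mixture <- function(weights, means, sds) {
  if (length(weights) != length(means) || length(means) != length(sds))
    stop_config("velocity mixture fields must have equal length")
  check_prob(weights, "weights")
  if (abs(sum(weights) - 1) > 1e-9)
    stop_config("velocity mixture weights must sum to 1")
  if (any(means <= 0) || any(sds <= 0))
    stop_config("velocity mixture means and sds must be > 0")
  structure(list(weights = as.numeric(weights), means = as.numeric(means),
                 sds = as.numeric(sds)), class = "dcv_vel_mix")
}

draw_speed <- function(mix, v_min) {
  repeat {
    k <- sample.int(length(mix$weights), 1L, prob = mix$weights)
    v <- stats::rnorm(1L, mix$means[k], mix$sds[k])
    if (v >= v_min) return(v)
  }
}

#' Simulation configuration
#'
#' Full parameterization of the synthetic transport model. Defaults mirror
#' the imaging geometry of the motivating experiments (500 frames at 156 ms,
#' 0.1074 um/px) and wild-type motility statistics; see [sim_preset()] for
#' strain presets.
#'
#' @param n_tracks number of primary tracks (cluster-shed tracks come on
#'   top).
#' @param n_frames movie length in frames.
#' @param frame_interval_s seconds per frame.
#' @param pixel_size_um micrometres per pixel.
#' @param field_length_um length of the imaged axon stretch; tracks are
#'   truncated (not reflected) when they leave it.
#' @param class_probs probabilities of the three observed phenotypes,
#'   named `stationary`, `no_pause`, `with_pause`; must sum to 1.
#' @param p_antero_start probability that a mover's first run is
#'   anterograde.
#' @param antero_velocity,retro_velocity [velocity_mixture()] objects for
#'   run speeds in each direction (um/s).
#' @param v_min lower truncation of run speeds (redraw on violation),
#'   um/s. Must be at least the minimum detectable speed `theta / tau_w`
#'   of the segmentation so planted runs are observable.
#' @param mean_run_s mean run duration (exponential), s.
#' @param mean_pause_s mean pause duration (exponential), s.
#' @param p_reversal probability that a new run flips direction.
#' @param noise_sd_um s.d. of Gaussian localization noise, um.
#' @param tracks_per_kymograph tracks grouped per synthetic kymograph.
#' @param n_clusters number of whole-movie stationary tracks designated as
#'   shedding clusters (capped at the number of stationary tracks).
#' @param shed_rate_per_100s expected shed events per cluster per 100 s.
#' @param shed_direction_probs probabilities (named `antero`, `retro`,
#'   sum 1) of the outgoing direction of a shed vesicle.
#' @param seed RNG seed; the whole simulation is reproducible from it.
#' @return A validated list with class `"dcv_sim_config"`.
#' @export
simulation_config <- function(n_tracks,
                              n_frames = 500L,
                              frame_interval_s = 0.156,
                              pixel_size_um = 0.1074,
                              field_length_um = 80,
                              class_probs = c(stationary = 0.666,
                                              no_pause = 0.215,
                                              with_pause = 0.119),
                              p_antero_start = 0.365,
                              antero_velocity = velocity_mixture(1, 1.4, 0.68),
                              retro_velocity = velocity_mixture(1, 2.14, 0.77),
                              v_min = 0.35,
                              mean_run_s = 20,
                              mean_pause_s = 4,
                              p_reversal = 0.02,
                              noise_sd_um = 0.05,
                              tracks_per_kymograph = 40L,
                              n_clusters = 4L,
                              shed_rate_per_100s = 0.5,
                              shed_direction_probs = c(antero = 0.716,
                                                       retro = 0.284),
                              seed = 1L) {
  if (!is.numeric(n_tracks) || n_tracks < 0)
    stop_config("'n_tracks' must be >= 0")
  check_number(n_frames, "n_frames")
  check_number(frame_interval_s, "frame_interval_s")
  check_number(pixel_size_um, "pixel_size_um")
  check_number(field_length_um, "field_length_um")
  check_prob(class_probs, "class_probs")
  if (length(class_probs) != 3L || abs(sum(class_probs) - 1) > 1e-9)
    stop_config("'class_probs' must be 3 probabilities summing to 1")
  names(class_probs) <- c("stationary", "no_pause", "with_pause")
  check_prob(p_antero_start, "p_antero_start")
  if (!inherits(antero_velocity, "dcv_vel_mix") ||
      !inherits(retro_velocity, "dcv_vel_mix"))
    stop_config("velocity distributions must be velocity_mixture() objects")
  check_number(v_min, "v_min")
  check_number(mean_run_s, "mean_run_s")
  check_number(mean_pause_s, "mean_pause_s")
  check_prob(p_reversal, "p_reversal")
  check_number(noise_sd_um, "noise_sd_um", positive = FALSE)
  if (noise_sd_um < 0) stop_config("'noise_sd_um' must be >= 0")
  check_number(tracks_per_kymograph, "tracks_per_kymograph")
  if (!is.numeric(n_clusters) || n_clusters < 0)
    stop_config("'n_clusters' must be >= 0")
  check_number(shed_rate_per_100s, "shed_rate_per_100s", positive = FALSE)
  if (shed_rate_per_100s < 0) stop_config("'shed_rate_per_100s' must be >= 0")
  check_prob(shed_direction_probs, "shed_direction_probs")
  if (length(shed_direction_probs) != 2L ||
      abs(sum(shed_direction_probs) - 1) > 1e-9)
    stop_config("'shed_direction_probs' must be 2 probabilities summing to 1")
  names(shed_direction_probs) <- c("antero", "retro")
  structure(list(
    n_tracks = as.integer(n_tracks), n_frames = as.integer(n_frames),
    frame_interval_s = frame_interval_s, pixel_size_um = pixel_size_um,
    field_length_um = field_length_um, class_probs = class_probs,
    p_antero_start = p_antero_start, antero_velocity = antero_velocity,
    retro_velocity = retro_velocity, v_min = v_min,
    mean_run_s = mean_run_s, mean_pause_s = mean_pause_s,
    p_reversal = p_reversal, noise_sd_um = noise_sd_um,
    tracks_per_kymograph = as.integer(tracks_per_kymograph),
    n_clusters = as.integer(n_clusters),
    shed_rate_per_100s = shed_rate_per_100s,
    shed_direction_probs = shed_direction_probs,
    seed = as.integer(seed)), class = "dcv_sim_config")
}

#' Strain presets for the simulator
#'
#' Returns a complete [simulation_config()] whose per-direction run-velocity
#' distributions carry the published mean +/- s.d. motility statistics of
#' the named strain:
#'
#' * `wild_type`: anterograde 1.4 +/- 0.68, retrograde 2.14 +/- 0.77 um/s;
#'   observed-class fractions 66.6% stationary, 21.5% moving without pause,
#'   11.9% moving with pauses; `p_antero_start` set so the planted
#'   anterograde participation is 12.2% of tracks (retrograde 22.7%).
#' * `unc116_rf`: anterograde 0.67 +/- 0.26, retrograde 0.63 +/- 0.24 um/s;
#'   an increased stationary fraction (0.78/0.13/0.09 - the source data
#'   reports the increase only qualitatively, so these are documented
#'   assumptions).
#' * `klc1_null`: anterograde as wild type, retrograde 2.38 +/- 1.03 um/s.
#' * `klc2_km11`: anterograde 1.2 +/- 0.48, retrograde 1.66 +/- 0.67 um/s.
#'
#' `antero_components = 3` for `wild_type` swaps the single anterograde
#' Gaussian for a three-peak mixture (a synthetic surrogate for the
#' multi-modal anterograde velocity distribution) with a matching overall
#' mean.
#'
#' @param name one of `"wild_type"`, `"unc116_rf"`, `"klc1_null"`,
#'   `"klc2_km11"`.
#' @param n_tracks,seed passed to [simulation_config()].
#' @param antero_components 1 (default) or 3 (wild type only).
#' @param ... further overrides passed to [simulation_config()].
#' @return A `"dcv_sim_config"` object.
#' @export
sim_preset <- function(name, n_tracks = 2000L, seed = 1L,
                       antero_components = 1L, ...) {
  presets <- c("wild_type", "unc116_rf", "klc1_null", "klc2_km11")
  if (!is.character(name) || length(name) != 1L || !(name %in% presets))
    stop_config("unknown preset '%s'; available: %s",
                as.character(name)[1], paste(presets, collapse = ", "))
  wt_classes <- c(stationary = 0.666, no_pause = 0.215, with_pause = 0.119)
  # participation: P(>=1 anterograde segment) ~= P(moving) * p_antero_start
  p_a <- 0.122 / (1 - wt_classes[["stationary"]])
  antero <- switch(name,
    wild_type = if (antero_components == 3L)
      velocity_mixture(c(0.3, 0.5, 0.2), c(0.6, 1.4, 2.4),
                       c(0.25, 0.30, 0.35))
    else velocity_mixture(1, 1.4, 0.68),
    unc116_rf = velocity_mixture(1, 0.67, 0.26),
    klc1_null = velocity_mixture(1, 1.4, 0.68),
    klc2_km11 = velocity_mixture(1, 1.2, 0.48))
  retro <- switch(name,
    wild_type = velocity_mixture(1, 2.14, 0.77),
    unc116_rf = velocity_mixture(1, 0.63, 0.24),
    klc1_null = velocity_mixture(1, 2.38, 1.03),
    klc2_km11 = velocity_mixture(1, 1.66, 0.67))
  classes <- if (name == "unc116_rf")
    c(stationary = 0.78, no_pause = 0.13, with_pause = 0.09) else wt_classes
  simulation_config(n_tracks = n_tracks, seed = seed,
                    class_probs = classes, p_antero_start = p_a,
                    antero_velocity = antero, retro_velocity = retro, ...)
}

# Piecewise-linear trajectory for one mover, as a schedule of phases.
# Returns list(phases = data.frame(state, t0, t1, v), exits) where x(t) is
# integrated from x0; generation stops once the movie ends or the true
# position leaves the field.
mover_schedule <- function(config, x0, t_birth, duration, with_pause,
                           dir_antero) {
  t <- 0
  x <- x0
  phases <- list()
  dir <- if (dir_antero) 1 else -1
  first <- TRUE
  while (t < duration && x >= 0 && x <= config$field_length_um) {
    if (!first && stats::runif(1L) < config$p_reversal) dir <- -dir
    first <- FALSE
    mix <- if (dir > 0) config$antero_velocity else config$retro_velocity
    v <- dir * draw_speed(mix, config$v_min)
    len <- stats::rexp(1L, 1 / config$mean_run_s)
    # clip the run when the particle exits the field
    x_next <- x + v * len
    if (x_next < 0) len <- (0 - x) / v
    if (x_next > config$field_length_um)
      len <- (config$field_length_um - x) / v
    phases[[length(phases) + 1L]] <- c(state = if (dir > 0) 1 else 2,
                                       t0 = t, t1 = t + len, v = v)
    t <- t + len
    x <- x + v * len
    if (x <= 0 || x >= config$field_length_um) break
    if (with_pause && t < duration) {
      plen <- stats::rexp(1L, 1 / config$mean_pause_s)
      phases[[length(phases) + 1L]] <- c(state = 3, t0 = t, t1 = t + plen,
                                         v = 0)
      t <- t + plen
    }
  }
  m <- do.call(rbind, phases)
  data.frame(state = c("A", "R", "P")[m[, "state"]], t0 = m[, "t0"],
             t1 = m[, "t1"], v = m[, "v"], stringsAsFactors = FALSE)
}

# Evaluate a schedule at relative times tt (>= 0): position and state.
eval_schedule <- function(phases, x0, tt) {
  starts <- phases$t0
  idx <- findInterval(tt, starts)
  idx[idx < 1L] <- 1L
  # cumulative displacement at phase starts
  disp <- cumsum(c(0, phases$v * (phases$t1 - phases$t0)))
  within <- pmin(tt - phases$t0[idx], phases$t1[idx] - phases$t0[idx])
  within <- pmax(within, 0)
  x <- x0 + disp[idx] + phases$v[idx] * within
  state <- phases$state[idx]
  state[tt > phases$t1[length(phases$t1)]] <- NA_character_
  list(x = x, state = state)
}

# does the observed state sequence manifest the assigned phenotype?
manifests <- function(states, x, class, config) {
  run_frames <- states %in% c("A", "R")
  if (class == "no_pause")
    return(sum(run_frames) >= 2L && !any(states == "P"))
  if (class == "with_pause") {
    # need a pause at least one window long, flanked by observed run frames
    r <- rle(states)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    min_pause_frames <- ceiling(2.0 / config$frame_interval_s) + 1L
    for (k in seq_along(r$values)) {
      if (r$values[k] == "P" && r$lengths[k] >= min_pause_frames &&
          any(run_frames[seq_len(max(starts[k] - 1L, 0L))]) &&
          (ends[k] < length(states) && any(run_frames[(ends[k] + 1L):length(states)])))
        return(TRUE)
    }
    return(FALSE)
  }
  TRUE
}

#' Simulate synthetic kymograph tracks
#'
#' Generates a raw track collection in pixel/frame units together with the
#' full ground truth (per-track phenotype, per-frame state, per-run
#' velocities, clusters and shed events). Deterministic given
#' `config$seed`: the same configuration yields bit-identical output.
#'
#' @param config a [simulation_config()] or [sim_preset()] object.
#' @return A list of class `"dcv_simulation"` with elements
#'   * `tracks`: raw track data.frame (`kymograph_id`, `track_id`,
#'     `t_frame`, `x_pixel`) readable by the ingest step;
#'   * `truth`: list with `tracks` (per-track: ids, class, `is_shed`,
#'     frames, per-frame `states`, per-run table) and `clusters`
#'     (`cluster_id`, `kymograph_id`, `x_center_um`, shed counts);
#'   * `config`: the configuration used.
#' @export
simulate_tracks <- function(config) {
  if (!inherits(config, "dcv_sim_config"))
    stop_config("'config' must be a simulation_config() object")
  with_seed(config$seed, simulate_tracks_impl(config))
}

simulate_tracks_impl <- function(config) {
  n <- config$n_tracks
  movie_s <- (config$n_frames - 1L) * config$frame_interval_s
  frame_t <- (seq_len(config$n_frames) - 1L) * config$frame_interval_s

  truth_tracks <- list()
  rows <- list()
  class_names <- c("stationary", "no_pause", "with_pause")
  classes <- if (n > 0L)
    class_names[sample.int(3L, n, replace = TRUE,
                           prob = config$class_probs)] else character(0)
  n_clusters <- min(config$n_clusters, sum(classes == "stationary"))
  cluster_track_idx <- which(classes == "stationary")[seq_len(n_clusters)]

  make_track <- function(i, class, is_shed, t_birth, x_birth) {
    # returns list(df rows in um & frames, truth entry) or NULL if empty
    if (class == "stationary") {
      x0 <- if (is.na(x_birth)) stats::runif(1L, 0, config$field_length_um) else x_birth
      frames <- seq_len(config$n_frames) - 1L
      x_true <- rep(x0, config$n_frames)
      states <- rep("P", config$n_frames)
      runs <- data.frame(state = character(), t0 = numeric(),
                         t1 = numeric(), v = numeric(),
                         stringsAsFactors = FALSE)
      return(list(frames = frames, x_true = x_true, states = states,
                  runs = runs, class = class, x0 = x0))
    }
    for (attempt in 1:100) {
      x0 <- if (is.na(x_birth)) stats::runif(1L, 0, config$field_length_um) else x_birth
      dir_a <- stats::runif(1L) < config$p_antero_start
      sched <- mover_schedule(config, x0, t_birth, movie_s - t_birth,
                              with_pause = class == "with_pause",
                              dir_antero = dir_a)
      rel <- frame_t - t_birth
      keep <- rel >= 0 & rel <= max(sched$t1)
      if (!any(keep)) next
      ev <- eval_schedule(sched, x0, rel[keep])
      inside <- !is.na(ev$state) & ev$x >= 0 & ev$x <= config$field_length_um
      # truncate at first exit
      if (!all(inside)) {
        first_out <- which(!inside)[1L]
        if (first_out == 1L) next
        inside[first_out:length(inside)] <- FALSE
      }
      if (sum(inside) < 2L) next
      frames <- (which(keep)[inside]) - 1L
      x_true <- ev$x[inside]
      states <- ev$state[inside]
      if (!is_shed && !manifests(states, x_true, class, config)) next
      if (is_shed && sum(states %in% c("A", "R")) < 2L) next
      return(list(frames = frames, x_true = x_true, states = states,
                  runs = sched, class = class, x0 = x0))
    }
    NULL
  }

  emit <- function(tk, kid, tid, is_shed, source_cluster = NA_character_) {
    noise <- stats::rnorm(length(tk$x_true), 0, config$noise_sd_um)
    x_obs <- pmax(tk$x_true + noise, 0)
    rows[[length(rows) + 1L]] <<- data.frame(
      kymograph_id = kid, track_id = tid, t_frame = tk$frames,
      x_pixel = x_obs / config$pixel_size_um, stringsAsFactors = FALSE)
    truth_tracks[[length(truth_tracks) + 1L]] <<- list(
      kymograph_id = kid, track_id = tid, class = tk$class,
      is_shed = is_shed, source_cluster = source_cluster,
      x0_um = tk$x0, frames = tk$frames, states = tk$states,
      runs = tk$runs[tk$runs$state != "P", , drop = FALSE])
  }

  kymo_of <- function(i) sprintf("K%03d", (i - 1L) %/%
                                   config$tracks_per_kymograph + 1L)
  clusters <- list()
  shed_counter <- 0L
  for (i in seq_len(n)) {
    tk <- make_track(i, classes[i], FALSE, 0, NA_real_)
    if (is.null(tk)) next
    kid <- kymo_of(i)
    tid <- sprintf("T%05d", i)
    emit(tk, kid, tid, FALSE)
    if (i %in% cluster_track_idx) {
      cid <- sprintf("SC%03d", length(clusters) + 1L)
      n_shed <- stats::rpois(1L, config$shed_rate_per_100s * movie_s / 100)
      shed_times <- sort(stats::runif(n_shed, 0, movie_s * 0.8))
      shed_ids <- character(0)
      for (ts in shed_times) {
        dir_a <- stats::runif(1L) < config$shed_direction_probs[["antero"]]
        shed_counter <- shed_counter + 1L
        stid <- sprintf("TS%04d", shed_counter)
        # shed movers inherit the no-pause phenotype, with forced direction
        stk <- NULL
        for (a in 1:20) {
          sched <- mover_schedule(config, tk$x0, ts, movie_s - ts,
                                  with_pause = FALSE, dir_antero = dir_a)
          rel <- frame_t - ts
          keep <- rel >= 0 & rel <= max(sched$t1)
          if (!any(keep)) next
          ev <- eval_schedule(sched, tk$x0, rel[keep])
          inside <- !is.na(ev$state) & ev$x >= 0 &
            ev$x <= config$field_length_um
          if (!all(inside)) {
            fo <- which(!inside)[1L]
            if (fo == 1L) next
            inside[fo:length(inside)] <- FALSE
          }
          if (sum(inside) < 2L) next
          stk <- list(frames = (which(keep)[inside]) - 1L,
                      x_true = ev$x[inside], states = ev$state[inside],
                      runs = sched, class = "no_pause", x0 = tk$x0)
          break
        }
        if (!is.null(stk)) {
          emit(stk, kid, stid, TRUE, source_cluster = cid)
          shed_ids <- c(shed_ids, stid)
        }
      }
      clusters[[length(clusters) + 1L]] <- list(
        cluster_id = cid, kymograph_id = kid, source_track_id = tid,
        x_center_um = tk$x0, shed_track_ids = shed_ids)
    }
  }

  tracks <- if (length(rows)) sort_raw_tracks(do.call(rbind, rows)) else
    empty_raw_tracks()
  structure(list(tracks = tracks,
                 truth = list(tracks = truth_tracks, clusters = clusters),
                 config = config),
            class = "dcv_simulation")
}

#' @export
print.dcv_simulation <- function(x, ...) {
  cat(sprintf("synthetic simulation: %d tracks (%d points), %d clusters, seed %d\n",
              length(x$truth$tracks), nrow(x$tracks),
              length(x$truth$clusters), x$config$seed))
  invisible(x)
}

#' Write simulated tracks and ground truth to disk
#'
#' Emits the raw tracks in both ingest dialects (`tracks_long.csv`,
#' `tracks_kymobutler.json`) plus the ground truth as `truth.json`; both
#' track files read back identically via [read_tracks()].
#'
#' @param sim a `"dcv_simulation"` object from [simulate_tracks()].
#' @param out_dir output directory (created if needed).
#' @return Named character vector of the three file paths, invisibly.
#' @export
emit_input_files <- function(sim, out_dir) {
  stopifnot(inherits(sim, "dcv_simulation"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  csv_path <- file.path(out_dir, "tracks_long.csv")
  write_table(sim$tracks, csv_path)

  json_path <- file.path(out_dir, "tracks_kymobutler.json")
  by_kymo <- split(sim$tracks, sim$tracks$kymograph_id)
  obj <- lapply(by_kymo, function(k) {
    lapply(split(k, k$track_id), function(tr)
      lapply(seq_len(nrow(tr)), function(i)
        c(tr$t_frame[i], tr$x_pixel[i])))
  })
  jsonlite::write_json(obj, json_path, auto_unbox = TRUE, digits = NA)

  truth_path <- file.path(out_dir, "truth.json")
  jsonlite::write_json(sim$truth, truth_path, auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(c(tracks_csv = csv_path, tracks_json = json_path,
              truth_json = truth_path))
}

#' Ground-truth run-velocity summary
#'
#' Mean planted run speed per direction over all simulated runs, the
#' reference against which pipeline-recovered velocities are compared.
#'
#' @param sim a `"dcv_simulation"` object.
#' @return A data.frame with `direction`, `n_runs`, `mean_speed`,
#'   `sd_speed` (um/s).
#' @export
truth_velocity_summary <- function(sim) {
  runs <- do.call(rbind, lapply(sim$truth$tracks, function(t) t$runs))
  do.call(rbind, lapply(c(A = "A", R = "R"), function(lab) {
    v <- abs(runs$v[runs$state == lab])
    data.frame(direction = if (lab == "A") "anterograde" else "retrograde",
               n_runs = length(v),
               mean_speed = if (length(v)) mean(v) else NA_real_,
               sd_speed = if (length(v) > 1) stats::sd(v) else NA_real_,
               stringsAsFactors = FALSE)
  }))
}
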