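# One-command orchestration: simulate or ingest, segment, summarize, fit
# mixtures, compare conditions, score cluster interactions, and write a
# report bundle (CSVs + summary JSON). Deterministic given the config.

#' Build a pipeline run configuration
#'
#' A run configuration describes either simulated conditions (strain
#' presets) or on-disk track files per condition, plus all analysis
#' parameters. It can also be loaded from a YAML file whose keys mirror the
#' arguments below.
#'
#' @param conditions named list describing each condition. Each element is
#'   either `list(preset = "<name>", n_tracks = ...)` for simulated input or
#'   `list(tracks = "<path>", dialect = "long_csv", axon_distance_um = ...)`
#'   for file input.
#' @param calibration a [calibration()] object or list of its arguments.
#' @param segmentation a [segmentation_params()] object or list of its
#'   arguments.
#' @param gmm list of Gaussian-mixture options: `K_max`, `restarts`,
#'   `min_n` (smallest sample to attempt a fit).
#' @param ks list of comparison options: `adjust`, `exact`.
#' @param clusters list of cluster options: `enabled`, `min_duration_s`,
#'   `tol_um`.
#' @param displacement_windows frame windows for displacement
#'   distributions.
#' @param seed master seed; condition-level simulation seeds are derived
#'   from it.
#' @return A list of class `"dcv_run_config"`.
#' @export
run_config <- function(conditions,
                       calibration = dcvmotility::calibration(),
                       segmentation = segmentation_params(),
                       gmm = list(K_max = 6L, restarts = 10L, min_n = 50L),
                       ks = list(adjust = "holm", exact = FALSE),
                       clusters = list(enabled = TRUE, min_duration_s = 30,
                                       tol_um = 0.3222),
                       displacement_windows = c(5L, 10L, 20L, 40L),
                       seed = 1L) {
  if (!is.list(conditions) || is.null(names(conditions)) ||
      !length(conditions))
    stop_config("'conditions' must be a non-empty named list")
  if (is.list(calibration) && !inherits(calibration, "dcv_calibration"))
    calibration <- do.call(dcvmotility::calibration, calibration)
  if (is.list(segmentation) && !inherits(segmentation, "dcv_seg_params"))
    segmentation <- do.call(segmentation_params, segmentation)
  defaults <- list(K_max = 6L, restarts = 10L, min_n = 50L)
  gmm <- utils::modifyList(defaults, gmm)
  ks <- utils::modifyList(list(adjust = "holm", exact = FALSE), ks)
  clusters <- utils::modifyList(list(enabled = TRUE, min_duration_s = 30,
                                     tol_um = 0.3222), clusters)
  structure(list(conditions = conditions, calibration = calibration,
                 segmentation = segmentation, gmm = gmm, ks = ks,
                 clusters = clusters,
                 displacement_windows = as.integer(displacement_windows),
                 seed = as.integer(seed)),
            class = "dcv_run_config")
}

#' Load a pipeline configuration from YAML
#'
#' @param path YAML file whose top-level keys mirror the [run_config()]
#'   arguments.
#' @return A `"dcv_run_config"` object.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_config("config file does not exist: %s", path)
  y <- yaml::read_yaml(path)
  args <- list(conditions = y$conditions)
  if (!is.null(y$calibration)) args$calibration <- y$calibration
  if (!is.null(y$segmentation)) args$segmentation <- y$segmentation
  for (k in c("gmm", "ks", "clusters", "displacement_windows", "seed"))
    if (!is.null(y[[k]])) args[[k]] <- y[[k]]
  do.call(run_config, args)
}

pipeline_condition_tracks <- function(name, spec, config) {
  if (!is.null(spec$preset)) {
    seed <- if (!is.null(spec$seed)) spec$seed else
      config$seed + match(name, names(config$conditions))
    sim_args <- spec[setdiff(names(spec), c("preset", "seed"))]
    cfg <- do.call(sim_preset, c(list(name = spec$preset, seed = seed),
                                 sim_args))
    sim <- simulate_tracks(cfg)
    raw <- sim$tracks
  } else if (!is.null(spec$tracks)) {
    dialect <- if (!is.null(spec$dialect)) spec$dialect else "long_csv"
    raw <- read_tracks(spec$tracks, dialect)
    sim <- NULL
  } else {
    stop_config("condition '%s' needs either 'preset' or 'tracks'", name)
  }
  raw <- deduplicate_timepoints(raw)
  dist <- if (!is.null(spec$axon_distance_um)) {
    d <- spec$axon_distance_um
    if (is.list(d)) unlist(d) else d
  } else NA_real_
  list(tracks = calibrate_tracks(raw, config$calibration, name, dist),
       sim = sim)
}

#' Run the full analysis pipeline
#'
#' Executes simulate/ingest -> segment -> motility statistics -> Gaussian
#' mixtures -> pairwise KS comparison -> cluster interactions, writing
#' every artifact (tracks, segments, velocity summaries, track classes,
#' displacement distributions, GMM table, KS table, cluster tables) as CSV
#' plus a machine-readable `summary.json` into `out_dir`. Rerunning with
#' the same configuration reproduces the outputs byte for byte.
#'
#' @param config a `"dcv_run_config"` object ([run_config()]) or the path
#'   to a YAML file for [read_run_config()].
#' @param out_dir output directory (created if needed).
#' @param quiet suppress per-stage log messages.
#' @return The summary list, invisibly. Components: `seed`, `config_hash`,
#'   `conditions` (track/segment counts), `velocity_summaries`,
#'   `class_fractions`, `gmm_selection`, `ks`, `cluster_summary`.
#' @export
run_pipeline <- function(config, out_dir, quiet = FALSE) {
  if (is.character(config)) config <- read_run_config(config)
  if (!inherits(config, "dcv_run_config"))
    stop_config("'config' must be a run_config() object or a YAML path")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_line <- function(...) if (!quiet) message(sprintf(...))
  config_hash <- fnv1a_hash(paste(utils::capture.output(utils::str(config)),
                                  collapse = "\n"))

  all_tracks <- list()
  counts <- list()
  for (name in names(config$conditions)) {
    stage <- sprintf("ingest[%s]", name)
    res <- tryCatch(
      pipeline_condition_tracks(name, config$conditions[[name]], config),
      error = function(e) stop_config("stage %s failed: %s", stage,
                                      conditionMessage(e)))
    all_tracks[[name]] <- res$tracks
    n_tr <- length(unique(track_key(res$tracks)))
    log_line("%s: %d tracks, %d points", stage, n_tr, nrow(res$tracks))
    counts[[name]] <- list(n_tracks = n_tr, n_points = nrow(res$tracks))
  }
  tracks <- do.call(rbind, all_tracks)
  rownames(tracks) <- NULL
  write_tracks(tracks, file.path(out_dir, "tracks.csv"))

  segments <- segment_tracks(tracks, config$segmentation)
  eligible <- filter_for_velocity(segments, config$segmentation, quiet = TRUE)
  n_moving <- sum(segments$label != "S")
  log_line("segment: %d segments (%d moving; %d velocity-eligible, %.2f%% dropped)",
           nrow(segments), n_moving, nrow(eligible),
           if (n_moving) 100 * (n_moving - nrow(eligible)) / n_moving else 0)
  write_segments(segments, file.path(out_dir, "segments.csv"))

  summaries <- summarize_velocities(eligible)
  classes <- classify_tracks(segments)
  fractions <- class_fractions(classes)
  write_table(summaries, file.path(out_dir, "velocity_summaries.csv"))
  write_table(classes, file.path(out_dir, "track_classes.csv"))
  write_table(fractions, file.path(out_dir, "class_fractions.csv"))
  log_line("stats: %d summary rows, %d classified tracks",
           nrow(summaries), nrow(classes))

  disp <- do.call(rbind, lapply(config$displacement_windows, function(N)
    displacement_distribution(tracks, N, config$calibration)))
  write_table(disp, file.path(out_dir, "displacement_distributions.csv"))

  aligned <- align_tracks_to_origin(tracks)
  write_tracks(aligned, file.path(out_dir, "tracks_aligned.csv"))

  # Gaussian mixtures per condition x direction
  gmm_fits <- list()
  gmm_best <- list()
  for (cond in names(config$conditions)) {
    for (lab in c("A", "R")) {
      v <- eligible$velocity_um_per_s[eligible$condition == cond &
                                        eligible$label == lab]
      speeds <- abs(v)
      nm <- paste(cond, if (lab == "A") "anterograde" else "retrograde",
                  sep = "|")
      if (length(speeds) < config$gmm$min_n) {
        log_line("gmm[%s]: skipped (n = %d < %d)", nm, length(speeds),
                 config$gmm$min_n)
        next
      }
      sel <- select_gmm(speeds, K_max = config$gmm$K_max,
                        seed = config$seed,
                        restarts = config$gmm$restarts)
      gmm_fits[[nm]] <- sel$best
      gmm_best[[nm]] <- sel$best$K
      log_line("gmm[%s]: selected K = %d (n = %d)", nm, sel$best$K,
               length(speeds))
    }
  }
  if (length(gmm_fits))
    write_table(gmm_table(gmm_fits), file.path(out_dir, "gmm_components.csv"))

  # pairwise KS per direction
  ks_rows <- list()
  if (length(names(config$conditions)) >= 2L) {
    for (lab in c("A", "R")) {
      samples <- lapply(names(config$conditions), function(cond)
        abs(eligible$velocity_um_per_s[eligible$condition == cond &
                                         eligible$label == lab]))
      names(samples) <- names(config$conditions)
      samples <- samples[vapply(samples, length, integer(1)) > 0L]
      if (length(samples) >= 2L)
        ks_rows[[lab]] <- pairwise_compare(
          samples,
          direction = if (lab == "A") "anterograde" else "retrograde",
          adjust = config$ks$adjust, exact = config$ks$exact)
    }
  }
  ks_table <- if (length(ks_rows)) do.call(rbind, ks_rows) else NULL
  if (!is.null(ks_table)) {
    rownames(ks_table) <- NULL
    write_table(ks_table, file.path(out_dir, "ks_comparisons.csv"))
    log_line("compare: %d KS pairs", nrow(ks_table))
  }

  # cluster interactions, per condition (kymograph ids repeat across
  # conditions)
  cluster_summaries <- list()
  if (isTRUE(config$clusters$enabled)) {
    for (cond in names(config$conditions)) {
      tr <- tracks[tracks$condition == cond, , drop = FALSE]
      sg <- segments[segments$condition == cond, , drop = FALSE]
      cl <- detect_clusters(tr, sg,
                            min_duration_s = config$clusters$min_duration_s,
                            merge_tol_um = config$clusters$tol_um)
      sc <- score_interactions(tr, sg, cl, tol_um = config$clusters$tol_um)
      sc$summary <- cbind(condition = cond, sc$summary,
                          stringsAsFactors = FALSE)
      cluster_summaries[[cond]] <- sc$summary
      write_table(cl, file.path(out_dir, sprintf("clusters_%s.csv", cond)))
      write_table(sc$events,
                  file.path(out_dir, sprintf("cluster_events_%s.csv", cond)))
      log_line("clusters[%s]: %d clusters, %d events", cond, nrow(cl),
               nrow(sc$events))
    }
  }
  cluster_summary <- if (length(cluster_summaries))
    do.call(rbind, cluster_summaries) else NULL
  if (!is.null(cluster_summary)) {
    rownames(cluster_summary) <- NULL
    write_table(cluster_summary, file.path(out_dir, "cluster_summary.csv"))
  }

  summary <- list(
    seed = config$seed,
    config_hash = config_hash,
    conditions = counts,
    velocity_summaries = summaries,
    class_fractions = fractions,
    gmm_selection = gmm_best,
    ks = ks_table,
    cluster_summary = cluster_summary)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       dataframe = "rows", pretty = TRUE)
  log_line("report written to %s", out_dir)
  invisible(summary)
}
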