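#' Default pipeline configuration
#'
#' Nested list with one block per pipeline stage. Unknown keys are
#' rejected by [validateRunConfig()]; every run writes its resolved
#' configuration next to its outputs.
#'
#' @return nested named list.
#' @export
defaultRunConfig <- function() {
  list(
    seed = 1L,
    verbose = FALSE,
    flow = list(pattern = "four_cell_bounded", strain_rate = 1,
                droplet_radius = 6e-3),
    body = list(length_m = 4e-3, radius_m = 2.5e-4, viscosity = 1e-3),
    synth = list(n_per_class = 5L, activity_high = 5, rot_noise = 0.05,
                 duration_s = 300, ramp_duration_s = 1200, dt = 0.02),
    tracking = list(threshold = 0.5, min_area = 4L, max_disp_px = 5,
                    grid_n = 48L),
    stats = list(window_deg = 30, thresholds = list())
  )
}

# recursive unknown-key check against the default template
.checkKeys <- function(cfg, template, prefix = "") {
  unknown <- setdiff(names(cfg), names(template))
  if (length(unknown))
    stop("unknown config key: ", prefix, unknown[1], call. = FALSE)
  for (k in names(cfg)) {
    if (is.list(template[[k]]) && !is.null(names(template[[k]]))) {
      if (!is.list(cfg[[k]]))
        stop("config key ", prefix, k, " must be a block", call. = FALSE)
      if (k != "thresholds")  # thresholds block has its own key set
        .checkKeys(cfg[[k]], template[[k]], paste0(prefix, k, "."))
    }
  }
  invisible(TRUE)
}

#' Validate and resolve a pipeline configuration
#'
#' Merges a partial configuration (a nested list, or the path of a YAML
#' file) over [defaultRunConfig()], rejecting unknown keys with an error
#' that names the offending key.
#'
#' @param config nested list or YAML file path; NULL for the defaults.
#' @return the resolved configuration list.
#' @export
validateRunConfig <- function(config = NULL) {
  template <- defaultRunConfig()
  if (is.null(config)) return(template)
  if (is.character(config)) config <- yaml::read_yaml(config)
  .checkKeys(config, template)
  th <- config$stats$thresholds
  if (!is.null(th)) {
    bad <- setdiff(names(th), names(.DEFAULT_THRESHOLDS))
    if (length(bad))
      stop("unknown config key: stats.thresholds.", bad[1], call. = FALSE)
  }
  utils::modifyList(template, config)
}

.writeResolvedConfig <- function(config, outDir) {
  yaml::write_yaml(config, file.path(outDir, "run-config.yaml"))
}

#' Simulate a cohort and write it to disk
#'
#' Runs [generateCohort()] with the configured class parameters and writes
#' one trajectory CSV (plus JSON metadata) per fish, together with the
#' resolved configuration.
#'
#' @param config nested list or YAML path, see [validateRunConfig()].
#' @param outDir output directory (created if missing).
#' @return invisibly, list with \code{files} (CSV paths) and
#'   \code{cohort} (the in-memory cohort).
#' @export
runCohortSimulation <- function(config = NULL, outDir) {
  cfg <- validateRunConfig(config)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  spec <- cohortSpec(nPerClass = cfg$synth$n_per_class,
                     strainRate = cfg$flow$strain_rate,
                     activityHigh = cfg$synth$activity_high,
                     rotNoise = cfg$synth$rot_noise,
                     duration = cfg$synth$duration_s,
                     rampDuration = cfg$synth$ramp_duration_s,
                     dt = cfg$synth$dt, baseSeed = cfg$seed)
  cohort <- generateCohort(spec)
  files <- character(length(cohort))
  for (i in seq_along(cohort)) {
    entry <- cohort[[i]]
    files[i] <- file.path(outDir, sprintf("fish-%02d-%s.csv", i, entry$type))
    writeTrajectory(entry$traj, files[i])
  }
  .writeResolvedConfig(cfg, outDir)
  if (isTRUE(cfg$verbose))
    message("wrote ", length(files), " trajectories to ", outDir,
            " (seed ", cfg$seed, ")")
  invisible(list(files = files, cohort = cohort))
}

#' Track a recorded scene and reconstruct its velocity field
#'
#' Reads a TIFF stack, detects and links bright blobs, reconstructs the
#' velocity grid from the tracks, classifies the recirculation pattern,
#' and writes tracks CSV, grid CSV and a JSON report.
#'
#' @param stackPath path to a multi-page TIFF written by
#'   [writeFrameStack()], or a [FrameStack-class].
#' @inheritParams runCohortSimulation
#' @return invisibly, list with \code{tracks}, \code{grid},
#'   \code{classification}.
#' @export
runSceneTracking <- function(stackPath, config = NULL, outDir) {
  cfg <- validateRunConfig(config)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  stack <- if (is(stackPath, "FrameStack")) stackPath else {
    if (!file.exists(stackPath))
      stop("cannot read image stack: ", stackPath, call. = FALSE)
    readFrameStack(stackPath)
  }
  det <- detectStack(stack, threshold = cfg$tracking$threshold,
                     minArea = cfg$tracking$min_area)
  if (is.null(det) || !nrow(det))
    stop("no detections in the stack", call. = FALSE)
  tracks <- linkTracks(det, stack, maxDispPx = cfg$tracking$max_disp_px)
  grid <- velocityGridFromTracks(tracks, nPerAxis = cfg$tracking$grid_n)
  cls <- classifyPattern(grid)
  utils::write.csv(tracks, file.path(outDir, "tracks.csv"),
                   row.names = FALSE)
  writeVelocityGrid(grid, file.path(outDir, "velocity-grid.csv"))
  jsonlite::write_json(list(n_tracks = length(unique(tracks$track_id)),
                            n_detections = nrow(det),
                            pattern_label = cls$label,
                            n_cells = cls$nCells),
                       file.path(outDir, "tracking-report.json"),
                       auto_unbox = TRUE, digits = NA)
  .writeResolvedConfig(cfg, outDir)
  invisible(list(tracks = tracks, grid = grid, classification = cls))
}

#' Analyse trajectories into mobility reports
#'
#' Computes per-fish circular summaries, deviations and mobility classes,
#' the cohort table and the cohort alignment probability; writes a JSON
#' report and a cohort CSV.
#'
#' @param trajectories character vector of trajectory CSV paths, a
#'   directory containing them, or a list of
#'   [OrientationTrajectory-class] objects.
#' @inheritParams runCohortSimulation
#' @return invisibly, list with \code{reports} (list of
#'   [MobilityReport-class]), \code{table} and \code{alignmentP}.
#' @export
runMobilityAnalysis <- function(trajectories, config = NULL, outDir) {
  cfg <- validateRunConfig(config)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  trajs <- if (is.character(trajectories)) {
    paths <- if (length(trajectories) == 1L && dir.exists(trajectories))
      list.files(trajectories, pattern = "\\.csv$", full.names = TRUE)
    else trajectories
    if (!length(paths)) stop("no trajectory files found", call. = FALSE)
    lapply(paths, readTrajectory)
  } else trajectories
  if (!length(trajs)) stop("need at least one trajectory", call. = FALSE)
  reports <- lapply(seq_along(trajs), function(i) {
    tr <- trajs[[i]]
    meta <- list(fish_id = if (!is.null(tr@meta$fish_id)) tr@meta$fish_id
                           else i,
                 type = tr@meta$type, pattern = cfg$flow$pattern)
    mobilityReport(tr, thresholds = cfg$stats$thresholds, meta = meta)
  })
  ct <- cohortTable(reports, windowDeg = cfg$stats$window_deg)
  utils::write.csv(ct$table, file.path(outDir, "cohort-table.csv"),
                   row.names = FALSE)
  perFish <- lapply(reports, function(r)
    list(fish_id = r@meta$fish_id, type = r@meta$type,
         circ_mean_deg = r@circMeanDeg,
         resultant_length = r@resultantLength,
         source_deviation_deg = r@sourceDeviationDeg,
         sink_deviation_deg = r@sinkDeviationDeg,
         class = r@classLabel))
  jsonlite::write_json(list(fish = perFish,
                            alignment_p = ct$alignmentP,
                            window_deg = cfg$stats$window_deg),
                       file.path(outDir, "mobility-report.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  .writeResolvedConfig(cfg, outDir)
  invisible(list(reports = reports, table = ct$table,
                 alignmentP = ct$alignmentP))
}
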