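#' Configuration for an end-to-end analysis run
#'
#' Bundles the table layout, the analysis thresholds and the output
#' options of one run, mirroring the parameter dialog of the original
#' spreadsheet tool item for item.
#'
#' @param input path to the track table (CSV/TSV/XLSX).
#' @param output_stem path stem for outputs
#'   (`<stem>_particles.csv`, `<stem>_segments.csv`, `<stem>_msd.csv`,
#'   `<stem>_report.json`, optionally `<stem>_tracks.pdf`).
#' @param frame_column,x_column,y_column,z_column column identifiers
#'   (letters or header names), see [track_table_spec()].
#' @param frames_per_particle,n_particles stacked layout dimensions.
#' @param pixel_ratio length units per pixel (1 = already physical units).
#' @param length_unit,time_unit unit labels.
#' @param time_per_frame TF in `time_unit`.
#' @param distance_threshold DT in `length_unit`.
#' @param speed_threshold ST in `length_unit`/`time_unit`.
#' @param analyze_3d analyze X, Y and Z; requires `z_column`.
#' @param compute_persistence compute the D/T persistence ratio.
#' @param emit_per_track_plots write a PDF with each raw track and the
#'   segment anchor points the scan isolated.
#' @param max_lag,n_lags_used MSD/diffusion settings, see [msd_curve()]
#'   and [diffusion_coefficient()].
#' @param sheet worksheet for spreadsheet input.
#' @return a `"run_config"` list.
#' @export
run_config <- function(input, output_stem,
                       frame_column = "A", x_column = "B", y_column = "C",
                       z_column = NULL, frames_per_particle, n_particles,
                       pixel_ratio = 1, length_unit = "um",
                       time_unit = "min", time_per_frame,
                       distance_threshold, speed_threshold,
                       analyze_3d = FALSE, compute_persistence = TRUE,
                       emit_per_track_plots = FALSE,
                       max_lag = NULL, n_lags_used = NULL, sheet = NULL) {
  if (analyze_3d && is.null(z_column))
    stop("`analyze_3d = TRUE` requires `z_column`", call. = FALSE)
  spec <- track_table_spec(
    frame_column = frame_column, x_column = x_column, y_column = y_column,
    z_column = if (analyze_3d) z_column else NULL,
    frames_per_particle = frames_per_particle, n_particles = n_particles,
    pixel_ratio = pixel_ratio, length_unit = length_unit,
    time_unit = time_unit, time_per_frame = time_per_frame)
  params <- analysis_params(distance_threshold, speed_threshold,
                            time_per_frame, dim = if (analyze_3d) 3 else 2)
  structure(list(input = input, output_stem = output_stem,
                 table_spec = spec, params = params,
                 analyze_3d = analyze_3d,
                 compute_persistence = compute_persistence,
                 emit_per_track_plots = emit_per_track_plots,
                 max_lag = max_lag, n_lags_used = n_lags_used,
                 sheet = sheet),
            class = "run_config")
}

#' Analyze a list of trajectories in memory
#'
#' The core pipeline without file I/O: scan, motion summary, persistence,
#' MSD and diffusion coefficient per particle, then cohort aggregation.
#'
#' @param trajs list of [trajectory()] objects.
#' @param params an [analysis_params()].
#' @param max_lag,n_lags_used see [msd_curve()], [diffusion_coefficient()].
#' @param compute_persistence compute the D/T ratio per particle.
#' @return list with `reports` (per-particle `"particle_report"`s) and
#'   `cohort` (a [cohort_summary()]).
#' @export
analyze_trajectories <- function(trajs, params, max_lag = NULL,
                                 n_lags_used = NULL,
                                 compute_persistence = TRUE) {
  stopifnot(length(trajs) > 0)
  reports <- lapply(trajs, analyze_trajectory, params = params,
                    max_lag = max_lag, n_lags_used = n_lags_used,
                    compute_persistence = compute_persistence)
  list(reports = reports, cohort = cohort_summary(reports))
}

#' Run a full analysis from a config: read, scan, measure, write
#'
#' Reads the track table, runs the threshold scan and all derived metrics
#' per particle, aggregates the cohort and writes the outputs:
#' `<stem>_particles.csv`, `<stem>_segments.csv`, `<stem>_msd.csv` and
#' `<stem>_report.json` (which echoes every parameter used, so a later run
#' can be configured from it), plus optional per-track plots showing the
#' raw path and the anchor positions the scan isolated. On failure the
#' partially written outputs are removed.
#'
#' @param config a [run_config()].
#' @param quiet suppress the progress message.
#' @return invisibly, a list with `reports`, `cohort` and `paths`.
#' @export
run_analysis <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  stem <- config$output_stem
  paths <- c(particles = paste0(stem, "_particles.csv"),
             segments = paste0(stem, "_segments.csv"),
             msd = paste0(stem, "_msd.csv"),
             report = paste0(stem, "_report.json"),
             plots = paste0(stem, "_tracks.pdf"))
  ok <- FALSE
  on.exit(if (!ok) suppressWarnings(file.remove(paths[file.exists(paths)])))

  trajs <- read_tracks(config$input, config$table_spec, sheet = config$sheet)
  res <- analyze_trajectories(trajs, config$params,
                              max_lag = config$max_lag,
                              n_lags_used = config$n_lags_used,
                              compute_persistence = config$compute_persistence)

  write_particle_reports(res$reports, res$cohort, stem)
  segs <- lapply(res$reports, function(r) r$segments)
  names(segs) <- vapply(res$reports,
                        function(r) as.character(r$particle_id),
                        character(1))
  write_segments(segs, paths[["segments"]])
  write_report_json(res, config, paths[["report"]])

  if (config$emit_per_track_plots) {
    plot_tracks(trajs, res$reports, paths[["plots"]])
  } else {
    paths <- paths[names(paths) != "plots"]
  }
  ok <- TRUE
  if (!quiet)
    message(sprintf("analyzed %d particle(s); outputs at %s_*",
                    length(trajs), stem))
  invisible(list(reports = res$reports, cohort = res$cohort, paths = paths))
}

# JSON report: parameter echo (re-usable as a config), per-particle
# statistics and the cohort block.
write_report_json <- function(res, config, path) {
  spec <- config$table_spec
  params <- config$params
  per <- lapply(res$reports, function(r) {
    list(particle_id = as.character(r$particle_id),
         mean_moving_speed = r$mean_moving_speed,
         percent_time_in_motion = r$percent_time_in_motion,
         n_pauses = r$n_pauses,
         pause_durations = I(r$pause_durations),
         total_time = r$total_time,
         persistence = r$persistence,
         diffusion_coefficient = r$diffusion_coefficient,
         n_segments = nrow(r$segments))
  })
  payload <- list(
    parameters = list(
      frame_column = spec$frame_column, x_column = spec$x_column,
      y_column = spec$y_column, z_column = spec$z_column,
      frames_per_particle = spec$frames_per_particle,
      n_particles = spec$n_particles, pixel_ratio = spec$pixel_ratio,
      length_unit = spec$length_unit, time_unit = spec$time_unit,
      time_per_frame = spec$time_per_frame,
      distance_threshold = params$distance_threshold,
      speed_threshold = params$speed_threshold,
      dim = params$dim,
      compute_persistence = config$compute_persistence),
    particles = per,
    cohort = list(n_particles = res$cohort$n_particles,
                  dispersion_kind = res$cohort$dispersion_kind,
                  stats = res$cohort$stats))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null", pretty = TRUE)
  invisible(path)
}

# one page per particle: raw path in gray, scan anchor points in red
plot_tracks <- function(trajs, reports, path) {
  grDevices::pdf(path, width = 6, height = 6)
  on.exit(grDevices::dev.off())
  for (k in seq_along(trajs)) {
    t <- trajs[[k]]
    segs <- reports[[k]]$segments
    graphics::plot(t$positions[, 1L], t$positions[, 2L], type = "l",
                   col = "gray40", asp = 1,
                   xlab = sprintf("x (%s)", t$length_unit),
                   ylab = sprintf("y (%s)", t$length_unit),
                   main = sprintf("%s (%d segments)",
                                  as.character(t$particle_id), nrow(segs)))
    anchors <- unique(c(segs$start_frame, segs$end_frame))
    graphics::points(t$positions[anchors, 1L], t$positions[anchors, 2L],
                     col = "red", pch = 16)
  }
  invisible(path)
}
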