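#' Construct a particle trajectory
#'
#' A trajectory is one particle's ordered positions, with frame numbers, a
#' fixed time step, and unit labels. Positions are stored as a numeric
#' matrix with one row per frame and 2 or 3 columns (X, Y and optionally Z),
#' already expressed in `length_unit`.
#'
#' @param positions numeric matrix (or coercible data frame) with `NF` rows
#'   and 2 or 3 columns of finite coordinates.
#' @param time_per_frame time between consecutive frames, in `time_unit`
#'   (the TF of the recording). Must be positive.
#' @param particle_id label for the particle (string or integer).
#' @param frames optional integer frame numbers; must be consecutive with
#'   step 1. Defaults to `1:NF`.
#' @param length_unit,time_unit free-text unit labels (defaults "um", "min").
#'
#' @return An object of class `"trajectory"`: a list with elements
#'   `particle_id`, `frames`, `positions`, `time_per_frame`, `length_unit`,
#'   `time_unit` and `dim`.
#'
#' @examples
#' pos <- cbind(x = 0:9, y = rep(0, 10))
#' traj <- trajectory(pos, time_per_frame = 20)
#' traj
#' @export
trajectory <- function(positions, time_per_frame, particle_id = "particle_1",
                       frames = NULL, length_unit = "um", time_unit = "min") {
  positions <- as.matrix(positions)
  storage.mode(positions) <- "double"
  if (!ncol(positions) %in% c(2L, 3L))
    stop("`positions` must have 2 or 3 coordinate columns, not ",
         ncol(positions), call. = FALSE)
  if (nrow(positions) < 1L)
    stop("`positions` must have at least one row", call. = FALSE)
  if (!all(is.finite(positions)))
    stop("all coordinates must be finite", call. = FALSE)
  if (!is.numeric(time_per_frame) || length(time_per_frame) != 1L ||
      !is.finite(time_per_frame) || time_per_frame <= 0)
    stop("`time_per_frame` must be a single positive number", call. = FALSE)

  nf <- nrow(positions)
  if (is.null(frames)) frames <- seq_len(nf)
  frames <- as.integer(frames)
  if (length(frames) != nf)
    stop("`frames` must have one entry per position row", call. = FALSE)
  if (nf > 1L && !all(diff(frames) == 1L))
    stop("frame numbers must be consecutive (step 1)", call. = FALSE)

  structure(
    list(particle_id = particle_id,
         frames = frames,
         positions = positions,
         time_per_frame = as.numeric(time_per_frame),
         length_unit = length_unit,
         time_unit = time_unit,
         dim = ncol(positions)),
    class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory '%s'> %d frames, %dD, TF = %g %s, unit = %s\n",
              as.character(x$particle_id), n_frames(x), x$dim,
              x$time_per_frame, x$time_unit, x$length_unit))
  invisible(x)
}

# number of frames NF of a trajectory
n_frames <- function(traj) nrow(traj$positions)

#' Total recording duration of a trajectory
#'
#' The elapsed time covered by a track: `(NF - 1) * TF`.
#'
#' @param traj a [trajectory()].
#' @return duration in the trajectory's time unit.
#' @export
total_time <- function(traj) {
  stopifnot(inherits(traj, "trajectory"))
  (n_frames(traj) - 1) * traj$time_per_frame
}

#' Analysis parameters for the distance/speed-threshold scan
#'
#' Bundles the two thresholds that drive segmentation, mirroring the two
#' choices a kymograph user makes by eye: the net displacement that counts
#' as a significant movement (DT), and the speed above which a completed
#' displacement is called motion rather than a drifting pause (ST).
#'
#' @param distance_threshold DT, in the trajectory's length unit; a
#'   displacement is significant only once it strictly exceeds this. A
#'   typical choice is the particle's own size. Must be positive.
#' @param speed_threshold ST, in length per time; a completed segment is
#'   classified moving only when its speed strictly exceeds this.
#'   Non-negative.
#' @param time_per_frame TF, time between frames; must match the
#'   trajectories being analyzed.
#' @param dim dimensionality of the coordinates, 2 or 3.
#'
#' @return An object of class `"analysis_params"`.
#' @export
analysis_params <- function(distance_threshold, speed_threshold,
                            time_per_frame, dim = 2) {
  if (!is.numeric(distance_threshold) || length(distance_threshold) != 1L ||
      !is.finite(distance_threshold) || distance_threshold <= 0)
    stop("`distance_threshold` must be a single positive number", call. = FALSE)
  if (!is.numeric(speed_threshold) || length(speed_threshold) != 1L ||
      !is.finite(speed_threshold) || speed_threshold < 0)
    stop("`speed_threshold` must be a single non-negative number", call. = FALSE)
  if (!is.numeric(time_per_frame) || length(time_per_frame) != 1L ||
      !is.finite(time_per_frame) || time_per_frame <= 0)
    stop("`time_per_frame` must be a single positive number", call. = FALSE)
  if (!dim %in% c(2, 3))
    stop("`dim` must be 2 or 3", call. = FALSE)
  structure(
    list(distance_threshold = as.numeric(distance_threshold),
         speed_threshold = as.numeric(speed_threshold),
         time_per_frame = as.numeric(time_per_frame),
         dim = as.integer(dim)),
    class = "analysis_params")
}

#' @export
print.analysis_params <- function(x, ...) {
  cat(sprintf("<analysis_params> DT = %g, ST = %g, TF = %g, dim = %d\n",
              x$distance_threshold, x$speed_threshold, x$time_per_frame, x$dim))
  invisible(x)
}
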