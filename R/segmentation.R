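#' Net displacement between two frames of a trajectory
#'
#' Euclidean distance between the position at frame index `n` and the
#' position `i` frames later, over all 2 or 3 coordinates. This is the
#' distance the threshold scan accumulates until it exceeds DT.
#'
#' @param traj a [trajectory()].
#' @param n starting frame index (1-based).
#' @param i number of frames to advance; `n + i` must not exceed NF.
#' @return distance in the trajectory's length unit.
#'
#' @examples
#' traj <- trajectory(rbind(c(0, 0), c(3, 4)), time_per_frame = 1)
#' displacement(traj, 1, 1)  # 5
#' @export
displacement <- function(traj, n, i) {
  stopifnot(inherits(traj, "trajectory"))
  nf <- n_frames(traj)
  if (n < 1L || i < 1L || n + i > nf)
    stop(sprintf("frame indices out of range: n = %d, i = %d, NF = %d",
                 n, i, nf), call. = FALSE)
  sqrt(sum((traj$positions[n + i, ] - traj$positions[n, ])^2))
}

#' Partition a trajectory into threshold-crossing segments
#'
#' Scans the track left to right. Starting from an anchor frame `n`
#' (initially the first frame), the net displacement from `n` to `n + i` is
#' computed for increasing `i` until it strictly exceeds the distance
#' threshold DT; that stretch becomes one segment, its speed is the net
#' displacement divided by the elapsed time, and the scan restarts from the
#' closing frame `n + i`. Each completed segment is classified moving or
#' paused by [classify_segment()]. If the end of the track is reached
#' without crossing DT, one final segment with `state = "residual"` covers
#' the remaining frames: a displacement never confirmed as significant is
#' not called motion.
#'
#' The returned segments tile the track exactly: each segment starts at the
#' previous one's end frame, and spans sum to `NF - 1` frame intervals.
#'
#' @param traj a [trajectory()] with at least 2 frames.
#' @param params an [analysis_params()]; `dim` and `time_per_frame` must
#'   agree with the trajectory.
#' @return data frame of class `"skypad_segments"` with one row per
#'   segment: `start_frame`, `end_frame`, `span_frames`, `net_displacement`,
#'   `elapsed_time`, `speed`, `state` (`"moving"`, `"paused"` or
#'   `"residual"`).
#'
#' @examples
#' # straight line at 1 unit/frame: DT = 9.5 is crossed every 10 frames
#' traj <- trajectory(cbind(0:49, 0), time_per_frame = 1)
#' skypad_scan(traj, analysis_params(9.5, 0.5, 1))
#' @export
skypad_scan <- function(traj, params) {
  stopifnot(inherits(traj, "trajectory"), inherits(params, "analysis_params"))
  nf <- n_frames(traj)
  if (nf < 2L)
    stop("trajectory must have at least 2 frames", call. = FALSE)
  if (params$dim != traj$dim)
    stop("params$dim (", params$dim, ") does not match trajectory dim (",
         traj$dim, ")", call. = FALSE)
  if (!isTRUE(all.equal(params$time_per_frame, traj$time_per_frame)))
    stop("params$time_per_frame does not match the trajectory", call. = FALSE)

  dt <- params$distance_threshold
  tf <- params$time_per_frame
  pos <- traj$positions

  starts <- integer(0); ends <- integer(0)
  disps <- numeric(0); states <- character(0)

  n <- 1L
  while (n < nf) {
    later <- (n + 1L):nf
    d <- sqrt(rowSums((pos[later, , drop = FALSE] -
                         matrix(pos[n, ], length(later), traj$dim,
                                byrow = TRUE))^2))
    hit <- which(d > dt)
    if (length(hit) == 0L) {
      # track ends before DT is crossed: residual tail
      starts <- c(starts, n); ends <- c(ends, nf)
      disps <- c(disps, d[length(d)]); states <- c(states, "residual")
      break
    }
    x <- hit[1L]
    starts <- c(starts, n); ends <- c(ends, n + x)
    disps <- c(disps, d[x]); states <- c(states, "pending")
    n <- n + x
  }

  span <- ends - starts
  segs <- data.frame(
    start_frame = traj$frames[starts],
    end_frame = traj$frames[ends],
    span_frames = span,
    net_displacement = disps,
    elapsed_time = span * tf,
    speed = disps / (span * tf),
    state = states,
    stringsAsFactors = FALSE)

  pending <- segs$state == "pending"
  if (any(pending)) segs[pending, ] <- classify_segment(segs[pending, ], params)
  class(segs) <- c("skypad_segments", "data.frame")
  segs
}

#' Classify completed segments as moving or paused
#'
#' A completed segment is moving when its speed strictly exceeds the speed
#' threshold ST, paused otherwise; a speed exactly at ST counts as paused
#' (ties go to the not-yet-crossed side, matching the strict DT comparison).
#' Residual segments are left untouched: they end before DT was crossed and
#' are never classified moving.
#'
#' @param seg one or more segment rows as returned by [skypad_scan()].
#' @param params an [analysis_params()].
#' @return `seg` with `state` set to `"moving"` or `"paused"`.
#' @export
classify_segment <- function(seg, params) {
  stopifnot(inherits(params, "analysis_params"))
  idx <- seg$state != "residual"
  seg$state[idx] <- ifelse(seg$speed[idx] > params$speed_threshold,
                           "moving", "paused")
  seg
}

#' Per-particle motion statistics from a segmented trajectory
#'
#' Derives the quantities a kymograph analysis reports, from the segments
#' of the threshold scan:
#' \describe{
#'   \item{mean_moving_speed}{unweighted mean of the speeds of moving
#'     segments (the average of kymograph line slopes); `NA` when the
#'     particle never moves, so immobile particles do not drag cohort
#'     averages toward zero.}
#'   \item{percent_time_in_motion}{100 x (time in moving segments) /
#'     (total track time).}
#'   \item{pauses}{a pause is one maximal run of consecutive non-moving
#'     segments (paused and residual alike) -- one flat stretch on a
#'     kymograph; its duration is the run's summed elapsed time.}
#' }
#'
#' @param traj the [trajectory()] the segments came from.
#' @param segments output of [skypad_scan()] on `traj`.
#' @param params the [analysis_params()] used for the scan.
#' @return An object of class `"particle_report"`: a list with
#'   `particle_id`, `mean_moving_speed`, `percent_time_in_motion`,
#'   `n_pauses`, `pause_durations`, `total_time`, `persistence` (`NA` here;
#'   filled by [analyze_trajectory()]), `diffusion_coefficient` (likewise),
#'   and the `segments` table.
#' @export
motion_summary <- function(traj, segments, params) {
  stopifnot(inherits(traj, "trajectory"))
  nf <- n_frames(traj)
  tf <- traj$time_per_frame

  # segments must tile the track: no gaps, no overlaps
  if (nrow(segments) == 0L ||
      sum(segments$span_frames) != nf - 1L ||
      segments$start_frame[1L] != traj$frames[1L] ||
      (nrow(segments) > 1L &&
       !all(segments$start_frame[-1L] ==
              segments$end_frame[-nrow(segments)])))
    stop("segments do not tile the trajectory; were they produced by ",
         "skypad_scan() on this track?", call. = FALSE)

  tot <- (nf - 1L) * tf
  moving <- segments$state == "moving"
  mean_speed <- if (any(moving)) mean(segments$speed[moving]) else NA_real_
  pct <- 100 * sum(segments$elapsed_time[moving]) / tot

  # pauses: maximal runs of consecutive non-moving segments
  runs <- rle(!moving)
  pause_runs <- which(runs$values)
  pause_durs <- numeric(length(pause_runs))
  ends_at <- cumsum(runs$lengths)
  for (k in seq_along(pause_runs)) {
    r <- pause_runs[k]
    idx <- (ends_at[r] - runs$lengths[r] + 1L):ends_at[r]
    pause_durs[k] <- sum(segments$elapsed_time[idx])
  }

  structure(
    list(particle_id = traj$particle_id,
         mean_moving_speed = mean_speed,
         percent_time_in_motion = pct,
         n_pauses = length(pause_durs),
         pause_durations = pause_durs,
         total_time = tot,
         persistence = NA_real_,
         diffusion_coefficient = NA_real_,
         msd = NULL,
         segments = segments),
    class = "particle_report")
}

#' @export
print.particle_report <- function(x, ...) {
  cat(sprintf("<particle_report '%s'>\n", as.character(x$particle_id)))
  cat(sprintf("  mean moving speed : %s\n",
              if (is.na(x$mean_moving_speed)) "-- (never moving)"
              else format(x$mean_moving_speed, digits = 4)))
  cat(sprintf("  %% time in motion  : %.1f\n", x$percent_time_in_motion))
  cat(sprintf("  pauses            : %d (total %.4g)\n",
              x$n_pauses, sum(x$pause_durations)))
  if (!is.na(x$persistence))
    cat(sprintf("  persistence       : %.4f\n", x$persistence))
  if (!is.na(x$diffusion_coefficient))
    cat(sprintf("  diffusion coeff.  : %.4g\n", x$diffusion_coefficient))
  cat(sprintf("  segments          : %d\n", nrow(x$segments)))
  invisible(x)
}

#' Full per-particle analysis: scan, motion summary, persistence, MSD, D
#'
#' Convenience wrapper running the whole per-particle pipeline:
#' [skypad_scan()], [motion_summary()], [persistence()], [msd_curve()] and
#' [diffusion_coefficient()].
#'
#' @param traj a [trajectory()].
#' @param params an [analysis_params()].
#' @param max_lag largest MSD lag, in frames; default `NF - 1` (all lags).
#' @param n_lags_used lags averaged for the diffusion coefficient; default
#'   as in [diffusion_coefficient()].
#' @param compute_persistence set `FALSE` to skip the persistence ratio.
#' @return a `"particle_report"` with all statistics and the MSD curve.
#' @export
analyze_trajectory <- function(traj, params, max_lag = NULL,
                               n_lags_used = NULL,
                               compute_persistence = TRUE) {
  segs <- skypad_scan(traj, params)
  rep <- motion_summary(traj, segs, params)
  if (compute_persistence)
    rep$persistence <- persistence(traj)
  if (is.null(max_lag)) max_lag <- n_frames(traj) - 1L
  rep$msd <- msd_curve(traj, max_lag)
  rep$diffusion_coefficient <-
    diffusion_coefficient(rep$msd, dim = traj$dim, n_lags_used = n_lags_used)
  rep
}
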