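#' Directional persistence (D/T ratio)
#'
#' Ratio between the straight-line distance from a particle's first to last
#' position and its total path length (the sum of frame-to-frame step
#' lengths). This is the chemotactic index / directionality ratio used for
#' polarized cell migration: 1 for perfectly straight motion, 0 for a track
#' that returns exactly to its start.
#'
#' @param traj a [trajectory()] with at least 2 frames.
#' @return a ratio in \[0, 1\], or `NA` (with a warning) for a fully
#'   stationary track whose path length is zero.
#'
#' @examples
#' # L-shaped path: net 5, path 7
#' traj <- trajectory(rbind(c(0, 0), c(3, 0), c(3, 4)), time_per_frame = 1)
#' persistence(traj)  # 5/7
#' @export
persistence <- function(traj) {
  stopifnot(inherits(traj, "trajectory"))
  nf <- n_frames(traj)
  if (nf < 2L)
    stop("trajectory must have at least 2 frames", call. = FALSE)
  pos <- traj$positions
  steps <- sqrt(rowSums((pos[-1L, , drop = FALSE] -
                           pos[-nf, , drop = FALSE])^2))
  path <- sum(steps)
  if (path == 0) {
    warning("fully stationary track: persistence undefined", call. = FALSE)
    return(NA_real_)
  }
  net <- sqrt(sum((pos[nf, ] - pos[1L, ])^2))
  net / path
}

#' Time-averaged mean squared displacement curve
#'
#' For each lag of `n` frames (time interval `n * TF`), the MSD is the
#' average squared displacement over all `NF - n` overlapping start frames:
#' \deqn{MSD(n \cdot TF) = \frac{1}{NF-n} \sum_{j=1}^{NF-n}
#'   \lVert r_{j+n} - r_j \rVert^2}
#' The overlapping (time-averaged) convention uses every available
#' increment at each lag, the standard in single-particle tracking; the
#' increment count per lag is returned alongside the values since the large
#' lags average few increments and are correspondingly noisy.
#'
#' @param traj a [trajectory()].
#' @param max_lag largest lag in frames; between 1 and `NF - 1`.
#' @return data frame of class `"msd_curve"` with columns `lag_frames`,
#'   `lag` (in time units), `msd` (length squared) and `n_increments`
#'   (`NF - n`).
#'
#' @examples
#' # ballistic motion: MSD(n*TF) = (v n TF)^2 exactly
#' traj <- trajectory(cbind(0:19 * 2, 0), time_per_frame = 1)
#' head(msd_curve(traj, 5))
#' @export
msd_curve <- function(traj, max_lag = n_frames(traj) - 1L) {
  stopifnot(inherits(traj, "trajectory"))
  nf <- n_frames(traj)
  max_lag <- as.integer(max_lag)
  if (max_lag < 1L || max_lag > nf - 1L)
    stop("`max_lag` must be between 1 and NF - 1 = ", nf - 1L, call. = FALSE)
  pos <- traj$positions
  msd <- numeric(max_lag)
  for (n in seq_len(max_lag)) {
    d2 <- rowSums((pos[(1L + n):nf, , drop = FALSE] -
                     pos[1L:(nf - n), , drop = FALSE])^2)
    msd[n] <- mean(d2)
  }
  out <- data.frame(lag_frames = seq_len(max_lag),
                    lag = seq_len(max_lag) * traj$time_per_frame,
                    msd = msd,
                    n_increments = nf - seq_len(max_lag))
  class(out) <- c("msd_curve", "data.frame")
  out
}

#' Simple diffusion coefficient from an MSD curve
#'
#' Each lag yields a per-interval coefficient
#' \eqn{D_n = MSD(n \cdot TF) / (2 \, d \, n \, TF)} where `d` is the
#' dimensionality; the returned value is the unweighted mean of \eqn{D_n}
#' over the first `n_lags_used` lags. The default window is the first
#' quarter of available lags, which for the ~50-frame tracks this analysis
#' targets keeps the estimate away from the noisy large lags; for very long
#' tracks a small fixed window (e.g. the first 10 lags) is preferable, as
#' the variance of the time-averaged MSD grows with lag.
#'
#' For purely diffusive motion all \eqn{D_n} agree in expectation; a
#' systematic increase of \eqn{D_n} with lag is diagnostic of directed
#' motion (ballistic tracks give \eqn{D_n = v^2 n TF / (2d)}).
#'
#' @param curve an [msd_curve()].
#' @param dim dimensionality of the underlying coordinates, 2 or 3.
#' @param n_lags_used number of initial lags to average; default
#'   `floor((NF - 1) / 4)` (at least 1), capped at the curve length.
#' @return diffusion coefficient, length squared per time.
#' @export
diffusion_coefficient <- function(curve, dim, n_lags_used = NULL) {
  stopifnot(inherits(curve, "msd_curve"))
  if (nrow(curve) == 0L)
    stop("empty MSD curve", call. = FALSE)
  if (!dim %in% c(2, 3))
    stop("`dim` must be 2 or 3", call. = FALSE)
  nf <- curve$n_increments[1L] + curve$lag_frames[1L]  # NF recovered
  if (is.null(n_lags_used))
    n_lags_used <- max(1L, (nf - 1L) %/% 4L)
  n_lags_used <- min(as.integer(n_lags_used), nrow(curve))
  if (n_lags_used < 1L)
    stop("`n_lags_used` must be at least 1", call. = FALSE)
  idx <- seq_len(n_lags_used)
  d_n <- curve$msd[idx] / (2 * dim * curve$lag[idx])
  mean(d_n)
}

#' Cohort-level aggregation of particle reports
#'
#' Averages each per-particle statistic across the cohort and attaches a
#' dispersion per the small/large cohort rule: standard deviation when
#' fewer than 15 particles, standard error of the mean for 15 or more.
#' Statistics absent for some particles (the moving speed of a particle
#' that never moved, the persistence of a stationary one) are skipped, and
#' the effective n per statistic is reported, so immobile particles are
#' not silently imputed as zeros. Per-particle MSD curves, where present,
#' are averaged lag-wise into a cohort mean curve.
#'
#' @param reports list of `"particle_report"` objects (at least one).
#' @return An object of class `"cohort_summary"`: `n_particles`,
#'   `dispersion_kind` (`"SD"` or `"SEM"`), a `stats` data frame with one
#'   row per statistic (`mean`, `sd`, `sem`, `dispersion`, `n_used`), and
#'   `mean_msd` (data frame `lag`, `msd`, `n_particles`, or `NULL`).
#' @export
cohort_summary <- function(reports) {
  if (length(reports) == 0L)
    stop("at least one particle report is required", call. = FALSE)
  stopifnot(all(vapply(reports, inherits, logical(1), "particle_report")))
  n <- length(reports)

  pull <- function(f) vapply(reports, f, numeric(1))
  vals <- list(
    mean_moving_speed = pull(function(r) r$mean_moving_speed),
    percent_time_in_motion = pull(function(r) r$percent_time_in_motion),
    n_pauses = pull(function(r) as.numeric(r$n_pauses)),
    mean_pause_duration = pull(function(r)
      if (r$n_pauses > 0) mean(r$pause_durations) else NA_real_),
    persistence = pull(function(r) r$persistence),
    diffusion_coefficient = pull(function(r) r$diffusion_coefficient))

  one <- function(v) {
    v <- v[!is.na(v)]
    k <- length(v)
    m <- if (k > 0) mean(v) else NA_real_
    s <- if (k > 1) stats::sd(v) else if (k == 1) 0 else NA_real_
    c(mean = m, sd = s, sem = if (k > 0) s / sqrt(k) else NA_real_,
      n_used = k)
  }
  tab <- t(vapply(vals, one, numeric(4)))
  kind <- if (n < 15L) "SD" else "SEM"
  stats_df <- data.frame(
    statistic = rownames(tab),
    mean = tab[, "mean"], sd = tab[, "sd"], sem = tab[, "sem"],
    dispersion = if (kind == "SD") tab[, "sd"] else tab[, "sem"],
    n_used = as.integer(tab[, "n_used"]),
    row.names = NULL, stringsAsFactors = FALSE)

  mean_msd <- NULL
  curves <- lapply(reports, function(r) r$msd)
  have <- !vapply(curves, is.null, logical(1))
  if (any(have)) {
    curves <- curves[have]
    min_lag <- min(vapply(curves, nrow, integer(1)))
    vals_mat <- vapply(curves, function(cv) cv$msd[seq_len(min_lag)],
                       numeric(min_lag))
    vals_mat <- matrix(vals_mat, nrow = min_lag)
    mean_msd <- data.frame(
      lag_frames = curves[[1L]]$lag_frames[seq_len(min_lag)],
      lag = curves[[1L]]$lag[seq_len(min_lag)],
      msd = rowMeans(vals_mat),
      n_particles = sum(have))
  }

  structure(list(n_particles = n, dispersion_kind = kind,
                 stats = stats_df, mean_msd = mean_msd),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("<cohort_summary> %d particles (dispersion: %s)\n",
              x$n_particles, x$dispersion_kind))
  print(x$stats, digits = 4)
  invisible(x)
}
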