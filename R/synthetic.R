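# Seeded RNG without touching global state: evaluate `expr` under a local
# Mersenne-Twister stream and restore whatever .Random.seed was before.
with_local_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("`seed` must be a single integer", call. = FALSE)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister", normal.kind = "Inversion")
  expr
}

#' Describe one stage of a staged synthetic track
#'
#' Stages model the behaviour classes seen in tracked organelles: a
#' `"pause"` (stationary apart from localization jitter), a `"processive"`
#' run (constant speed along a fixed heading), or `"brownian"` diffusion.
#' Jitter is isotropic Gaussian added independently at each frame -- it
#' models localization error, not motion, and does not accumulate.
#'
#' @param duration_frames number of frames the stage lasts (>= 1).
#' @param mode one of `"pause"`, `"processive"`, `"brownian"`.
#' @param speed processive speed, length/time (ignored otherwise).
#' @param heading unit direction vector (length = `dim` of the track) for
#'   processive stages; normalized if needed.
#' @param step_noise_sd per-frame, per-axis localization jitter SD (length).
#' @param diffusion diffusion coefficient for brownian stages,
#'   length squared per time.
#' @return a `"motion_stage"` list.
#' @export
motion_stage <- function(duration_frames, mode = c("pause", "processive", "brownian"),
                         speed = 0, heading = c(1, 0), step_noise_sd = 0,
                         diffusion = 0) {
  mode <- match.arg(mode)
  duration_frames <- as.integer(duration_frames)
  if (duration_frames < 1L)
    stop("`duration_frames` must be at least 1", call. = FALSE)
  if (speed < 0 || step_noise_sd < 0 || diffusion < 0)
    stop("`speed`, `step_noise_sd` and `diffusion` must be non-negative",
         call. = FALSE)
  if (mode == "processive") {
    nrm <- sqrt(sum(heading^2))
    if (nrm == 0) stop("processive `heading` must be non-zero", call. = FALSE)
    heading <- heading / nrm
  }
  structure(list(duration_frames = duration_frames, mode = mode,
                 speed = speed, heading = heading,
                 step_noise_sd = step_noise_sd, diffusion = diffusion),
            class = "motion_stage")
}

#' Generate a staged track with known per-frame ground truth
#'
#' Concatenates [motion_stage()]s into one trajectory. The underlying
#' (noise-free) path is built first -- pauses hold position, processive
#' stages advance `speed * TF` per frame along their heading, brownian
#' stages take Gaussian increments with per-axis variance
#' `2 * diffusion * TF` -- then per-frame localization jitter is added on
#' top. The first frame sits at the origin and carries the first stage's
#' label. Output is a pure function of the arguments including `seed`.
#'
#' @param stages list of [motion_stage()]s (total frames >= 2).
#' @param time_per_frame TF.
#' @param dim 2 or 3.
#' @param seed integer seed; identical seeds give identical tracks.
#' @param particle_id label for the resulting trajectory.
#' @param length_unit,time_unit unit labels passed through.
#' @return list with `trajectory` (a [trajectory()]) and `labels`
#'   (character vector, one true mode per frame).
#' @export
make_staged_track <- function(stages, time_per_frame, dim = 2, seed,
                              particle_id = "staged",
                              length_unit = "um", time_unit = "min") {
  if (length(stages) == 0L)
    stop("at least one stage is required", call. = FALSE)
  stopifnot(all(vapply(stages, inherits, logical(1), "motion_stage")))
  nf <- sum(vapply(stages, function(s) s$duration_frames, integer(1)))
  if (nf < 2L)
    stop("stages must total at least 2 frames", call. = FALSE)
  if (!dim %in% c(2, 3)) stop("`dim` must be 2 or 3", call. = FALSE)
  tf <- time_per_frame

  with_local_seed(seed, {
    base <- matrix(0, nf, dim)
    labels <- character(nf)
    cur <- rep(0, dim)
    row <- 1L
    first <- TRUE
    for (s in stages) {
      for (k in seq_len(s$duration_frames)) {
        if (!first) {
          step <- switch(s$mode,
            pause = rep(0, dim),
            processive = {
              h <- s$heading
              if (length(h) != dim)
                stop("heading length must equal `dim`", call. = FALSE)
              h * s$speed * tf
            },
            brownian = stats::rnorm(dim, 0, sqrt(2 * s$diffusion * tf)))
          cur <- cur + step
        }
        base[row, ] <- cur
        labels[row] <- s$mode
        row <- row + 1L
        first <- FALSE
      }
    }
    jitter_sd <- vapply(stages, function(s) s$step_noise_sd, numeric(1))
    jit <- matrix(0, nf, dim)
    per_frame_sd <- rep(jitter_sd, vapply(stages, function(s) s$duration_frames,
                                          integer(1)))
    nz <- per_frame_sd > 0
    if (any(nz))
      jit[nz, ] <- stats::rnorm(sum(nz) * dim, 0, rep(per_frame_sd[nz], dim))
    list(trajectory = trajectory(base + jit, time_per_frame = tf,
                                 particle_id = particle_id,
                                 length_unit = length_unit,
                                 time_unit = time_unit),
         labels = labels)
  })
}

#' Generate a pure random walk (Brownian) trajectory
#'
#' Per-frame independent Gaussian increments with per-axis variance
#' `2 * diffusion * TF`, so the ensemble MSD is `2 * dim * D * lag`.
#'
#' @param diffusion diffusion coefficient D, length squared per time (>= 0).
#' @param NF number of frames (>= 2).
#' @param time_per_frame TF.
#' @param dim 2 or 3.
#' @param seed integer seed.
#' @param particle_id,length_unit,time_unit labels passed through.
#' @return a [trajectory()].
#' @export
make_random_walk <- function(diffusion, NF, time_per_frame, dim = 2, seed,
                             particle_id = "brownian",
                             length_unit = "um", time_unit = "min") {
  if (diffusion < 0) stop("`diffusion` must be non-negative", call. = FALSE)
  NF <- as.integer(NF)
  if (NF < 2L) stop("`NF` must be at least 2", call. = FALSE)
  with_local_seed(seed, {
    steps <- matrix(stats::rnorm((NF - 1L) * dim, 0,
                                 sqrt(2 * diffusion * time_per_frame)),
                    NF - 1L, dim)
    csum <- apply(steps, 2, cumsum)
    pos <- rbind(rep(0, dim), matrix(csum, NF - 1L, dim))
    trajectory(pos, time_per_frame = time_per_frame,
               particle_id = particle_id,
               length_unit = length_unit, time_unit = time_unit)
  })
}

#' Generate a confined oscillator trajectory
#'
#' A sinusoidal 1D oscillation of the given amplitude embedded in 2D, with
#' optional per-frame localization jitter. This is the failure mode that
#' motivates threshold-based segmentation: the particle's instantaneous
#' speed is strictly positive at almost every frame, yet its net
#' displacement from any anchor never exceeds `2 * amplitude`, so with a
#' distance threshold above that the scan reports no motion at all.
#'
#' @param amplitude oscillation amplitude (> 0), length units.
#' @param period_frames frames per full oscillation period (>= 2).
#' @param NF number of frames (>= 2).
#' @param time_per_frame TF.
#' @param seed integer seed (used only when `step_noise_sd > 0`).
#' @param step_noise_sd per-frame, per-axis jitter SD; default 0.
#' @param particle_id,length_unit,time_unit labels passed through.
#' @return a [trajectory()].
#' @export
make_oscillator <- function(amplitude, period_frames, NF, time_per_frame,
                            seed = 0, step_noise_sd = 0,
                            particle_id = "oscillator",
                            length_unit = "um", time_unit = "min") {
  if (amplitude <= 0) stop("`amplitude` must be positive", call. = FALSE)
  period_frames <- as.integer(period_frames)
  if (period_frames < 2L) stop("`period_frames` must be >= 2", call. = FALSE)
  NF <- as.integer(NF)
  if (NF < 2L) stop("`NF` must be at least 2", call. = FALSE)
  t <- seq_len(NF) - 1L
  x <- amplitude * sin(2 * pi * t / period_frames)
  pos <- cbind(x, rep(0, NF))
  with_local_seed(seed, {
    if (step_noise_sd > 0)
      pos <- pos + matrix(stats::rnorm(NF * 2, 0, step_noise_sd), NF, 2)
    trajectory(pos, time_per_frame = time_per_frame,
               particle_id = particle_id,
               length_unit = length_unit, time_unit = time_unit)
  })
}

#' Mean instantaneous speed of a trajectory
#'
#' The conventional statistic the threshold scan is designed to improve on:
#' mean frame-to-frame displacement divided by TF. For an oscillating but
#' confined particle this is strictly positive even though no significant
#' displacement ever occurs.
#'
#' @param traj a [trajectory()].
#' @return mean speed, length/time.
#' @export
mean_instantaneous_speed <- function(traj) {
  stopifnot(inherits(traj, "trajectory"))
  nf <- n_frames(traj)
  if (nf < 2L) stop("trajectory must have at least 2 frames", call. = FALSE)
  pos <- traj$positions
  steps <- sqrt(rowSums((pos[-1L, , drop = FALSE] -
                           pos[-nf, , drop = FALSE])^2))
  mean(steps) / traj$time_per_frame
}
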