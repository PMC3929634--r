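# Independent brute-force reference implementations, written directly from
# the algorithm's verbal description and kept free of any code from R/.

# Literal scan: from anchor n, increment i one frame at a time until the
# straight-line distance between positions n and n+i strictly exceeds dt;
# classify by strict speed comparison; restart at n+i; residual tail if the
# track ends first.
oracle_scan <- function(pos, dt, st, tf) {
  nf <- nrow(pos)
  segs <- list()
  n <- 1
  while (n < nf) {
    i <- 1
    crossed <- FALSE
    while (n + i <= nf) {
      d <- sqrt(sum((pos[n + i, ] - pos[n, ])^2))
      if (d > dt) { crossed <- TRUE; break }
      i <- i + 1
    }
    if (!crossed) {
      i <- nf - n
      d <- sqrt(sum((pos[nf, ] - pos[n, ])^2))
      speed <- d / (i * tf)
      segs[[length(segs) + 1]] <- list(start = n, end = nf, d = d,
                                       speed = speed, state = "residual")
      break
    }
    speed <- d / (i * tf)
    state <- if (speed > st) "moving" else "paused"
    segs[[length(segs) + 1]] <- list(start = n, end = n + i, d = d,
                                     speed = speed, state = state)
    n <- n + i
  }
  do.call(rbind, lapply(segs, function(s)
    data.frame(start = s$start, end = s$end, d = s$d, speed = s$speed,
               state = s$state, stringsAsFactors = FALSE)))
}

# Motion statistics recomputed from an oracle segment table.
oracle_summary <- function(segs, nf, tf) {
  total <- (nf - 1) * tf
  moving <- segs$state == "moving"
  spans <- segs$end - segs$start
  mean_speed <- if (any(moving)) mean(segs$speed[moving]) else NA_real_
  pct <- 100 * sum(spans[moving] * tf) / total
  # pauses: maximal runs of non-moving segments
  pauses <- c()
  run <- 0
  for (k in seq_len(nrow(segs))) {
    if (!moving[k]) run <- run + spans[k] * tf
    else if (run > 0) { pauses <- c(pauses, run); run <- 0 }
  }
  if (run > 0) pauses <- c(pauses, run)
  list(mean_moving_speed = mean_speed, percent_time_in_motion = pct,
       n_pauses = length(pauses), pause_durations = pauses)
}

# Plain double-loop MSD.
oracle_msd <- function(pos, max_lag) {
  nf <- nrow(pos)
  vapply(seq_len(max_lag), function(n) {
    acc <- 0
    for (j in 1:(nf - n))
      acc <- acc + sum((pos[j + n, ] - pos[j, ])^2)
    acc / (nf - n)
  }, numeric(1))
}

# Random trajectory mixing the three behaviour families; pure function of
# the seed.
random_track <- function(seed, max_nf = 200, tf = 1) {
  set.seed(seed)
  kind <- sample(c("staged", "brownian", "oscillator"), 1)
  nf <- sample(10:max_nf, 1)
  if (kind == "brownian") {
    make_random_walk(stats::runif(1, 0.01, 2), nf, tf, seed = seed + 10000L)
  } else if (kind == "oscillator") {
    make_oscillator(stats::runif(1, 0.5, 5), sample(4:20, 1), nf, tf,
                    seed = seed + 10000L,
                    step_noise_sd = stats::runif(1, 0, 0.3))
  } else {
    remaining <- nf
    stages <- list()
    while (remaining > 0) {
      len <- min(remaining, sample(5:30, 1))
      remaining <- remaining - len
      mode <- sample(c("pause", "processive", "brownian"), 1)
      stages[[length(stages) + 1]] <- motion_stage(
        len, mode, speed = stats::runif(1, 0.2, 3),
        heading = stats::rnorm(2), step_noise_sd = stats::runif(1, 0, 0.3),
        diffusion = stats::runif(1, 0.01, 1))
    }
    if (sum(vapply(stages, function(s) s$duration_frames, integer(1))) < 2)
      stages[[1]]$duration_frames <- 2L
    make_staged_track(stages, tf, seed = seed + 10000L)$trajectory
  }
}

# Random analysis parameters on a scale matched to random_track output.
random_params <- function(seed, tf = 1) {
  set.seed(seed + 5000L)
  analysis_params(distance_threshold = stats::runif(1, 0.5, 20),
                  speed_threshold = stats::runif(1, 0, 2),
                  time_per_frame = tf)
}
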