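test_that("displacement is the Euclidean distance over 2 or 3 coordinates", {
  t2 <- trajectory(rbind(c(0, 0), c(3, 4), c(3, 4)), time_per_frame = 1)
  expect_equal(displacement(t2, 1, 1), 5)
  expect_equal(displacement(t2, 2, 1), 0)
  t3 <- trajectory(rbind(c(0, 0, 0), c(1, 2, 2)), time_per_frame = 1)
  expect_equal(displacement(t3, 1, 1), 3)
  expect_error(displacement(t2, 1, 5), "out of range")
  expect_error(displacement(t2, 3, 1), "out of range")
})

test_that("a stationary particle yields a single residual segment", {
  traj <- trajectory(matrix(1, 20, 2), time_per_frame = 2)
  segs <- skypad_scan(traj, analysis_params(0.5, 0.1, 2))
  expect_equal(nrow(segs), 1L)
  expect_equal(segs$state, "residual")
  expect_equal(segs$start_frame, 1L)
  expect_equal(segs$end_frame, 20L)
  expect_equal(segs$net_displacement, 0)
})

test_that("constant-velocity track segments at the closed-form boundaries", {
  # 1 unit/frame, DT = 9.5: crossing at every 10th frame, residual tail
  traj <- trajectory(cbind(0:49, 0), time_per_frame = 1)
  segs <- skypad_scan(traj, analysis_params(9.5, 0.5, 1))
  expect_equal(segs$start_frame, c(1L, 11L, 21L, 31L, 41L))
  expect_equal(segs$end_frame, c(11L, 21L, 31L, 41L, 50L))
  expect_equal(segs$net_displacement[1:4], rep(10, 4))
  expect_equal(segs$speed[1:4], rep(1, 4))
  expect_equal(segs$state, c(rep("moving", 4), "residual"))
})

test_that("segment speeds are exactly net displacement over elapsed time", {
  for (seed in 1:20) {
    traj <- random_track(seed)
    segs <- skypad_scan(traj, random_params(seed))
    expect_equal(segs$speed, segs$net_displacement / segs$elapsed_time)
    expect_equal(segs$elapsed_time, segs$span_frames * traj$time_per_frame)
  }
})

test_that("classification is strict: ties at ST are paused, residuals untouched", {
  seg <- data.frame(start_frame = 1L, end_frame = 5L, span_frames = 4L,
                    net_displacement = 0.8, elapsed_time = 4,
                    speed = 0.2, state = "pending",
                    stringsAsFactors = FALSE)
  p <- analysis_params(0.5, 0.2, 1)
  expect_equal(classify_segment(seg, p)$state, "paused")   # speed == ST
  seg$speed <- 0.2000001
  expect_equal(classify_segment(seg, p)$state, "moving")
  seg$state <- "residual"
  expect_equal(classify_segment(seg, p)$state, "residual")
  # ST = 0: any positive speed is moving
  seg$state <- "pending"; seg$speed <- 1e-9
  expect_equal(classify_segment(seg, analysis_params(0.5, 0, 1))$state,
               "moving")
})

test_that("motion summary of a stationary track is one pause, zero motion", {
  traj <- trajectory(matrix(0, 30, 2), time_per_frame = 20)
  p <- analysis_params(10, 0.2, 20)
  rep <- motion_summary(traj, skypad_scan(traj, p), p)
  expect_equal(rep$percent_time_in_motion, 0)
  expect_equal(rep$n_pauses, 1L)
  expect_equal(rep$pause_durations, rep$total_time)
  expect_equal(rep$total_time, 29 * 20)
  expect_true(is.na(rep$mean_moving_speed))
})

test_that("pauses merge across consecutive paused and residual segments", {
  # fast run, slow run, fast run, then a stationary tail: the slow run is
  # one pause, the residual tail another
  pos <- rbind(cbind(seq(0, 10, length.out = 6), 0),      # fast: 2/frame
               cbind(seq(12, 20, length.out = 21), 0)[-1, ],  # slow
               cbind(seq(20.4, 30, length.out = 25), 0)[-1, ],# fast
               matrix(c(30, 0), 10, 2, byrow = TRUE))         # stationary
  traj <- trajectory(pos, time_per_frame = 1)
  p <- analysis_params(3, 0.3, 1)
  segs <- skypad_scan(traj, p)
  rep <- motion_summary(traj, segs, p)
  states <- rle(segs$state)$values
  expect_true("residual" %in% segs$state)
  expect_equal(rep$n_pauses,
               sum(rle(segs$state %in% c("paused", "residual"))$values))
  expect_equal(sum(rep$pause_durations) + rep$percent_time_in_motion / 100 *
                 rep$total_time, rep$total_time)
})

test_that("scan and summary agree with the brute-force oracle on random tracks", {
  for (seed in 1:150) {
    traj <- random_track(seed)
    params <- random_params(seed)
    segs <- skypad_scan(traj, params)
    ora <- oracle_scan(traj$positions, params$distance_threshold,
                       params$speed_threshold, params$time_per_frame)
    expect_equal(segs$start_frame, ora$start)
    expect_equal(segs$end_frame, ora$end)
    expect_equal(segs$net_displacement, ora$d)
    expect_equal(segs$state, ora$state)
    rep <- motion_summary(traj, segs, params)
    osum <- oracle_summary(ora, n_frames(traj), traj$time_per_frame)
    expect_equal(rep$mean_moving_speed, osum$mean_moving_speed)
    expect_equal(rep$percent_time_in_motion, osum$percent_time_in_motion)
    expect_equal(rep$n_pauses, osum$n_pauses)
    expect_equal(unname(rep$pause_durations), as.numeric(osum$pause_durations))
  }
})

test_that("segments tile the trajectory: no gaps, no overlaps", {
  for (seed in 1:200) {
    traj <- random_track(seed)
    segs <- skypad_scan(traj, random_params(seed))
    expect_equal(sum(segs$span_frames), n_frames(traj) - 1L)
    expect_equal(segs$start_frame[1], 1L)
    expect_equal(segs$end_frame[nrow(segs)], n_frames(traj))
    if (nrow(segs) > 1)
      expect_equal(segs$start_frame[-1], segs$end_frame[-nrow(segs)])
    # completed segments crossed DT strictly; residual never did
    done <- segs$state != "residual"
    expect_true(all(segs$net_displacement[done] >
                      random_params(seed)$distance_threshold))
    expect_true(all(segs$net_displacement[!done] <=
                      random_params(seed)$distance_threshold))
  }
})

test_that("raising DT never increases the number of completed segments", {
  for (seed in 1:200) {
    traj <- random_track(seed)
    tf <- traj$time_per_frame
    set.seed(seed + 900)
    dts <- sort(stats::runif(2, 0.5, 20))
    n_done <- vapply(dts, function(dt) {
      segs <- skypad_scan(traj, analysis_params(dt, 0.2, tf))
      sum(segs$state != "residual")
    }, numeric(1))
    expect_true(n_done[2] <= n_done[1])
  }
})

test_that("raising ST never increases percent time in motion", {
  for (seed in 1:200) {
    traj <- random_track(seed)
    tf <- traj$time_per_frame
    set.seed(seed + 901)
    dt <- stats::runif(1, 0.5, 10)
    sts <- sort(stats::runif(2, 0, 2))
    pct <- vapply(sts, function(st) {
      p <- analysis_params(dt, st, tf)
      motion_summary(traj, skypad_scan(traj, p), p)$percent_time_in_motion
    }, numeric(1))
    expect_true(pct[2] <= pct[1])
  }
})

test_that("segments are invariant under rigid rotation and translation", {
  for (seed in 1:200) {
    traj <- random_track(seed)
    params <- random_params(seed)
    set.seed(seed + 902)
    th <- stats::runif(1, 0, 2 * pi)
    rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    shift <- stats::rnorm(2, sd = 50)
    moved <- trajectory(sweep(traj$positions %*% rot, 2, -shift),
                        time_per_frame = traj$time_per_frame)
    a <- skypad_scan(traj, params)
    b <- skypad_scan(moved, params)
    expect_equal(a$start_frame, b$start_frame)
    expect_equal(a$net_displacement, b$net_displacement)
    expect_equal(a$speed, b$speed)
    expect_equal(a$state, b$state)
  }
})

test_that("percent time in motion recovers staged ground truth within the boundary bound", {
  tf <- 1
  for (seed in 1:25) {
    set.seed(seed + 300)
    v <- stats::runif(1, 1, 3)          # processive speed
    dt <- stats::runif(1, 1, 3)
    st <- v / stats::runif(1, 2.5, 5)   # speed >= 2.5 x ST
    move_frames <- ceiling(3.5 * dt / (v * tf))  # displacement >= 3 x DT
    pause_frames <- sample(15:40, 1)
    stages <- list(motion_stage(pause_frames, "pause"),
                   motion_stage(move_frames, "processive", speed = v),
                   motion_stage(pause_frames, "pause"))
    stt <- make_staged_track(stages, tf, seed = seed)
    nf <- n_frames(stt$trajectory)
    p <- analysis_params(dt, st, tf)
    rep <- motion_summary(stt$trajectory, skypad_scan(stt$trajectory, p), p)
    truth <- 100 * sum(stt$labels == "processive") / (nf - 1)
    bound <- 100 * 2 * dt / (v * (nf - 1) * tf)
    expect_lt(abs(rep$percent_time_in_motion - truth),
              bound + 100 * 2 / (nf - 1))  # + one frame quantization per boundary
  }
})

test_that("scan validates its inputs", {
  traj1 <- trajectory(matrix(0, 1, 2), time_per_frame = 1)
  expect_error(skypad_scan(traj1, analysis_params(1, 0.1, 1)), "2 frames")
  t3 <- trajectory(matrix(0, 5, 3), time_per_frame = 1)
  expect_error(skypad_scan(t3, analysis_params(1, 0.1, 1, dim = 2)),
               "does not match")
  traj <- trajectory(matrix(0, 5, 2), time_per_frame = 2)
  expect_error(skypad_scan(traj, analysis_params(1, 0.1, 1)),
               "time_per_frame")
  # summary rejects segments that do not tile
  p <- analysis_params(1, 0.1, 2)
  segs <- skypad_scan(traj, p)
  expect_error(motion_summary(traj, segs[0, ], p), "tile")
})
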