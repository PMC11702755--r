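make_track <- function(x, y, likelihood = NULL, frame_rate = 30,
                       px_per_cm = 10) {
  n <- length(x)
  if (is.null(likelihood)) likelihood <- rep(1, n)
  pose_track(tibble::tibble(frame = seq_len(n) - 1L, bodypart = "spine2",
                            x = x, y = y, likelihood = likelihood),
             frame_rate = frame_rate, px_per_cm = px_per_cm)
}

kp0 <- kinematics_params(analysis_window = NULL)

test_that("pose filtering excludes exactly the sub-threshold frames and removes spikes", {
  n <- 60
  lik <- rep(1, n); lik[21:30] <- 0.94
  tr <- make_track(rep(5, n), rep(5, n), lik)
  f <- filter_pose(tr, kp0)
  expect_equal(which(f$excluded), 21:30)
  # median filter of a constant track is the identity
  expect_true(all(f$x == 5))

  # a single-frame +50 px spike is removed by the length-5 median
  x <- rep(10, n); x[30] <- 60
  f2 <- filter_pose(make_track(x, rep(0, n)), kp0)
  expect_equal(f2$x[30], 10)
  expect_true(all(f2$x == 10))

  # boundary: likelihood exactly at the cutoff is retained (strict <)
  lik3 <- rep(0.95, n)
  f3 <- filter_pose(make_track(rep(1, n), rep(1, n), lik3), kp0)
  expect_false(any(f3$excluded))

  expect_warning(filter_pose(make_track(rep(1, n), rep(1, n), rep(0.5, n)), kp0),
                 class = "motorpheno_empty_result")
})

test_that("speed is the backward-difference displacement in cm/s", {
  # straight line at 3 px/frame, 30 Hz, 10 px/cm: 9 cm/s everywhere
  n <- 50
  tr <- make_track(3 * (seq_len(n) - 1), rep(0, n))
  sp <- compute_speed(filter_pose(tr, kp0), kp0)
  expect_true(is.na(sp$speed[1]))
  expect_equal(sp$speed[-1], rep(9, n - 1))

  # stationary track: zero speed
  sp0 <- compute_speed(filter_pose(make_track(rep(4, n), rep(4, n)), kp0), kp0)
  expect_true(all(sp0$speed[-1] == 0))

  # rotation invariance of the speed computation (isometry)
  th <- 0.7
  x <- cumsum(runif(n)); y <- cumsum(runif(n))
  tr1 <- make_track(x, y)
  tr2 <- make_track(cos(th) * x - sin(th) * y, sin(th) * x + cos(th) * y)
  s1 <- compute_speed(tr1, kp0)
  s2 <- compute_speed(tr2, kp0)
  expect_equal(s1$speed, s2$speed)

  # frames adjacent to exclusions carry no speed
  lik <- rep(1, n); lik[10] <- 0.5
  spx <- compute_speed(filter_pose(make_track(x, y, lik), kp0), kp0)
  expect_true(all(is.na(spx$speed[10:11])))
  expect_false(is.na(spx$speed[12]))
})

test_that("bout segmentation applies the strict more-than-0.5 s rule", {
  fr <- 30
  mk_speed <- function(v) {
    structure(tibble::tibble(frame = seq_along(v) - 1L,
                             time = seq_along(v) / fr, speed = v,
                             excluded = FALSE),
              frame_rate = fr, animal_id = "t",
              class = c("speed_series", class(tibble::tibble())))
  }
  # 30 slow frames (1.0 s) flanked by fast frames: one immobile bout of 1 s
  v <- c(rep(5, 30), rep(0.2, 30), rep(5, 30))
  seg <- segment_bouts(mk_speed(v), kp0)
  imm <- seg[seg$state == "immobile", ]
  expect_equal(nrow(imm), 1)
  expect_equal(imm$end - imm$start, 1)

  # exactly 15 frames (0.5 s) below threshold: no immobile bout
  v15 <- c(rep(5, 30), rep(0.2, 15), rep(5, 30))
  seg15 <- segment_bouts(mk_speed(v15), kp0)
  expect_equal(sum(seg15$state == "immobile"), 0)
  # 16 frames: counted
  v16 <- c(rep(5, 30), rep(0.2, 16), rep(5, 30))
  seg16 <- segment_bouts(mk_speed(v16), kp0)
  expect_equal(sum(seg16$state == "immobile"), 1)

  # states tile the window without gaps
  expect_equal(seg$start[-1], seg$end[-nrow(seg)])
})

test_that("segmentation equals the brute-force run-length oracle on random traces", {
  fr <- 30
  set.seed(99)
  for (i in 1:150) {
    n <- 400
    v <- abs(rnorm(n, 0.5, 0.4))
    v[sample(n, 10)] <- NA  # excluded frames break runs
    sp <- structure(tibble::tibble(frame = seq_len(n) - 1L, time = seq_len(n) / fr,
                                   speed = v, excluded = is.na(v)),
                    frame_rate = fr, animal_id = "t",
                    class = c("speed_series", class(tibble::tibble())))
    seg <- segment_bouts(sp, kp0)
    oracle <- oracle_segment(v, fr)
    got <- motorpheno:::frame_states(seg, sp$time)
    expect_identical(got, oracle)
  }
})

test_that("locomotion metrics match construction and truth", {
  fr <- 30
  # alternating 1 s immobile / 1 s mobile at 6 cm/s over 900 s
  v <- rep(c(rep(0.1, 30), rep(6, 30)), 450)
  sp <- structure(tibble::tibble(frame = seq_along(v) - 1L,
                                 time = seq_along(v) / fr, speed = v,
                                 excluded = FALSE),
                  frame_rate = fr, animal_id = "t",
                  class = c("speed_series", class(tibble::tibble())))
  seg <- segment_bouts(sp, kp0)
  m <- locomotion_metrics(seg, sp, kp0)
  expect_equal(m$immobility_time, 450)
  expect_equal(m$n_stops, 450)
  expect_equal(m$mobile_mean_speed, 6)

  # fully mobile trace
  v2 <- rep(6, 300)
  sp2 <- structure(tibble::tibble(frame = seq_along(v2) - 1L,
                                  time = seq_along(v2) / fr, speed = v2,
                                  excluded = FALSE),
                   frame_rate = fr, animal_id = "t",
                   class = c("speed_series", class(tibble::tibble())))
  seg2 <- segment_bouts(sp2, kp0)
  m2 <- locomotion_metrics(seg2, sp2, kp0)
  expect_equal(m2$immobility_time, 0)
  expect_equal(m2$n_stops, 0)
  expect_equal(m2$total_distance, 6 * 300 / 30)

  # fully immobile: mean mobile speed is an explicit empty result
  v3 <- rep(0.1, 300)
  sp3 <- structure(tibble::tibble(frame = seq_along(v3) - 1L,
                                  time = seq_along(v3) / fr, speed = v3,
                                  excluded = FALSE),
                   frame_rate = fr, animal_id = "t",
                   class = c("speed_series", class(tibble::tibble())))
  seg3 <- segment_bouts(sp3, kp0)
  expect_warning(m3 <- locomotion_metrics(seg3, sp3, kp0),
                 class = "motorpheno_empty_result")
  expect_true(is.na(m3$mobile_mean_speed))
})

test_that("pipeline metrics match generator truth on noise-free simulations", {
  for (s in 1:12) {
    p <- bout_sim_params(duration = 120, seed = s, dropout = 0,
                         immobile_speed_sd = 0)
    sim <- simulate_pose(p)
    tr <- filter_pose(sim$track, kp0)
    sp <- compute_speed(tr, kp0)
    seg <- segment_bouts(sp, kp0)
    m <- locomotion_metrics(seg, sp, kp0)
    iv <- sim$truth$intervals
    truth_imm <- iv[iv$state == "immobile" & iv$end - iv$start > 0.5, ]
    n_bound <- 2 * nrow(truth_imm)
    expect_equal(m$n_stops, nrow(truth_imm))
    expect_lt(abs(m$immobility_time - sum(truth_imm$end - truth_imm$start)),
              (n_bound + 1) / 30)
  }
})

test_that("metrics are invariant to translation and rotation of the track", {
  sim <- simulate_pose(bout_sim_params(duration = 60, seed = 3, dropout = 0))
  tr <- sim$track
  th <- 1.1
  tr2 <- dplyr::mutate(tr, x0 = x, x = cos(th) * x0 - sin(th) * y + 500,
                       y = sin(th) * x0 + cos(th) * y - 200)
  tr2 <- pose_track(tr2[, c("frame", "time", "bodypart", "x", "y", "likelihood")],
                    frame_rate = 30, px_per_cm = 32)
  m1 <- locomotion_metrics(segment_bouts(compute_speed(filter_pose(tr, kp0), kp0), kp0),
                           compute_speed(filter_pose(tr, kp0), kp0), kp0)
  m2 <- locomotion_metrics(segment_bouts(compute_speed(filter_pose(tr2, kp0), kp0), kp0),
                           compute_speed(filter_pose(tr2, kp0), kp0), kp0)
  expect_equal(m1$immobility_time, m2$immobility_time)
  expect_equal(m1$n_stops, m2$n_stops)
  # the componentwise median filter is only approximately rotation
  # equivariant, so the speed metric matches to a fraction of a percent
  expect_equal(m1$mobile_mean_speed, m2$mobile_mean_speed, tolerance = 5e-3)
})

test_that("duration densities integrate to one and separate identical cohorts rarely", {
  sim <- simulate_pose(bout_sim_params(duration = 600, seed = 10, dropout = 0))
  sp <- compute_speed(filter_pose(sim$track, kp0), kp0)
  seg <- segment_bouts(sp, kp0)
  dd <- duration_distributions(seg)
  for (st in c("stop", "move")) {
    d <- dd[dd$state == st, ]
    integral <- sum(diff(d$duration) * (head(d$density, -1) + tail(d$density, -1)) / 2)
    expect_lt(abs(integral - 1), 1e-3)
  }
  # mass concentrates at the planted value when all stops last ~2 s
  fr <- 30
  v <- rep(c(rep(5, 60), rep(0.1, 60)), 10)
  spx <- structure(tibble::tibble(frame = seq_along(v) - 1L,
                                  time = seq_along(v) / fr, speed = v,
                                  excluded = FALSE),
                   frame_rate = fr, animal_id = "t",
                   class = c("speed_series", class(tibble::tibble())))
  ddx <- duration_distributions(segment_bouts(spx, kp0))
  stp <- ddx[ddx$state == "stop", ]
  expect_lt(abs(stp$duration[which.max(stp$density)] - 2), 0.1)

  # same dwell distributions in two cohorts: KS rarely significant
  rej <- vapply(1:40, function(s) {
    d1 <- simulate_pose(bout_sim_params(duration = 300, seed = s, dropout = 0))
    d2 <- simulate_pose(bout_sim_params(duration = 300, seed = s + 500, dropout = 0))
    dur <- function(sim) {
      iv <- sim$truth$intervals
      iv$end[iv$state == "immobile"] - iv$start[iv$state == "immobile"]
    }
    suppressWarnings(ks.test(dur(d1), dur(d2))$p.value) < 0.05
  }, logical(1))
  expect_lte(mean(rej), 0.10)
})

test_that("rearing detection honors the inclusive 0.5 s rule and truth counts", {
  ev1 <- tibble::tibble(start = 2, duration = 0.6)
  sim1 <- simulate_height_trace(ev1, duration = 6, seed = 1)
  expect_equal(detect_rearing(sim1$heights,
                              rearing_params(sim1$truth$threshold))$count, 1)
  ev2 <- tibble::tibble(start = 2, duration = 0.4)
  sim2 <- simulate_height_trace(ev2, duration = 6, seed = 1)
  expect_equal(detect_rearing(sim2$heights,
                              rearing_params(sim2$truth$threshold))$count, 0)
  # planted event counts are recovered exactly for k = 0..10
  for (k in 0:10) {
    ev <- tibble::tibble(start = seq_len(k) * 2,
                         duration = rep(c(0.5, 0.8, 1.2), length.out = k))
    sim <- simulate_height_trace(ev, duration = 2 * k + 4, seed = k + 1)
    got <- detect_rearing(sim$heights, rearing_params(sim$truth$threshold))
    expect_equal(got$count, k)
  }
  # threshold outside the observed range warns
  expect_warning(detect_rearing(sim1$heights, rearing_params(1e5)),
                 class = "motorpheno_config_warning")
})
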