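mi_arena <- function() {
  arena_config(50, 50, fps = 30, zones = list(
    nest = list(type = "rect", xmin = 35, xmax = 50, ymin = 35, ymax = 50),
    fresh1 = list(type = "rect", xmin = 0, xmax = 15, ymin = 35, ymax = 50),
    fresh2 = list(type = "rect", xmin = 35, xmax = 50, ymin = 0, ymax = 15)))
}

test_that("zone occupancy sums dwell frames with boundary-inside semantics", {
  ar <- mi_arena()
  # trajectory entirely inside one zone
  tr <- trajectory(seq(0, 2, by = 1 / 30), rep(42, 61), rep(42, 61))
  occ <- zone_occupancy(tr, ar)
  expect_equal(occ$proportion[occ$zone == "nest"], 1)
  expect_equal(occ$proportion[occ$zone == "fresh1"], 0)
  # a centroid exactly on the zone boundary counts as inside
  tb <- trajectory(c(0, 1 / 30), c(35, 35), c(35, 42))
  expect_equal(zone_occupancy(tb, ar)$time_s[1], 2 / 30)
  # zone times sum to the duration when zones partition the arena
  quad <- arena_config(10, 10, fps = 10, zones = list(
    a = list(type = "rect", xmin = 0, xmax = 5, ymin = 0, ymax = 10),
    b = list(type = "polygon", x = c(5, 10, 10, 5), y = c(0, 0, 10, 10))))
  set.seed(13)
  rt <- trajectory(seq(0, 9.9, by = 0.1), runif(100, 0.1, 9.9),
                   runif(100, 0.1, 9.9))
  oq <- zone_occupancy(rt, quad)
  expect_equal(sum(oq$time_s[oq$zone != "none"]), 10)
  # overlapping zones are a configuration error
  bad <- arena_config(10, 10, zones = list(
    a = list(type = "rect", xmin = 0, xmax = 6, ymin = 0, ymax = 10),
    b = list(type = "rect", xmin = 5, xmax = 10, ymin = 0, ymax = 10)))
  expect_error(zone_occupancy(rt, bad), "overlap")
  # zones outside the arena are refused at configuration time
  expect_error(arena_config(20, 20, zones = list(
    far = list(type = "disc", center = c(25, 10), radius = 3))),
    "outside")
})

test_that("discrimination index formula, bounds and symmetries", {
  expect_equal(discrimination_index(300, 100), 0.5)
  expect_equal(discrimination_index(7, 7), 0)
  expect_equal(discrimination_index(100, 300),
               -discrimination_index(300, 100))
  # invariant to rescaling both times
  expect_equal(discrimination_index(30, 10),
               discrimination_index(300, 100))
  expect_true(abs(discrimination_index(1e4, 1)) <= 1)
  expect_warning(di <- discrimination_index(0, 0), "undefined")
  expect_true(is.na(di))
})

test_that("approach latency and first choice follow first zone entry", {
  ar <- arena_config(50, 50, fps = 30, zones = list(
    A = list(type = "disc", center = c(40, 40), radius = 6),
    B = list(type = "disc", center = c(10, 40), radius = 6)))
  # enters A at frame 90 (t = 3.0 s), never enters B
  n <- 150
  x <- rep(25, n); y <- rep(10, n)
  x[91:n] <- 40; y[91:n] <- 40
  tr <- trajectory((seq_len(n) - 1) / 30, x, y)
  am <- approach_metrics(tr, ar)
  expect_equal(am$latency_s[["A"]], 3.0)
  expect_true(is.na(am$latency_s[["B"]]))
  expect_equal(am$first_choice, "A")
  # starting inside a zone of interest is an error
  tr2 <- trajectory(c(0, 1), c(40, 41), c(40, 40))
  expect_error(approach_metrics(tr2, ar), "starts inside")
})

test_that("an unbiased cohort approaches either cup first about half the time", {
  ar <- arena_config(50, 50, fps = 30, zones = list(
    dam = list(type = "disc", center = c(40, 40), radius = 10),
    empty = list(type = "disc", center = c(10, 10), radius = 10)))
  first <- vapply(1:40, function(s) {
    g <- generate_trajectory(ar, duration_s = 120, step_sd = 3,
                             start = c(10, 40), seed = 800 + s)
    approach_metrics(g$traj, ar)$first_choice
  }, character(1))
  p_dam <- mean(first == "dam", na.rm = TRUE)
  ci <- 1.96 * sqrt(0.25 / sum(!is.na(first)))
  expect_gt(p_dam, 0.5 - ci)
  expect_lt(p_dam, 0.5 + ci)
})

test_that("kinematics: uniform motion, rest, and sawtooth arc length", {
  # uniform straight motion at 2 cm/s for 10 s
  tr <- trajectory(seq(0, 10, by = 0.1), seq(0, 20, by = 0.2),
                   rep(3, 101))
  k <- kinematics(tr)
  expect_equal(k$max_velocity, 2, tolerance = 1e-9)
  expect_equal(k$mean_velocity, 2, tolerance = 1e-9)
  expect_equal(k$total_distance, 20, tolerance = 1e-9)
  # stationary animal
  ks <- kinematics(trajectory(0:9, rep(5, 10), rep(5, 10)))
  expect_equal(ks$max_velocity, 0)
  expect_equal(ks$total_distance, 0)
  # sawtooth: 10 legs of length sqrt(1^2 + 2^2), smoothing shortens
  # corners slightly
  xs <- seq(0, 10, by = 0.05)
  ys <- 2 * abs((xs %% 2) - 1)
  trs <- trajectory(seq_along(xs) / 20, xs, ys)
  analytic <- 10 * sqrt(1 + 4)
  # unsmoothed path length is exactly the analytic arc length
  expect_equal(kinematics(trs, smooth_window_frames = 1)$total_distance,
               analytic, tolerance = 1e-9)
  # boxcar smoothing rounds the 10 corners, shortening the path a little
  ksw <- kinematics(trs, smooth_window_frames = 3)
  expect_equal(ksw$total_distance, analytic, tolerance = 0.05)
  expect_error(kinematics(trajectory(0, 1, 1)), "2 frames")
})

test_that("grooming summaries count bouts and durations", {
  empty <- grooming_summary(data.frame(start_s = numeric(0),
                                       end_s = numeric(0)))
  expect_equal(empty$occurrences, 0L)
  expect_true(is.na(empty$mean_duration_s))
  expect_equal(empty$total_time_s, 0)
  g <- grooming_summary(cbind(c(0, 5), c(2, 7)))
  expect_equal(g$occurrences, 2L)
  expect_equal(g$mean_duration_s, 2)
  expect_equal(g$total_time_s, 4)
  # randomized non-overlapping sets match the oracle sum
  set.seed(3)
  starts <- cumsum(runif(20, 1, 5))
  ends <- starts + runif(20, 0.2, 0.9)
  gr <- grooming_summary(cbind(starts, ends))
  expect_equal(gr$total_time_s, sum(ends - starts))
  expect_error(grooming_summary(cbind(c(0, 1), c(2, 3))), "overlap")
})

test_that("Bregma interpolation is exact for linear profiles and refuses extrapolation", {
  # counts linear in bregma: every-other counting reproduces the total
  b <- seq(3.0, 1.6, by = -0.05)
  full <- 1000 - 300 * (3.0 - b)
  half <- full; half[seq(2, length(b), by = 2)] <- NA
  ic <- interpolate_cell_counts(data.frame(bregma_mm = b, count = half))
  expect_equal(ic$total, sum(full))
  expect_equal(ic$sections$count, full)
  # midpoint case
  mid <- interpolate_cell_counts(
    data.frame(bregma_mm = c(3.0, 2.95, 2.9), count = c(100, NA, 200)))
  expect_equal(mid$sections$count[2], 150)
  # a smooth (nonlinear) profile is recovered within 5% total error
  prof <- 800 * exp(-((b - 2.3) / 0.35)^2)
  h2 <- prof; h2[seq(2, length(b), by = 2)] <- NA
  ic2 <- interpolate_cell_counts(data.frame(bregma_mm = b, count = h2))
  expect_lt(abs(ic2$total - sum(prof)) / sum(prof), 0.05)
  # uncounted section outside the counted range
  out <- data.frame(bregma_mm = c(3.0, 2.9, 2.8), count = c(NA, 100, 200))
  expect_error(interpolate_cell_counts(out), "refused")
  expect_message(ic3 <- interpolate_cell_counts(out, drop_outside = TRUE),
                 "dropped")
  expect_equal(ic3$total, 300)
  expect_error(interpolate_cell_counts(
    data.frame(bregma_mm = c(2, 3), count = c(1, 2))), "decreasing")
})

test_that("trajectories and arenas round-trip through CSV and YAML", {
  ar <- mi_arena()
  g <- generate_trajectory(ar, duration_s = 5, seed = 21)
  tpath <- file.path(tempdir(), "traj.csv")
  write_trajectory_csv(g$traj, tpath)
  back <- read_trajectory_csv(tpath)
  expect_equal(back$x, g$traj$x)
  apath <- file.path(tempdir(), "arena.yaml")
  yaml::write_yaml(list(width_cm = 50, height_cm = 50, fps = 30,
                        zones = list(nest = list(type = "rect", xmin = 35,
                                                 xmax = 50, ymin = 35,
                                                 ymax = 50))), apath)
  ar2 <- read_arena_yaml(apath)
  expect_equal(zone_occupancy(g$traj, ar2)$time_s[1],
               zone_occupancy(g$traj, ar)$time_s[1])
  unlink(c(tpath, apath))
})
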