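arena <- arena_config()

# trajectory moving along +x with prescribed per-step displacements (dt = 1)
dx_traj <- function(dx) make_traj(0:length(dx), c(0, cumsum(dx)),
                                  numeric(length(dx) + 1))

test_that("median walking speed uses moving steps only", {
  expect_equal(median_speed(compute_steps(dx_traj(c(2, 4, 6, 8, 100)))), 6)
  expect_equal(median_speed(compute_steps(dx_traj(rep(10, 20)))), 10)
  steps <- compute_steps(make_traj(0:5, rep(0, 6), rep(0, 6)))
  expect_warning(v <- median_speed(steps), "no moving steps")
  expect_true(is.nan(v))
  # immobile steps are excluded from the median
  expect_equal(median_speed(compute_steps(dx_traj(c(0.1, 0.1, 10, 20, 30)))), 20)
})

test_that("distance per minute is raw path length over duration", {
  traj <- make_traj(seq(0, 300, by = 10), seq(0, 300, by = 10),
                    numeric(31))  # straight 300 mm walked over 300 s
  expect_equal(distance_per_min(traj), 60)
  still <- make_traj(0:300, rep(5, 301), rep(5, 301))
  expect_equal(distance_per_min(still), 0)
  # oracle: polyline length of a simulated fly
  fly <- simulate_fly(fly_model_params(seed = 9, duration_s = 30), arena,
                      fly_metadata("f"))
  expect_equal(distance_per_min(fly),
               sum(sqrt(diff(fly$x_mm)^2 + diff(fly$y_mm)^2)) * 60 /
                 traj_duration(fly),
               tolerance = 1e-12)
})

test_that("turning angle is the median wrapped heading change of moving pairs", {
  expect_equal(turning_angle(compute_steps(dx_traj(rep(5, 10)))), 0)

  # square wave: alternate +x and +y unit steps, 90 degrees every step
  n <- 20
  dx <- rep(c(5, 0), n / 2); dy <- rep(c(0, 5), n / 2)
  traj <- make_traj(0:n, c(0, cumsum(dx)), c(0, cumsum(dy)))
  expect_equal(turning_angle(compute_steps(traj)), 90)

  # oracle: brute-force wrapped differences of random headings
  set.seed(31)
  h <- runif(100, 0, 2 * pi)
  traj <- make_traj(0:100, cumsum(c(0, 5 * cos(h))), cumsum(c(0, 5 * sin(h))))
  d <- abs(diff(h)) %% (2 * pi)
  d <- pmin(d, 2 * pi - d) * 180 / pi
  expect_equal(turning_angle(compute_steps(traj)), median(d), tolerance = 1e-9)
})

test_that("meander is the median per-step turn/speed ratio", {
  expect_equal(meander(compute_steps(dx_traj(rep(5, 10)))), 0)
  # constant 90 degree turns at constant 10 mm/s -> 9 deg*s/mm
  n <- 20
  dx <- rep(c(10, 0), n / 2); dy <- rep(c(0, 10), n / 2)
  traj <- make_traj(0:n, c(0, cumsum(dx)), c(0, cumsum(dy)))
  steps <- compute_steps(traj)
  expect_equal(meander(steps), 9)
  # per-step ratio oracle on a random walker
  set.seed(32)
  h <- runif(60, 0, 2 * pi); v <- rgamma(60, 10, 1)
  traj <- make_traj(0:60, cumsum(c(0, v * cos(h))), cumsum(c(0, v * sin(h))))
  steps <- compute_steps(traj)
  ok <- !is.na(steps$turn_deg)
  expect_equal(meander(steps),
               median(steps$turn_deg[ok] / steps$speed_mm_s[ok]),
               tolerance = 1e-12)
  expect_equal(meander(steps, per_step = FALSE),
               turning_angle(steps) / median_speed(steps), tolerance = 1e-12)
})

test_that("thigmotaxis splits time at the equal-area radius", {
  # fly circling at r = 55 mm, well outside the 41.37 mm boundary
  th <- seq(0, 4 * pi, length.out = 200)
  traj <- make_traj(seq_along(th), 55 * cos(th), 55 * sin(th))
  steps <- compute_steps(traj)
  seg <- segment_bouts(steps)
  expect_equal(thigmotaxis(steps, seg, arena, "moving"), 1)
  expect_true(is.nan(thigmotaxis(steps, seg, arena, "sitting")))

  # sitting fly parked on the edge: thigmo_sitting 1, thigmo_moving NaN
  sit <- make_traj(0:20, rep(50, 21), rep(0, 21))
  st <- compute_steps(sit); sg <- segment_bouts(st)
  expect_equal(thigmotaxis(st, sg, arena, "sitting"), 1)
  expect_true(is.nan(thigmotaxis(st, sg, arena, "moving")))

  # Monte-Carlo oracle: uniform positions over the disc -> 0.5
  set.seed(41)
  n <- 20000
  r <- arena$platform_radius_mm * sqrt(runif(n))
  th <- runif(n, 0, 2 * pi)
  traj <- point_weighted_traj(r * cos(th), r * sin(th))
  steps <- compute_steps(traj)
  seg <- segment_bouts(steps)
  expect_equal(thigmotaxis(steps, seg, arena, "moving"), 0.5, tolerance = 0.02)
})

test_that("stripe deviation is the nearest-stripe heading mismatch", {
  # heading straight at the upper stripe from the center -> 0
  up <- make_traj(c(0, 1), c(0, 0), c(-0.5, 0.5))
  expect_equal(stripe_deviation(compute_steps(up), arena), 0)
  # heading perpendicular to the stripe axis -> 90 to both stripes
  across <- make_traj(c(0, 1), c(-0.5, 0.5), c(0, 0))
  expect_equal(stripe_deviation(compute_steps(across), arena), 90)
  # never moving -> NaN with warning
  still <- compute_steps(make_traj(0:3, rep(0, 4), rep(0, 4)))
  expect_warning(v <- stripe_deviation(still, arena), "no moving steps")
  expect_true(is.nan(v))
})

test_that("walks between the stripes are counted by end-zone alternation", {
  # shuttle along the stripe axis rim-to-rim: 7 traversals -> 7 walks
  y <- seq(-55, 55, by = 10)
  for (k in 2:7)
    y <- c(y, if (k %% 2 == 0) seq(45, -55, by = -10) else seq(-45, 55, by = 10))
  traj <- make_traj(seq_along(y) - 1, numeric(length(y)), y)
  expect_equal(count_walks(compute_steps(traj), arena), 7)

  # circling at mid-platform below the zone radius -> 0 walks
  th <- seq(0, 6 * pi, length.out = 300)
  ring <- make_traj(seq_along(th), 20 * cos(th), 20 * sin(th))
  expect_equal(count_walks(compute_steps(ring), arena), 0)
})

test_that("pause statistics summarize the segmentation", {
  traj <- scripted_traj(list(c("move", 10), c("stop", 2), c("move", 10),
                             c("stop", 3), c("move", 10)))
  ps <- pause_stats(segment_bouts(compute_steps(traj)))
  expect_equal(ps$n_pauses, 2)
  expect_equal(ps$pause_length, 2.5, tolerance = 1e-9)
  expect_equal(ps$time_active, 30, tolerance = 1e-9)
  expect_equal(ps$bout_duration, 10, tolerance = 1e-9)

  walker <- scripted_traj(list(c("move", 30)))
  ps <- pause_stats(segment_bouts(compute_steps(walker)))
  expect_equal(ps$n_pauses, 0)
  expect_true(is.nan(ps$pause_length))
  expect_equal(ps$time_active, 30, tolerance = 1e-9)
})

test_that("all twelve metrics respect their ranges on simulated flies", {
  for (seed in 1:4) {
    fly <- simulate_fly(fly_model_params(seed = seed, duration_s = 60,
                                         fixation_strength = runif(1)),
                        arena, fly_metadata(paste0("f", seed), "S", "1"))
    row <- suppressWarnings(compute_all_metrics(fly, arena))
    expect_gte(row$stripe_deviation, 0); expect_lte(row$stripe_deviation, 90)
    expect_gte(row$turning_angle, 0); expect_lte(row$turning_angle, 180)
    for (p in c("thigmo_moving", "thigmo_sitting"))
      expect_true(is.nan(row[[p]]) || (row[[p]] >= 0 && row[[p]] <= 1))
    expect_gte(row$n_walks, 0); expect_gte(row$n_pauses, 0)
    expect_lte(row$time_active, traj_duration(fly) + 1e-9)
  }
})

test_that("a stationary fly yields a degenerate but complete metrics row", {
  still <- make_traj(seq(0, 300, 0.5), rep(30, 601), rep(30, 601))
  row <- suppressWarnings(compute_all_metrics(still, arena))
  expect_equal(row$distance_per_min, 0)
  expect_equal(row$time_active, 0)
  expect_true(is.nan(row$median_speed))
  expect_true(is.nan(row$stripe_deviation))
  expect_equal(row$thigmo_sitting, 1)  # parked at r = 42.4 mm, outer ring
})

test_that("metrics are equivariant under rotation and mirror symmetry", {
  fly <- simulate_fly(fly_model_params(seed = 77, duration_s = 60), arena,
                      fly_metadata("f", "S", "1"))
  base <- suppressWarnings(compute_all_metrics(fly, arena))

  phi <- deg <- 33
  c0 <- cos(deg * pi / 180); s0 <- sin(deg * pi / 180)
  rot <- make_traj(fly$time_s, c0 * fly$x_mm - s0 * fly$y_mm,
                   s0 * fly$x_mm + c0 * fly$y_mm)
  arena_rot <- arena_config(stripe_bearings_deg = c(90 + deg, 270 + deg))
  rotated <- suppressWarnings(compute_all_metrics(rot, arena_rot))

  mir <- make_traj(fly$time_s, -fly$x_mm, fly$y_mm)  # reflect across stripe axis
  mirrored <- suppressWarnings(compute_all_metrics(mir, arena))

  for (col in metric_columns()) {
    expect_equal(rotated[[col]], base[[col]], tolerance = 1e-9, label = col)
    expect_equal(mirrored[[col]], base[[col]], tolerance = 1e-9, label = col)
  }
})

test_that("strong simulated fixators score far below the random-walk baseline", {
  devs <- vapply(1:5, function(i) {
    fly <- simulate_fly(fly_model_params(seed = 100 + i, duration_s = 120,
                                         fixation_strength = 0.9,
                                         fixation_kappa = 10,
                                         p_stop = 0.02), arena,
                        fly_metadata("f"))
    stripe_deviation(compute_steps(fly), arena)
  }, numeric(1))
  expect_lt(mean(devs), 20)
})
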