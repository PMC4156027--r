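# Shared fixtures: trajectories built from explicit positions or from a
# scripted move/stop schedule. All constructed in code; no files.

make_traj <- function(t, x, y, id = "f1", strain = "S1", rep = "2012",
                      arena = NULL) {
  trajectory(t, x, y, fly_metadata(id, strain, rep), arena = arena)
}

# Build a trajectory from a schedule of (state, duration) segments.
# Moving segments advance along +x at `speed`; the fly is not confined
# (use only where no arena is involved).
scripted_traj <- function(schedule, speed = 10, dt = 0.1, ...) {
  t <- 0; x <- 0
  ts <- 0; xs <- 0
  for (seg in schedule) {
    n <- round(as.numeric(seg[[2]]) / dt)
    for (i in seq_len(n)) {
      t <- t + dt
      if (seg[[1]] == "move") x <- x + speed * dt
      ts <- c(ts, t); xs <- c(xs, x)
    }
  }
  make_traj(ts, xs, numeric(length(ts)), ...)
}

# independent run-length oracle for bout/pause segmentation: operates on
# the per-step moving flags and interval durations directly
segmentation_oracle <- function(moving, dt, min_pause_s = 1) {
  n <- length(moving)
  runs <- rle(as.logical(moving))
  out <- list(pauses = 0L, pause_durs = numeric(), active = 0)
  idx <- 1L
  pause_durs <- numeric()
  for (k in seq_along(runs$lengths)) {
    len <- runs$lengths[k]
    dur <- sum(dt[idx:(idx + len - 1L)])
    if (!runs$values[k] && dur > min_pause_s) pause_durs <- c(pause_durs, dur)
    idx <- idx + len
  }
  if (!any(moving)) pause_durs <- sum(dt)
  list(n_pauses = length(pause_durs), pause_durs = pause_durs,
       time_active = sum(dt) - sum(pause_durs))
}

# steps whose midpoints sit exactly at prescribed positions with unit time
# weight: each position gets a symmetric jitter step (midpoint = the point,
# speed eps mm/s over 1 s, i.e. moving) and the travel between positions
# takes negligible time (dt = 1e-6 s), so time-weighted step-midpoint
# statistics sample the prescribed positions
point_weighted_traj <- function(px, py, eps = 2, ...) {
  n <- length(px)
  ts <- numeric(2 * n); xs <- numeric(2 * n); ys <- numeric(2 * n)
  t <- 0
  for (i in seq_len(n)) {
    xs[2 * i - 1] <- px[i] - eps / 2; ys[2 * i - 1] <- py[i]
    xs[2 * i] <- px[i] + eps / 2; ys[2 * i] <- py[i]
    ts[2 * i - 1] <- t
    ts[2 * i] <- t + 1
    t <- t + 1 + 1e-6
  }
  make_traj(ts, xs, ys, ...)
}
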