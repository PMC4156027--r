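# The twelve per-fly locomotor parameters. Angle metrics and speed use
# moving steps only; path length uses every step; thigmotaxis splits the
# platform at radius R/sqrt(2) into two equal-area regions.

#' Median walking speed (mm/s)
#'
#' Median of per-step speed over moving steps only.
#' @param steps a [compute_steps()] result
#' @return speed in mm/s, `NaN` (with a warning) if the fly never moves
#' @export
median_speed <- function(steps) {
  v <- steps$speed_mm_s[steps$moving]
  if (!length(v)) {
    warning("no moving steps: median_speed is undefined", call. = FALSE)
    return(NaN)
  }
  stats::median(v)
}

#' Distance travelled per minute (mm/min)
#'
#' Total path length of the raw trajectory (all steps, moving or not)
#' normalized by the recording duration. Tracker jitter during pauses is
#' deliberately not excluded here: path length is defined on the raw
#' track, and the immobility flag only gates the speed and angle metrics.
#' @param traj a [trajectory()]
#' @return mm/min
#' @export
distance_per_min <- function(traj) {
  stopifnot(inherits(traj, "buridan_trajectory"))
  dur <- traj_duration(traj)
  if (dur <= 0) stop("trajectory duration must be positive")
  path <- sum(sqrt(diff(traj$x_mm)^2 + diff(traj$y_mm)^2))
  path * 60 / dur
}

#' Median turning angle (degrees)
#'
#' Median absolute heading change between consecutive moving steps,
#' wrapped to [0, 180].
#' @param steps a [compute_steps()] result
#' @return degrees; `NaN` with a warning if no turn is defined
#' @export
turning_angle <- function(steps) {
  tu <- steps$turn_deg[!is.na(steps$turn_deg)]
  if (!length(tu)) {
    warning("no consecutive moving steps: turning_angle is undefined", call. = FALSE)
    return(NaN)
  }
  stats::median(tu)
}

#' Meander (degrees * s / mm)
#'
#' Median over steps of the per-step turning angle divided by the
#' instantaneous speed of that step — a path-tortuosity measure. The
#' median of per-step ratios is used (not the ratio of medians); see the
#' methods vignette for the alternative.
#' @param steps a [compute_steps()] result
#' @param per_step if `FALSE`, return the ratio of medians
#'   (`turning_angle / median_speed`) instead of the median of per-step
#'   ratios
#' @return degrees * s / mm; `NaN` with a warning if no turn is defined
#' @export
meander <- function(steps, per_step = TRUE) {
  ok <- !is.na(steps$turn_deg)
  if (!any(ok)) {
    warning("no consecutive moving steps: meander is undefined", call. = FALSE)
    return(NaN)
  }
  if (per_step) {
    stats::median(steps$turn_deg[ok] / steps$speed_mm_s[ok])
  } else {
    stats::median(steps$turn_deg[ok]) / stats::median(steps$speed_mm_s[steps$moving])
  }
}

#' Thigmotaxis: proportion of time spent in the outer ring
#'
#' Fraction of the selected time (moving steps, or immobile time within
#' pauses) spent beyond the equal-area boundary radius
#' `platform_radius / sqrt(2)`, weighting each step by its duration. The
#' outer ring and the inner disc have equal surface, so a position-
#' indifferent fly scores 0.5.
#'
#' @param steps a [compute_steps()] result
#' @param segmentation a [segment_bouts()] result (needed for
#'   `state = "sitting"`)
#' @param arena an [arena_config()]
#' @param state `"moving"` (time in moving steps) or `"sitting"` (time in
#'   immobile steps that belong to a pause)
#' @return proportion in [0, 1]; `NaN` if the selected time is zero
#' @export
thigmotaxis <- function(steps, segmentation, arena, state = c("moving", "sitting")) {
  state <- match.arg(state)
  if (state == "moving") {
    sel <- steps$moving
  } else {
    in_pause <- rep(FALSE, nrow(steps))
    for (i in seq_len(nrow(segmentation$pauses))) {
      p <- segmentation$pauses[i, ]
      in_pause <- in_pause |
        (steps$t_mid_s >= p$start_s & steps$t_mid_s <= p$end_s)
    }
    sel <- !steps$moving & in_pause
  }
  w <- steps$dt_s[sel]
  if (!sum(w)) return(NaN)
  outer_ring <- steps$r_mm[sel] > arena$thigmotaxis_boundary_radius_mm
  sum(w[outer_ring]) / sum(w)
}

#' Stripe deviation (degrees)
#'
#' For each moving step, the angle between the direction of motion and the
#' direction from the fly's position toward the nearer of the two stripe
#' centers, wrapped to [0, 180]; because the stripes are opposed the
#' per-step value lies in [0, 90]. The fly's score is the median over
#' moving steps: 0 means perfect fixation, ~45 is the level of an
#' uncorrelated random walk.
#'
#' @param steps a [compute_steps()] result
#' @param arena an [arena_config()]
#' @return degrees in [0, 90]; `NaN` with a warning if the fly never moves
#' @export
stripe_deviation <- function(steps, arena) {
  mv <- steps$moving & !is.na(steps$heading_deg)
  if (!any(mv)) {
    warning("no moving steps: stripe_deviation is undefined", call. = FALSE)
    return(NaN)
  }
  stats::median(step_stripe_deviation(steps, arena)[mv])
}

# per-step nearest-stripe deviation (NA for non-moving / zero-length steps)
step_stripe_deviation <- function(steps, arena) {
  sc <- stripe_centers(arena)
  b1 <- rad2deg(atan2(sc[1, 2] - steps$y_mid_mm, sc[1, 1] - steps$x_mid_mm))
  b2 <- rad2deg(atan2(sc[2, 2] - steps$y_mid_mm, sc[2, 1] - steps$x_mid_mm))
  pmin(angle_diff(steps$heading_deg, b1), angle_diff(steps$heading_deg, b2))
}

#' Number of walks between the stripes
#'
#' An end zone is defined in front of each stripe: positions farther from
#' the center than `walk_zone_fraction * platform_radius` and within
#' `walk_zone_half_angle_deg` of the stripe bearing. A walk is counted
#' each time the fly enters one end zone having last occupied the other.
#'
#' @param steps a [compute_steps()] result
#' @param arena an [arena_config()]
#' @return a non-negative count (0 for a fly that never visits both zones)
#' @export
count_walks <- function(steps, arena) {
  zone <- zone_of(steps$x_mid_mm, steps$y_mid_mm, arena)
  visits <- zone[!is.na(zone)]
  if (!length(visits)) return(0L)
  visits <- visits[c(TRUE, diff(visits) != 0)]
  length(visits) - 1L
}

# which end zone (1, 2 or NA) each position falls in
zone_of <- function(x, y, arena) {
  r <- sqrt(x^2 + y^2)
  pos_bearing <- rad2deg(atan2(y, x))
  far <- r > arena$walk_zone_fraction * arena$platform_radius_mm
  z <- rep(NA_integer_, length(x))
  for (k in 1:2) {
    hit <- far & angle_diff(pos_bearing, arena$stripe_bearings_deg[k]) <=
      arena$walk_zone_half_angle_deg
    z[hit] <- k
  }
  z
}

#' Pause and activity-bout statistics
#'
#' @param segmentation a [segment_bouts()] result
#' @return a list with `n_pauses` (count), `pause_length` (median pause
#'   duration in s, `NaN` if none), `bout_duration` (median activity-bout
#'   duration in s, `NaN` if none) and `time_active` (summed bout
#'   duration in s)
#' @export
pause_stats <- function(segmentation) {
  stopifnot(inherits(segmentation, "bout_segmentation"))
  p <- segmentation$pauses$duration_s
  b <- segmentation$bouts$duration_s
  list(
    n_pauses = nrow(segmentation$pauses),
    pause_length = if (length(p)) stats::median(p) else NaN,
    bout_duration = if (length(b)) stats::median(b) else NaN,
    time_active = if (length(b)) sum(b) else 0
  )
}

#' Compute all twelve locomotor parameters for one fly
#'
#' Shares a single step series and bout segmentation across the individual
#' metric functions and returns one metrics row. Degenerate but parseable
#' flies (e.g. completely immobile) yield `NaN` for the undefined angle
#' and speed metrics, with warnings, but never an error.
#'
#' @param traj a [trajectory()]
#' @param arena an [arena_config()]
#' @param immobility_speed_mm_s walking/sitting speed cutoff, mm/s
#' @param min_pause_s minimal pause duration, s (strict)
#' @param smooth_window optional boxcar smoothing window (samples)
#' @return a one-row data frame: `fly_id`, `strain`, `replicate` and the
#'   twelve columns of [metric_columns()]
#' @examples
#' arena <- arena_config()
#' fly <- simulate_fly(fly_model_params(seed = 1), arena,
#'                     fly_metadata("fly1", "CS_TP", "2012"))
#' compute_all_metrics(fly, arena)
#' @export
compute_all_metrics <- function(traj, arena,
                                immobility_speed_mm_s = 1,
                                min_pause_s = 1,
                                smooth_window = 0) {
  steps <- compute_steps(traj, immobility_speed_mm_s, smooth_window)
  seg <- segment_bouts(steps, min_pause_s)
  ps <- pause_stats(seg)
  meta <- traj_meta(traj)
  data.frame(
    fly_id = meta$fly_id, strain = meta$strain, replicate = meta$replicate,
    median_speed = median_speed(steps),
    distance_per_min = distance_per_min(traj),
    turning_angle = turning_angle(steps),
    meander = meander(steps),
    thigmo_moving = thigmotaxis(steps, seg, arena, "moving"),
    thigmo_sitting = thigmotaxis(steps, seg, arena, "sitting"),
    stripe_deviation = stripe_deviation(steps, arena),
    n_walks = count_walks(steps, arena),
    n_pauses = ps$n_pauses,
    bout_duration = ps$bout_duration,
    pause_length = ps$pause_length,
    time_active = ps$time_active,
    stringsAsFactors = FALSE
  )
}
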