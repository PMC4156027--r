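# Step-level kinematics. A trajectory of n samples yields n-1 steps; step i
# covers the interval [t_i, t_{i+1}] and carries the displacement between
# the two samples. "Moving" is decided per step by a speed threshold;
# headings are undefined (NA) for zero-length steps.

#' Per-step kinematic series of a trajectory
#'
#' Differentiates the centroid track into per-step displacement, speed,
#' heading and turning angle, and flags each step as moving or immobile.
#' The walking/sitting cutoff is a speed threshold: steps slower than
#' `immobility_speed_mm_s` (or with zero displacement) count as immobile.
#' An optional centered boxcar smooth of the coordinates can be applied
#' before differentiation; it is off by default.
#'
#' @param traj a [trajectory()]
#' @param immobility_speed_mm_s speed cutoff in mm/s separating walking
#'   from sitting (default 1, roughly body-length-scale tracker jitter per
#'   second)
#' @param smooth_window boxcar width in samples (odd; 0 or 1 disables)
#' @return an object of class `step_series`: a data frame with one row per
#'   step and columns `t_start_s`, `t_mid_s`, `dt_s`, `x_mid_mm`,
#'   `y_mid_mm`, `r_mm` (radial distance of the step midpoint), `step_mm`,
#'   `speed_mm_s`, `heading_deg` (direction of motion in [0,360), NA when
#'   the step has zero length), `turn_deg` (absolute heading change from
#'   the previous step, in [0,180], NA unless both steps are moving) and
#'   `moving`. The fly metadata and total record duration are attached as
#'   attributes.
#' @export
compute_steps <- function(traj, immobility_speed_mm_s = 1,
                          smooth_window = 0) {
  stopifnot(inherits(traj, "buridan_trajectory"))
  if (nrow(traj) < 2L) stop("trajectory needs at least 2 samples")
  if (!is.numeric(immobility_speed_mm_s) || immobility_speed_mm_s <= 0)
    stop("immobility_speed_mm_s must be positive")

  t <- traj$time_s; x <- traj$x_mm; y <- traj$y_mm
  if (smooth_window > 1) {
    if (smooth_window %% 2 == 0)
      stop("smooth_window must be odd")
    k <- rep(1 / smooth_window, smooth_window)
    xs <- stats::filter(x, k, sides = 2)
    ys <- stats::filter(y, k, sides = 2)
    keep <- !is.na(xs)  # filter() leaves NA at the ends; keep raw values there
    x[keep] <- xs[keep]; y[keep] <- ys[keep]
  }

  dt <- diff(t)
  if (any(dt == 0))
    stop("duplicate timestamp at index ", which(dt == 0)[1] + 1L)
  dx <- diff(x); dy <- diff(y)
  step <- sqrt(dx^2 + dy^2)
  speed <- step / dt
  heading <- ifelse(step > 0, wrap360(rad2deg(atan2(dy, dx))), NA_real_)
  moving <- step > 0 & speed >= immobility_speed_mm_s

  n <- length(step)
  turn <- rep(NA_real_, n)
  if (n >= 2L) {
    both <- moving[-1] & moving[-n]
    turn[-1][both] <- angle_diff(heading[-1][both], heading[-n][both])
  }

  xm <- (x[-1] + x[-length(x)]) / 2
  ym <- (y[-1] + y[-length(y)]) / 2
  steps <- data.frame(
    t_start_s = t[-length(t)], t_mid_s = t[-length(t)] + dt / 2, dt_s = dt,
    x_mid_mm = xm, y_mid_mm = ym, r_mm = sqrt(xm^2 + ym^2),
    step_mm = step, speed_mm_s = speed, heading_deg = heading,
    turn_deg = turn, moving = moving
  )
  attr(steps, "meta") <- traj_meta(traj)
  attr(steps, "duration_s") <- t[length(t)] - t[1]
  attr(steps, "immobility_speed_mm_s") <- immobility_speed_mm_s
  class(steps) <- c("step_series", "data.frame")
  steps
}

#' Segment a step series into activity bouts and pauses
#'
#' A pause is a maximal run of immobile steps lasting strictly longer than
#' `min_pause_s` (the classical rule counts a stop only when the fly stands
#' still for more than 1 s). Shorter stops are absorbed into the
#' surrounding activity bout, so bouts and pauses tile the record exactly.
#' A record with no moving step at all is a single pause regardless of its
#' length.
#'
#' @param steps a [compute_steps()] result
#' @param min_pause_s minimal immobile duration, in seconds, for a stop to
#'   count as a pause (strict inequality; default 1)
#' @return an object of class `bout_segmentation`: a list with data frames
#'   `bouts` and `pauses` (columns `start_s`, `end_s`, `duration_s`),
#'   plus the total record duration.
#' @export
segment_bouts <- function(steps, min_pause_s = 1) {
  stopifnot(inherits(steps, "step_series"))
  if (nrow(steps) == 0L) stop("step series is empty")

  t0 <- steps$t_start_s
  t1 <- steps$t_start_s + steps$dt_s
  r <- rle(as.logical(steps$moving))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  seg <- data.frame(start_s = t0[starts], end_s = t1[ends],
                    moving = r$values)
  seg$duration_s <- seg$end_s - seg$start_s

  if (!any(seg$moving)) {
    pauses <- data.frame(start_s = t0[1], end_s = t1[length(t1)])
    pauses$duration_s <- pauses$end_s - pauses$start_s
    bouts <- pauses[0, ]
  } else {
    is_pause <- !seg$moving & seg$duration_s > min_pause_s
    pauses <- seg[is_pause, c("start_s", "end_s", "duration_s")]
    # everything between consecutive pauses (and record edges) is one bout
    cuts <- c(t0[1], as.vector(t(pauses[, c("start_s", "end_s")])), t1[length(t1)])
    bs <- cuts[seq(1, length(cuts) - 1, by = 2)]
    be <- cuts[seq(2, length(cuts), by = 2)]
    keep <- be > bs
    bouts <- data.frame(start_s = bs[keep], end_s = be[keep])
    bouts$duration_s <- bouts$end_s - bouts$start_s
  }
  rownames(pauses) <- NULL; rownames(bouts) <- NULL
  res <- list(bouts = bouts, pauses = pauses,
              duration_s = t1[length(t1)] - t0[1],
              min_pause_s = min_pause_s)
  class(res) <- "bout_segmentation"
  res
}

#' @export
print.bout_segmentation <- function(x, ...) {
  cat(sprintf("Bout segmentation: %d bout(s), %d pause(s) over %.1f s (pause if > %g s immobile)\n",
              nrow(x$bouts), nrow(x$pauses), x$duration_s, x$min_pause_s))
  invisible(x)
}
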