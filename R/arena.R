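#' Arena geometry for Buridan's paradigm
#'
#' Describes the walking platform and the two opposing stripe landmarks.
#' Defaults correspond to the classical setup: a 117 mm-diameter platform
#' surrounded by water, with two 11 degree-wide black stripes placed 293 mm
#' from the platform center on opposite bearings. The stripe axis is
#' vertical (bearings 90 and 270 degrees) so that transition plots show the
#' landmarks at the top and bottom.
#'
#' The thigmotaxis boundary radius is derived, not settable: it is
#' `platform_radius_mm / sqrt(2)`, the radius at which the outer annulus and
#' the inner disc have exactly equal area, so that a fly with no edge
#' preference spends half its time in each region.
#'
#' @param platform_radius_mm platform radius in mm (default 58.5, i.e. a
#'   117 mm diameter)
#' @param stripe_distance_mm distance from platform center to each stripe,
#'   in mm (default 293); must exceed the platform radius (the stripes are
#'   inaccessible)
#' @param stripe_width_deg angular width of each stripe as seen from the
#'   platform center, in degrees (default 11)
#' @param stripe_bearings_deg bearings of the two stripes in degrees; they
#'   must be 180 degrees apart (default `c(90, 270)`)
#' @param walk_zone_fraction fraction of the platform radius beyond which a
#'   stripe-facing sector counts as an end zone for walk counting, in (0,1)
#' @param walk_zone_half_angle_deg angular half-width of each end zone
#'   around its stripe bearing, in degrees
#'
#' @return an object of class `buridan_arena`
#' @examples
#' arena <- arena_config()
#' arena$thigmotaxis_boundary_radius_mm  # 58.5 / sqrt(2) = 41.37 mm
#' @export
arena_config <- function(platform_radius_mm = 58.5,
                         stripe_distance_mm = 293,
                         stripe_width_deg = 11,
                         stripe_bearings_deg = c(90, 270),
                         walk_zone_fraction = 0.5,
                         walk_zone_half_angle_deg = 45) {
  stopifnot(is.numeric(platform_radius_mm), length(platform_radius_mm) == 1L,
            is.numeric(stripe_distance_mm), length(stripe_distance_mm) == 1L,
            is.numeric(stripe_bearings_deg), length(stripe_bearings_deg) == 2L)
  if (!is.finite(platform_radius_mm) || platform_radius_mm <= 0)
    stop("platform_radius_mm must be a positive length (mm)")
  if (stripe_distance_mm <= platform_radius_mm)
    stop("stripe_distance_mm must exceed platform_radius_mm: the stripes are outside the water moat")
  if (abs(angle_diff(stripe_bearings_deg[1], stripe_bearings_deg[2]) - 180) > 1e-9)
    stop("the two stripe bearings must be opposed (180 degrees apart)")
  if (!(walk_zone_fraction > 0 && walk_zone_fraction < 1))
    stop("walk_zone_fraction must lie in (0, 1)")
  if (!(walk_zone_half_angle_deg > 0 && walk_zone_half_angle_deg <= 90))
    stop("walk_zone_half_angle_deg must lie in (0, 90]")

  arena <- list(
    platform_radius_mm = platform_radius_mm,
    stripe_distance_mm = stripe_distance_mm,
    stripe_width_deg = stripe_width_deg,
    stripe_bearings_deg = wrap360(stripe_bearings_deg),
    thigmotaxis_boundary_radius_mm = platform_radius_mm / sqrt(2),
    walk_zone_fraction = walk_zone_fraction,
    walk_zone_half_angle_deg = walk_zone_half_angle_deg
  )
  class(arena) <- "buridan_arena"
  arena
}

#' Cartesian coordinates of the two stripe centers
#' @param arena a `buridan_arena`
#' @return 2 x 2 matrix, one row per stripe, columns `x_mm`, `y_mm`
#' @keywords internal
stripe_centers <- function(arena) {
  b <- deg2rad(arena$stripe_bearings_deg)
  cbind(x_mm = arena$stripe_distance_mm * cos(b),
        y_mm = arena$stripe_distance_mm * sin(b))
}

#' @export
print.buridan_arena <- function(x, ...) {
  cat("Buridan arena\n")
  cat(sprintf("  platform radius: %.1f mm (diameter %.0f mm)\n",
              x$platform_radius_mm, 2 * x$platform_radius_mm))
  cat(sprintf("  stripes: %.0f mm from center, %.0f deg wide, bearings %g / %g deg\n",
              x$stripe_distance_mm, x$stripe_width_deg,
              x$stripe_bearings_deg[1], x$stripe_bearings_deg[2]))
  cat(sprintf("  thigmotaxis boundary (equal areas): %.2f mm\n",
              x$thigmotaxis_boundary_radius_mm))
  invisible(x)
}

#' Read an arena configuration from a YAML file
#'
#' Any subset of the [arena_config()] arguments may be given; the rest take
#' their defaults.
#' @param path path to a YAML file
#' @return a `buridan_arena`
#' @export
read_arena_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(arena_config))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop("unknown arena configuration key(s): ", paste(bad, collapse = ", "))
  do.call(arena_config, vals)
}
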