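# Angle helpers. All public-facing angles are degrees; headings live in
# [0, 360), differences in [0, 180].

deg2rad <- function(deg) deg * pi / 180

rad2deg <- function(rad) rad * 180 / pi

#' Wrap an angle to [0, 360)
#' @param deg angle(s) in degrees
#' @return wrapped angle(s)
#' @keywords internal
wrap360 <- function(deg) deg %% 360

#' Absolute angular difference wrapped to [0, 180]
#'
#' @param a,b angles in degrees (any range)
#' @return elementwise `|a - b|` wrapped to the half-circle
#' @keywords internal
angle_diff <- function(a, b) abs(((a - b + 180) %% 360) - 180)
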