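# Transition plots: positional histograms of moving time, Gaussian
# smoothed. The grid extends a few smoothing scales beyond the platform so
# that the kernel never runs off the edge and total mass is conserved.

#' Moving-time occupancy map (transition plot data)
#'
#' Bins the fly's position during moving steps into a square grid over the
#' platform, weighting each step by its duration, then applies a separable
#' Gaussian smooth. Immobile time contributes nothing — transition plots
#' show where the fly walked, not where it sat.
#'
#' @param traj a [trajectory()] (used for metadata only; positions come
#'   from `steps`)
#' @param steps a [compute_steps()] result for the same fly
#' @param arena an [arena_config()]
#' @param bin_size_mm histogram bin edge length in mm (default 2, about a
#'   59 x 59 grid over the 117 mm platform)
#' @param sigma_bins Gaussian smoothing scale in bins (default 1; 0
#'   disables smoothing)
#' @return an object of class `occupancy_map`: a list with the `grid`
#'   matrix (rows = x bins, columns = y bins, seconds of moving time),
#'   bin centers `x_mm` / `y_mm`, and the smoothing settings
#' @export
occupancy <- function(traj, steps, arena, bin_size_mm = 2, sigma_bins = 1) {
  if (bin_size_mm <= 0) stop("bin_size_mm must be positive")
  R <- arena$platform_radius_mm
  pad <- ceiling(4 * max(sigma_bins, 0)) * bin_size_mm
  half <- ceiling((R + pad) / bin_size_mm) * bin_size_mm
  edges <- seq(-half, half, by = bin_size_mm)
  nb <- length(edges) - 1L

  grid <- matrix(0, nb, nb)
  mv <- steps$moving
  if (any(mv)) {
    ix <- findInterval(steps$x_mid_mm[mv], edges, rightmost.closed = TRUE)
    iy <- findInterval(steps$y_mid_mm[mv], edges, rightmost.closed = TRUE)
    ok <- ix >= 1 & ix <= nb & iy >= 1 & iy <= nb
    ixo <- ix[ok]; iyo <- iy[ok]; w <- steps$dt_s[mv][ok]
    for (j in seq_along(w)) grid[ixo[j], iyo[j]] <- grid[ixo[j], iyo[j]] + w[j]
  }
  if (sigma_bins > 0) grid <- gaussian_smooth2d(grid, sigma_bins)

  centers <- edges[-1] - bin_size_mm / 2
  map <- list(grid = grid, x_mm = centers, y_mm = centers,
              bin_size_mm = bin_size_mm, sigma_bins = sigma_bins,
              meta = traj_meta(traj))
  class(map) <- "occupancy_map"
  map
}

# separable Gaussian convolution, kernel truncated at 4 sigma and
# renormalized; zero padding (the grid is padded at construction so no
# platform mass reaches the border)
gaussian_smooth2d <- function(m, sigma) {
  half <- ceiling(4 * sigma)
  k <- stats::dnorm(-half:half, sd = sigma)
  k <- k / sum(k)
  conv1 <- function(v) {
    padded <- c(numeric(half), v, numeric(half))
    out <- numeric(length(v))
    for (i in seq_along(v)) out[i] <- sum(padded[i:(i + 2 * half)] * rev(k))
    out
  }
  m <- apply(m, 2, conv1)
  t(apply(m, 1, conv1))
}

#' Pool occupancy maps (e.g. all flies of one strain and replicate)
#'
#' Grids are summed cell-wise; maps must share geometry. Normalization for
#' display happens after pooling, in [render_levels()].
#' @param maps a list of `occupancy_map`s on identical grids
#' @return a pooled `occupancy_map`
#' @export
pool_occupancy <- function(maps) {
  stopifnot(length(maps) >= 1L)
  g <- maps[[1]]$grid
  for (m in maps[-1]) {
    if (!identical(dim(m$grid), dim(g)))
      stop("occupancy maps have mismatched grids and cannot be pooled")
    g <- g + m$grid
  }
  out <- maps[[1]]
  out$grid <- g
  out$meta <- NULL
  out
}

#' Normalize an occupancy map for display
#'
#' Divides by the maximum and clips at `cap_fraction`: every cell at or
#' above `cap_fraction` of the maximum maps to the top color level (1),
#' with a proportional scale below. This reproduces the usual transition-
#' plot convention where saturated cells mark positions visited at least
#' 95% as often as the most-visited position.
#'
#' @param map an `occupancy_map`
#' @param cap_fraction saturation level as a fraction of the maximum
#'   (default 0.95)
#' @return the map with `grid` replaced by normalized levels in [0, 1]
#'   (and a `cap_fraction` element recorded); an all-zero map is returned
#'   unchanged with a warning
#' @export
render_levels <- function(map, cap_fraction = 0.95) {
  stopifnot(inherits(map, "occupancy_map"))
  mx <- max(map$grid)
  if (mx <= 0) {
    warning("occupancy map is all zero; nothing to normalize", call. = FALSE)
    map$cap_fraction <- cap_fraction
    return(map)
  }
  g <- map$grid / mx
  g[g >= cap_fraction] <- 1
  map$grid <- g
  map$cap_fraction <- cap_fraction
  map
}

#' Write an occupancy grid as a CSV matrix
#' @param map an `occupancy_map`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_occupancy <- function(map, path) {
  utils::write.table(map$grid, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Plot an occupancy map as a heat image
#'
#' @param x an `occupancy_map` (typically after [render_levels()])
#' @param file optional PNG path; when given the plot is written there
#' @param ... passed on to [graphics::image()]
#' @export
plot.occupancy_map <- function(x, file = NULL, ...) {
  if (!is.null(file)) {
    grDevices::png(file, width = 600, height = 600)
    on.exit(grDevices::dev.off())
  }
  pal <- grDevices::hcl.colors(64, "YlOrRd", rev = TRUE)
  graphics::image(x$x_mm, x$y_mm, x$grid, col = pal, asp = 1,
                  xlab = "x (mm)", ylab = "y (mm)", ...)
  invisible(x)
}
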