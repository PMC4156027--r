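# Synthetic fly-trajectory generator: a correlated random walk on the
# platform with von Mises heading noise, optional attraction toward the
# nearer stripe, gamma-distributed step speeds, and two-state move/pause
# Markov switching. The rim is handled by reflection (a real fly turns at
# the water moat).

#' Draw from a von Mises distribution
#'
#' Best-Fisher rejection sampler. `kappa = 0` gives the uniform circular
#' distribution; `kappa = Inf` returns `mu` exactly.
#' @param n number of draws
#' @param mu mean direction, radians
#' @param kappa concentration parameter (>= 0)
#' @return angles in radians (unwrapped around `mu`)
#' @keywords internal
rvonmises <- function(n, mu, kappa) {
  if (kappa == 0) return(stats::runif(n, -pi, pi) + mu)
  if (!is.finite(kappa)) return(rep(mu, n))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u <- stats::runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    c0 <- kappa * (r - f)
    if (c0 * (2 - c0) - u[2] > 0 || log(c0 / u[2]) + 1 - c0 >= 0) {
      out[i] <- mu + sign(u[3] - 0.5) * acos(f)
      i <- i + 1L
    }
  }
  out
}

#' Behavioral parameters of a simulated fly
#'
#' The walker alternates between a moving and a paused state (Markov
#' switching with per-second rates `p_stop` and `p_go`). While moving, the
#' new heading is a von Mises mixture: with weight `1 - fixation_strength`
#' it continues the previous heading (concentration `persistence_kappa`),
#' with weight `fixation_strength` it is drawn around the bearing toward
#' the nearer stripe (concentration `fixation_kappa`). Step speeds are
#' gamma distributed with the given mean and coefficient of variation.
#'
#' @param mean_speed_mm_s mean walking speed, mm/s (default 15)
#' @param speed_cv coefficient of variation of step speeds (default 0.3)
#' @param persistence_kappa von Mises concentration of heading
#'   continuation (default 8; larger = straighter paths)
#' @param fixation_strength mixing weight in [0,1] of stripe attraction
#'   versus heading persistence (0 = ignores the stripes)
#' @param fixation_kappa von Mises concentration of the attraction
#'   component (default 4)
#' @param p_stop probability per second of stopping while moving, in (0,1)
#'   (0 allowed: never stops)
#' @param p_go probability per second of resuming while paused, in (0,1)
#' @param dt_s sampling interval, s (default 0.05, i.e. 20 Hz)
#' @param duration_s recording length, s (default 300, the 5-minute
#'   standard)
#' @param seed optional per-fly RNG seed
#' @return an object of class `fly_model_params`
#' @export
fly_model_params <- function(mean_speed_mm_s = 15, speed_cv = 0.3,
                             persistence_kappa = 8,
                             fixation_strength = 0.5, fixation_kappa = 4,
                             p_stop = 0.1, p_go = 0.5,
                             dt_s = 0.05, duration_s = 300, seed = NULL) {
  if (mean_speed_mm_s <= 0) stop("mean_speed_mm_s must be positive")
  if (speed_cv < 0) stop("speed_cv must be non-negative")
  if (fixation_strength < 0 || fixation_strength > 1)
    stop("fixation_strength must lie in [0, 1]")
  if (persistence_kappa < 0 || fixation_kappa < 0)
    stop("kappa parameters must be non-negative")
  if (p_stop < 0 || p_stop >= 1 || p_go <= 0 || p_go >= 1)
    stop("p_stop and p_go are per-second probabilities in [0, 1)")
  if (dt_s <= 0 || duration_s <= 0)
    stop("dt_s and duration_s must be positive")
  p <- list(mean_speed_mm_s = mean_speed_mm_s, speed_cv = speed_cv,
            persistence_kappa = persistence_kappa,
            fixation_strength = fixation_strength,
            fixation_kappa = fixation_kappa,
            p_stop = p_stop, p_go = p_go,
            dt_s = dt_s, duration_s = duration_s, seed = seed)
  class(p) <- "fly_model_params"
  p
}

#' Simulate one fly in the arena
#'
#' @param params a [fly_model_params()]
#' @param arena an [arena_config()]
#' @param meta a [fly_metadata()] to attach (default an anonymous fly)
#' @return a [trajectory()], fully reproducible from `params$seed`
#' @examples
#' fly <- simulate_fly(fly_model_params(seed = 7), arena_config(),
#'                     fly_metadata("sim1", "CS_TP", "2012"))
#' @export
simulate_fly <- function(params, arena = arena_config(),
                         meta = fly_metadata("sim")) {
  stopifnot(inherits(params, "fly_model_params"))
  if (!is.null(params$seed)) set.seed(params$seed)
  R <- arena$platform_radius_mm
  dt <- params$dt_s
  n <- round(params$duration_s / dt)
  sc <- stripe_centers(arena)

  # per-step speed draws (gamma; degenerate at the mean when cv = 0)
  if (params$speed_cv > 0) {
    shape <- 1 / params$speed_cv^2
    speeds <- stats::rgamma(n, shape = shape,
                            scale = params$mean_speed_mm_s / shape)
  } else speeds <- rep(params$mean_speed_mm_s, n)

  p_stop_step <- 1 - (1 - params$p_stop)^dt
  p_go_step <- 1 - (1 - params$p_go)^dt
  switch_u <- stats::runif(n)
  mix_u <- stats::runif(n)

  x <- numeric(n + 1); y <- numeric(n + 1)
  r0 <- R * sqrt(stats::runif(1)) * 0.9  # start inside, uniform over area
  th0 <- stats::runif(1, 0, 2 * pi)
  x[1] <- r0 * cos(th0); y[1] <- r0 * sin(th0)
  heading <- stats::runif(1, 0, 2 * pi)
  moving <- TRUE

  for (i in seq_len(n)) {
    if (moving) {
      if (mix_u[i] < params$fixation_strength) {
        # aim at the stripe the fly is currently facing
        b1 <- atan2(sc[1, 2] - y[i], sc[1, 1] - x[i])
        b2 <- atan2(sc[2, 2] - y[i], sc[2, 1] - x[i])
        d1 <- abs(((heading - b1 + pi) %% (2 * pi)) - pi)
        d2 <- abs(((heading - b2 + pi) %% (2 * pi)) - pi)
        target <- if (d1 <= d2) b1 else b2
        heading <- rvonmises(1, target, params$fixation_kappa)
      } else {
        heading <- rvonmises(1, heading, params$persistence_kappa)
      }
      px <- x[i] + speeds[i] * dt * cos(heading)
      py <- y[i] + speeds[i] * dt * sin(heading)
      rr <- sqrt(px^2 + py^2)
      if (rr > R) {  # radial reflection at the rim
        px <- px * (2 * R - rr) / rr
        py <- py * (2 * R - rr) / rr
      }
      x[i + 1] <- px; y[i + 1] <- py
      if (px != x[i] || py != y[i])
        heading <- atan2(py - y[i], px - x[i])  # persistence follows the realized step
      if (switch_u[i] < p_stop_step) moving <- FALSE
    } else {
      x[i + 1] <- x[i]; y[i + 1] <- y[i]
      if (switch_u[i] < p_go_step) moving <- TRUE
    }
  }
  trajectory(seq(0, by = dt, length.out = n + 1), x, y, meta, arena = arena)
}

#' Simulate an uncorrelated random walk on the platform
#'
#' The stripe-fixation null model: headings i.i.d. uniform at every step,
#' constant speed, no pauses, rim-reflected. Its median stripe deviation
#' is the classical ~44-45 degree baseline against which fixation scores
#' are read; in the zero-step-length limit at the platform center the
#' median is exactly 45 degrees.
#'
#' @param duration_s recording length, s (default 300)
#' @param dt_s sampling interval, s (default 0.05)
#' @param speed_mm_s constant step speed, mm/s (default 15)
#' @param seed optional RNG seed
#' @param arena an [arena_config()]
#' @param meta a [fly_metadata()] to attach
#' @return a [trajectory()]
#' @export
simulate_random_walk <- function(duration_s = 300, dt_s = 0.05,
                                 speed_mm_s = 15, seed = NULL,
                                 arena = arena_config(),
                                 meta = fly_metadata("rw")) {
  stopifnot(duration_s > 0, dt_s > 0, speed_mm_s > 0)
  if (!is.null(seed)) set.seed(seed)
  R <- arena$platform_radius_mm
  n <- round(duration_s / dt_s)
  h <- stats::runif(n, 0, 2 * pi)
  step <- speed_mm_s * dt_s
  x <- numeric(n + 1); y <- numeric(n + 1)
  for (i in seq_len(n)) {
    px <- x[i] + step * cos(h[i])
    py <- y[i] + step * sin(h[i])
    rr <- sqrt(px^2 + py^2)
    if (rr > R) {
      px <- px * (2 * R - rr) / rr
      py <- py * (2 * R - rr) / rr
    }
    x[i + 1] <- px; y[i + 1] <- py
  }
  trajectory(seq(0, by = dt_s, length.out = n + 1), x, y, meta, arena = arena)
}

#' Specification of one simulated strain
#'
#' @param name strain label
#' @param params a [fly_model_params()] shared by all flies of the strain
#' @param n_flies flies per replicate (default 12)
#' @param replicate_shift named list of additive perturbations applied to
#'   the parameters in the second replicate, modelling a small global
#'   replicate effect on activity (default: mean speed +1 mm/s)
#' @return an object of class `strain_spec`
#' @export
strain_spec <- function(name, params, n_flies = 12,
                        replicate_shift = list(mean_speed_mm_s = 1)) {
  stopifnot(nzchar(name), inherits(params, "fly_model_params"), n_flies >= 1)
  s <- list(name = name, params = params, n_flies = n_flies,
            replicate_shift = replicate_shift)
  class(s) <- "strain_spec"
  s
}

#' Simulate a full multi-strain, two-replicate study
#'
#' Generates `n_flies` trajectories per strain and replicate. Each fly
#' gets its own seed derived from `seed`, so the study is reproducible as
#' a whole and per fly. In the second replicate the `replicate_shift`
#' perturbations of each strain are added to its parameters.
#'
#' @param strains a list of [strain_spec()]s
#' @param seed master seed (integer)
#' @param replicates replicate labels (default `c("2012", "2013")`)
#' @param arena an [arena_config()]
#' @return a list of [trajectory()] objects with populated metadata
#' @export
simulate_study <- function(strains, seed = 1,
                           replicates = c("2012", "2013"),
                           arena = arena_config()) {
  stopifnot(length(strains) >= 1L)
  flies <- list()
  counter <- 0L
  for (s in strains) {
    stopifnot(inherits(s, "strain_spec"))
    for (ri in seq_along(replicates)) {
      pars <- s$params
      if (ri > 1L) {
        for (nm in names(s$replicate_shift))
          pars[[nm]] <- pars[[nm]] + s$replicate_shift[[nm]]
      }
      for (f in seq_len(s$n_flies)) {
        counter <- counter + 1L
        pars$seed <- (seed * 10000L + counter) %% .Machine$integer.max
        id <- sprintf("%s_%s_f%02d", s$name, replicates[ri], f)
        meta <- fly_metadata(id, strain = s$name,
                             replicate = replicates[ri])
        flies[[id]] <- simulate_fly(do.call(fly_model_params, unclass(pars)),
                                    arena, meta)
      }
    }
  }
  flies
}

#' The default five-strain study design
#'
#' Emulates the classical design: five wild-type sub-strains, two yearly
#' replicates, 12 flies per cell, with the strains falling into three
#' planted behavioral groups — two strong stripe-fixators (CS_TP, CS_TZ),
#' two weak fixators (CS_BS, CS_HS), and one intermediate but
#' hyperactive strain (CS_JC).
#'
#' @param n_flies flies per strain per replicate (default 12)
#' @param duration_s per-fly recording length, s (default 300)
#' @return a list of [strain_spec()]s
#' @export
default_study_spec <- function(n_flies = 12, duration_s = 300) {
  base <- function(...) fly_model_params(duration_s = duration_s, ...)
  list(
    strain_spec("CS_TP", base(fixation_strength = 0.7, fixation_kappa = 6,
                              mean_speed_mm_s = 14, p_stop = 0.10), n_flies),
    strain_spec("CS_TZ", base(fixation_strength = 0.7, fixation_kappa = 6,
                              mean_speed_mm_s = 14, p_stop = 0.10), n_flies),
    strain_spec("CS_JC", base(fixation_strength = 0.45, fixation_kappa = 4,
                              mean_speed_mm_s = 22, p_stop = 0.03), n_flies),
    strain_spec("CS_BS", base(fixation_strength = 0.15, fixation_kappa = 3,
                              mean_speed_mm_s = 11, p_stop = 0.25), n_flies),
    strain_spec("CS_HS", base(fixation_strength = 0.15, fixation_kappa = 3,
                              mean_speed_mm_s = 11, p_stop = 0.25), n_flies)
  )
}

#' Simulate a metrics table directly (statistical calibration generator)
#'
#' For calibrating the statistical stage (PCA + ANOVA + Tukey grouping) at
#' scale, this generator skips trajectory simulation and draws the twelve
#' standardized metrics per fly directly: independent unit normals, plus a
#' planted group shift on a subset of metrics and a small additive
#' replicate effect. Group structure is given as an integer vector
#' assigning each strain to a behavioral group; group `g` receives a shift
#' of `effect_size * (g - mean(g))` standard deviations on each of
#' `n_shifted_metrics` metrics.
#'
#' @param strains strain labels
#' @param group integer group assignment, one per strain (equal values =
#'   same planted group); `NULL` plants no strain effect (the null model)
#' @param n_per_cell flies per strain x replicate cell (default 12)
#' @param effect_size planted between-adjacent-group shift in units of the
#'   within-group SD (default 1.5)
#' @param n_shifted_metrics how many of the twelve metrics carry the shift
#'   (default 3)
#' @param replicate_effect additive shift of the second replicate on the
#'   first metric, in SD units (default 0.3, a numerically small effect)
#' @param seed RNG seed
#' @return a metrics data frame as produced by the trajectory pipeline
#' @export
simulate_metrics_table <- function(strains = c("CS_TP", "CS_TZ", "CS_JC",
                                               "CS_BS", "CS_HS"),
                                   group = NULL, n_per_cell = 12,
                                   effect_size = 1.5, n_shifted_metrics = 3,
                                   replicate_effect = 0.3, seed = 1) {
  set.seed(seed)
  if (is.null(group)) group <- rep(1L, length(strains))
  stopifnot(length(group) == length(strains))
  reps <- c("2012", "2013")
  cells <- expand.grid(strain = strains, replicate = reps,
                       stringsAsFactors = FALSE)
  rows <- list()
  mcols <- metric_columns()
  centered <- effect_size * (group - mean(group))
  names(centered) <- strains
  for (i in seq_len(nrow(cells))) {
    m <- matrix(stats::rnorm(n_per_cell * 12), n_per_cell, 12,
                dimnames = list(NULL, mcols))
    m[, seq_len(n_shifted_metrics)] <-
      m[, seq_len(n_shifted_metrics)] + centered[cells$strain[i]]
    if (cells$replicate[i] == reps[2]) m[, 1] <- m[, 1] + replicate_effect
    df <- data.frame(fly_id = sprintf("%s_%s_f%02d", cells$strain[i],
                                      cells$replicate[i], seq_len(n_per_cell)),
                     strain = cells$strain[i], replicate = cells$replicate[i],
                     m, stringsAsFactors = FALSE)
    rows[[i]] <- df
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
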