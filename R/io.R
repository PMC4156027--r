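# File dialect: one CSV data file per fly (header time_s,x_mm,y_mm; a
# permissive reader also accepts t/x/y and time/x/y) plus one flat YAML
# metadata file with at least fly_id, strain and replicate.

#' Metric column names, in the stable output order
#'
#' The twelve per-fly locomotor parameters, in the order they appear in
#' every metrics table written by the package.
#' @return character vector of length 12
#' @export
metric_columns <- function() {
  c("median_speed", "distance_per_min", "turning_angle", "meander",
    "thigmo_moving", "thigmo_sitting", "stripe_deviation",
    "n_walks", "n_pauses", "bout_duration", "pause_length", "time_active")
}

id_columns <- function() c("fly_id", "strain", "replicate")

#' Per-fly metadata
#'
#' @param fly_id unique fly identifier (string)
#' @param strain strain / genotype label, e.g. `"CS_TP"`
#' @param replicate replicate label, e.g. `"2012"`
#' @param setup_id tracker setup identifier (optional)
#' @param extra named list of additional key-value pairs
#' @return an object of class `fly_metadata`
#' @export
fly_metadata <- function(fly_id, strain = "", replicate = "",
                         setup_id = "", extra = list()) {
  if (missing(fly_id) || !nzchar(as.character(fly_id)))
    stop("fly_id is required and must be non-empty")
  meta <- list(fly_id = as.character(fly_id),
               strain = as.character(strain),
               replicate = as.character(replicate),
               setup_id = as.character(setup_id),
               extra = extra)
  class(meta) <- "fly_metadata"
  meta
}

#' Read / write fly metadata (flat YAML)
#'
#' @param path path to a YAML file with at least `fly_id`; `strain`,
#'   `replicate` and `setup_id` are recognized and all other keys are kept
#'   in `extra`.
#' @return [read_fly_metadata()] returns a `fly_metadata`;
#'   [write_fly_metadata()] returns `path` invisibly.
#' @export
read_fly_metadata <- function(path) {
  if (!file.exists(path)) stop("metadata file not found: ", path)
  vals <- yaml::read_yaml(path)
  if (is.null(vals) || is.null(vals$fly_id))
    stop("metadata file ", path, " lacks required key 'fly_id'")
  known <- c("fly_id", "strain", "replicate", "setup_id")
  fly_metadata(fly_id = vals$fly_id,
               strain = if (is.null(vals$strain)) "" else vals$strain,
               replicate = if (is.null(vals$replicate)) "" else vals$replicate,
               setup_id = if (is.null(vals$setup_id)) "" else vals$setup_id,
               extra = vals[setdiff(names(vals), known)])
}

#' @rdname read_fly_metadata
#' @param meta a `fly_metadata`
#' @export
write_fly_metadata <- function(meta, path) {
  stopifnot(inherits(meta, "fly_metadata"))
  flat <- c(meta[c("fly_id", "strain", "replicate", "setup_id")], meta$extra)
  yaml::write_yaml(flat, path)
  invisible(path)
}

#' Construct a trajectory
#'
#' A trajectory is the centroid position of one fly, sampled at the tracker
#' frame rate, in the arena frame (origin at the platform center,
#' millimetres). Sampling may be irregular; times must be non-decreasing.
#'
#' @param times_s sample times in seconds, non-decreasing
#' @param x_mm,y_mm centroid coordinates in mm
#' @param meta a [fly_metadata()]
#' @param arena optional [arena_config()]; when given, points farther than
#'   `position_tol_mm` outside the platform rim are clipped to the rim with
#'   a warning
#' @param position_tol_mm positional noise tolerance for the rim check (mm)
#' @return an object of class `buridan_trajectory`: a data frame with
#'   columns `time_s`, `x_mm`, `y_mm` and attribute `meta`
#' @export
trajectory <- function(times_s, x_mm, y_mm, meta, arena = NULL,
                       position_tol_mm = 1) {
  n <- length(times_s)
  if (n == 0L) stop("trajectory is empty")
  if (length(x_mm) != n || length(y_mm) != n)
    stop("times_s, x_mm and y_mm must have equal lengths")
  bad <- which(diff(times_s) < 0)
  if (length(bad))
    stop("time column decreases at index ", bad[1] + 1L)
  if (!inherits(meta, "fly_metadata")) stop("meta must be a fly_metadata")

  x_mm <- as.numeric(x_mm); y_mm <- as.numeric(y_mm)
  if (!is.null(arena)) {
    r <- sqrt(x_mm^2 + y_mm^2)
    out <- which(r > arena$platform_radius_mm + position_tol_mm)
    if (length(out)) {
      warning(length(out), " point(s) beyond the platform rim clipped to the rim",
              call. = FALSE)
      scale <- arena$platform_radius_mm / r[out]
      x_mm[out] <- x_mm[out] * scale
      y_mm[out] <- y_mm[out] * scale
    }
  }
  traj <- data.frame(time_s = as.numeric(times_s), x_mm = x_mm, y_mm = y_mm)
  attr(traj, "meta") <- meta
  class(traj) <- c("buridan_trajectory", "data.frame")
  traj
}

#' Metadata of a trajectory
#' @param traj a `buridan_trajectory`
#' @return the attached `fly_metadata`
#' @export
traj_meta <- function(traj) attr(traj, "meta")

#' Recording duration of a trajectory, in seconds
#' @param traj a `buridan_trajectory`
#' @export
traj_duration <- function(traj) {
  diff(range(traj$time_s))
}

# header synonyms accepted by the permissive reader
.col_synonyms <- list(
  time_s = c("time_s", "t", "time", "t_s"),
  x_mm = c("x_mm", "x"),
  y_mm = c("y_mm", "y")
)

#' Read one fly's trajectory from a data/metadata file pair
#'
#' The data file is delimited text with a header naming columns `time_s`,
#' `x_mm`, `y_mm` (synonyms `t`/`time` and `x`/`y` are accepted); the
#' metadata file is flat YAML, see [read_fly_metadata()]. Records whose
#' duration falls outside `nominal_duration_s` by more than
#' `duration_tol_frac` pass through with a warning; all metrics are
#' computed on the actual duration.
#'
#' @param data_path path to the trajectory CSV
#' @param meta_path path to the metadata YAML
#' @param arena an [arena_config()]; off-platform points are clipped to the
#'   rim (see [trajectory()])
#' @param nominal_duration_s nominal recording length in seconds (default
#'   300, the 5-minute standard); `NULL` disables the duration check
#' @param duration_tol_frac accepted fractional deviation from the nominal
#'   duration (default 0.05)
#' @return a `buridan_trajectory`
#' @export
read_trajectory <- function(data_path, meta_path, arena = arena_config(),
                            nominal_duration_s = 300,
                            duration_tol_frac = 0.05) {
  if (!file.exists(data_path)) stop("data file not found: ", data_path)
  dat <- utils::read.csv(data_path, check.names = FALSE)
  if (nrow(dat) == 0L) stop("data file ", data_path, " contains no samples")
  cols <- lapply(.col_synonyms, function(syn) {
    hit <- intersect(syn, names(dat))
    if (length(hit)) hit[1] else NA_character_
  })
  missing_cols <- names(cols)[is.na(unlist(cols))]
  if (length(missing_cols))
    stop("data file ", data_path, " lacks required column(s): ",
         paste(missing_cols, collapse = ", "))
  times <- dat[[cols$time_s]]
  bad <- which(diff(times) < 0)
  if (length(bad))
    stop("time column decreases at row ", bad[1] + 1L, " of ", data_path)

  meta <- read_fly_metadata(meta_path)
  traj <- trajectory(times, dat[[cols$x_mm]], dat[[cols$y_mm]], meta,
                     arena = arena)
  if (!is.null(nominal_duration_s)) {
    dur <- traj_duration(traj)
    if (abs(dur - nominal_duration_s) > duration_tol_frac * nominal_duration_s)
      warning(sprintf("fly %s: recording duration %.1f s deviates from nominal %.0f s",
                      meta$fly_id, dur, nominal_duration_s), call. = FALSE)
  }
  traj
}

#' Write one fly's trajectory to a data/metadata file pair
#'
#' @param traj a `buridan_trajectory`
#' @param data_path,meta_path output paths (CSV and YAML)
#' @return `data_path`, invisibly
#' @export
write_trajectory <- function(traj, data_path, meta_path = NULL) {
  stopifnot(inherits(traj, "buridan_trajectory"))
  df <- as.data.frame(traj)
  utils::write.csv(df, data_path, row.names = FALSE, quote = FALSE)
  if (!is.null(meta_path)) write_fly_metadata(traj_meta(traj), meta_path)
  invisible(data_path)
}

#' Write / read the per-fly metrics table
#'
#' One row per fly: the three identifier columns (`fly_id`, `strain`,
#' `replicate`) followed by the twelve locomotor parameters in the order of
#' [metric_columns()].
#'
#' @param rows a data frame of metric rows (e.g. from
#'   [compute_all_metrics()] rbind-ed together)
#' @param path output path (CSV)
#' @return `path` invisibly; [read_metrics_table()] returns the data frame.
#' @export
write_metrics_table <- function(rows, path) {
  if (is.null(rows) || nrow(as.data.frame(rows)) == 0L)
    stop("metrics table is empty: nothing to write")
  rows <- as.data.frame(rows)
  wanted <- c(id_columns(), metric_columns())
  missing_cols <- setdiff(wanted, names(rows))
  if (length(missing_cols))
    stop("metrics rows lack column(s): ", paste(missing_cols, collapse = ", "))
  utils::write.csv(rows[, wanted], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_metrics_table
#' @export
read_metrics_table <- function(path) {
  dat <- utils::read.csv(path, check.names = FALSE,
                         colClasses = c(fly_id = "character",
                                        strain = "character",
                                        replicate = "character"))
  missing_cols <- setdiff(c(id_columns(), metric_columns()), names(dat))
  if (length(missing_cols))
    stop("metrics table ", path, " lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  dat
}
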