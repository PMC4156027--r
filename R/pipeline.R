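# End-to-end orchestration: read a directory of trajectory/metadata file
# pairs (or write one from the simulator), compute per-fly metrics, filter
# outliers, run the PCA/ANOVA/Tukey stage, and emit a report bundle.

#' Run the full analysis pipeline on a directory of fly files
#'
#' Expects one `<fly_id>.csv` trajectory and one `<fly_id>.yaml` metadata
#' file per fly (see [read_trajectory()] for the dialect). The pipeline is
#' a pure function of the input files and configuration: read ->
#' kinematics -> twelve metrics per fly -> activity-outlier filter -> PCA
#' -> Shapiro gate -> two-way ANOVA + Tukey HSD -> strain grouping.
#' Files that fail to parse are logged and skipped, never silently
#' dropped.
#'
#' @param input_dir directory of trajectory/metadata pairs
#' @param arena an [arena_config()]
#' @param out_dir output directory (created if needed); `NULL` skips all
#'   file output and just returns the bundle
#' @param min_distance_per_min outlier threshold, mm/min (default 50)
#' @param component principal component to test (default 2)
#' @param immobility_speed_mm_s walking/sitting cutoff, mm/s
#' @param min_pause_s minimal pause duration, s
#' @param bin_size_mm,sigma_bins occupancy-map geometry (see [occupancy()])
#' @param write_maps write per-strain pooled occupancy CSVs and PNGs
#' @return (invisibly) a list: `metrics`, `filter` (kept/excluded),
#'   `pca`, `anova`, `grouping`, `boxplots`, `pc_summary` (per-strain
#'   mean and SEM of PC1-PC3, replicates pooled), `warnings`, `skipped`
#' @export
run_analysis <- function(input_dir, arena = arena_config(), out_dir = NULL,
                         min_distance_per_min = 50, component = 2,
                         immobility_speed_mm_s = 1, min_pause_s = 1,
                         bin_size_mm = 2, sigma_bins = 1,
                         write_maps = TRUE) {
  data_files <- sort(list.files(input_dir, pattern = "\\.csv$",
                                full.names = TRUE))
  data_files <- data_files[basename(data_files) != "metrics.csv"]
  if (!length(data_files)) stop("no trajectory files (*.csv) in ", input_dir)

  log_lines <- character()
  note <- function(...) {
    line <- sprintf(...)
    log_lines <<- c(log_lines, line)
    message(line)
  }
  note("buridan %s analysis of %s (%d candidate flies)",
       as.character(utils::packageVersion("buridan")), input_dir,
       length(data_files))

  warns <- character()
  skipped <- character()
  metrics <- list()
  maps <- list()
  for (df in data_files) {
    meta_path <- sub("\\.csv$", ".yaml", df)
    res <- tryCatch({
      withCallingHandlers({
        traj <- read_trajectory(df, meta_path, arena)
        steps <- compute_steps(traj, immobility_speed_mm_s)
        row <- compute_all_metrics(traj, arena, immobility_speed_mm_s,
                                   min_pause_s)
        map <- occupancy(traj, steps, arena, bin_size_mm, sigma_bins)
        list(row = row, map = map)
      }, warning = function(w) {
        warns <<- c(warns, sprintf("%s: %s", basename(df), conditionMessage(w)))
        invokeRestart("muffleWarning")
      })
    }, error = function(e) e)
    if (inherits(res, "error")) {
      skipped <- c(skipped, basename(df))
      note("SKIP %s: %s", basename(df), conditionMessage(res))
      next
    }
    metrics[[df]] <- res$row
    key <- paste(res$row$strain, res$row$replicate, sep = "_")
    maps[[key]] <- c(maps[[key]], list(res$map))
  }
  if (!length(metrics)) stop("no valid flies in ", input_dir)
  metrics <- do.call(rbind, c(metrics, make.row.names = FALSE))
  note("%d fly/flies analyzed, %d skipped, %d warning(s)",
       nrow(metrics), length(skipped), length(warns))

  filt <- filter_outliers(metrics, min_distance_per_min)
  for (r in filt$reasons) note("%s", r)
  note("%d data point(s) excluded by the %g mm/min activity filter",
       nrow(filt$excluded), min_distance_per_min)

  pca <- NULL; anova <- NULL; grouping <- NULL; boxplots <- NULL
  pc_summary <- NULL
  enough <- nrow(filt$kept) >= 3 &&
    length(unique(filt$kept$strain)) >= 2 &&
    all(table(filt$kept$strain, filt$kept$replicate) >= 2)
  if (enough) {
    stat_err <- tryCatch({
      pca <- withCallingHandlers(run_pca(filt$kept), warning = function(w) {
        warns <<- c(warns, conditionMessage(w)); invokeRestart("muffleWarning")
      })
      anova <- withCallingHandlers(anova_on_component(pca, component),
        warning = function(w) {
          warns <<- c(warns, conditionMessage(w)); invokeRestart("muffleWarning")
        })
      grouping <- grouping_summary(anova)
      NULL
    }, error = function(e) conditionMessage(e))
    if (is.null(stat_err)) {
      note("Shapiro p: %s", paste(sprintf("%s=%.3g", names(anova$shapiro_p),
                                          anova$shapiro_p), collapse = ", "))
      note("strain groups: %s",
           paste(sprintf("%s=%s", names(grouping$letters), grouping$letters),
                 collapse = " "))
      boxplots <- rbind(
        cbind(quantity = "stripe_deviation",
              boxplot_summary(filt$kept$stripe_deviation, filt$kept$strain)),
        cbind(quantity = anova$component,
              boxplot_summary(pca$scores[[anova$component]],
                              pca$scores$strain)))
      # per-strain mean +/- SEM of the leading components (replicates
      # pooled), the numbers behind a PC cross plot
      npc <- min(3, sum(grepl("^PC\\d+$", names(pca$scores))))
      pc_summary <- do.call(rbind, lapply(paste0("PC", seq_len(npc)),
        function(pc) {
          v <- split(pca$scores[[pc]], pca$scores$strain)
          data.frame(component = pc, strain = names(v),
                     mean = vapply(v, mean, numeric(1)),
                     sem = vapply(v, function(x)
                       stats::sd(x) / sqrt(length(x)), numeric(1)),
                     n = lengths(v), row.names = NULL)
        }))
    } else {
      pca <- NULL; anova <- NULL; grouping <- NULL; pc_summary <- NULL
      note("statistical stage skipped: %s", stat_err)
    }
  } else {
    note("statistical stage skipped: fewer than 2 flies per strain x replicate cell")
  }

  bundle <- list(metrics = metrics, filter = filt, pca = pca, anova = anova,
                 grouping = grouping, boxplots = boxplots,
                 pc_summary = pc_summary,
                 warnings = warns, skipped = skipped, log = log_lines)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_metrics_table(metrics, file.path(out_dir, "metrics.csv"))
    if (!is.null(pca)) {
      jsonlite::write_json(list(
        explained_variance_fraction = pca$explained_variance_fraction,
        loadings = as.data.frame(pca$loadings),
        scores = pca$scores), file.path(out_dir, "pca.json"),
        auto_unbox = TRUE, digits = NA)
      jsonlite::write_json(list(
        component = anova$component, shapiro_p = as.list(anova$shapiro_p),
        normality_ok = anova$normality_ok, anova = anova$anova_table,
        tukey = anova$tukey, groups = grouping$letters,
        n_excluded = nrow(filt$excluded), exclusions = filt$reasons,
        warnings = warns), file.path(out_dir, "anova.json"),
        auto_unbox = TRUE, digits = NA)
      utils::write.csv(boxplots, file.path(out_dir, "boxplot_data.csv"),
                       row.names = FALSE)
      utils::write.csv(pc_summary, file.path(out_dir, "pc_means.csv"),
                       row.names = FALSE)
    }
    if (write_maps) {
      for (key in names(maps)) {
        pooled <- render_levels(pool_occupancy(maps[[key]]))
        write_occupancy(pooled, file.path(out_dir,
                                          paste0("occupancy_", key, ".csv")))
        plot(pooled, file = file.path(out_dir,
                                      paste0("occupancy_", key, ".png")),
             main = key)
      }
    }
    writeLines(log_lines, file.path(out_dir, "run.log"))
  }
  invisible(bundle)
}

#' Read a study specification from YAML
#'
#' The file maps strain names to [fly_model_params()] fields plus
#' `n_flies` and optional `replicate_shift`:
#' ```yaml
#' CS_TP: {fixation_strength: 0.7, n_flies: 12}
#' CS_BS: {fixation_strength: 0.15, n_flies: 12}
#' ```
#' @param path YAML file path
#' @return a list of [strain_spec()]s
#' @export
read_strain_spec <- function(path) {
  vals <- yaml::read_yaml(path)
  if (!length(vals)) stop("study specification ", path, " is empty")
  lapply(names(vals), function(nm) {
    v <- vals[[nm]]
    n_flies <- if (is.null(v$n_flies)) 12 else v$n_flies
    shift <- if (is.null(v$replicate_shift))
      list(mean_speed_mm_s = 1) else v$replicate_shift
    v$n_flies <- NULL; v$replicate_shift <- NULL
    bad <- setdiff(names(v), names(formals(fly_model_params)))
    if (length(bad))
      stop("unknown parameter(s) for strain ", nm, ": ",
           paste(bad, collapse = ", "))
    strain_spec(nm, do.call(fly_model_params, v), n_flies, shift)
  })
}

#' Simulate a study and write it as a directory of fly files
#'
#' @param spec a list of [strain_spec()]s, or a path to a YAML study
#'   specification (see [read_strain_spec()])
#' @param out_dir output directory
#' @param seed master seed
#' @param arena an [arena_config()]
#' @return (invisibly) the manifest data frame (fly_id, strain, replicate,
#'   seed, files), which is also written as `manifest.json`
#' @export
run_simulate <- function(spec, out_dir, seed = 1, arena = arena_config()) {
  if (is.character(spec)) spec <- read_strain_spec(spec)
  flies <- simulate_study(spec, seed = seed, arena = arena)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- lapply(flies, function(traj) {
    meta <- traj_meta(traj)
    data_path <- file.path(out_dir, paste0(meta$fly_id, ".csv"))
    write_trajectory(traj, data_path, sub("\\.csv$", ".yaml", data_path))
    data.frame(fly_id = meta$fly_id, strain = meta$strain,
               replicate = meta$replicate,
               data_file = basename(data_path),
               meta_file = paste0(meta$fly_id, ".yaml"))
  })
  manifest <- do.call(rbind, c(manifest, make.row.names = FALSE))
  manifest$master_seed <- seed
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
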