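# Statistical stage: activity-outlier filtering, correlation-matrix PCA
# over the twelve metrics, Shapiro-gated two-way ANOVA on a principal
# component, Tukey HSD contrasts, and a compact-letter grouping of strains.

#' Exclude low-activity outlier flies
#'
#' Flies whose mean distance travelled is smaller than
#' `min_distance_per_min` are excluded ("smaller than" is strict: a fly at
#' exactly the threshold is kept).
#'
#' @param rows a metrics data frame with a `distance_per_min` column
#' @param min_distance_per_min threshold in mm/min (default 50)
#' @return a list with `kept` (data frame), `excluded` (data frame) and
#'   `reasons` (character, one per excluded fly)
#' @export
filter_outliers <- function(rows, min_distance_per_min = 50) {
  rows <- as.data.frame(rows)
  if (is.null(rows$distance_per_min))
    stop("metrics rows lack a distance_per_min column")
  drop <- rows$distance_per_min < min_distance_per_min
  drop[is.na(drop)] <- TRUE
  reasons <- sprintf("fly %s excluded: distance %.1f mm/min < %g mm/min",
                     rows$fly_id[drop], rows$distance_per_min[drop],
                     min_distance_per_min)
  list(kept = rows[!drop, , drop = FALSE],
       excluded = rows[drop, , drop = FALSE],
       reasons = reasons)
}

#' Principal component analysis of the twelve locomotor metrics
#'
#' Metrics are centered and, by default, scaled to unit variance before
#' the eigendecomposition (correlation-matrix PCA): the twelve parameters
#' carry incommensurable units (mm/s, counts, proportions, degrees), so
#' unscaled PCA would be dominated by whichever metric has the largest
#' numeric range. Covariance-matrix PCA is available via `scale. = FALSE`
#' for sensitivity analysis. Rows containing NaN in any metric are dropped
#' with a warning, as are zero-variance metric columns (which cannot be
#' scaled). Component signs are fixed by making the largest-magnitude
#' loading of each component positive.
#'
#' @param rows a metrics data frame (identifier columns + the twelve
#'   metrics)
#' @param scale. scale metrics to unit variance (default `TRUE`)
#' @return an object of class `buridan_pca`: `scores` (data frame with
#'   identifiers and `PC1..PCk`), `loadings` (metrics x components
#'   matrix), `explained_variance_fraction`, and the scaling record
#' @export
run_pca <- function(rows, scale. = TRUE) {
  rows <- as.data.frame(rows)
  mcols <- intersect(metric_columns(), names(rows))
  if (length(mcols) < 2L) stop("metrics table lacks the metric columns")
  m <- as.matrix(rows[, mcols])
  ok <- stats::complete.cases(m) & apply(is.finite(m), 1, all)
  if (!all(ok)) {
    warning(sum(!ok), " fly/flies with undefined metrics dropped before PCA",
            call. = FALSE)
    rows <- rows[ok, , drop = FALSE]
    m <- m[ok, , drop = FALSE]
  }
  if (nrow(m) < 3L) stop("PCA needs at least 3 flies with complete metrics")
  v <- apply(m, 2, stats::var)
  if (any(v == 0)) {
    warning("constant metric column(s) dropped: ",
            paste(colnames(m)[v == 0], collapse = ", "), call. = FALSE)
    m <- m[, v > 0, drop = FALSE]
  }
  pc <- stats::prcomp(m, center = TRUE, scale. = scale.)
  # fix signs: largest-|loading| entry of each component positive
  for (j in seq_len(ncol(pc$rotation))) {
    i <- which.max(abs(pc$rotation[, j]))
    if (pc$rotation[i, j] < 0) {
      pc$rotation[, j] <- -pc$rotation[, j]
      pc$x[, j] <- -pc$x[, j]
    }
  }
  scores <- cbind(rows[, intersect(id_columns(), names(rows)), drop = FALSE],
                  as.data.frame(pc$x))
  rownames(scores) <- NULL
  res <- list(scores = scores,
              loadings = pc$rotation,
              explained_variance_fraction = pc$sdev^2 / sum(pc$sdev^2),
              scaling = list(center = pc$center,
                             scale = if (scale.) pc$scale else NULL),
              metrics_used = colnames(m))
  class(res) <- "buridan_pca"
  res
}

#' @export
print.buridan_pca <- function(x, ...) {
  ev <- x$explained_variance_fraction
  cat(sprintf("PCA over %d metrics, %d flies\n", nrow(x$loadings),
              nrow(x$scores)))
  cat("  explained variance:",
      paste(sprintf("PC%d %.1f%%", seq_len(min(4, length(ev))),
                    100 * ev[seq_len(min(4, length(ev)))]), collapse = ", "),
      "\n")
  invisible(x)
}

#' Normality-gated two-way ANOVA on a principal component
#'
#' Shapiro-Wilk normality is assessed for the first three components and
#' recorded; a non-normal chosen component triggers a prominent warning
#' (the classical analysis tests only a component that passes the gate).
#' The chosen component's scores are then analyzed with a two-way
#' fixed-effects ANOVA (strain, replicate and their interaction; Type II
#' sums of squares), followed by Tukey HSD contrasts over strains.
#'
#' @param pca a [run_pca()] result
#' @param component which component to test (default 2)
#' @param alpha significance level for the normality gate warning
#' @return an object of class `buridan_anova`: `component`, `shapiro_p`
#'   (named vector over PC1..PC3), `anova_table` (effect, df, F, p),
#'   `tukey` (pairwise strain contrasts with adjusted p), and
#'   `normality_ok` for the chosen component
#' @export
anova_on_component <- function(pca, component = 2, alpha = 0.05) {
  stopifnot(inherits(pca, "buridan_pca"))
  sc <- pca$scores
  if (is.null(sc$strain) || is.null(sc$replicate) ||
      !all(nzchar(sc$strain)) || !all(nzchar(sc$replicate)))
    stop("ANOVA requires strain and replicate labels for every fly")
  pc_name <- paste0("PC", component)
  if (is.null(sc[[pc_name]])) stop("no such component: ", pc_name)

  cells <- table(sc$strain, sc$replicate)
  if (any(cells < 2)) {
    bad <- which(cells < 2, arr.ind = TRUE)[1, ]
    stop(sprintf("cell %s x %s has fewer than 2 flies",
                 rownames(cells)[bad[1]], colnames(cells)[bad[2]]))
  }

  ncomp <- sum(grepl("^PC\\d+$", names(sc)))
  test_pcs <- paste0("PC", seq_len(min(3, ncomp)))
  shapiro_p <- vapply(test_pcs,
                      function(p) stats::shapiro.test(sc[[p]])$p.value,
                      numeric(1))
  normality_ok <- shapiro_p[pc_name] >= alpha
  if (!is.na(normality_ok) && !normality_ok)
    warning(sprintf(
      "%s fails the Shapiro normality gate (p = %.3g); ANOVA on it is reported but suspect",
      pc_name, shapiro_p[pc_name]), call. = FALSE)

  dat <- data.frame(score = sc[[pc_name]],
                    strain = factor(sc$strain),
                    replicate = factor(sc$replicate))
  # with a single replicate the design collapses to a one-way ANOVA
  fit <- if (nlevels(dat$replicate) > 1L)
    stats::aov(score ~ strain * replicate, data = dat)
  else stats::aov(score ~ strain, data = dat)
  a2 <- car::Anova(fit, type = 2)
  eff <- rownames(a2)
  keep <- eff != "Residuals"
  anova_table <- data.frame(effect = trimws(eff[keep]),
                            df = a2$Df[keep],
                            F = a2$`F value`[keep],
                            p = a2$`Pr(>F)`[keep])
  tk <- stats::TukeyHSD(fit, which = "strain")$strain
  tukey <- data.frame(contrast = rownames(tk),
                      diff = tk[, "diff"], lwr = tk[, "lwr"],
                      upr = tk[, "upr"], p_adj = tk[, "p adj"])
  rownames(tukey) <- NULL

  res <- list(component = pc_name, shapiro_p = shapiro_p,
              normality_ok = unname(normality_ok),
              anova_table = anova_table, tukey = tukey,
              strains = levels(dat$strain))
  class(res) <- "buridan_anova"
  res
}

#' @export
print.buridan_anova <- function(x, ...) {
  cat("Two-way ANOVA on", x$component,
      if (isTRUE(x$normality_ok)) "(normality gate passed)"
      else "(NORMALITY GATE FAILED)", "\n")
  print(x$anova_table, row.names = FALSE, digits = 4)
  cat("Tukey HSD strain contrasts:\n")
  print(x$tukey, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Group strains by their Tukey HSD contrasts
#'
#' Strains are merged into groups whenever their pairwise contrast is not
#' significant, using a compact-letter display (insert-and-absorb): each
#' letter marks a maximal set of strains with no significant difference
#' inside it. When the significance pattern is transitive the letters are
#' disjoint groups; non-transitive patterns yield overlapping letters and
#' are reported as such rather than forced into a partition.
#'
#' @param report a [anova_on_component()] result
#' @param alpha significance level on the Tukey-adjusted p (default 0.05)
#' @return a list with `letters` (named character vector, one letter
#'   string per strain), `groups` (list of strain sets, one per letter),
#'   `n_groups`, and `disjoint` (TRUE when the letters partition the
#'   strains)
#' @export
grouping_summary <- function(report, alpha = 0.05) {
  stopifnot(inherits(report, "buridan_anova"))
  strains <- report$strains
  sig <- report$tukey$p_adj < alpha
  pairs <- strsplit(report$tukey$contrast, "-", fixed = TRUE)

  sets <- list(strains)
  for (k in which(sig)) {
    a <- pairs[[k]][1]; b <- pairs[[k]][2]
    new_sets <- list()
    for (s in sets) {
      if (a %in% s && b %in% s) {
        new_sets <- c(new_sets, list(setdiff(s, a)), list(setdiff(s, b)))
      } else new_sets <- c(new_sets, list(s))
    }
    # absorb duplicates and proper subsets
    new_sets <- unique(lapply(new_sets[lengths(new_sets) > 0], sort))
    keep <- vapply(seq_along(new_sets), function(i) {
      !any(vapply(seq_along(new_sets), function(j)
        j != i && length(new_sets[[j]]) > length(new_sets[[i]]) &&
          all(new_sets[[i]] %in% new_sets[[j]]), logical(1)))
    }, logical(1))
    sets <- new_sets[keep]
  }
  sets <- sets[order(vapply(sets, function(s) min(match(s, strains)), 1))]
  lett <- letters[seq_along(sets)]
  assignment <- vapply(strains, function(s)
    paste(lett[vapply(sets, function(g) s %in% g, TRUE)], collapse = ""),
    character(1))
  disjoint <- all(nchar(assignment) == 1L)
  list(letters = assignment, groups = stats::setNames(sets, lett),
       n_groups = length(sets), disjoint = disjoint)
}

#' Per-strain boxplot summaries of a metric or component
#'
#' Median, quartiles, Tukey whiskers (last observation within 1.5 IQR of
#' the box) and the 10th/90th percentiles, per strain — the numbers behind
#' a per-strain boxplot figure.
#'
#' @param values numeric vector
#' @param strain strain label per value
#' @return a data frame, one row per strain
#' @export
boxplot_summary <- function(values, strain) {
  stats_one <- function(v) {
    v <- v[is.finite(v)]
    q <- stats::quantile(v, c(0.1, 0.25, 0.5, 0.75, 0.9), names = FALSE)
    iqr <- q[4] - q[2]
    lo <- min(v[v >= q[2] - 1.5 * iqr]); hi <- max(v[v <= q[4] + 1.5 * iqr])
    c(n = length(v), p10 = q[1], q1 = q[2], median = q[3], q3 = q[4],
      p90 = q[5], whisker_lo = lo, whisker_hi = hi)
  }
  out <- t(vapply(split(values, strain), stats_one, numeric(8)))
  data.frame(strain = rownames(out), out, row.names = NULL)
}
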