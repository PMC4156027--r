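# helper: wrap hand-made component scores in the PCA result structure so
# the ANOVA stage can be exercised with exactly known inputs
fake_pca <- function(scores_df) {
  structure(list(scores = scores_df, loadings = NULL,
                 explained_variance_fraction = NA, scaling = NULL),
            class = "buridan_pca")
}

test_that("the activity filter is strict at the 50 mm/min boundary", {
  rows <- data.frame(fly_id = c("a", "b", "c"),
                     distance_per_min = c(49.9, 50.0, 120))
  out <- filter_outliers(rows)
  expect_equal(out$excluded$fly_id, "a")
  expect_equal(out$kept$fly_id, c("b", "c"))
  expect_match(out$reasons, "49.9")
})

test_that("PCA standardizes metrics and fixes component signs", {
  # one dominant planted axis of variation
  set.seed(61)
  n <- 40
  axis <- rnorm(n, sd = 10)
  m <- sapply(1:12, function(j) axis + rnorm(n, sd = 0.5))
  colnames(m) <- metric_columns()
  rows <- data.frame(fly_id = as.character(1:n), strain = "S",
                     replicate = "1", m)
  pca <- run_pca(rows)
  expect_gt(pca$explained_variance_fraction[1], 0.9)
  expect_true(all(diff(pca$explained_variance_fraction) <= 1e-12))
  expect_lte(sum(pca$explained_variance_fraction), 1 + 1e-9)

  # unit-variance scaling makes scores invariant to metric units
  rows2 <- rows
  rows2$median_speed <- rows2$median_speed * 1000
  pca2 <- run_pca(rows2)
  expect_equal(pca2$scores$PC1, pca$scores$PC1, tolerance = 1e-9)

  # sign convention: the largest loading of each component is positive
  for (j in seq_len(ncol(pca$loadings)))
    expect_gt(pca$loadings[which.max(abs(pca$loadings[, j])), j], 0)

  # loadings columns are orthonormal
  expect_equal(crossprod(pca$loadings), diag(ncol(pca$loadings)),
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("PCA agrees with an independent eigendecomposition and reconstructs the data", {
  set.seed(62)
  m <- matrix(rnorm(10 * 12), 10, 12, dimnames = list(NULL, metric_columns()))
  rows <- data.frame(fly_id = as.character(1:10), strain = "S",
                     replicate = "1", m)
  pca <- run_pca(rows)

  # oracle: eigendecomposition of the correlation matrix
  eig <- eigen(stats::cor(m), symmetric = TRUE)
  k <- 9  # with 10 flies the last centered component is degenerate
  expect_equal(pca$explained_variance_fraction[1:k],
               (eig$values / sum(eig$values))[1:k], tolerance = 1e-8)
  for (j in 1:k)
    expect_equal(abs(pca$loadings[, j]), abs(eig$vectors[, j]),
                 tolerance = 1e-6, ignore_attr = TRUE)

  # scores x loadings^T reproduces the standardized metrics
  z <- scale(m)
  rec <- as.matrix(pca$scores[, paste0("PC", 1:10)]) %*% t(pca$loadings)
  expect_equal(rec, unclass(z), tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("PCA drops incomplete flies and constant columns with warnings", {
  set.seed(63)
  m <- matrix(rnorm(8 * 12), 8, 12, dimnames = list(NULL, metric_columns()))
  rows <- data.frame(fly_id = as.character(1:8), strain = "S",
                     replicate = "1", m)
  rows$turning_angle[3] <- NaN
  rows$n_walks <- 0
  expect_warning(expect_warning(pca <- run_pca(rows), "dropped before PCA"),
                 "constant metric")
  expect_equal(nrow(pca$scores), 7)
  expect_false("n_walks" %in% rownames(pca$loadings))
})

test_that("two-group ANOVA F equals the squared pooled-variance t statistic", {
  set.seed(64)
  scores <- data.frame(fly_id = as.character(1:24),
                       strain = rep(c("A", "B"), each = 12),
                       replicate = "1",
                       PC1 = c(rnorm(12), rnorm(12, mean = 1)))
  rep_av <- anova_on_component(fake_pca(scores), component = 1)
  tt <- t.test(PC1 ~ strain, data = scores, var.equal = TRUE)
  expect_equal(rep_av$anova_table$F[rep_av$anova_table$effect == "strain"],
               unname(tt$statistic)^2, tolerance = 1e-9)
})

test_that("identical group means with residual variance give F = 0", {
  cell <- c(-2, -1, 1, 2)
  scores <- data.frame(fly_id = as.character(1:16),
                       strain = rep(c("A", "B"), each = 8),
                       replicate = rep(c("r1", "r2", "r1", "r2"), each = 4),
                       PC1 = rep(cell, 4))
  rep_av <- suppressWarnings(anova_on_component(fake_pca(scores), 1))
  expect_equal(rep_av$anova_table$F, rep(0, 3), tolerance = 1e-12)
})

test_that("the normality gate flags non-normal components and empty cells error", {
  set.seed(65)
  scores <- data.frame(fly_id = as.character(1:40),
                       strain = rep(c("A", "B"), each = 20),
                       replicate = rep(c("r1", "r2"), 20),
                       PC1 = exp(rnorm(40, sd = 2)))  # clearly non-normal
  expect_warning(rep_av <- anova_on_component(fake_pca(scores), 1),
                 "Shapiro normality gate")
  expect_false(rep_av$normality_ok)

  scores$replicate <- "r1"
  scores$replicate[1] <- "r2"
  expect_error(anova_on_component(fake_pca(scores), 1), "fewer than 2 flies")
})

test_that("Tukey grouping recovers planted structure and handles the edge patterns", {
  m <- simulate_metrics_table(group = c(1, 1, 2, 3, 3), seed = 71)
  pca <- run_pca(m)
  rep_av <- suppressWarnings(anova_on_component(pca, 1))
  g <- grouping_summary(rep_av)
  expect_equal(g$n_groups, 3)
  expect_true(g$disjoint)
  expect_equal(g$letters[["CS_TP"]], g$letters[["CS_TZ"]])
  expect_equal(g$letters[["CS_BS"]], g$letters[["CS_HS"]])
  expect_false(g$letters[["CS_JC"]] %in%
                 c(g$letters[["CS_TP"]], g$letters[["CS_BS"]]))

  strains <- c("A", "B", "C")
  pair_report <- function(p_adj) {
    structure(list(strains = strains,
                   tukey = data.frame(contrast = c("B-A", "C-A", "C-B"),
                                      p_adj = p_adj)),
              class = "buridan_anova")
  }
  all_sig <- grouping_summary(pair_report(c(0.001, 0.001, 0.001)))
  expect_equal(all_sig$n_groups, 3)
  none_sig <- grouping_summary(pair_report(c(0.9, 0.3, 0.8)))
  expect_equal(none_sig$n_groups, 1)

  # non-transitive pattern: A~B, B~C but A|C -> overlapping letters for B
  overlap <- grouping_summary(pair_report(c(0.5, 0.01, 0.5)))
  expect_false(overlap$disjoint)
  expect_equal(nchar(overlap$letters[["B"]]), 2)
})

test_that("per-strain boxplot summaries carry quartiles and both whisker variants", {
  set.seed(66)
  v <- rnorm(60); s <- rep(c("A", "B", "C"), each = 20)
  bs <- boxplot_summary(v, s)
  expect_equal(nrow(bs), 3)
  expect_true(all(bs$q1 <= bs$median & bs$median <= bs$q3))
  expect_true(all(bs$whisker_lo <= bs$q1 & bs$q3 <= bs$whisker_hi))
  expect_true(all(bs$p10 <= bs$median & bs$median <= bs$p90))
  expect_equal(bs$median[bs$strain == "A"], median(v[s == "A"]))
})
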