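test_that("the voxel-wise t map matches the textbook formula and its
          symmetries", {
  set.seed(41)
  a <- matrix(rnorm(5 * 4), 5, 4)
  b <- matrix(rnorm(5 * 4, 0.5), 5, 4)
  t_pkg <- tmap_independent(a, b)
  # brute-force pooled-variance two-sample t, voxel by voxel
  t_ref <- vapply(1:4, function(v) {
    sp2 <- (4 * var(a[, v]) + 4 * var(b[, v])) / 8
    (mean(a[, v]) - mean(b[, v])) / sqrt(sp2 * (1 / 5 + 1 / 5))
  }, numeric(1))
  expect_equal(t_pkg, t_ref, tolerance = 1e-12)
  expect_equal(tmap_independent(b, a), -t_pkg, tolerance = 1e-12)
  expect_equal(tmap_independent(a, a), rep(0, 4))
  expect_warning(tmap_independent(matrix(1, 3, 2), matrix(1, 3, 2)),
                 "zero pooled variance")
})

test_that("cluster definitions respect adjacency and sign", {
  d <- simulate_zmaps(3, 3, dim = c(3, 3, 1), seed = 1)
  t <- rep(0, 9)
  t[c(1, 2)] <- 3      # adjacent pair
  t[9] <- 3            # isolated voxel
  t[5] <- -4           # negative voxel between them
  cl <- amypower:::find_clusters(t, 2.5, d$adjacency)
  sizes <- sort(vapply(cl, function(c_) length(c_$voxels), integer(1)))
  expect_identical(sizes, c(1L, 1L, 2L))
  signs <- vapply(cl, `[[`, character(1), "sign")
  expect_identical(sum(signs == "+"), 2L)
  expect_identical(sum(signs == "-"), 1L)
  sums <- vapply(cl, `[[`, numeric(1), "sum_t")
  expect_true(any(abs(sums - 6) < 1e-12))
})

test_that("the permutation test finds a planted effect with a valid
          Monte-Carlo p", {
  blk <- central_block(c(6, 6, 6))
  d <- simulate_zmaps(20, 20, dim = c(6, 6, 6), effect_voxels = blk,
                      effect_size = 2, seed = 9)
  cfg <- stat_config(n_permutations = 500, seed = 13)
  res <- cluster_permutation_test(d$maps, d$labels, d$adjacency, cfg)
  expect_true(any(res$clusters$significant))
  best <- which.min(res$clusters$p_mc)
  # A+ has higher power, so the detected cluster is negative (A- minus A+)
  expect_identical(res$clusters$sign[best], "-")
  expect_gte(length(intersect(res$clusters$voxels[[best]], blk)),
             ceiling(length(blk) / 2))
  expect_true(all(res$clusters$p_mc >= 1 / 501))
  expect_true(all(res$clusters$p_mc <= 1))
  # threshold is the two-tailed critical t at cluster_alpha
  expect_equal(res$threshold_t, qt(1 - 0.05 / 2, 38), tolerance = 1e-12)
})

test_that("permuted labels on identical data give no significant
          clusters at the configured level", {
  d <- simulate_zmaps(12, 12, dim = c(5, 5, 4), seed = 21)
  cfg <- stat_config(n_permutations = 400, seed = 5)
  res <- cluster_permutation_test(d$maps, d$labels, d$adjacency, cfg)
  if (nrow(res$clusters)) expect_true(all(res$clusters$p_mc > 0.01))
})

test_that("bootstrap equalization subsamples without replacement and
          detects a strong effect", {
  blk <- central_block(c(6, 6, 6))
  d <- simulate_zmaps(40, 15, dim = c(6, 6, 6), effect_voxels = blk,
                      effect_size = 2, seed = 17)
  cfg <- stat_config(n_permutations = 200, n_bootstrap = 10, seed = 3)
  rel <- bootstrap_equalized_reliability(
    d$maps, d$labels, d$adjacency, cfg,
    effect_spec = list(sign = "-", roi_voxels = blk))
  expect_equal(rel$proportion, rel$replication_count / 10)
  expect_gte(rel$proportion, 0.8)
  expect_error(bootstrap_equalized_reliability(
    d$maps, d$labels, d$adjacency, cfg,
    effect_spec = list(sign = "-", roi_voxels = integer(0))),
    "non-empty")
})

test_that("amyloid classification applies the strict threshold rule", {
  expect_identical(as.character(classify_amyloid(c(0.79, 0.80, 0.50))),
                   c("A-", "A+", "A-"))
  expect_error(classify_amyloid(-0.2), "positive")
  expect_error(classify_amyloid(0), "positive")
})

test_that("vincentization yields equal-count bins in value order", {
  expect_identical(vincentize_quantiles(rev(seq_len(14)), 7)[14:1],
                   rep(1:7, each = 2))
  set.seed(51)
  v <- rnorm(272)
  bins <- vincentize_quantiles(v, 7)
  sizes <- as.integer(table(bins))
  expect_true(all(sizes %in% c(38L, 39L)))
  expect_identical(min(sizes), 38L)
  # bin order follows value order
  expect_true(all(diff(bins[order(v)]) >= 0))
  # permutation equivariance (tie-free values)
  perm <- sample(272)
  expect_identical(vincentize_quantiles(v[perm], 7), bins[perm])
  expect_error(vincentize_quantiles(rnorm(5), 7), "at least k")
})

test_that("the quantile ANOVA matches a brute-force decomposition and
          reports the Bonferroni factor", {
  vals <- c(2, 3, 4, 6, 7, 8, 1, 1, 2)
  bins <- rep(1:3, each = 3)
  res <- oneway_anova_bonferroni(vals, bins)
  # hand-computed sums of squares
  gm <- mean(vals)
  ssb <- sum(3 * (tapply(vals, bins, mean) - gm)^2)
  ssw <- sum((vals - rep(tapply(vals, bins, mean), each = 3))^2)
  F_ref <- (ssb / 2) / (ssw / 6)
  expect_equal(res$F, F_ref, tolerance = 1e-10)
  expect_equal(res$df, c(2, 6))
  expect_equal(res$eta_squared, ssb / (ssb + ssw), tolerance = 1e-12)
  expect_identical(nrow(res$pairwise), 3L)  # k(k-1)/2 pairs for k = 3
  expect_equal(res$pairwise$p_adj,
               pmin(1, res$pairwise$p_raw * 3), tolerance = 1e-12)
  # for k = 7 the factor is 21
  set.seed(52)
  res7 <- oneway_anova_bonferroni(rnorm(70), rep(1:7, each = 10))
  expect_identical(nrow(res7$pairwise), 21L)
  expect_error(oneway_anova_bonferroni(1:5, c(1, 1, 2, 2, 3)),
               ">= 2 subjects")
})

test_that("flat bin means give a small F at moderate n", {
  set.seed(53)
  F_null <- replicate(20, {
    oneway_anova_bonferroni(rnorm(70), rep(1:7, each = 10))$F
  })
  expect_lt(mean(F_null), 2)            # E[F] ~ 1 under the null
})

test_that("the power-on-memory regression recovers exact and planted
          slopes and dies on constant scores", {
  x <- seq_len(20)
  fit <- suppressWarnings(regress_power_on_score(2 * x + 1, x))
  expect_equal(fit$slope, 2, tolerance = 1e-12)
  expect_equal(fit$intercept, 1, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  set.seed(54)
  score <- rnorm(272, 45, 2)
  y <- -0.05 * score + rnorm(272)
  fit2 <- regress_power_on_score(y, score)
  expect_lt(abs(fit2$slope - (-0.05)), 2 * fit2$se_slope)
  # permuting the outcome destroys the association
  r2_perm <- replicate(100, {
    regress_power_on_score(sample(y), score)$r_squared
  })
  expect_lt(mean(r2_perm), 0.02)
  expect_error(regress_power_on_score(y, rep(1, 272)), "constant")
  # per-group fits are returned
  g <- rep(c("A-", "A+"), 136)
  bg <- regress_power_on_score(y, score, group = g)$by_group
  expect_setequal(names(bg), c("A-", "A+"))
})

test_that("the amyloid x APOE ANCOVA isolates a planted amyloid effect
          and ignores covariate centering", {
  set.seed(55)
  n <- 272
  meta <- data.frame(
    amyloid = rep(c("A-", "A+"), c(184, 88)),
    apoe_e4 = rbinom(n, 1, 0.2),
    sex = sample(c("F", "M"), n, replace = TRUE),
    age = runif(n, 70, 85))
  hits <- replicate(50, {
    y <- 0.5 * (meta$amyloid == "A+") + rnorm(n)
    tab <- ancova_amyloid_apoe(y, meta)$table
    c(amy = tab["amyloid", "Pr(>F)"] < 0.05,
      apoe = tab["apoe", "Pr(>F)"] > 0.05)
  })
  expect_gte(mean(hits["amy", ]), 0.9)
  expect_gte(mean(hits["apoe", ]), 0.9)
  y <- rnorm(n)
  t1 <- ancova_amyloid_apoe(y, meta)$table
  meta2 <- meta; meta2$age <- meta2$age + 100
  t2 <- ancova_amyloid_apoe(y, meta2)$table
  expect_equal(t1$`F value`, t2$`F value`, tolerance = 1e-9)
  # empty-cell error names the cell
  meta3 <- meta; meta3$apoe_e4[meta3$amyloid == "A+"] <- 0
  expect_error(ancova_amyloid_apoe(y, meta3), "A\\+ x 1")
})

test_that("null term p-values are uniform under a fully independent
          response", {
  set.seed(56)
  n <- 60
  meta <- data.frame(
    amyloid = rep(c("A-", "A+"), each = 30),
    apoe_e4 = rep(c(0, 1), 30),
    sex = sample(rep(c("F", "M"), each = 30)),
    age = runif(n, 70, 85))
  p_amy <- replicate(200, {
    ancova_amyloid_apoe(rnorm(n), meta)$table["amyloid", "Pr(>F)"]
  })
  expect_gt(ks.test(p_amy, "punif")$p.value, 0.01)
})

test_that("the Welch variant of the t map matches t.test", {
  set.seed(57)
  a <- matrix(rnorm(8 * 3), 8, 3)
  b <- matrix(rnorm(12 * 3, 0, 2), 12, 3)
  tw <- tmap_independent(a, b, welch = TRUE)
  t_ref <- vapply(1:3, function(v)
    unname(t.test(a[, v], b[, v])$statistic), numeric(1))
  expect_equal(tw, t_ref, tolerance = 1e-12)
})
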