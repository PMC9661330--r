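test_that("the theta dose-response rule evaluates exactly", {
  cfg <- short_config(effect_size = 2, theta_baseline = 1)
  expect_equal(theta_source_amplitude(cfg, 0.60), 1)    # below threshold
  expect_equal(theta_source_amplitude(cfg, 1.00), 1.42) # 1 + 2 * 0.21
  expect_equal(theta_source_amplitude(cfg, 0.79), 1)    # boundary
})

test_that("the generator is deterministic under a fixed seed", {
  cfg <- short_config(seed = 12)
  lf <- small_leadfield()
  r1 <- simulate_subject(cfg, lf, list(suvr = 0.85), seed = 99)
  r2 <- simulate_subject(cfg, lf, list(suvr = 0.85), seed = 99)
  expect_identical(r1$data, r2$data)
  c1 <- simulate_cohort(cfg, leadfield = lf, recordings = FALSE)
  c2 <- simulate_cohort(cfg, leadfield = lf, recordings = FALSE)
  expect_identical(c1$meta, c2$meta)
})

test_that("cohort metadata reproduces the requested group split exactly", {
  cfg <- sim_config(n_neg = 230, n_pos = 88, seed = 8)
  co <- simulate_cohort(cfg, leadfield = small_leadfield(),
                        recordings = FALSE)
  status <- classify_amyloid(co$meta$suvr)
  expect_identical(as.integer(table(status)), c(230L, 88L))
  expect_true(all(co$meta$age >= 70 & co$meta$age <= 85))
  expect_true(all(co$meta$fcsrt_tr >= 41))
  expect_error(simulate_cohort(sim_config(n_neg = 0, n_pos = 0)),
               "empty cohort")
})

test_that("recordings honour the run layout and plant the stated
          structure", {
  cfg <- short_config(seed = 3)
  lf <- small_leadfield()
  rec <- simulate_subject(cfg, lf, list(suvr = 0.60), seed = 3)
  expect_identical(rec$markers$condition, c("EC", "EO"))
  expect_equal(ncol(rec$data), 20 * 250)
  # posterior alpha is stronger during EC than EO
  post_ch <- which.min(lf$model$electrode_positions[, 2])
  ec <- condition_samples(rec, "EC")[post_ch, ]
  eo <- condition_samples(rec, "EO")[post_ch, ]
  expect_gt(voxel_band_power(ec, 250, 8, 13),
            voxel_band_power(eo, 250, 8, 13))
  # the EC posterior spectrum peaks inside the alpha range
  spec <- sapply(seq(2, 30, by = 1), function(f)
    voxel_band_power(ec, 250, f, f + 2))
  peak_f <- seq(2, 30, by = 1)[which.max(spec)] + 1
  expect_gte(peak_f, 8); expect_lte(peak_f, 13)
})

test_that("missing ROI labels are a configuration error", {
  lf <- small_leadfield()
  lf$roi[lf$roi == "mid_frontal"] <- "other"
  expect_error(simulate_subject(short_config(), lf, list(suvr = 1)),
               "mid_frontal")
  lf2 <- small_leadfield()
  expect_error(simulate_subject(short_config(), lf2, list(x = 1)),
               "suvr")
})

test_that("forward projection is linear in the source configuration", {
  lf <- small_leadfield()
  g1 <- lf$gain[5, , ]; g2 <- lf$gain[80, , ]
  q1 <- c(1, 0.5, -2); q2 <- c(-1, 1, 0)
  sum_proj <- as.vector(q1 %*% g1) + as.vector(q2 %*% g2)
  # stacking both dipoles into one configuration projects to the same
  combined <- as.vector(q1 %*% g1 + q2 %*% g2)
  expect_lt(max(abs(combined - sum_proj)) / max(abs(sum_proj)), 1e-9)
})

test_that("map-level generator plants the effect where asked and is
          reproducible", {
  blk <- central_block(c(10, 10, 10))
  expect_length(blk, 27L)
  d1 <- simulate_zmaps(15, 15, effect_voxels = blk, effect_size = 1,
                       seed = 4)
  d2 <- simulate_zmaps(15, 15, effect_voxels = blk, effect_size = 1,
                       seed = 4)
  expect_identical(d1$maps, d2$maps)
  shift <- mean(d1$maps[16:30, blk]) - mean(d1$maps[16:30, -blk])
  expect_gt(shift, 0.5)
  expect_identical(levels(d1$labels), c("A-", "A+"))
  expect_length(d1$adjacency, 1000L)
})

test_that("planted theta power rises with effect size (dose
          monotonicity)", {
  lf <- small_leadfield()
  mf <- which(lf$roi == "mid_frontal")
  theta_mean <- vapply(c(0, 0.5, 1, 2), function(es) {
    cfg <- short_config(effect_size = es, seed = 71, noise_sd = 0.2,
                        n_bad_channels = 0)
    vals <- vapply(1:3, function(i) {
      rec <- simulate_subject(cfg, lf, list(suvr = 1.1),
                              seed = 500 + i)
      cleaned <- suppressWarnings(preprocess_recording(rec))
      pcfg <- pipeline_config(simulate = list(n_neg = 1, n_pos = 1))
      m <- subject_source_power(cleaned, lf, pcfg)
      mean(m$relative[mf, "theta"])
    }, numeric(1))
    mean(vals)
  }, numeric(1))
  expect_true(all(diff(theta_mean) >= 0))
})
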