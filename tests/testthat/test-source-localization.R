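test_that("the default filter bank has the seven canonical bands and
          separates a pure tone", {
  b <- default_bands()
  expect_identical(nrow(b), 7L)
  expect_identical(b$name[2], "theta")
  expect_equal(b$f_lo, c(2, 4, 8, 10, 13, 20, 30))
  expect_equal(b$f_hi, c(4, 8, 10, 13, 20, 30, 40))
  # contiguous, non-overlapping
  expect_equal(b$f_hi[-7], b$f_lo[-1])

  fs <- 250
  tone <- sin(2 * pi * 6 * seq(1, 3000) / fs)
  rec <- eeg_recording(rbind(tone, tone), fs)
  out <- band_filter_bank(rec, b)
  expect_length(out, 7L)
  mid <- 1000:2000
  v <- vapply(out, function(r) var(r$data[1, mid]), numeric(1))
  expect_identical(names(which.max(v)), "theta")
  expect_gt(v["theta"], 10 * max(v[names(v) != "theta"]))
  expect_error(band_filter_bank(rec, data.frame()), "non-empty")
})

test_that("merged covariance is symmetric, PSD, and consistent", {
  set.seed(21)
  n <- 60 * 250
  ec <- matrix(rnorm(8 * n / 2), 8)
  eo <- matrix(rnorm(8 * n / 2), 8)
  C <- merged_covariance(ec, eo)
  expect_identical(C, t(C))
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-10 * sum(diag(C)) / 8)
  # unit-variance independent channels: diagonal near 1, off-diagonal near 0
  expect_lt(max(abs(diag(C) - 1)), 0.05)
  expect_lt(max(abs(C[upper.tri(C)])), 0.05)
  # merging a segment with itself reproduces its own covariance
  Cs <- merged_covariance(ec, ec)
  Xc <- ec - rowMeans(ec)
  expect_equal(Cs, tcrossprod(Xc) / (2 * ncol(ec) - 1) * 2,
               tolerance = 1e-10)
  expect_error(merged_covariance(ec, eo[1:5, ]), "mismatch")
})

test_that("unregularized LCMV filters satisfy unit gain at every voxel", {
  lf <- small_leadfield()
  set.seed(31)
  C <- merged_covariance(matrix(rnorm(16 * 5000), 16),
                         matrix(rnorm(16 * 5000), 16))
  filt <- lcmv_filters(lf, C, lambda_fraction = 0)
  dev <- vapply(seq_len(nrow(lf$grid)), function(v) {
    W3 <- filt$filters3[v, , ]
    L <- t(lf$gain[v, , ])
    max(abs(W3 %*% L - diag(3)))
  }, numeric(1))
  expect_lt(max(dev), 1e-6)
})

test_that("beamformer localizes a planted source and the scaling law
          holds", {
  lf <- small_leadfield()
  set.seed(32)
  v_true <- which.min(rowSums((lf$grid - c(24, 24, 24))^2))
  topo <- as.vector(c(0.2, 0.5, sqrt(1 - 0.29)) %*% lf$gain[v_true, , ])
  n <- 20000
  s <- rnorm(n)
  X <- outer(topo, s)
  X <- X + sd(topo %o% s) / sqrt(10) * matrix(rnorm(16 * n), 16)
  C <- tcrossprod(X - rowMeans(X)) / (n - 1)
  filt <- lcmv_filters(lf, C, lambda_fraction = 0.05)
  p <- beamformer_power(filt, C, normalize = "nai")
  v_peak <- which.max(p)
  step <- sqrt(sum((lf$grid[v_peak, ] - lf$grid[v_true, ])^2))
  expect_lte(step, lf$spacing + 1e-9)
  # scaling C by 5 leaves W L unchanged and scales power by 5
  filt5 <- lcmv_filters(lf, 5 * C, lambda_fraction = 0.05)
  p5 <- beamformer_power(filt5, 5 * C, normalize = "none")
  p1 <- beamformer_power(filt, C, normalize = "none")
  expect_equal(p5, 5 * p1, tolerance = 1e-8)
  expect_equal(abs(filt5$weights %*% topo), abs(filt$weights %*% topo),
               tolerance = 1e-8)
})

test_that("projection is linear, zero maps to zero, and reconstructs the
          planted source", {
  lf <- small_leadfield()
  set.seed(33)
  v_true <- 40
  topo <- as.vector(c(0, 1, 0) %*% lf$gain[v_true, , ])
  n <- 10000
  s <- as.vector(bandpass_fir(rnorm(n), 8, 13, fs = 250))
  X <- outer(topo, s) + sd(outer(topo, s)) / sqrt(10) *
    matrix(rnorm(16 * n), 16)
  C <- tcrossprod(X - rowMeans(X)) / (n - 1)
  filt <- lcmv_filters(lf, C)
  Y <- project_sources(X, filt)
  expect_identical(dim(Y), c(nrow(lf$grid), as.integer(n)))
  expect_gte(abs(cor(Y[v_true, ], s)), 0.9)
  expect_true(all(project_sources(matrix(0, 16, 5), filt) == 0))
  X2 <- matrix(rnorm(16 * 100), 16)
  X3 <- matrix(rnorm(16 * 100), 16)
  expect_lt(max(abs(project_sources(X2 + X3, filt) -
                      project_sources(X2, filt) -
                      project_sources(X3, filt))), 1e-9)
})

test_that("EC and EO projections share identical weights", {
  rec <- small_recording()
  cleaned <- suppressWarnings(preprocess_recording(rec))
  lf <- small_leadfield()
  good_names <- rec$channels[cleaned$good_channels]
  ec <- condition_samples(cleaned$recording, "EC", channels = good_names)
  eo <- condition_samples(cleaned$recording, "EO", channels = good_names)
  C <- merged_covariance(ec, eo)
  filt <- lcmv_filters(lf, C,
                       channels = match(good_names, lf$channels))
  proj <- project_sources(cleaned$recording, filt)
  expect_identical(sort(names(proj)), c("EC", "EO"))
  expect_equal(proj$EC, filt$weights %*% ec, tolerance = 1e-12)
  expect_equal(proj$EO, filt$weights %*% eo, tolerance = 1e-12)
})
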