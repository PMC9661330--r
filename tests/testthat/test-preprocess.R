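test_that("band-pass removes DC, passes the band, stops the stopband", {
  fs <- 250
  t <- seq(0, 12, by = 1 / fs)[-1]
  mid <- seq(round(length(t) * 0.3), round(length(t) * 0.7))
  # DC offset suppressed
  y <- bandpass_fir(rep(5, length(t)), 1, 80, fs = fs)
  expect_lt(mean(abs(y[mid])), 0.05)
  # 10 Hz tone passes at unit amplitude (within 2%)
  y <- bandpass_fir(sin(2 * pi * 10 * t), 1, 80, fs = fs)
  amp <- sqrt(2) * sqrt(mean(y[mid]^2))
  expect_lt(abs(amp - 1), 0.02)
  # 100 Hz tone attenuated by >= 20 dB
  y <- bandpass_fir(sin(2 * pi * 100 * t), 1, 80, fs = fs)
  att <- sqrt(mean(y[mid]^2)) / sqrt(0.5)
  expect_lt(att, 10^(-20 / 20))
  expect_error(bandpass_fir(y, 1, 130, fs = fs), "Nyquist")
})

test_that("filtering is linear and length-preserving", {
  fs <- 250
  set.seed(1)
  x <- rnorm(2000); y <- rnorm(2000)
  fx <- bandpass_fir(x, 4, 8, fs = fs)
  fy <- bandpass_fir(y, 4, 8, fs = fs)
  fxy <- bandpass_fir(2 * x - 3 * y, 4, 8, fs = fs)
  expect_equal(length(fx), length(x))
  expect_lt(max(abs(fxy - (2 * fx - 3 * fy))), 1e-9)
})

test_that("channel QC flags the planted artifactual channel and only it", {
  set.seed(11)
  x <- matrix(rnorm(21 * 2500), 21)
  x[13, ] <- 50 * rnorm(2500)
  rec <- eeg_recording(x, 250)
  qc <- detect_bad_channels(rec)
  expect_identical(which(qc$rejected), 13L)
  # z columns standardized across scalp channels
  for (z in list(qc$z_variance, qc$z_range, qc$z_min)) {
    expect_lt(abs(mean(z)), 1e-12)
    expect_lt(abs(sd(z) - 1), 1e-9)
  }
  # brute-force z of the variance metric agrees
  v <- apply(x, 1, var)
  expect_equal(qc$z_variance, (v - mean(v)) / sd(v), tolerance = 1e-12)
})

test_that("degenerate QC inputs follow the SD = 0 rule and the
          channel-count precondition", {
  x <- matrix(rep(sin(seq_len(500) / 10), each = 20), 20, byrow = FALSE)
  rec <- eeg_recording(x, 250)
  qc <- detect_bad_channels(rec)
  expect_identical(sum(qc$rejected), 0L)
  expect_true(all(qc$z_variance == 0))
  expect_error(detect_bad_channels(
    eeg_recording(matrix(rnorm(500), 1), 250)), "at least 3")
  # threshold is configurable
  set.seed(2)
  rec2 <- eeg_recording(matrix(rnorm(10 * 500), 10), 250)
  qc2 <- detect_bad_channels(rec2, z_threshold = 0.1)
  expect_gt(sum(qc2$rejected), 0L)
})

test_that("common-average reference zeroes the good-channel mean and is
          idempotent", {
  set.seed(3)
  rec <- eeg_recording(matrix(rnorm(6 * 400), 6), 250)
  # hand example: two good channels 3 and 1 become 1 and -1
  rec$data[1, 1] <- 3; rec$data[2, 1] <- 1
  out <- rereference_common_average(rec, good_channels = 1:2)
  expect_equal(out$data[1:2, 1], c(1, -1) + 0, ignore_attr = TRUE)
  gm <- colMeans(out$data[1:2, ])
  expect_lt(max(abs(gm)), 1e-12 * max(abs(rec$data)))
  twice <- rereference_common_average(out, good_channels = 1:2)
  expect_equal(twice$data, out$data, tolerance = 1e-14)
})

test_that("ICA removes exactly the planted blink component and keeps the
          energy budget", {
  rec <- small_recording()
  filt <- bandpass_fir(rec, 1, 80)
  reref <- rereference_common_average(filt)
  res <- suppressWarnings(remove_ocular_ica(reref, seed = 5))
  expect_length(res$report$removed_components, 1L)
  expect_true(max(abs(res$report$eog_correlations)) >= 0.8)
  # residual scalp-to-EOG correlation is small
  sc <- scalp_channels(rec)
  r_after <- abs(cor(t(res$recording$data[sc, ]),
                     t(res$recording$data[eog_channels(rec), ])))
  expect_lt(max(r_after), 0.3)
  # removed-subspace energy equals input-minus-output energy
  d_in <- reref$data[sc, ] - rowMeans(reref$data[sc, ])
  d_out <- res$recording$data[sc, ] - rowMeans(res$recording$data[sc, ])
  removed <- d_in - d_out
  expect_equal(sum(d_in^2) - sum(d_out^2), sum(removed^2),
               tolerance = 1e-6 * sum(d_in^2))
  expect_identical(dim(res$recording$data), dim(rec$data))
})

test_that("ICA is a no-op when nothing correlates with the EOG", {
  set.seed(9)
  x <- rbind(matrix(rnorm(8 * 3000), 8), matrix(rnorm(2 * 3000), 2))
  rec <- eeg_recording(x, 250, roles = c(rep("scalp", 8), "eog", "eog"))
  reref <- rereference_common_average(rec)
  res <- suppressWarnings(remove_ocular_ica(reref, seed = 4))
  expect_length(res$report$removed_components, 0L)
  expect_equal(res$recording$data, reref$data, tolerance = 1e-12)
})

test_that("the optional segment mask flags only high-amplitude
          segments", {
  set.seed(77)
  x <- matrix(rnorm(4 * 2500), 4)
  x[2, 1300:1320] <- 40                 # burst in the 6th 1 s segment
  rec <- eeg_recording(x, 250)
  keep <- segment_mask(rec, threshold_sd = 6)
  expect_length(keep, 10L)
  expect_false(keep[6])
  expect_true(all(keep[-6]))
})
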