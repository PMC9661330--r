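#' Simulation configuration
#'
#' Parameters of the synthetic cohort generator. Defaults emulate the study
#' conditions: 250 Hz sampling, two runs each made of a 30 s eyes-closed and
#' a 30 s eyes-open block, amyloid groups of 230 (A-) and 88 (A+) subjects,
#' an SUVr positivity threshold of 0.79, and a mid-frontal theta source
#' whose amplitude grows with supra-threshold SUVr.
#'
#' @param n_neg,n_pos subjects per amyloid group.
#' @param effect_size standardized theta-amplitude increment per unit SUVr
#'   above the threshold (source amplitude = baseline * (1 + effect_size *
#'   max(0, SUVr - suvr_threshold))).
#' @param suvr_threshold amyloid-positivity cutoff on SUVr.
#' @param fs sampling rate (Hz); must exceed twice the highest analysis
#'   band edge (40 Hz).
#' @param run_layout list of `c(condition, duration_s)` pairs defining the
#'   block sequence of one recording.
#' @param n_channels scalp montage size (two EOG channels are appended).
#' @param noise_sd sensor white-noise level, as a fraction of the median
#'   clean-signal channel SD.
#' @param blink_rate mean blink rate (events per second, Poisson arrivals).
#' @param n_bad_channels number of scalp channels replaced by
#'   high-variance noise.
#' @param n_background number of broadband background sources (capped at
#'   the voxel count; the default places one at every voxel, emulating
#'   spatially distributed resting activity).
#' @param theta_baseline,alpha_ec_amp,alpha_eo_amp source amplitudes
#'   (arbitrary moment units) of the planted rhythms; background sources
#'   have unit 1/f-weighted amplitude.
#' @param blink_amp,eog_gain blink source amplitude and its gain into the
#'   synthetic EOG channels.
#' @param anatomy_seed seed of the shared "anatomy" stream: source dipole
#'   orientations are drawn once from this stream and reused for every
#'   subject, emulating cohorts normalized to a common anatomical space
#'   (cortical geometry is shared; only activity differs across subjects).
#' @param seed master RNG seed; identical configurations give identical
#'   cohorts.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_neg = 230, n_pos = 88, effect_size = 2,
                       suvr_threshold = 0.79, fs = 250,
                       run_layout = default_run_layout(),
                       n_channels = 32, noise_sd = 0.3, blink_rate = 0.15,
                       n_bad_channels = 1, n_background = 1000,
                       theta_baseline = 0.7, alpha_ec_amp = 2.5,
                       alpha_eo_amp = 1.25, blink_amp = 40, eog_gain = 1,
                       anatomy_seed = 7321, seed = 1) {
  if (n_neg < 0 || n_pos < 0) stop("group counts must be >= 0")
  if (fs <= 2 * 40) stop("fs must exceed twice the highest band edge (40 Hz)")
  lay <- lapply(run_layout, function(x) {
    if (length(x) != 2L || !x[[1]] %in% c("EC", "EO") ||
        as.numeric(x[[2]]) <= 0)
      stop("run_layout entries must be list(condition, duration_s)")
    list(condition = x[[1]], duration_s = as.numeric(x[[2]]))
  })
  structure(list(
    n_neg = n_neg, n_pos = n_pos, effect_size = effect_size,
    suvr_threshold = suvr_threshold, fs = fs, run_layout = lay,
    n_channels = n_channels, noise_sd = noise_sd, blink_rate = blink_rate,
    n_bad_channels = n_bad_channels, n_background = n_background,
    theta_baseline = theta_baseline, alpha_ec_amp = alpha_ec_amp,
    alpha_eo_amp = alpha_eo_amp, blink_amp = blink_amp,
    eog_gain = eog_gain, anatomy_seed = as.integer(anatomy_seed),
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' @rdname sim_config
#' @export
default_run_layout <- function() {
  list(list("EC", 30), list("EO", 30), list("EC", 30), list("EO", 30))
}

#' Planted mid-frontal theta source amplitude
#'
#' The dose-response rule of the generator: the theta source amplitude is
#' flat at baseline below the SUVr threshold and rises linearly above it.
#'
#' @param config a [sim_config()].
#' @param suvr SUVr value(s).
#' @return numeric amplitude(s).
#' @export
theta_source_amplitude <- function(config, suvr) {
  config$theta_baseline *
    (1 + config$effect_size * pmax(0, suvr - config$suvr_threshold))
}

# Band-limited Gaussian noise via spectral masking: white noise whose FFT
# is zeroed outside [f_lo, f_hi). Returns n_series x n matrix with unit
# sample variance per row.
band_noise <- function(n_series, n, fs, f_lo, f_hi) {
  if (n_series == 0L) return(matrix(0, 0L, n))
  x <- matrix(stats::rnorm(n_series * n), n, n_series)
  f <- stats::mvfft(x)
  freq <- (seq_len(n) - 1L) * fs / n
  freq <- pmin(freq, fs - freq)                 # fold to [0, fs/2]
  keep <- freq >= f_lo & freq < f_hi
  f[!keep, ] <- 0
  y <- Re(stats::mvfft(f, inverse = TRUE)) / n
  y <- t(y)
  s <- sqrt(pmax(apply(y, 1L, stats::var), .Machine$double.eps))
  y / s
}

# Stereotyped biphasic blink waveform (unit peak), duration ~0.4 s.
blink_waveform <- function(fs) {
  t <- seq(0, 0.4, by = 1 / fs)
  w <- exp(-((t - 0.10) / 0.05)^2) - 0.4 * exp(-((t - 0.22) / 0.08)^2)
  w / max(abs(w))
}

#' Simulate one subject's sensor recording
#'
#' Generates a sensor-space EEG recording by forward-projecting planted
#' sources through the leadfield: broadband 1/f-weighted background sources
#' at random voxels, a posterior alpha source stronger during eyes-closed
#' blocks, a mid-frontal theta source whose amplitude follows
#' [theta_source_amplitude()] for the subject's SUVr, Poisson-arriving
#' biphasic blinks projected from a fixed anterior dipole (carried at high
#' gain by two appended EOG channels), white sensor noise, and a configured
#' number of scalp channels replaced by high-variance noise.
#'
#' @param config a [sim_config()].
#' @param leadfield a [make_leadfield()] result whose ROI labels include
#'   `mid_frontal` and `posterior`.
#' @param subject_meta one-row data.frame (or list) with at least `suvr`.
#' @param seed RNG seed for this subject.
#' @return an [eeg_recording()] with scalp + EOG channels and EC/EO markers.
#' @export
simulate_subject <- function(config, leadfield, subject_meta,
                             seed = config$seed) {
  stopifnot(inherits(config, "sim_config"), inherits(leadfield, "leadfield"))
  if (is.null(subject_meta$suvr)) stop("subject_meta must contain suvr")
  roi <- leadfield$roi
  if (!any(roi == "mid_frontal") || !any(roi == "posterior"))
    stop("leadfield must label mid_frontal and posterior ROIs")
  fs <- config$fs
  gain <- leadfield$gain
  n_ch <- dim(gain)[3L]
  bands <- default_bands()
  f_center <- (bands$f_lo + bands$f_hi) / 2

  rand_orient <- function(k) {
    v <- matrix(stats::rnorm(3 * k), k, 3)
    v / sqrt(rowSums(v^2))
  }
  topo_of <- function(vox, orient) {
    t(vapply(seq_along(vox), function(i)
      as.vector(orient[i, ] %*% gain[vox[i], , ]), numeric(n_ch)))
  }

  # shared anatomy: source positions and dipole orientations are common
  # to the whole cohort (subjects live in one normalized space); only the
  # activity time courses below are subject-specific
  set.seed(config$anatomy_seed)
  n_bg <- min(config$n_background, nrow(leadfield$grid))
  bg_vox <- sample(nrow(leadfield$grid), n_bg)
  bg_topo <- topo_of(bg_vox, rand_orient(n_bg))
  th_vox <- which(roi == "mid_frontal")
  th_topo <- topo_of(th_vox, rand_orient(length(th_vox)))
  po_vox <- which(roi == "posterior")
  po_topo <- topo_of(po_vox, rand_orient(length(po_vox)))
  set.seed(seed)

  theta_amp <- theta_source_amplitude(config, subject_meta$suvr)
  bg_amp <- 1 / sqrt(f_center / f_center[1L])   # 1/f power weighting

  # blink topography: fixed anterior-inferior dipole
  r1 <- leadfield$model$radii[1]
  S <- shell_transfer(leadfield$model$radii / leadfield$model$radii[3],
                      leadfield$model$conductivities, 60L)
  blink_topo <- as.vector(c(0, 0.5, sqrt(0.75)) %*% t(dipole_potential(
    c(0, 0.85 * r1, -0.25 * r1), leadfield$model$electrode_positions,
    leadfield$model$radii[3], leadfield$model$conductivities[1], S)))
  bw <- blink_waveform(fs)

  segments <- list(); markers <- empty_markers(); t0 <- 0
  eog_rows <- list()
  for (seg in config$run_layout) {
    n <- round(seg$duration_s * fs)
    sens <- matrix(0, n_ch, n)
    for (b in seq_len(nrow(bands))) {
      w <- band_noise(n_bg, n, fs, bands$f_lo[b], bands$f_hi[b])
      sens <- sens + bg_amp[b] * crossprod(bg_topo, w)
    }
    a_amp <- if (seg$condition == "EC") config$alpha_ec_amp else
      config$alpha_eo_amp
    sens <- sens + a_amp *
      crossprod(po_topo, band_noise(length(po_vox), n, fs, 8, 13))
    sens <- sens + theta_amp *
      crossprod(th_topo, band_noise(length(th_vox), n, fs, 4, 8))
    # blinks
    blink_tc <- numeric(n)
    n_blinks <- stats::rpois(1L, config$blink_rate * seg$duration_s)
    if (n_blinks > 0) {
      onsets <- sort(sample.int(max(1L, n - length(bw)), n_blinks))
      for (o in onsets) {
        idx <- o:(o + length(bw) - 1L)
        blink_tc[idx] <- blink_tc[idx] + bw
      }
    }
    sig_scale <- stats::median(apply(sens, 1L, stats::sd))
    blink_scaled <- config$blink_amp * sig_scale * blink_tc
    sens <- sens + outer(blink_topo / max(abs(blink_topo)), blink_scaled)
    sens <- sens + config$noise_sd * sig_scale *
      matrix(stats::rnorm(n_ch * n), n_ch, n)
    eog <- rbind(blink_scaled * config$eog_gain,
                 blink_scaled * 0.9 * config$eog_gain) +
      0.02 * sig_scale * matrix(stats::rnorm(2L * n), 2L, n)
    segments[[length(segments) + 1L]] <- sens
    eog_rows[[length(eog_rows) + 1L]] <- eog
    markers <- rbind(markers, data.frame(
      onset_s = t0, duration_s = seg$duration_s,
      condition = seg$condition, stringsAsFactors = FALSE))
    t0 <- t0 + seg$duration_s
  }
  data <- do.call(cbind, segments)
  eog <- do.call(cbind, eog_rows)
  if (config$n_bad_channels > 0) {
    bad <- sample(n_ch, min(config$n_bad_channels, n_ch))
    scale_all <- stats::median(apply(data, 1L, stats::sd))
    data[bad, ] <- 50 * scale_all *
      matrix(stats::rnorm(length(bad) * ncol(data)), length(bad))
  }
  data <- rbind(data, eog)
  eeg_recording(data, fs,
                channels = c(leadfield$channels, "EOG1", "EOG2"),
                roles = c(rep("scalp", n_ch), "eog", "eog"),
                markers = markers)
}

# Truncated-normal draws via inverse-CDF (exact truncation).
rtrunc_norm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  pl <- stats::pnorm(lower, mean, sd)
  pu <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, pl, pu), mean, sd)
}

#' Simulate a cohort: metadata, leadfield, and (optionally) recordings
#'
#' Draws subject metadata with the marginals of the emulated cohort: SUVr
#' from a two-component truncated-Gaussian mixture split exactly at the
#' positivity threshold (so [classify_amyloid()] reproduces the requested
#' group counts exactly), APOE epsilon-4 carriage with group-specific rates
#' (25/230 in A-, 33/88 in A+), sex (58% female), age truncated-normal
#' within 70-85 years, and a memory score (FCSRT total recall, floor 41).
#' Recordings are forward-simulated per subject with derived seeds.
#'
#' @param config a [sim_config()].
#' @param model a [head_model()] (default desk-scale model).
#' @param leadfield optional precomputed [make_leadfield()] result.
#' @param recordings if `FALSE`, skip the (expensive) sensor simulations and
#'   return metadata + leadfield only.
#' @return list with `meta` (data.frame), `leadfield`, and `recordings`
#'   (named list of [eeg_recording()] or `NULL`).
#' @export
simulate_cohort <- function(config, model = head_model(),
                            leadfield = NULL, recordings = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_neg + config$n_pos
  if (n == 0L) stop("empty cohort: n_neg + n_pos must be positive")
  if (is.null(leadfield)) leadfield <- make_leadfield(model)
  set.seed(config$seed)
  thr <- config$suvr_threshold
  suvr <- c(rtrunc_norm(config$n_neg, 0.70, 0.06, upper = thr),
            rtrunc_norm(config$n_pos, 0.92, 0.10, lower = thr + 1e-9))
  status <- c(rep("A-", config$n_neg), rep("A+", config$n_pos))
  apoe <- c(stats::rbinom(config$n_neg, 1L, 25 / 230),
            stats::rbinom(config$n_pos, 1L, 33 / 88))
  sex <- ifelse(stats::runif(n) < 185 / 318, "F", "M")
  age <- rtrunc_norm(n, 76.1, 3.5, lower = 70, upper = 85)
  fcsrt <- pmin(48, pmax(41, round(stats::rnorm(n, 46, 2))))
  meta <- data.frame(
    subject_id = sprintf("S%03d", seq_len(n)),
    suvr = suvr, amyloid = status, apoe_e4 = apoe, sex = sex,
    age = age, fcsrt_tr = fcsrt, visit = "M0",
    stringsAsFactors = FALSE)
  recs <- NULL
  if (recordings) {
    recs <- lapply(seq_len(n), function(i) {
      simulate_subject(config, leadfield, meta[i, ],
                       seed = derive_seed(config$seed, i))
    })
    names(recs) <- meta$subject_id
  }
  list(meta = meta, leadfield = leadfield, recordings = recs)
}

# Deterministic per-unit seed stream below 2^31.
derive_seed <- function(master, i) {
  as.integer((as.numeric(master) * 2654435761 + i * 40503) %% 2147483647)
}

#' Simulate source-level z-power maps directly
#'
#' Map-level generator for the statistics stages: independent standard
#' normal voxel values on a regular lattice, with an optional mean shift
#' planted in one group over a chosen voxel block. This emulates the
#' between-subject variability of z-scored relative-power maps under
#' exchangeability, the setting in which the permutation test's error rates
#' are defined.
#'
#' @param n_neg,n_pos subjects per group (`A-` listed first).
#' @param dim lattice dimensions, e.g. `c(10, 10, 10)`.
#' @param effect_voxels voxel indices receiving the shift in the A+ group.
#' @param effect_size mean shift (in within-group SD units).
#' @param seed RNG seed.
#' @return list: `maps` (subjects x voxels), `labels` (factor `A-`/`A+`),
#'   `adjacency`, `ijk`, `effect_voxels`.
#' @export
simulate_zmaps <- function(n_neg, n_pos, dim = c(10, 10, 10),
                           effect_voxels = integer(0), effect_size = 0,
                           seed = 1) {
  set.seed(seed)
  V <- prod(dim)
  n <- n_neg + n_pos
  maps <- matrix(stats::rnorm(n * V), n, V)
  if (length(effect_voxels) && effect_size != 0)
    maps[seq.int(n_neg + 1L, n), effect_voxels] <-
      maps[seq.int(n_neg + 1L, n), effect_voxels] + effect_size
  ijk <- as.matrix(expand.grid(i = seq_len(dim[1]), j = seq_len(dim[2]),
                               k = seq_len(dim[3])))
  list(maps = maps,
       labels = factor(c(rep("A-", n_neg), rep("A+", n_pos)),
                       levels = c("A-", "A+")),
       adjacency = lattice_adjacency(ijk), ijk = ijk,
       effect_voxels = effect_voxels)
}

#' Central contiguous voxel block of a lattice
#'
#' @param dim lattice dimensions.
#' @param side block side length (default 3, i.e. a 27-voxel block).
#' @return integer voxel indices (column-major order of `expand.grid`).
#' @export
central_block <- function(dim, side = 3) {
  lo <- floor((dim - side) / 2) + 1L
  sel <- lapply(seq_along(dim), function(a) seq.int(lo[a], lo[a] + side - 1L))
  idx <- as.matrix(expand.grid(i = sel[[1]], j = sel[[2]], k = sel[[3]]))
  as.integer(idx[, 1] + (idx[, 2] - 1L) * dim[1] +
               (idx[, 3] - 1L) * dim[1] * dim[2])
}
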