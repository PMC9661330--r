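#' Zero-phase band-pass FIR filter
#'
#' Windowed-sinc (Hamming) linear-phase FIR band-pass, applied in a single
#' forward pass with group-delay compensation, so the net phase response is
#' zero and the output has the same length as the input. The filter order is
#' chosen for a transition band of about `transition` Hz at each edge
#' (Hamming rule of thumb: order ~ 3.3 fs / transition), which also sets
#' the stopband attenuation at roughly 53 dB. The 1 Hz default keeps DC
#' fully inside the stopband of the broadband 1-80 Hz filter.
#'
#' @param x an [eeg_recording()], a channels x samples matrix, or a vector.
#' @param f_lo,f_hi band edges (Hz), `0 < f_lo < f_hi < fs/2`.
#' @param fs sampling rate (Hz); taken from the recording when `x` is one.
#' @param transition transition-band width (Hz) used to pick the order.
#' @param order optional explicit filter order (forced even).
#' @return filtered object of the same type and size as `x`.
#' @export
bandpass_fir <- function(x, f_lo, f_hi, fs = NULL, transition = 1,
                         order = NULL) {
  if (inherits(x, "eeg_recording")) {
    out <- x
    out$data <- bandpass_fir(x$data, f_lo, f_hi, fs = x$fs,
                             transition = transition, order = order)
    return(out)
  }
  if (is.null(fs)) stop("fs is required for matrix/vector input")
  if (!(f_lo > 0 && f_lo < f_hi)) stop("need 0 < f_lo < f_hi")
  if (f_hi >= fs / 2) stop("f_hi must be below the Nyquist frequency fs/2")
  if (is.null(order)) order <- ceiling(3.3 * fs / transition)
  order <- as.integer(order + order %% 2L)       # even order, odd length
  h <- signal::fir1(order, c(f_lo, f_hi) / (fs / 2), type = "pass")
  delay <- order / 2L
  vec <- is.null(dim(x))
  xm <- if (vec) matrix(x, nrow = 1L) else x
  n <- ncol(xm)
  pad <- matrix(0, nrow(xm), delay)
  xp <- cbind(xm, pad)
  out <- t(apply(xp, 1L, function(ch) {
    signal::fftfilt(h, ch)[(delay + 1L):(delay + n)]
  }))
  dimnames(out) <- dimnames(xm)
  if (vec) drop(out) else out
}

#' Three-metric z-score detection of artifactual channels
#'
#' For each scalp channel, computes the variance, the amplitude range
#' (max - min) and the minimum sample value over the whole time series,
#' z-scores each metric using the mean and standard deviation across scalp
#' channels, and flags channels whose absolute z-score reaches the threshold
#' on at least one metric. A metric with zero spread across channels gets
#' z = 0. Detection is restricted to scalp-role channels.
#'
#' @param recording an [eeg_recording()].
#' @param z_threshold rejection threshold on |z| (default 2.5).
#' @param use_abs_min if `TRUE`, use |min| instead of the signed minimum.
#' @return object of class `channel_qc`: data.frame of metrics, z-scores and
#'   the `rejected` flag per scalp channel, with the threshold as attribute.
#' @export
detect_bad_channels <- function(recording, z_threshold = 2.5,
                                use_abs_min = FALSE) {
  stopifnot(inherits(recording, "eeg_recording"))
  sc <- scalp_channels(recording)
  if (length(sc) < 3L) stop("need at least 3 scalp channels to z-score")
  x <- recording$data[sc, , drop = FALSE]
  variance <- apply(x, 1L, stats::var)
  rng <- apply(x, 1L, function(v) diff(range(v)))
  mn <- apply(x, 1L, min)
  if (use_abs_min) mn <- abs(mn)
  zcol <- function(v) {
    s <- stats::sd(v)
    if (s == 0) rep(0, length(v)) else (v - mean(v)) / s
  }
  zv <- zcol(variance); zr <- zcol(rng); zm <- zcol(mn)
  rejected <- pmax(abs(zv), abs(zr), abs(zm)) >= z_threshold
  qc <- data.frame(channel = recording$channels[sc],
                   variance = variance, amplitude_range = rng,
                   min_value = mn, z_variance = zv, z_range = zr,
                   z_min = zm, rejected = rejected,
                   stringsAsFactors = FALSE)
  attr(qc, "z_threshold") <- z_threshold
  class(qc) <- c("channel_qc", "data.frame")
  qc
}

#' @export
print.channel_qc <- function(x, ...) {
  cat(sprintf("Channel QC: %d scalp channels, %d rejected (|z| >= %g)\n",
              nrow(x), sum(x$rejected), attr(x, "z_threshold")))
  if (any(x$rejected))
    cat("  rejected:", paste(x$channel[x$rejected], collapse = ", "), "\n")
  invisible(x)
}

#' Common-average re-referencing
#'
#' Subtracts, at every sample, the mean over the artifact-free scalp
#' channels from all scalp channels. Rejected channels do not contribute to
#' the average; EOG and other-role channels are left untouched.
#'
#' @param recording an [eeg_recording()].
#' @param good_channels indices (into the recording) of the artifact-free
#'   scalp channels; defaults to all scalp channels.
#' @return re-referenced [eeg_recording()].
#' @export
rereference_common_average <- function(recording, good_channels = NULL) {
  stopifnot(inherits(recording, "eeg_recording"))
  sc <- scalp_channels(recording)
  if (is.null(good_channels)) good_channels <- sc
  good_channels <- intersect(good_channels, sc)
  if (length(good_channels) < 2L) stop("need at least 2 good channels")
  avg <- colMeans(recording$data[good_channels, , drop = FALSE])
  recording$data[sc, ] <- sweep(recording$data[sc, , drop = FALSE], 2L, avg)
  recording
}

# Whitened symmetric fixed-point ICA (logcosh contrast). X: components in
# rows, zero-mean. Returns unmixed sources S = W X and mixing A with
# X ~ A S + residual of the discarded PCA subspace.
fastica_fit <- function(X, n_comp, max_iter = 200, tol = 1e-4, seed = 1,
                        n_restarts = 3, strict = FALSE) {
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed))
      assign(".Random.seed", old_seed, envir = globalenv())
  })
  n <- ncol(X)
  C <- tcrossprod(X) / (n - 1)
  e <- eigen(C, symmetric = TRUE)
  # common-average referenced data is rank-deficient by one; whiten only
  # the numerically non-degenerate subspace
  rank <- sum(e$values > 1e-10 * e$values[1L])
  n_comp <- min(n_comp, rank)
  keep <- seq_len(n_comp)
  d <- e$values[keep]
  K <- diag(1 / sqrt(d), n_comp) %*% t(e$vectors[, keep, drop = FALSE])
  Z <- K %*% X                               # whitened: Z Z' / (n-1) = I
  sym_decorrelate <- function(W) {
    s <- svd(W)
    s$u %*% t(s$v)
  }
  W_last <- NULL
  for (attempt in seq_len(n_restarts)) {
    set.seed(seed + attempt - 1L)
    W <- sym_decorrelate(matrix(stats::rnorm(n_comp^2), n_comp))
    converged <- FALSE
    best <- Inf; stall <- 0L
    for (it in seq_len(max_iter)) {
      WZ <- W %*% Z
      G <- tanh(WZ)
      gprime <- rowMeans(1 - G^2)
      W1 <- (G %*% t(Z)) / n - diag(gprime, n_comp) %*% W
      W1 <- sym_decorrelate(W1)
      delta <- max(abs(abs(rowSums(W1 * W)) - 1))
      W <- W1
      if (delta < tol) { converged <- TRUE; break }
      # give up on a restart whose criterion has stopped improving (an
      # unidentifiable near-Gaussian subspace keeps it bounded away from 0)
      if (delta < 0.99 * best) { best <- delta; stall <- 0L }
      else { stall <- stall + 1L; if (stall >= 15L) break }
    }
    W_last <- W
    if (converged) break
  }
  if (!converged) {
    # near-Gaussian sources leave part of the rotation unidentified and the
    # symmetric fixed point cannot settle there; the decomposition is still
    # an exact decorrelated factorization, so proceed unless strict
    if (strict)
      stop("ICA failed to converge after ", n_restarts, " restarts")
    warning("ICA did not reach tolerance after ", n_restarts,
            " restarts; using the final decorrelated unmixing")
    W <- W_last
  }
  S <- W %*% Z
  A <- e$vectors[, keep, drop = FALSE] %*% diag(sqrt(d), n_comp) %*% t(W)
  list(S = S, A = A, W = W %*% K, converged = converged)
}

#' ICA-based removal of ocular artifacts
#'
#' Decomposes the good scalp channels with whitened fixed-point ICA,
#' correlates every component time course with the EOG-role channels, and
#' subtracts from the data the back-projection of all components whose
#' maximum absolute Pearson correlation with any EOG channel reaches the
#' threshold. If no component crosses the threshold the recording is
#' returned unchanged.
#'
#' @param recording filtered, re-referenced [eeg_recording()] with at least
#'   one EOG-role channel.
#' @param good_channels indices of artifact-free scalp channels (default all
#'   scalp channels).
#' @param abs_corr_threshold removal threshold on max |r| (default 0.8).
#' @param n_components number of components (default: number of good
#'   channels, capped at `max_components`).
#' @param max_components cap on the component count (default 40).
#' @param seed RNG seed for the ICA initialisation.
#' @param strict error (rather than warn) when the fixed-point iteration
#'   does not reach tolerance; near-Gaussian rhythmic sources generically
#'   leave part of the rotation unidentified, so the default proceeds with
#'   the final decorrelated unmixing.
#' @return list with elements `recording` (cleaned) and `report`
#'   (class `ica_report`: component count, removed indices, the component x
#'   EOG correlation matrix).
#' @export
remove_ocular_ica <- function(recording, good_channels = NULL,
                              abs_corr_threshold = 0.8,
                              n_components = NULL, max_components = 40,
                              seed = 1, strict = FALSE) {
  stopifnot(inherits(recording, "eeg_recording"))
  eog <- eog_channels(recording)
  if (length(eog) == 0L) stop("no EOG-role channel in the recording")
  sc <- scalp_channels(recording)
  if (is.null(good_channels)) good_channels <- sc
  good_channels <- intersect(good_channels, sc)
  if (is.null(n_components))
    n_components <- min(length(good_channels), max_components)
  X <- recording$data[good_channels, , drop = FALSE]
  mu <- rowMeans(X)
  Xc <- X - mu
  fit <- fastica_fit(Xc, n_components, seed = seed, strict = strict)
  n_components <- nrow(fit$S)           # may shrink to the data rank
  E <- recording$data[eog, , drop = FALSE]
  r <- stats::cor(t(fit$S), t(E))
  rownames(r) <- paste0("IC", seq_len(n_components))
  colnames(r) <- recording$channels[eog]
  maxr <- apply(abs(r), 1L, max)
  removed <- which(maxr >= abs_corr_threshold)
  if (length(removed)) {
    artefact <- fit$A[, removed, drop = FALSE] %*%
      fit$S[removed, , drop = FALSE]
    recording$data[good_channels, ] <- X - artefact
  }
  report <- structure(list(n_components = n_components,
                           removed_components = as.integer(removed),
                           eog_correlations = r),
                      class = "ica_report")
  list(recording = recording, report = report)
}

#' @export
print.ica_report <- function(x, ...) {
  cat(sprintf("ICA report: %d components, %d removed",
              x$n_components, length(x$removed_components)))
  if (length(x$removed_components))
    cat(" (", paste0("IC", x$removed_components, collapse = ", "), ")")
  cat("\n  max |r| with EOG:",
      paste(signif(sort(apply(abs(x$eog_correlations), 1, max),
                        decreasing = TRUE)[seq_len(min(3, x$n_components))],
                   2), collapse = ", "), "...\n")
  invisible(x)
}

#' Automatic high-amplitude segment mask
#'
#' Replacement for by-eye rejection of residual artifact segments: splits
#' the recording into fixed-length segments and flags any segment in which
#' some good channel's peak amplitude exceeds `threshold_sd` times that
#' channel's robust (median-absolute-deviation) scale. The mask is
#' returned for the caller to apply; no stage applies it by default.
#'
#' @param recording an [eeg_recording()].
#' @param threshold_sd amplitude threshold in robust SD units (default 6).
#' @param segment_s segment length in seconds (default 1).
#' @param good_channels channels considered (default all scalp channels).
#' @return logical vector, one flag per segment (`TRUE` = keep).
#' @export
segment_mask <- function(recording, threshold_sd = 6, segment_s = 1,
                         good_channels = NULL) {
  stopifnot(inherits(recording, "eeg_recording"))
  if (is.null(good_channels)) good_channels <- scalp_channels(recording)
  x <- recording$data[good_channels, , drop = FALSE]
  scale <- apply(x, 1L, stats::mad)
  scale[scale == 0] <- Inf
  n_seg <- floor(ncol(x) / (segment_s * recording$fs))
  if (n_seg < 1L) stop("recording shorter than one segment")
  vapply(seq_len(n_seg), function(s) {
    idx <- ((s - 1L) * segment_s * recording$fs + 1L):
      (s * segment_s * recording$fs)
    all(apply(abs(x[, idx, drop = FALSE]) / scale, 1L, max) <
          threshold_sd)
  }, logical(1))
}

#' Full sensor-space cleaning of one recording
#'
#' Convenience wrapper running the cleaning chain: 1-80 Hz zero-phase FIR
#' band-pass, three-metric z-score channel rejection, common-average
#' re-referencing over the retained channels, and ICA ocular-artifact
#' removal.
#'
#' @param recording raw [eeg_recording()].
#' @param f_lo,f_hi broadband filter edges (Hz).
#' @param z_threshold channel-rejection threshold.
#' @param ic_corr_threshold ICA removal threshold on |r| with EOG.
#' @param max_components ICA component cap.
#' @param seed ICA seed.
#' @return list: `recording` (cleaned), `good_channels` (indices),
#'   `qc` (`channel_qc`), `ica` (`ica_report`).
#' @export
preprocess_recording <- function(recording, f_lo = 1, f_hi = 80,
                                 z_threshold = 2.5,
                                 ic_corr_threshold = 0.8,
                                 max_components = 40, seed = 1) {
  filt <- bandpass_fir(recording, f_lo, f_hi)
  qc <- detect_bad_channels(filt, z_threshold = z_threshold)
  sc <- scalp_channels(filt)
  good <- sc[!qc$rejected]
  reref <- rereference_common_average(filt, good)
  ica <- remove_ocular_ica(reref, good_channels = good,
                           abs_corr_threshold = ic_corr_threshold,
                           max_components = max_components, seed = seed)
  list(recording = ica$recording, good_channels = good,
       qc = qc, ica = ica$report)
}
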