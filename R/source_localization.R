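#' The seven-band analysis filter bank
#'
#' Contiguous, non-overlapping canonical bands: delta 2-4, theta 4-8,
#' alpha1 8-10, alpha2 10-13, beta1 13-20, beta2 20-30, gamma 30-40 Hz.
#'
#' @return data.frame with columns `name`, `f_lo`, `f_hi`.
#' @export
default_bands <- function() {
  data.frame(
    name = c("delta", "theta", "alpha1", "alpha2", "beta1", "beta2",
             "gamma"),
    f_lo = c(2, 4, 8, 10, 13, 20, 30),
    f_hi = c(4, 8, 10, 13, 20, 30, 40),
    stringsAsFactors = FALSE)
}

validate_bands <- function(bands) {
  if (!is.data.frame(bands) || nrow(bands) == 0L)
    stop("band list must be a non-empty data.frame")
  if (!all(c("name", "f_lo", "f_hi") %in% names(bands)))
    stop("bands need columns name, f_lo, f_hi")
  if (any(bands$f_lo >= bands$f_hi)) stop("band edges must satisfy f_lo < f_hi")
  invisible(bands)
}

#' Band-pass filter bank
#'
#' Applies [bandpass_fir()] once per band, returning one recording per band.
#'
#' @param recording an [eeg_recording()] (or channels x samples matrix with
#'   `fs` supplied).
#' @param bands band definition table, see [default_bands()].
#' @param fs sampling rate for matrix input.
#' @return named list of filtered recordings/matrices, one per band.
#' @export
band_filter_bank <- function(recording, bands = default_bands(), fs = NULL) {
  validate_bands(bands)
  out <- lapply(seq_len(nrow(bands)), function(b)
    bandpass_fir(recording, bands$f_lo[b], bands$f_hi[b], fs = fs))
  names(out) <- bands$name
  out
}

#' Covariance of merged eyes-closed and eyes-open data
#'
#' Concatenates the EC and EO segments, removes the per-channel mean of the
#' merged data, and returns the symmetrized sample covariance.
#'
#' @param ec_segments,eo_segments a channels x samples matrix or a list of
#'   such matrices; channel counts must agree.
#' @return symmetric positive semi-definite covariance matrix.
#' @export
merged_covariance <- function(ec_segments, eo_segments) {
  as_list <- function(x) if (is.list(x)) x else list(x)
  segs <- c(as_list(ec_segments), as_list(eo_segments))
  ncs <- vapply(segs, nrow, integer(1))
  if (length(unique(ncs)) != 1L)
    stop("channel count mismatch between EC and EO segments")
  X <- do.call(cbind, segs)
  X <- X - rowMeans(X)
  C <- tcrossprod(X) / (ncol(X) - 1L)
  (C + t(C)) / 2
}

#' LCMV beamformer spatial filters
#'
#' Builds the linearly constrained minimum-variance filter for every voxel
#' from the (regularized) data covariance `C' = C + lambda_fraction *
#' (trace(C)/n) * I`: the unreduced filter is `W = (L' C'^-1 L)^-1 L' C'^-1`
#' (3 x channels, unit gain `W L = I3`), then reduced to one scalar filter
#' per voxel along the dominant source orientation — the leading eigenvector
#' of the voxel's 3 x 3 source covariance `W C' W'`. One common filter set
#' serves both recording conditions.
#'
#' @param leadfield a [make_leadfield()] result.
#' @param covariance channel covariance (merged EC+EO), with dimnames
#'   matching leadfield channels or given in the same order via `channels`.
#' @param lambda_fraction regularization as a fraction of the mean sensor
#'   variance (default 0.05).
#' @param channels indices (into the leadfield channel set) of the channels
#'   present in `covariance`; defaults to all.
#' @return object of class `lcmv_filters`: `weights` (n_vox x n_channels),
#'   `orientations` (n_vox x 3), `filters3` (n_vox x 3 x n_channels),
#'   `lambda`, `channels`.
#' @export
lcmv_filters <- function(leadfield, covariance, lambda_fraction = 0.05,
                         channels = NULL) {
  stopifnot(inherits(leadfield, "leadfield"))
  if (lambda_fraction < 0) stop("lambda_fraction must be >= 0")
  if (is.null(channels)) channels <- seq_along(leadfield$channels)
  n_ch <- length(channels)
  if (!all(dim(covariance) == n_ch))
    stop("covariance dimension does not match the channel subset")
  Creg <- covariance + lambda_fraction * (sum(diag(covariance)) / n_ch) *
    diag(n_ch)
  Ci <- tryCatch(solve(Creg), error = function(e)
    stop("regularized covariance is singular; increase lambda_fraction"))
  n_vox <- nrow(leadfield$grid)
  W <- matrix(0, n_vox, n_ch)
  ori <- matrix(0, n_vox, 3L)
  W3 <- array(0, c(n_vox, 3L, n_ch))
  for (v in seq_len(n_vox)) {
    L <- t(leadfield$gain[v, , channels])        # n_ch x 3
    CiL <- Ci %*% L
    G <- crossprod(L, CiL)                       # L' C^-1 L, 3 x 3
    Gi <- tryCatch(solve(G), error = function(e)
      stop("singular L' C^-1 L at voxel ", v,
           "; consider a larger lambda_fraction"))
    Wv <- Gi %*% t(CiL)                          # 3 x n_ch
    S3 <- Wv %*% Creg %*% t(Wv)
    u <- eigen((S3 + t(S3)) / 2, symmetric = TRUE)$vectors[, 1L]
    W3[v, , ] <- Wv
    W[v, ] <- as.vector(u %*% Wv)
    ori[v, ] <- u
  }
  structure(list(weights = W, orientations = ori, filters3 = W3,
                 lambda = lambda_fraction, channels = channels,
                 channel_names = leadfield$channels[channels]),
            class = "lcmv_filters")
}

#' @export
print.lcmv_filters <- function(x, ...) {
  cat(sprintf(
    "LCMV spatial filters: %d voxels x %d channels (lambda = %g)\n",
    nrow(x$weights), ncol(x$weights), x$lambda))
  invisible(x)
}

#' Beamformer source power / neural activity index
#'
#' Source variance `w C w'` per voxel, optionally normalized by the filter
#' norm (`w w'`, the projected white-noise power), which removes the depth
#' bias when scanning for a power peak.
#'
#' @param filters an [lcmv_filters()] object.
#' @param covariance channel covariance on the same channel set.
#' @param normalize `"nai"` (default) or `"none"`.
#' @return numeric vector of per-voxel power.
#' @export
beamformer_power <- function(filters, covariance,
                             normalize = c("nai", "none")) {
  normalize <- match.arg(normalize)
  W <- filters$weights
  p <- rowSums((W %*% covariance) * W)
  if (normalize == "nai") p <- p / rowSums(W * W)
  p
}

#' Project sensor data into source space
#'
#' Applies the common scalar spatial filters to sensor data: one source
#' time series per voxel. For an [eeg_recording()], projects each marked
#' condition separately (the same weights for EC and EO).
#'
#' @param x an [eeg_recording()] or a channels x samples matrix ordered as
#'   `filters$channel_names`.
#' @param filters an [lcmv_filters()] object.
#' @return for a matrix: an n_vox x samples matrix; for a recording: a
#'   named list with one matrix per condition present in the markers.
#' @export
project_sources <- function(x, filters) {
  stopifnot(inherits(filters, "lcmv_filters"))
  if (inherits(x, "eeg_recording")) {
    if (!all(filters$channel_names %in% x$channels))
      stop("recording is missing filter channels: ",
           paste(setdiff(filters$channel_names, x$channels), collapse = ", "))
    conds <- unique(x$markers$condition)
    out <- lapply(conds, function(cd)
      filters$weights %*%
        condition_samples(x, cd, channels = filters$channel_names))
    names(out) <- conds
    return(out)
  }
  x <- as.matrix(x)
  if (nrow(x) != ncol(filters$weights))
    stop("matrix has ", nrow(x), " channels but filters expect ",
         ncol(filters$weights))
  filters$weights %*% x
}
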