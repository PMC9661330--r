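#' Band power of source time series
#'
#' Hann-tapered FFT power: the series is cut into non-overlapping windows
#' (default 2 s, i.e. 0.5 Hz resolution), each window is tapered and
#' Fourier-transformed, and the squared magnitudes are averaged over
#' windows; the band power is the mean over frequency bins within
#' `[f_lo, f_hi)`.
#'
#' @param x voxels x samples matrix (or a vector).
#' @param fs sampling rate (Hz).
#' @param f_lo,f_hi band edges (Hz).
#' @param window_s window length (s); the series must contain at least one
#'   full window.
#' @return numeric vector of non-negative per-voxel band power.
#' @export
voxel_band_power <- function(x, fs, f_lo, f_hi, window_s = 2) {
  vec <- is.null(dim(x))
  xm <- if (vec) matrix(x, nrow = 1L) else as.matrix(x)
  nw <- round(window_s * fs)
  n_win <- floor(ncol(xm) / nw)
  if (n_win < 1L)
    stop("series shorter than one ", window_s, " s window")
  if (f_hi > fs / 2 || f_lo < 0 || f_lo >= f_hi)
    stop("band [", f_lo, ", ", f_hi, ") outside the resolvable range")
  taper <- 0.5 * (1 - cos(2 * pi * seq_len(nw) / (nw + 1)))
  freq <- (seq_len(nw) - 1L) * fs / nw
  bins <- which(freq >= f_lo & freq < f_hi & freq <= fs / 2)
  if (length(bins) == 0L)
    stop("band [", f_lo, ", ", f_hi, ") contains no frequency bin at ",
         1 / window_s, " Hz resolution")
  acc <- 0
  for (w in seq_len(n_win)) {
    seg <- xm[, ((w - 1L) * nw + 1L):(w * nw), drop = FALSE]
    F <- stats::mvfft(t(seg) * taper)
    acc <- acc + colSums(Mod(F[bins, , drop = FALSE])^2) / length(bins)
  }
  p <- acc / (n_win * sum(taper^2))
  if (vec) unname(p[1L]) else p
}

#' Relative band power
#'
#' Divides each band's power by the summed power over the analyzed bands,
#' voxel by voxel.
#'
#' @param power voxels x bands matrix of absolute band power.
#' @return matrix of fractions in `[0, 1]` whose rows sum to 1.
#' @export
relative_power <- function(power) {
  power <- as.matrix(power)
  if (any(power < 0)) stop("band power must be non-negative")
  tot <- rowSums(power)
  zero <- which(tot == 0)
  if (length(zero))
    stop("all-zero band power at voxel(s): ",
         paste(utils::head(zero, 5L), collapse = ", "))
  power / tot
}

#' Voxel-wise z-scoring of a band map
#'
#' Standardizes the values across voxels (mean 0, SD 1) so maps are
#' comparable between subjects and frequency bands.
#'
#' @param values per-voxel values of one band (vector) or a voxels x bands
#'   matrix (each column standardized independently).
#' @return z-scored object of the same shape.
#' @export
zscore_map <- function(values) {
  zs <- function(v) {
    if (length(v) < 2L) stop("need at least 2 voxels to z-score")
    s <- stats::sd(v)
    if (s == 0) stop("zero across-voxel SD; map cannot be z-scored")
    (v - mean(v)) / s
  }
  if (is.matrix(values)) apply(values, 2L, zs) else zs(values)
}

#' Per-subject source power map
#'
#' Computes, from per-band source time series, the absolute band power
#' (Hann-tapered FFT, each band's own edges applied to its band-filtered
#' series), the relative power over the seven bands, and the across-voxel
#' z-scores. The construction asserts the conservation and normalization
#' contracts (band fractions sum to 1 per voxel; each z column has mean 0,
#' SD 1).
#'
#' @param source_series named list (one entry per band) of n_vox x samples
#'   matrices, e.g. from [project_sources()] applied per band.
#' @param fs sampling rate (Hz).
#' @param bands band table matching the list names.
#' @param subject_id,visit,condition identifying labels.
#' @param window_s FFT window length (s).
#' @return object of class `power_map` with matrices `power`, `relative`,
#'   `z` (voxels x bands).
#' @export
source_power_map <- function(source_series, fs, bands = default_bands(),
                             subject_id = "S000", visit = "M0",
                             condition = "EC", window_s = 2) {
  validate_bands(bands)
  if (!all(bands$name %in% names(source_series)))
    stop("source_series must have one entry per band")
  power <- vapply(seq_len(nrow(bands)), function(b)
    voxel_band_power(source_series[[bands$name[b]]], fs,
                     bands$f_lo[b], bands$f_hi[b], window_s = window_s),
    numeric(nrow(source_series[[1L]])))
  colnames(power) <- bands$name
  rel <- relative_power(power)
  z <- zscore_map(rel)
  stopifnot(max(abs(rowSums(rel) - 1)) < 1e-10)
  structure(list(subject_id = subject_id, visit = visit,
                 condition = condition, bands = bands,
                 power = power, relative = rel, z = z),
            class = "power_map")
}

#' @export
print.power_map <- function(x, ...) {
  cat(sprintf("Source power map: subject %s, visit %s, condition %s\n",
              x$subject_id, x$visit, x$condition))
  cat(sprintf("  %d voxels x %d bands; mean relative power: %s\n",
              nrow(x$power), ncol(x$power),
              paste(sprintf("%s %.2f", colnames(x$power),
                            colMeans(x$relative)), collapse = ", ")))
  invisible(x)
}

#' Exclude outlier subjects on global power
#'
#' The global power of a subject is the mean over voxels and bands of the
#' absolute (pre-normalization) band power. Subjects whose global power
#' exceeds the upper bound of the across-subject 95% interval
#' (mean + 1.96 SD) are excluded; with `two_sided = TRUE` the lower bound
#' is applied as well.
#'
#' @param maps list of [source_power_map()] objects (>= 10 subjects).
#' @param two_sided apply the lower bound too (default `FALSE`).
#' @return list: `kept`, `excluded` (indices), `global` (values),
#'   `bounds`.
#' @export
exclude_outlier_subjects <- function(maps, two_sided = FALSE) {
  if (length(maps) < 10L) stop("need at least 10 subjects")
  global <- vapply(maps, function(m) mean(m$power), numeric(1))
  mu <- mean(global); s <- stats::sd(global)
  hi <- mu + 1.96 * s
  lo <- if (two_sided) mu - 1.96 * s else -Inf
  excluded <- which(global > hi | global < lo)
  kept <- setdiff(seq_along(maps), excluded)
  list(kept = kept, excluded = excluded, global = global,
       bounds = c(lower = lo, upper = hi))
}
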