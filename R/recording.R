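#' Multichannel sensor recording
#'
#' Container for a continuous multichannel EEG recording: a channels x
#' samples matrix, the sampling rate, per-channel roles (`scalp`, `eog`,
#' `other`), and a marker table delimiting eyes-closed / eyes-open blocks.
#' Marker intervals are half-open `[onset, onset + duration)` in seconds
#' from recording start.
#'
#' @param data numeric matrix, channels in rows, samples in columns.
#' @param fs sampling rate (Hz).
#' @param channels character channel names (defaults to rownames or E1..En).
#' @param roles character vector in `{scalp, eog, other}` per channel.
#' @param markers data.frame with columns `onset_s`, `duration_s`,
#'   `condition` (values `EC` or `EO`); may be empty.
#' @return an object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, fs, channels = NULL, roles = NULL,
                          markers = empty_markers()) {
  data <- as.matrix(data)
  if (is.null(channels))
    channels <- rownames(data) %||% paste0("E", seq_len(nrow(data)))
  if (is.null(roles)) roles <- rep("scalp", nrow(data))
  if (length(channels) != nrow(data) || length(roles) != nrow(data))
    stop("channels/roles length must match the number of rows of data")
  if (!all(roles %in% c("scalp", "eog", "other")))
    stop("roles must be one of scalp, eog, other")
  if (!is.numeric(fs) || fs <= 0) stop("fs must be positive")
  validate_markers(markers, n_samples = ncol(data), fs = fs)
  rownames(data) <- channels
  structure(list(data = data, fs = fs, channels = channels,
                 roles = roles, markers = markers),
            class = "eeg_recording")
}

empty_markers <- function() {
  data.frame(onset_s = numeric(0), duration_s = numeric(0),
             condition = character(0), stringsAsFactors = FALSE)
}

validate_markers <- function(markers, n_samples = NULL, fs = NULL) {
  need <- c("onset_s", "duration_s", "condition")
  if (!is.data.frame(markers) || !all(need %in% names(markers)))
    stop("markers must be a data.frame with onset_s, duration_s, condition")
  if (nrow(markers) == 0L) return(invisible(markers))
  if (!all(markers$condition %in% c("EC", "EO")))
    stop("unknown marker condition: ",
         paste(setdiff(markers$condition, c("EC", "EO")), collapse = ", "))
  if (any(markers$onset_s < 0) || any(markers$duration_s <= 0))
    stop("marker onsets must be >= 0 and durations > 0")
  o <- order(markers$onset_s)
  ends <- markers$onset_s[o] + markers$duration_s[o]
  if (any(markers$onset_s[o][-1] < ends[-length(ends)] - 1e-9))
    stop("marker intervals overlap")
  if (!is.null(n_samples) && !is.null(fs) &&
      max(ends) > n_samples / fs + 1e-9)
    stop("marker intervals extend beyond the recording")
  invisible(markers)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Extract the samples of one condition
#'
#' Concatenates all marker blocks of the requested condition into one
#' channels x samples matrix (sample index `floor(onset*fs)+1` to
#' `floor((onset+duration)*fs)`, half-open interval convention).
#'
#' @param recording an [eeg_recording()].
#' @param condition `"EC"` or `"EO"`.
#' @param channels optional channel subset (names or indices).
#' @return numeric matrix.
#' @export
condition_samples <- function(recording, condition, channels = NULL) {
  stopifnot(inherits(recording, "eeg_recording"))
  m <- recording$markers
  m <- m[m$condition == condition, , drop = FALSE]
  if (nrow(m) == 0L) stop("no markers for condition ", condition)
  fs <- recording$fs
  idx <- unlist(lapply(seq_len(nrow(m)), function(i) {
    seq.int(floor(m$onset_s[i] * fs) + 1L,
            floor((m$onset_s[i] + m$duration_s[i]) * fs))
  }))
  idx <- idx[idx <= ncol(recording$data)]
  x <- recording$data
  if (!is.null(channels)) x <- x[channels, , drop = FALSE]
  x[, idx, drop = FALSE]
}

#' Indices of scalp-role channels
#' @param recording an [eeg_recording()].
#' @return integer vector.
#' @export
scalp_channels <- function(recording) which(recording$roles == "scalp")

#' Indices of EOG-role channels
#' @param recording an [eeg_recording()].
#' @return integer vector.
#' @export
eog_channels <- function(recording) which(recording$roles == "eog")

#' @export
print.eeg_recording <- function(x, ...) {
  dur <- ncol(x$data) / x$fs
  cat(sprintf("EEG recording: %d channels x %d samples (%.1f s @ %g Hz)\n",
              nrow(x$data), ncol(x$data), dur, x$fs))
  cat("  roles:", paste(sprintf("%s:%d", names(table(x$roles)),
                                table(x$roles)), collapse = " "), "\n")
  if (nrow(x$markers))
    cat("  markers:", nrow(x$markers), "blocks (",
        paste(sprintf("%s:%d", names(table(x$markers$condition)),
                      table(x$markers$condition)), collapse = " "), ")\n")
  invisible(x)
}
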