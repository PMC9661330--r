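pad_field <- function(x, width) {
  s <- substr(format(x, trim = TRUE), 1L, width)
  formatC(s, width = width, flag = "-")
}

# Per-channel symmetric physical range: the smallest +/-M covering the data
# whose 2-significant-digit mantissa representation ("-1.2e-04", 8 chars)
# fits the EDF header field exactly, with the mantissa rounded up so no
# sample is clipped.
edf_phys_range <- function(x) {
  M <- max(abs(x), 1e-30)
  e <- floor(log10(M))
  mant <- ceiling(M / 10^e * 10) / 10
  if (mant >= 10) { mant <- 1; e <- e + 1L }
  mant * 10^e
}

#' Write a recording to EDF
#'
#' Minimal European Data Format writer: 16-bit samples, one-second data
#' records, per-channel physical scaling computed from the data range. The
#' sample count is truncated to a whole number of records. Because EDF
#' quantizes to 16 bits, a write/read round trip reproduces each sample to
#' within one digital step, i.e. `(phys_max - phys_min) / 65535` per
#' channel. Marker tables are not part of the EDF payload; write them with
#' [write_markers()].
#'
#' @param recording an [eeg_recording()] with integer-valued `fs`.
#' @param path output file path.
#' @return invisibly, the path.
#' @export
write_edf <- function(recording, path) {
  stopifnot(inherits(recording, "eeg_recording"))
  fs <- recording$fs
  if (abs(fs - round(fs)) > 1e-9)
    stop("EDF writer requires an integer sampling rate")
  fs <- as.integer(round(fs))
  ns <- nrow(recording$data)
  n_rec <- ncol(recording$data) %/% fs
  if (n_rec < 1L) stop("recording shorter than one 1 s data record")
  x <- recording$data[, seq_len(n_rec * fs), drop = FALSE]
  M <- apply(x, 1L, edf_phys_range)
  pmin_ <- -M
  pmax_ <- M
  dmin <- -32768L; dmax <- 32767L
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad_field("0", 8L),
    pad_field("synthetic subject", 80L),
    pad_field("amypower recording", 80L),
    pad_field("01.01.20", 8L), pad_field("00.00.00", 8L),
    pad_field(256L * (1L + ns), 8L),
    pad_field("", 44L),
    pad_field(n_rec, 8L),
    pad_field(1L, 8L),
    pad_field(ns, 4L))
  writeChar(hdr, con, nchars = nchar(hdr), eos = NULL)
  sig <- paste0(
    paste0(vapply(recording$channels, pad_field, "", width = 16L),
           collapse = ""),
    paste0(vapply(recording$roles, pad_field, "", width = 80L),
           collapse = ""),
    paste0(rep(pad_field("uV", 8L), ns), collapse = ""),
    paste0(vapply(sprintf("%.1e", pmin_), pad_field, "", width = 8L),
           collapse = ""),
    paste0(vapply(sprintf("%.1e", pmax_), pad_field, "", width = 8L),
           collapse = ""),
    paste0(rep(pad_field(dmin, 8L), ns), collapse = ""),
    paste0(rep(pad_field(dmax, 8L), ns), collapse = ""),
    paste0(rep(pad_field("", 80L), ns), collapse = ""),
    paste0(rep(pad_field(fs, 8L), ns), collapse = ""),
    paste0(rep(pad_field("", 32L), ns), collapse = ""))
  writeChar(sig, con, nchars = nchar(sig), eos = NULL)
  pmin_h <- as.numeric(sprintf("%.1e", pmin_))  # header-exact values
  pmax_h <- as.numeric(sprintf("%.1e", pmax_))
  scale <- (dmax - dmin) / (pmax_h - pmin_h)
  for (r in seq_len(n_rec)) {
    cols <- ((r - 1L) * fs + 1L):(r * fs)
    dig <- round((x[, cols, drop = FALSE] - pmin_h) * scale) + dmin
    dig <- pmin(pmax(dig, dmin), dmax)
    writeBin(as.integer(t(dig)), con, size = 2L, endian = "little")
  }
  invisible(path)
}

#' Read an EDF recording
#'
#' Counterpart of [write_edf()]. Channel roles default to `eog` for labels
#' starting with "EOG" and `scalp` otherwise; a montage table (see
#' [read_montage()]) overrides this.
#'
#' @param path EDF file.
#' @param roles optional named character vector (channel -> role).
#' @param markers optional marker data.frame to attach.
#' @return an [eeg_recording()].
#' @export
read_edf <- function(path, roles = NULL, markers = empty_markers()) {
  if (!file.exists(path)) stop("no such EDF file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(k) {
    s <- readChar(con, k, useBytes = TRUE)
    if (nchar(s, type = "bytes") < k) stop("truncated EDF header in ", path)
    trimws(s)
  }
  version <- rd(8L)
  if (version != "0") stop("unsupported EDF version field: ", version)
  rd(80L); rd(80L); rd(8L); rd(8L)
  rd(8L)                                  # header bytes
  rd(44L)
  n_rec <- as.integer(rd(8L))
  rec_dur <- as.numeric(rd(8L))
  ns <- as.integer(rd(4L))
  if (is.na(ns) || ns < 1L) stop("bad signal count in EDF header")
  labels <- vapply(seq_len(ns), function(i) rd(16L), "")
  transducer <- vapply(seq_len(ns), function(i) rd(80L), "")
  vapply(seq_len(ns), function(i) rd(8L), "")       # phys dim
  pmin_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8L), ""))
  pmax_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8L), ""))
  dmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8L), ""))
  dmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8L), ""))
  vapply(seq_len(ns), function(i) rd(80L), "")      # prefilter
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8L), ""))
  vapply(seq_len(ns), function(i) rd(32L), "")
  if (length(unique(spr)) != 1L)
    stop("mixed per-signal sampling rates are not supported")
  fs <- spr[1L] / rec_dur
  data <- matrix(0, ns, n_rec * spr[1L])
  for (r in seq_len(n_rec)) {
    raw <- readBin(con, integer(), n = ns * spr[1L], size = 2L,
                   endian = "little")
    if (length(raw) < ns * spr[1L]) stop("truncated EDF data record ", r)
    block <- matrix(raw, nrow = spr[1L])            # samples x signals
    cols <- ((r - 1L) * spr[1L] + 1L):(r * spr[1L])
    data[, cols] <- t(block)
  }
  scale <- (pmax_ - pmin_) / (dmax - dmin)
  data <- (data - dmin) * scale + pmin_
  role <- if (!is.null(roles)) unname(roles[labels]) else
    ifelse(transducer %in% c("scalp", "eog", "other"), transducer,
           ifelse(grepl("^EOG", labels), "eog", "scalp"))
  eeg_recording(data, fs, channels = labels, roles = role,
                markers = markers)
}

#' Read/write condition marker tables
#'
#' TSV with columns `onset_s`, `duration_s`, `condition` (EC/EO);
#' intervals are validated as non-overlapping on read and write.
#'
#' @param markers marker data.frame.
#' @param path TSV path.
#' @return `read_markers`: the validated data.frame.
#' @export
write_markers <- function(markers, path) {
  validate_markers(markers)
  utils::write.table(markers, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_markers
#' @export
read_markers <- function(path) {
  if (!file.exists(path)) stop("no such marker file: ", path)
  m <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  validate_markers(m)
  m
}

#' Read a montage table
#'
#' TSV with columns `channel` and `role` (scalp/eog/other).
#'
#' @param path TSV path.
#' @return named character vector channel -> role.
#' @export
read_montage <- function(path) {
  m <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  if (!all(c("channel", "role") %in% names(m)))
    stop("montage table needs columns channel, role")
  if (!all(m$role %in% c("scalp", "eog", "other")))
    stop("montage roles must be scalp, eog or other")
  stats::setNames(m$role, m$channel)
}

#' Read/write subject metadata tables
#'
#' TSV with columns `subject_id`, `suvr`, `apoe_e4` (0/1), `sex` (F/M),
#' `age`, `fcsrt_tr`, `visit` (M0/M24). The amyloid status column is
#' recomputed from SUVr on read.
#'
#' @param meta metadata data.frame.
#' @param path TSV path.
#' @param suvr_threshold positivity cutoff used to derive `amyloid`.
#' @return `read_metadata`: the data.frame with an `amyloid` factor column.
#' @export
write_metadata <- function(meta, path) {
  cols <- c("subject_id", "suvr", "apoe_e4", "sex", "age", "fcsrt_tr",
            "visit")
  utils::write.table(meta[, cols], path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_metadata
#' @export
read_metadata <- function(path, suvr_threshold = 0.79) {
  if (!file.exists(path)) stop("no such metadata file: ", path)
  meta <- utils::read.table(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
  need <- c("subject_id", "suvr", "apoe_e4", "sex", "age", "fcsrt_tr",
            "visit")
  miss <- setdiff(need, names(meta))
  if (length(miss))
    stop("metadata is missing column(s): ", paste(miss, collapse = ", "))
  meta$amyloid <- as.character(classify_amyloid(meta$suvr, suvr_threshold))
  meta
}

#' Write/read a leadfield container
#'
#' Plain-text container: `grid.tsv` (voxel, x, y, z, roi_label),
#' `gain.tsv` (voxel, orientation, channel, gain in long format), and
#' `meta.json` (spacing, channel order). Adjacency is recomputed from the
#' grid on read.
#'
#' @param leadfield a [make_leadfield()] result.
#' @param dir container directory (created if needed).
#' @return `read_leadfield`: a `leadfield` object (without the generating
#'   head model).
#' @export
write_leadfield <- function(leadfield, dir) {
  stopifnot(inherits(leadfield, "leadfield"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  grid <- data.frame(voxel = seq_len(nrow(leadfield$grid)),
                     x = leadfield$grid[, 1], y = leadfield$grid[, 2],
                     z = leadfield$grid[, 3], roi_label = leadfield$roi)
  utils::write.table(grid, file.path(dir, "grid.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  g <- leadfield$gain
  long <- data.frame(
    voxel = rep(seq_len(dim(g)[1]), times = 3L * dim(g)[3]),
    orientation = rep(rep(c("x", "y", "z"), each = dim(g)[1]),
                      times = dim(g)[3]),
    channel = rep(leadfield$channels, each = 3L * dim(g)[1]),
    gain = as.vector(g))
  utils::write.table(long, file.path(dir, "gain.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(spacing = leadfield$spacing,
                            channels = leadfield$channels),
                       file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' @rdname write_leadfield
#' @export
read_leadfield <- function(dir) {
  gpath <- file.path(dir, "grid.tsv")
  if (!file.exists(gpath)) stop("no leadfield container at ", dir)
  grid_df <- utils::read.table(gpath, header = TRUE, sep = "\t",
                               stringsAsFactors = FALSE)
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  long <- utils::read.table(file.path(dir, "gain.tsv"), header = TRUE,
                            sep = "\t", stringsAsFactors = FALSE)
  n_vox <- nrow(grid_df)
  channels <- meta$channels
  g <- array(0, c(n_vox, 3L, length(channels)),
             dimnames = list(NULL, c("x", "y", "z"), channels))
  oi <- match(long$orientation, c("x", "y", "z"))
  ci <- match(long$channel, channels)
  g[cbind(long$voxel, oi, ci)] <- long$gain
  grid <- as.matrix(grid_df[, c("x", "y", "z")])
  h <- meta$spacing
  ijk <- round((grid + h / 2) / h)
  on_lattice <- max(abs(grid - (ijk * h - h / 2))) < 1e-6
  adjacency <- if (on_lattice) lattice_adjacency(ijk) else
    grid_adjacency(grid, h)
  structure(list(gain = g, grid = grid, ijk = if (on_lattice) ijk else NULL,
                 roi = grid_df$roi_label, adjacency = adjacency,
                 channels = channels, spacing = h, model = NULL),
            class = "leadfield")
}

#' Serialize power maps to long-format TSV
#'
#' One row per subject x band x voxel with the relative power and z-score.
#'
#' @param maps list of [source_power_map()] objects.
#' @param path TSV path.
#' @return invisibly, the path.
#' @export
write_power_maps <- function(maps, path) {
  rows <- lapply(maps, function(m) {
    nb <- ncol(m$power); nv <- nrow(m$power)
    data.frame(subject_id = m$subject_id, visit = m$visit,
               condition = m$condition,
               band = rep(colnames(m$power), each = nv),
               voxel_id = rep(seq_len(nv), nb),
               relative_power = as.vector(m$relative),
               z_power = as.vector(m$z))
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
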