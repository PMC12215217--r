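# Minimal European Data Format (EDF) writer/reader: 16-bit samples,
# one-second data records, physical units uV. Covers exactly what the
# package needs for round-tripping synthetic polysomnography.

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) stop(sprintf("EDF field '%s' exceeds %d bytes", x, width))
  formatC(x, width = -width)
}

#' Write a recording to an EDF file
#'
#' Signals are scaled per channel to symmetric integer physical bounds and
#' quantized to 16 bits; data records span one second, so the sampling
#' rate must be a whole number and the written duration is truncated to
#' whole seconds.
#'
#' @param recording a [new_recording()].
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_edf <- function(recording, path) {
  stopifnot(inherits(recording, "recording"))
  fs <- recording$sample_rate
  if (fs != round(fs)) stop("EDF export requires an integer sampling rate")
  labels <- names(recording$channels)
  ns <- length(labels)
  n_rec <- length(recording$channels[[1]]) %/% fs
  if (n_rec < 1) stop("recording shorter than one EDF data record")

  phys_max <- vapply(recording$channels, function(x) {
    max(1, ceiling(max(abs(x[seq_len(n_rec * fs)])) * 1.01))
  }, numeric(1))

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8),
    edf_pad(recording$participant, 80),
    edf_pad("remslope synthetic", 80),
    edf_pad("01.01.00", 8), edf_pad("00.00.00", 8),
    edf_pad(256 * (ns + 1), 8),
    edf_pad("", 44),
    edf_pad(n_rec, 8),
    edf_pad("1", 8),
    edf_pad(ns, 4)
  )
  field <- function(vals, width) paste0(vapply(vals, edf_pad, "", width = width), collapse = "")
  hdr <- paste0(
    hdr,
    field(labels, 16),
    field(rep("synthetic", ns), 80),
    field(rep("uV", ns), 8),
    field(-phys_max, 8),
    field(phys_max, 8),
    field(rep(-32768, ns), 8),
    field(rep(32767, ns), 8),
    field(rep("", ns), 80),
    field(rep(fs, ns), 8),
    field(rep("", ns), 32)
  )
  writeChar(hdr, con, eos = NULL)
  dig <- lapply(seq_len(ns), function(j) {
    x <- recording$channels[[j]][seq_len(n_rec * fs)]
    as.integer(round(x / phys_max[j] * 32767))
  })
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * fs + 1):(r * fs)
    for (j in seq_len(ns)) {
      writeBin(dig[[j]][idx], con, size = 2, endian = "little")
    }
  }
  invisible(path)
}

#' Read an EDF file
#'
#' Supports the subset written by [write_edf()] plus any EDF whose
#' channels share one sampling rate. Samples are returned in physical
#' units (uV); channels with differing rates raise an error rather than
#' being silently resampled.
#'
#' @param path EDF file.
#' @return list with `channels` (named list of numeric vectors),
#'   `sample_rate` (Hz) and `patient`.
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  version <- rd(8)
  patient <- rd(80)
  rd(80); rd(8); rd(8)
  header_bytes <- as.integer(rd(8))
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(ns) || ns < 1) stop("unreadable EDF header")
  rdv <- function(w) vapply(seq_len(ns), function(i) rd(w), "")
  labels <- rdv(16)
  rdv(80)
  rdv(8)
  phys_min <- as.numeric(rdv(8))
  phys_max <- as.numeric(rdv(8))
  dig_min <- as.numeric(rdv(8))
  dig_max <- as.numeric(rdv(8))
  rdv(80)
  spr <- as.integer(rdv(8))
  rdv(32)
  if (length(unique(spr / rec_dur)) != 1) {
    stop("channels disagree on sampling rate; refusing to resample silently")
  }
  seek(con, header_bytes)
  per_rec <- sum(spr)
  raw <- readBin(con, integer(), n = n_rec * per_rec, size = 2,
                 endian = "little", signed = TRUE)
  if (length(raw) < n_rec * per_rec) stop("EDF truncated: fewer samples than declared")
  channels <- vector("list", ns)
  names(channels) <- labels
  offs <- cumsum(c(0, spr[-ns]))
  for (j in seq_len(ns)) {
    idx <- as.vector(outer(offs[j] + seq_len(spr[j]),
                           (seq_len(n_rec) - 1) * per_rec, `+`))
    scale <- (phys_max[j] - phys_min[j]) / (dig_max[j] - dig_min[j])
    channels[[j]] <- (raw[idx] - dig_min[j]) * scale + phys_min[j]
  }
  list(channels = channels, sample_rate = spr[1] / rec_dur, patient = patient)
}

#' Write/read a hypnogram CSV
#'
#' One scored stage per row: `epoch_index,stage`.
#'
#' @param hypnogram character vector of stages.
#' @param path CSV file.
#' @return `write_hypnogram`: invisibly, `path`; `read_hypnogram`: the
#'   stage vector.
#' @export
write_hypnogram <- function(hypnogram, path) {
  utils::write.csv(
    data.frame(epoch_index = seq_along(hypnogram), stage = hypnogram),
    path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_hypnogram
#' @export
read_hypnogram <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("epoch_index", "stage") %in% names(df))) {
    stop("hypnogram CSV must have columns epoch_index,stage")
  }
  as.character(df$stage[order(df$epoch_index)])
}
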