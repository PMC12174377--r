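# Minimal European Data Format (EDF) I/O.
#
# EDF stores a 256-byte ASCII global header, 256 ASCII bytes per signal,
# then data records of 16-bit little-endian integers, channel-blocked per
# record. One-second records are used here; recordings are zero-padded to a
# whole number of seconds. Physical scaling is symmetric per channel.

.edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = -width)  # left-justified, space padded
}

#' Write a recording as EDF
#'
#' @param raw A [raw_recording()]. Events are not stored in the EDF; write
#'   them to a CSV sidecar.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_edf <- function(raw, path) {
  stopifnot(inherits(raw, "raw_recording"))
  fs <- raw$fs
  if (fs != round(fs)) stop("write_edf requires an integer sampling rate")
  ns <- nrow(raw$data)
  n_samp <- ncol(raw$data)
  n_rec <- ceiling(n_samp / fs)
  data <- raw$data
  if (n_rec * fs > n_samp) {
    data <- cbind(data, matrix(0, ns, n_rec * fs - n_samp))
  }
  phys_max <- pmax(apply(abs(data), 1, max) * 1.01, 1e-2)
  phys_max <- pmin(signif(phys_max, 4), 1e6)
  # header string and scaling must agree exactly (<= 7 chars in [1e-2, 1e6])
  pm_str <- trimws(vapply(phys_max, formatC, "", format = "fg", digits = 4))
  phys_max <- as.numeric(pm_str)
  dig_max <- 32767
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    .edf_pad("0", 8), .edf_pad("X X X X", 80), .edf_pad("Startdate X X X X", 80),
    .edf_pad("01.01.00", 8), .edf_pad("00.00.00", 8),
    .edf_pad(256 * (1 + ns), 8), .edf_pad("", 44),
    .edf_pad(n_rec, 8), .edf_pad(1, 8), .edf_pad(ns, 4))
  writeChar(hdr, con, eos = NULL)
  fld <- function(vals, width) {
    writeChar(paste0(vapply(vals, .edf_pad, "", width = width),
                     collapse = ""), con, eos = NULL)
  }
  fld(paste("EEG", raw$channel_names), 16)
  fld(rep("", ns), 80)
  fld(rep("uV", ns), 8)
  fld(paste0("-", pm_str), 8)
  fld(pm_str, 8)
  fld(rep(-dig_max, ns), 8)
  fld(rep(dig_max, ns), 8)
  fld(rep("", ns), 80)
  fld(rep(fs, ns), 8)
  fld(rep("", ns), 32)
  scale <- dig_max / phys_max
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * fs + 1):(r * fs)
    block <- round(data[, idx, drop = FALSE] * scale)
    writeBin(as.integer(t(block)), con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Read an EDF file written by [write_edf()]
#'
#' Supports the plain 16-bit EDF layout with equal sampling rates across
#' signals, which is what this package writes.
#'
#' @param path EDF file path.
#' @return A [raw_recording()] (without events).
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(nc) trimws(readChar(con, nc, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8)  # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  rdv <- function(width) vapply(seq_len(ns), function(i) rd(width), "")
  labels <- sub("^EEG ", "", rdv(16))
  rdv(80)
  rdv(8)  # dims
  pmin_ <- as.numeric(rdv(8)); pmax_ <- as.numeric(rdv(8))
  dmin_ <- as.numeric(rdv(8)); dmax_ <- as.numeric(rdv(8))
  rdv(80)
  spr <- as.integer(rdv(8))
  rdv(32)
  if (length(unique(spr)) != 1L)
    stop("read_edf supports equal sampling rates only")
  fs <- spr[1] / rec_dur
  data <- matrix(0, nrow = ns, ncol = n_rec * spr[1])
  gain <- (pmax_ - pmin_) / (dmax_ - dmin_)
  off <- pmax_ - gain * dmax_
  for (r in seq_len(n_rec)) {
    block <- readBin(con, "integer", n = ns * spr[1], size = 2,
                     signed = TRUE, endian = "little")
    block <- matrix(block, nrow = spr[1], ncol = ns)
    idx <- ((r - 1) * spr[1] + 1):(r * spr[1])
    data[, idx] <- t(block) * gain + off
  }
  raw_recording(data, fs, labels)
}
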