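# Minimal EDF (European Data Format) reader/writer for continuous,
# uniformly sampled recordings: 16-bit samples with per-signal physical
# scaling, 1-s data records. Covers the interchange needs of this package;
# discontinuous (EDF+D) files are rejected.

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = width, flag = "-")
}

#' Write a recording to an EDF file
#'
#' All channels share the sampling rate; samples are quantized to 16 bits
#' over the channel's physical range. Header date/time fields are fixed so
#' identical recordings produce byte-identical files.
#'
#' @param rec a [nap_recording()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  rate <- rec$sampling_rate
  if (rate != round(rate)) abort("EDF writer requires an integer sampling rate.")
  ns <- nrow(rec$data)
  n <- ncol(rec$data)
  n_rec <- ceiling(n / rate)
  pad <- n_rec * rate - n
  dat <- cbind(rec$data, matrix(0, ns, pad))
  phys_min <- apply(dat, 1, min)
  phys_max <- apply(dat, 1, max)
  same <- phys_max - phys_min < 1e-9
  phys_min[same] <- phys_min[same] - 1
  phys_max[same] <- phys_max[same] + 1
  dig_min <- -32768; dig_max <- 32767

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8),
    edf_pad("X X X X", 80),
    edf_pad(paste0("Startdate 01-JAN-2000 X X X block_", rec$block), 80),
    edf_pad("01.01.00", 8), edf_pad("00.00.00", 8),
    edf_pad(256 * (ns + 1), 8),
    edf_pad("", 44),
    edf_pad(n_rec, 8),
    edf_pad("1", 8),
    edf_pad(ns, 4))
  writeChar(hdr, con, eos = NULL)
  fields <- list(
    vapply(rec$channel_names, edf_pad, "", width = 16),
    rep(edf_pad("", 80), ns),
    rep(edf_pad("uV", 8), ns),
    vapply(sprintf("%.6g", phys_min), edf_pad, "", width = 8),
    vapply(sprintf("%.6g", phys_max), edf_pad, "", width = 8),
    rep(edf_pad(dig_min, 8), ns),
    rep(edf_pad(dig_max, 8), ns),
    rep(edf_pad("", 80), ns),
    rep(edf_pad(rate, 8), ns),
    rep(edf_pad("", 32), ns))
  for (f in fields) writeChar(paste(f, collapse = ""), con, eos = NULL)

  scale <- (dig_max - dig_min) / (phys_max - phys_min)
  dig <- round((dat - phys_min) * scale) + dig_min
  dig <- pmin(pmax(dig, dig_min), dig_max)
  for (r in seq_len(n_rec)) {
    ii <- ((r - 1) * rate + 1):(r * rate)
    block <- t(dig[, ii, drop = FALSE])      # per-signal contiguous
    writeBin(as.integer(block), con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Read an EDF file into a recording
#'
#' Requires a uniform sampling rate across signals; EDF+D (discontinuous)
#' files and rate mismatches are rejected.
#'
#' @param path EDF file path.
#' @param block block label to attach (parsed from the header if present).
#' @return a [nap_recording()].
#' @export
read_edf <- function(path, block = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(k) trimws(readChar(con, k, useBytes = TRUE))
  rd(8)                                   # version
  rd(80)                                  # patient
  rec_field <- rd(80)
  rd(8); rd(8); rd(8)                     # date, time, header bytes
  reserved <- rd(44)
  if (grepl("EDF\\+D", reserved)) abort("discontinuous EDF+D is not supported.")
  n_rec <- as.integer(rd(8))
  dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- vapply(seq_len(ns), function(i) rd(16), "")
  vapply(seq_len(ns), function(i) rd(80), "")
  vapply(seq_len(ns), function(i) rd(8), "")
  phys_min <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  phys_max <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dig_min <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dig_max <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  vapply(seq_len(ns), function(i) rd(80), "")
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8), ""))
  vapply(seq_len(ns), function(i) rd(32), "")
  if (length(unique(spr / dur)) != 1) {
    abort("mismatched sampling rates across EDF signals.")
  }
  rate <- spr[1] / dur
  dat <- matrix(0, ns, n_rec * spr[1])
  for (r in seq_len(n_rec)) {
    raw <- readBin(con, "integer", n = sum(spr), size = 2, signed = TRUE,
                   endian = "little")
    off <- 0
    for (s in seq_len(ns)) {
      v <- raw[(off + 1):(off + spr[s])]
      dat[s, ((r - 1) * spr[s] + 1):(r * spr[s])] <-
        phys_min[s] + (v - dig_min[s]) *
        (phys_max[s] - phys_min[s]) / (dig_max[s] - dig_min[s])
      off <- off + spr[s]
    }
  }
  if (is.null(block)) {
    m <- regmatches(rec_field, regexec("block_(\\w+)", rec_field))[[1]]
    block <- if (length(m) == 2 &&
                 m[2] %in% c("round1", "nap", "round2")) m[2] else "nap"
  }
  nap_recording(dat, labels, rate, block)
}
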