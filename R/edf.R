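#' Minimal EDF reader and writer
#'
#' Reads European Data Format (EDF) files: the 256-byte ASCII header, the
#' per-signal header block, and the 16-bit little-endian data records, with
#' digital-to-physical scaling applied per signal. All signals must share one
#' sampling rate; annotation channels ("EDF Annotations") are dropped.
#'
#' This is a deliberately small reader covering plain continuous EDF; it does
#' not handle EDF+ discontinuous records or embedded annotations beyond
#' skipping the annotation signal.
#'
#' @param path an EDF file.
#' @return A `recording` in physical units.
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr_field <- function(n) trimws(rawToChar(readBin(con, "raw", n)))
  version <- hdr_field(8)
  if (version != "0") stop("not an EDF file (version field ", version, "): ", path)
  hdr_field(80); hdr_field(80); hdr_field(8); hdr_field(8) # patient, rec, date, time
  header_bytes <- as.integer(hdr_field(8))
  hdr_field(44) # reserved
  n_records <- as.integer(hdr_field(8))
  record_dur <- as.numeric(hdr_field(8))
  ns <- as.integer(hdr_field(4))
  if (is.na(ns) || ns < 1) stop("EDF header declares no signals: ", path)
  sig_field <- function(n) {
    vapply(seq_len(ns), function(i) trimws(rawToChar(readBin(con, "raw", n))),
           character(1))
  }
  labels <- sig_field(16)
  sig_field(80); sig_field(8) # transducer, physical dimension
  phys_min <- as.numeric(sig_field(8))
  phys_max <- as.numeric(sig_field(8))
  dig_min <- as.numeric(sig_field(8))
  dig_max <- as.numeric(sig_field(8))
  sig_field(80) # prefiltering
  n_samp <- as.integer(sig_field(8))
  sig_field(32) # reserved
  seek(con, header_bytes)

  keep <- labels != "EDF Annotations"
  if (!any(keep)) stop("EDF file contains only annotation signals: ", path)
  if (length(unique(n_samp[keep])) > 1) {
    stop("EDF signals have differing sampling rates (samples per record: ",
         paste(unique(n_samp[keep]), collapse = ", "), "); not supported")
  }
  if (record_dur <= 0) stop("EDF record duration must be positive")
  fs <- n_samp[keep][1] / record_dur

  scale <- (phys_max - phys_min) / (dig_max - dig_min)
  out <- vector("list", ns)
  for (i in which(keep)) out[[i]] <- vector("list", n_records)
  for (r in seq_len(n_records)) {
    for (i in seq_len(ns)) {
      dig <- readBin(con, "integer", n = n_samp[i], size = 2,
                     signed = TRUE, endian = "little")
      if (keep[i]) {
        out[[i]][[r]] <- (dig - dig_min[i]) * scale[i] + phys_min[i]
      }
    }
  }
  data <- do.call(rbind, lapply(which(keep), function(i) unlist(out[[i]])))
  recording(data, fs = fs, channel_names = labels[keep])
}

#' @rdname read_edf
#' @param rec a `recording` to write. Samples are scaled into the 16-bit
#'   digital range using each channel's observed amplitude range, so the
#'   round trip is lossy at roughly `range / 65534` resolution.
#' @param record_seconds data-record length in seconds; `duration(rec)` must
#'   be an integer multiple of it. Defaults to 1 second, or the whole
#'   recording if shorter.
#' @export
write_edf <- function(rec, path, record_seconds = NULL) {
  stopifnot(inherits(rec, "recording"))
  if (is.null(record_seconds)) {
    record_seconds <- min(1, duration(rec))
  }
  n_per_rec <- round(record_seconds * rec$fs)
  if (n_per_rec < 1 || n_samples(rec) %% n_per_rec != 0) {
    stop("duration must be an integer multiple of record_seconds")
  }
  n_records <- n_samples(rec) %/% n_per_rec
  nc <- n_channels(rec)
  pmin_ <- apply(rec$data, 1, min)
  pmax_ <- apply(rec$data, 1, max)
  flat <- pmax_ == pmin_
  pmax_[flat] <- pmin_[flat] + 1
  dmin <- -32767; dmax <- 32767

  pad <- function(x, n) {
    x <- as.character(x)
    vapply(x, function(s) {
      if (nchar(s) > n) s <- substr(s, 1, n)
      sprintf("%-*s", n, s)
    }, character(1), USE.NAMES = FALSE)
  }
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(x) writeChar(paste(x, collapse = ""), con, eos = NULL)
  wr(pad("0", 8)); wr(pad("X", 80)); wr(pad("X", 80))
  wr(pad("01.01.26", 8)); wr(pad("00.00.00", 8))
  wr(pad(256 * (1 + nc), 8)); wr(pad("", 44))
  wr(pad(n_records, 8)); wr(pad(format(record_seconds), 8)); wr(pad(nc, 4))
  wr(pad(rec$channel_names, 16)); wr(pad(rep("", nc), 80)); wr(pad(rep("uV", nc), 8))
  wr(pad(formatC(pmin_, digits = 6, format = "g"), 8))
  wr(pad(formatC(pmax_, digits = 6, format = "g"), 8))
  wr(pad(rep(dmin, nc), 8)); wr(pad(rep(dmax, nc), 8))
  wr(pad(rep("", nc), 80)); wr(pad(rep(n_per_rec, nc), 8)); wr(pad(rep("", nc), 32))
  pmin_num <- as.numeric(pad(formatC(pmin_, digits = 6, format = "g"), 8))
  pmax_num <- as.numeric(pad(formatC(pmax_, digits = 6, format = "g"), 8))
  for (r in seq_len(n_records)) {
    cols <- ((r - 1) * n_per_rec + 1):(r * n_per_rec)
    for (i in seq_len(nc)) {
      x <- rec$data[i, cols]
      dig <- round((x - pmin_num[i]) / (pmax_num[i] - pmin_num[i]) *
                     (dmax - dmin) + dmin)
      dig <- pmin(pmax(dig, dmin), dmax)
      writeBin(as.integer(dig), con, size = 2, endian = "little")
    }
  }
  invisible(path)
}
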