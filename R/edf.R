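# Minimal EDF (European Data Format) reader and writer.
#
# EDF stores a fixed-width ASCII header (256 bytes + 256 per signal) followed
# by data records of 16-bit little-endian integers, linearly mapped between
# digital and physical ranges. Only the continuous-signal subset needed for
# polysomnography is implemented: one sampling rate per signal, uniform
# record duration.

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1L, width)
  formatC(x, width = width, flag = "-")
}

edf_num <- function(x, width) {
  # shrink precision until the rendering fits the fixed-width field intact
  for (dg in seq(8L, 1L)) {
    s <- formatC(signif(x, dg), format = "g", digits = dg)
    if (nchar(s) <= width) break
  }
  if (nchar(s) > width) stop("numeric header field does not fit: ", x)
  formatC(s, width = width, flag = "-")
}

#' Write signals to an EDF file
#'
#' @param path Output file path.
#' @param signals Named list of numeric vectors (one per channel); all channels
#'   must share the sampling rate `fs` and have a common duration that is an
#'   integer number of seconds.
#' @param fs Sampling rate in Hz (integer).
#' @param patient,recording Free-text EDF identification fields.
#' @return `path`, invisibly.
#' @export
write_edf <- function(path, signals, fs, patient = "X", recording = "synthetic") {
  stopifnot(is.list(signals), length(signals) >= 1L, fs > 0)
  ns <- length(signals)
  n <- unique(vapply(signals, length, integer(1)))
  if (length(n) != 1L) stop("all channels must have equal length")
  record_dur <- 1L
  spr <- as.integer(round(fs * record_dur))
  n_rec <- n %/% spr
  if (n_rec < 1L) stop("signals shorter than one data record")
  n_use <- n_rec * spr

  phys_min <- phys_max <- numeric(ns)
  dig <- matrix(0L, nrow = n_use, ncol = ns)
  for (i in seq_len(ns)) {
    x <- signals[[i]][seq_len(n_use)]
    lo <- min(x); hi <- max(x)
    if (hi - lo < 1e-12) { hi <- lo + 1 }  # degenerate constant channel
    phys_min[i] <- lo; phys_max[i] <- hi
    dig[, i] <- as.integer(round((x - lo) / (hi - lo) * 65535 - 32768))
  }

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8), edf_pad(patient, 80), edf_pad(recording, 80),
    edf_pad("01.01.26", 8), edf_pad("00.00.00", 8),
    edf_pad(256L * (ns + 1L), 8), edf_pad("", 44),
    edf_pad(n_rec, 8), edf_pad(record_dur, 8), edf_pad(ns, 4))
  labs <- names(signals) %||% paste0("ch", seq_len(ns))
  sig_hdr <- paste0(
    paste(vapply(labs, edf_pad, "", width = 16), collapse = ""),
    paste(rep(edf_pad("", 80), ns), collapse = ""),
    paste(rep(edf_pad("uV", 8), ns), collapse = ""),
    paste(vapply(phys_min, edf_num, "", width = 8), collapse = ""),
    paste(vapply(phys_max, edf_num, "", width = 8), collapse = ""),
    paste(rep(edf_pad(-32768L, 8), ns), collapse = ""),
    paste(rep(edf_pad(32767L, 8), ns), collapse = ""),
    paste(rep(edf_pad("", 80), ns), collapse = ""),
    paste(rep(edf_pad(spr, 8), ns), collapse = ""),
    paste(rep(edf_pad("", 32), ns), collapse = ""))
  writeChar(paste0(hdr, sig_hdr), con, eos = NULL)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1L) * spr + 1L):(r * spr)
    writeBin(as.integer(as.vector(dig[idx, ])), con, size = 2L, endian = "little")
  }
  invisible(path)
}

#' Read an EDF file
#'
#' @param path EDF file path.
#' @return List with `signals` (named list of numeric vectors in physical
#'   units), `fs` (per-channel sampling rates), `labels`, `n_records`,
#'   `record_duration`, `patient`, `recording`.
#' @export
read_edf <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) {
    raw <- readChar(con, w, useBytes = TRUE)
    if (nchar(raw, type = "bytes") < w) stop("unreadable EDF header (truncated)")
    trimws(raw)
  }
  version <- rd(8)
  if (!identical(version, "0")) stop("unreadable EDF header (bad version field)")
  patient <- rd(80); recording <- rd(80)
  rd(8); rd(8)                      # start date/time
  rd(8); rd(44)                     # header bytes, reserved
  n_rec <- as.integer(rd(8)); record_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(ns) || ns < 1L) stop("unreadable EDF header (signal count)")
  field <- function(w) vapply(seq_len(ns), function(i) rd(w), "")
  labels <- field(16); field(80); field(8)
  phys_min <- as.numeric(field(8)); phys_max <- as.numeric(field(8))
  dig_min <- as.numeric(field(8)); dig_max <- as.numeric(field(8))
  field(80)
  spr <- as.integer(field(8)); field(32)

  total <- sum(spr) * n_rec
  raw <- readBin(con, integer(), n = total, size = 2L, endian = "little")
  sig <- vector("list", ns)
  names(sig) <- labels
  offs <- c(0L, cumsum(spr))
  rec_len <- sum(spr)
  for (i in seq_len(ns)) {
    idx <- as.vector(outer((offs[i] + 1L):offs[i + 1L], (seq_len(n_rec) - 1L) * rec_len, "+"))
    d <- raw[idx]
    scale <- (phys_max[i] - phys_min[i]) / (dig_max[i] - dig_min[i])
    sig[[i]] <- phys_min[i] + (d - dig_min[i]) * scale
  }
  list(signals = sig, fs = spr / record_dur, labels = labels,
       n_records = n_rec, record_duration = record_dur,
       patient = patient, recording = recording)
}

#' Write a plain-text hypnogram
#'
#' Two whitespace-separated columns: 0-based epoch index and stage code
#' (`W`, `N1`, `N2`, `N3`, `R`), one 30-s epoch per line.
#'
#' @param path Output path.
#' @param labels Stage codes (character, factor or 1..5 integer).
#' @return `path`, invisibly.
#' @export
write_hypnogram <- function(path, labels) {
  lab <- as.character(as_stage_factor(labels))
  writeLines(paste(seq_along(lab) - 1L, lab), path)
  invisible(path)
}

#' Read a plain-text hypnogram
#'
#' @param path Path to a two-column text file (epoch index, stage code).
#' @param epoch_len_s Epoch length in seconds (30 by convention).
#' @return A `hypnogram` object.
#' @export
read_hypnogram <- function(path, epoch_len_s = 30) {
  tab <- utils::read.table(path, header = FALSE, col.names = c("epoch", "stage"),
                           colClasses = c("integer", "character"))
  tab <- tab[order(tab$epoch), , drop = FALSE]
  hypnogram(tab$stage, epoch_len_s = epoch_len_s)
}

#' Construct a hypnogram
#'
#' @param labels Per-epoch stage codes.
#' @param epoch_len_s Epoch length in seconds.
#' @return Object of class `hypnogram`: a stage factor with the epoch length
#'   attached.
#' @export
hypnogram <- function(labels, epoch_len_s = 30) {
  structure(list(labels = as_stage_factor(labels), epoch_len_s = epoch_len_s),
            class = "hypnogram")
}

#' @export
print.hypnogram <- function(x, ...) {
  cat("<hypnogram> ", length(x$labels), " epochs x ", x$epoch_len_s, " s\n", sep = "")
  print(table(x$labels))
  invisible(x)
}

#' @export
length.hypnogram <- function(x) length(x$labels)
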