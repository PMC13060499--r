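# Polysomnography ingestion: EDF -> preprocessed recording -> per-epoch
# time-frequency tensors -> fixed-length sequence batches.
#
# Preprocessing follows the standard sequence-to-sequence sleep-staging recipe:
# resample everything to 100 Hz, band-pass EEG/EOG to [0.3, 40] Hz, high-pass
# EMG at 10 Hz, then per 30-s epoch compute a 2-s/50%-overlap Hamming STFT with
# a 256-point FFT, convert the amplitude spectrum to dB and clip at -25 dB.

PSG_FS <- 100L          # target sampling rate (Hz)
EPOCH_SAMPLES <- 3000L  # 30 s at 100 Hz
STFT_WIN <- 200L        # 2 s window
STFT_HOP <- 100L        # 50% overlap
STFT_NFFT <- 256L
SPEC_T <- 29L           # frames per epoch: floor((3000-200)/100)+1
SPEC_F <- 129L          # one-sided bins: 256/2+1
SPEC_CLIP_DB <- -25

#' Construct a PSG recording object
#'
#' @param signals Named list of numeric waveforms; names are channel roles.
#' @param fs Sampling rate in Hz (shared by all channels).
#' @param channel_roles Ordered roles, default `c("EEG","EOG","EMG")`.
#' @param subject_id Opaque subject identifier.
#' @param preprocessed Logical flag set by [preprocess_signals()].
#' @return Object of class `psg_recording`.
#' @export
psg_recording <- function(signals, fs, channel_roles = c("EEG", "EOG", "EMG"),
                          subject_id = "subject", preprocessed = FALSE) {
  stopifnot(is.list(signals), fs > 0)
  if (!all(channel_roles %in% names(signals))) {
    stop("signals must be named by the channel roles: ",
         paste(channel_roles, collapse = ", "))
  }
  signals <- signals[channel_roles]
  len <- unique(vapply(signals, length, integer(1)))
  if (length(len) != 1L) stop("all channels must have equal length")
  structure(list(signals = signals, fs = fs, channel_roles = channel_roles,
                 subject_id = subject_id, preprocessed = preprocessed),
            class = "psg_recording")
}

#' @export
print.psg_recording <- function(x, ...) {
  cat("<psg_recording> ", x$subject_id, ": ",
      paste(x$channel_roles, collapse = "/"), ", ",
      length(x$signals[[1]]) / x$fs, " s @ ", x$fs, " Hz",
      if (x$preprocessed) " (preprocessed)", "\n", sep = "")
  invisible(x)
}

#' Load a PSG recording from an EDF file
#'
#' Reads the file and keeps only the three channels named by `channel_map`,
#' attaching them to their roles. Extra channels in the file are dropped.
#'
#' @param path EDF file path.
#' @param channel_map Named character vector mapping roles to channel labels in
#'   the file, e.g. `c(EEG = "C4-A1", EOG = "EOG", EMG = "chin")`.
#' @param subject_id Identifier stored on the recording (default: file name).
#' @return A `psg_recording` at the file's native sampling rate.
#' @export
load_psg_recording <- function(path, channel_map = c(EEG = "EEG", EOG = "EOG", EMG = "EMG"),
                               subject_id = NULL) {
  roles <- c("EEG", "EOG", "EMG")
  missing_roles <- setdiff(roles, names(channel_map))
  if (length(missing_roles) > 0L) {
    stop("channel_map missing role(s): ", paste(missing_roles, collapse = ", "))
  }
  edf <- read_edf(path)
  sig <- vector("list", length(roles))
  names(sig) <- roles
  fs <- NULL
  for (r in roles) {
    lab <- channel_map[[r]]
    j <- match(lab, edf$labels)
    if (is.na(j)) {
      stop("role ", r, ": channel '", lab, "' not found in file (available: ",
           paste(edf$labels, collapse = ", "), ")")
    }
    sig[[r]] <- edf$signals[[j]]
    fs <- c(fs, edf$fs[j])
  }
  if (length(unique(fs)) != 1L) stop("mapped channels have differing sampling rates")
  psg_recording(sig, fs = fs[1],
                subject_id = subject_id %||% basename(path))
}

resample_to <- function(x, fs_from, fs_to) {
  if (fs_from == fs_to) return(x)
  p <- as.integer(round(fs_to)); q <- as.integer(round(fs_from))
  g <- gcd_int(p, q)
  as.numeric(signal::resample(x, p %/% g, q %/% g))
}

gcd_int <- function(a, b) if (b == 0L) a else gcd_int(b, a %% b)

#' Preprocess a PSG recording
#'
#' Resamples all channels to 100 Hz (polyphase rational resampling), band-pass
#' filters EEG and EOG to [0.3, 40] Hz, and high-pass filters EMG at 10 Hz.
#' Filters are 4th-order Butterworth applied forward-backward (zero phase).
#'
#' @param rec A `psg_recording`.
#' @return A preprocessed `psg_recording` at 100 Hz.
#' @export
preprocess_signals <- function(rec) {
  stopifnot(inherits(rec, "psg_recording"))
  if (rec$fs < 20) stop("sampling rate below 20 Hz cannot represent the sleep bands")
  if (length(rec$signals[[1]]) < rec$fs) stop("need at least 1 s of data per channel")
  sig <- lapply(rec$signals, resample_to, fs_from = rec$fs, fs_to = PSG_FS)
  nyq <- PSG_FS / 2
  bp <- signal::butter(4, c(0.3, 40) / nyq, type = "pass")
  hp <- signal::butter(4, 10 / nyq, type = "high")
  for (r in rec$channel_roles) {
    flt <- if (r == "EMG") hp else bp
    sig[[r]] <- as.numeric(signal::filtfilt(flt, sig[[r]]))
  }
  psg_recording(sig, fs = PSG_FS, channel_roles = rec$channel_roles,
                subject_id = rec$subject_id, preprocessed = TRUE)
}

# One-sided amplitude-spectrum STFT of one channel split into 30-s epochs.
# Returns array (n_epochs, T, F) in dB, clipped below at SPEC_CLIP_DB.
channel_spectrogram <- function(x, n_epochs) {
  win <- signal::hamming(STFT_WIN)
  starts <- as.vector(outer(seq(0L, by = STFT_HOP, length.out = SPEC_T),
                            (seq_len(n_epochs) - 1L) * EPOCH_SAMPLES, "+"))
  frames <- matrix(0, nrow = STFT_NFFT, ncol = length(starts))
  idx <- outer(seq_len(STFT_WIN), starts, "+")   # 1-based sample indices
  frames[seq_len(STFT_WIN), ] <- x[idx] * win
  spec <- Mod(stats::mvfft(frames))[seq_len(SPEC_F), , drop = FALSE]
  db <- pmax(20 * log10(spec + 1e-12), SPEC_CLIP_DB)
  aperm(array(db, dim = c(SPEC_F, SPEC_T, n_epochs)), c(3L, 2L, 1L))
}

#' Epoch a recording into time-frequency images
#'
#' Splits each channel into 30-s epochs aligned to the hypnogram (epoch n
#' covers samples `[n*3000, (n+1)*3000)` at 100 Hz, 0-based) and computes the
#' per-epoch log-power spectrogram. Channels are standardized to zero mean and
#' unit variance per recording before the STFT so the dB scale is comparable
#' across subjects.
#'
#' @param rec A preprocessed `psg_recording` (100 Hz).
#' @param hyp A `hypnogram` aligned to the recording.
#' @return An `epoch_tensor`: list with `values` array
#'   `(n_epochs, C = 3, T = 29, F = 129)` in dB (elementwise >= -25) and
#'   `labels` stage factor.
#' @export
epoch_and_spectrogram <- function(rec, hyp) {
  stopifnot(inherits(rec, "psg_recording"), inherits(hyp, "hypnogram"))
  if (rec$fs != PSG_FS) stop("recording must be preprocessed to 100 Hz first")
  n_epochs <- length(hyp$labels)
  need <- n_epochs * EPOCH_SAMPLES
  if (need > length(rec$signals[[1]])) {
    stop("hypnogram longer than recording (", n_epochs, " epochs need ",
         need, " samples, have ", length(rec$signals[[1]]), ")")
  }
  C <- length(rec$channel_roles)
  values <- array(0, dim = c(n_epochs, C, SPEC_T, SPEC_F))
  for (ci in seq_len(C)) {
    x <- rec$signals[[ci]]
    sdx <- stats::sd(x)
    if (sdx > 0) x <- (x - mean(x)) / sdx
    values[, ci, , ] <- channel_spectrogram(x, n_epochs)
  }
  epoch_tensor(values, hyp$labels, channel_roles = rec$channel_roles)
}

#' Construct an epoch tensor
#'
#' @param values Array `(n_epochs, C, T, F)` of dB spectrogram cells.
#' @param labels Stage codes aligned to the first dimension.
#' @param channel_roles Channel role names for the second dimension.
#' @return Object of class `epoch_tensor`.
#' @export
epoch_tensor <- function(values, labels, channel_roles = c("EEG", "EOG", "EMG")) {
  stopifnot(length(dim(values)) == 4L, dim(values)[1] == length(labels))
  structure(list(values = values, labels = as_stage_factor(labels),
                 channel_roles = channel_roles),
            class = "epoch_tensor")
}

#' @export
print.epoch_tensor <- function(x, ...) {
  d <- dim(x$values)
  cat("<epoch_tensor> ", d[1], " epochs x ", d[2], " ch x ", d[3], " frames x ",
      d[4], " bins (dB, clipped at ", SPEC_CLIP_DB, ")\n", sep = "")
  invisible(x)
}

#' Trim over-represented wake at the recording edges
#'
#' Removes leading and trailing Wake runs beyond a margin around the first and
#' last non-Wake epoch. Never removes non-Wake epochs; a recording with no
#' sleep at all is returned unchanged with attribute `all_wake = TRUE` and a
#' warning.
#'
#' @param epochs An `epoch_tensor`.
#' @param margin Number of Wake epochs to retain on each side (default 60,
#'   i.e. 30 minutes).
#' @return A trimmed `epoch_tensor`.
#' @export
trim_wake <- function(epochs, margin = 60L) {
  stopifnot(inherits(epochs, "epoch_tensor"), margin >= 0L)
  lab <- epochs$labels
  sleep <- which(lab != "W")
  if (length(sleep) == 0L) {
    warning("recording contains no sleep epochs; returned unchanged")
    attr(epochs, "all_wake") <- TRUE
    return(epochs)
  }
  lo <- max(1L, min(sleep) - margin)
  hi <- min(length(lab), max(sleep) + margin)
  keep <- lo:hi
  epoch_tensor(epochs$values[keep, , , , drop = FALSE], lab[keep],
               channel_roles = epochs$channel_roles)
}

#' Cut an epoch tensor into fixed-length sequences
#'
#' @param epochs An `epoch_tensor`.
#' @param L Sequence length in epochs (default 21).
#' @param stride Window stride in epochs (default `L`, i.e. non-overlapping).
#' @return A `sequence_batch`: list with `values` `(B, L, C, T, F)` and
#'   `labels` `(B, L)` stage matrix. `B = 0` with a warning when fewer than
#'   `L` epochs are available.
#' @export
make_sequences <- function(epochs, L = 21L, stride = L) {
  stopifnot(inherits(epochs, "epoch_tensor"), L >= 1L, stride >= 1L)
  d <- dim(epochs$values)
  n <- d[1]
  if (n < L) {
    warning("fewer epochs (", n, ") than sequence length (", L, "); empty batch")
    starts <- integer(0)
  } else {
    starts <- seq(1L, n - L + 1L, by = stride)
  }
  B <- length(starts)
  values <- array(0, dim = c(B, L, d[2], d[3], d[4]))
  labels <- matrix(NA_integer_, nrow = B, ncol = L)
  for (b in seq_len(B)) {
    idx <- starts[b]:(starts[b] + L - 1L)
    values[b, , , , ] <- epochs$values[idx, , , , drop = FALSE]
    labels[b, ] <- as.integer(epochs$labels[idx])
  }
  sequence_batch(values, labels, channel_roles = epochs$channel_roles)
}

#' Construct a sequence batch
#'
#' @param values Array `(B, L, C, T, F)`.
#' @param labels Integer matrix `(B, L)` of stage codes 1..5, or NULL.
#' @param channel_roles Channel role names.
#' @return Object of class `sequence_batch`.
#' @export
sequence_batch <- function(values, labels = NULL, channel_roles = c("EEG", "EOG", "EMG")) {
  stopifnot(length(dim(values)) == 5L)
  if (!is.null(labels)) stopifnot(all(dim(labels) == dim(values)[1:2]))
  structure(list(values = values, labels = labels, channel_roles = channel_roles),
            class = "sequence_batch")
}

#' @export
print.sequence_batch <- function(x, ...) {
  d <- dim(x$values)
  cat("<sequence_batch> B=", d[1], " L=", d[2], " C=", d[3], " T=", d[4],
      " F=", d[5], "\n", sep = "")
  invisible(x)
}
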