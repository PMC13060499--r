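# Stage-structured synthetic polysomnography.
#
# The generator emulates the features the downstream pipeline consumes:
# stage-dependent EEG band power (band-limited noise mixed by template
# weights), EOG blink/REM event trains convolved with biphasic/sharp kernels,
# EMG tone as amplitude-modulated broadband noise, and Markovian 30-s stage
# sequences. Cohort-level condition effects shift transition rows and band
# powers multiplicatively so the clinical pipeline has planted group
# differences to find.

EEG_BANDS <- list(delta = c(0.5, 4), theta = c(4, 8), alpha = c(8, 12),
                  sigma = c(12, 16), beta = c(16, 30), gamma = c(30, 40))

#' Per-stage synthesis templates
#'
#' Relative EEG band powers, EOG event rates (blinks with 0.5-2 Hz content,
#' rapid eye movements with 2-5 Hz content, per minute) and EMG tone for each
#' of the five stages. Values are the package's standing description of
#' textbook stage physiology: wake is beta/alpha-rich with blinks and high
#' muscle tone, N2 is sigma (spindle) and delta dominated, N3 is delta
#' dominated, REM couples wake-like EEG with dense eye movements and atonia.
#'
#' @return Named list of five stage templates.
#' @export
default_stage_templates <- function() {
  tmpl <- function(eeg, blinks, rems, emg) {
    names(eeg) <- names(EEG_BANDS)
    list(eeg_band_powers = eeg,
         eog_event_rates = c(blinks = blinks, rems = rems),
         emg_tone = emg)
  }
  list(
    W  = tmpl(c(0.5, 0.7, 1.5, 0.4, 1.6, 0.8), blinks = 15, rems = 2,  emg = 1.0),
    N1 = tmpl(c(1.0, 1.6, 0.8, 0.5, 0.5, 0.2), blinks = 0,  rems = 1,  emg = 0.6),
    N2 = tmpl(c(2.2, 1.2, 0.6, 1.8, 0.4, 0.15), blinks = 0, rems = 0,  emg = 0.4),
    N3 = tmpl(c(5.0, 1.0, 0.4, 0.8, 0.2, 0.1), blinks = 0,  rems = 0,  emg = 0.3),
    R  = tmpl(c(0.8, 1.2, 0.6, 0.3, 1.0, 0.4), blinks = 4,  rems = 12, emg = 0.1)
  )
}

#' Default stage transition matrix
#'
#' Row-stochastic 5x5 matrix of per-30-s stage transition probabilities with
#' strong self-transitions and the canonical Wake -> N1 -> N2 -> N3 / REM
#' progression of healthy overnight sleep.
#'
#' @return 5x5 matrix with rows/columns named by [stage_levels()].
#' @export
default_transition_matrix <- function() {
  P <- rbind(
    W  = c(0.88, 0.09, 0.01, 0.00, 0.02),
    N1 = c(0.05, 0.68, 0.24, 0.00, 0.03),
    N2 = c(0.02, 0.03, 0.84, 0.08, 0.03),
    N3 = c(0.01, 0.01, 0.11, 0.86, 0.01),
    R  = c(0.02, 0.03, 0.05, 0.00, 0.90))
  colnames(P) <- stage_levels()
  P / rowSums(P)
}

#' Synthetic recording configuration
#'
#' @param stage_templates Named list of 5 stage templates
#'   (see [default_stage_templates()]).
#' @param transition_matrix 5x5 row-stochastic matrix.
#' @param duration_epochs Number of 30-s epochs to generate.
#' @param fs Native sampling rate in Hz.
#' @param noise_sd Additive white-noise standard deviation on every channel.
#' @param initial_stage Stage the chain starts in.
#' @param seed Integer master seed; the whole recording is deterministic in it.
#' @return Object of class `synthetic_config`.
#' @export
synthetic_config <- function(stage_templates = default_stage_templates(),
                             transition_matrix = default_transition_matrix(),
                             duration_epochs = 120L, fs = 100L, noise_sd = 0.1,
                             initial_stage = "W", seed = 1L) {
  stopifnot(length(stage_templates) == 5L, duration_epochs >= 1L, fs >= 20)
  if (any(abs(rowSums(transition_matrix) - 1) > 1e-9)) {
    stop("transition matrix rows must sum to 1")
  }
  for (t in stage_templates) {
    if (any(t$eeg_band_powers < 0) || all(t$eeg_band_powers == 0)) {
      stop("band powers must be nonnegative with at least one positive")
    }
  }
  structure(list(stage_templates = stage_templates,
                 transition_matrix = transition_matrix,
                 duration_epochs = as.integer(duration_epochs), fs = fs,
                 noise_sd = noise_sd, initial_stage = initial_stage,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

sample_markov_stages <- function(P, n, initial = "W") {
  states <- stage_levels()
  out <- integer(n)
  out[1] <- match(initial, states)
  for (i in seq_len(n - 1L)) {
    out[i + 1L] <- sample.int(5L, 1L, prob = P[out[i], ])
  }
  factor(states[out], levels = states)
}

band_noise <- function(n, fs, band) {
  nyq <- fs / 2
  lo <- max(band[1], 0.01) / nyq
  hi <- min(band[2], nyq * 0.99) / nyq
  flt <- signal::butter(2, c(lo, hi), type = "pass")
  x <- as.numeric(signal::filter(flt, stats::rnorm(n + 2 * fs)))
  x <- x[(fs + 1):(fs + n)]            # drop filter transients
  s <- stats::sd(x)
  if (s > 0) x / s else x
}

blink_kernel <- function(fs) {
  # 300-ms biphasic pulse
  t <- seq(0, 0.3, by = 1 / fs)
  sin(2 * pi * t / 0.3) * exp(-((t - 0.15) / 0.1)^2)
}

rem_kernel <- function(fs) {
  # 150-ms sharp deflection, alternating polarity applied at call site
  t <- seq(0, 0.15, by = 1 / fs)
  c(seq(0, 1, length.out = floor(length(t) / 3)),
    seq(1, -0.6, length.out = length(t) - 2 * floor(length(t) / 3)),
    seq(-0.6, 0, length.out = floor(length(t) / 3)))
}

event_train <- function(n, fs, rate_per_min, kernel, alternate = FALSE) {
  out <- numeric(n)
  k <- stats::rpois(1L, rate_per_min * (n / fs) / 60)
  if (k == 0L) return(out)
  pos <- sort(sample.int(max(1L, n - length(kernel)), k, replace = TRUE))
  sgn <- 1
  for (p in pos) {
    idx <- p:(p + length(kernel) - 1L)
    out[idx] <- out[idx] + sgn * kernel
    if (alternate) sgn <- -sgn
  }
  out
}

#' Generate one synthetic recording with its hypnogram
#'
#' @param cfg A `synthetic_config`.
#' @return List with elements `recording` (a `psg_recording` at the native
#'   rate) and `hypnogram`.
#' @export
generate_recording <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  with_seed(cfg$seed, {
    fs <- cfg$fs
    n_ep <- cfg$duration_epochs
    spe <- as.integer(30 * fs)
    stages <- sample_markov_stages(cfg$transition_matrix, n_ep, cfg$initial_stage)
    bk <- blink_kernel(fs); rk <- rem_kernel(fs)
    eeg <- eog <- emg <- numeric(n_ep * spe)
    for (i in seq_len(n_ep)) {
      tm <- cfg$stage_templates[[as.character(stages[i])]]
      idx <- ((i - 1L) * spe + 1L):(i * spe)
      w <- tm$eeg_band_powers
      e <- numeric(spe)
      for (b in names(EEG_BANDS)) {
        if (w[[b]] > 0) e <- e + sqrt(w[[b]]) * band_noise(spe, fs, EEG_BANDS[[b]])
      }
      eeg[idx] <- e
      eog[idx] <- 3 * event_train(spe, fs, tm$eog_event_rates[["blinks"]], bk) +
        1.5 * event_train(spe, fs, tm$eog_event_rates[["rems"]], rk, alternate = TRUE) +
        0.3 * band_noise(spe, fs, c(0.3, 5))
      env <- 1 + 0.3 * sin(2 * pi * seq_len(spe) / spe * 3 + stats::runif(1, 0, 2 * pi))
      emg[idx] <- tm$emg_tone * env * stats::rnorm(spe)
    }
    noise <- function(x) x + cfg$noise_sd * stats::rnorm(length(x))
    rec <- psg_recording(list(EEG = noise(eeg), EOG = noise(eog), EMG = noise(emg)),
                         fs = fs, subject_id = paste0("synth", cfg$seed))
    list(recording = rec, hypnogram = hypnogram(stages))
  })
}

#' Cohort specification for synthetic clinical studies
#'
#' @param n_per_condition Named integer vector, subjects per condition.
#' @param condition_effects Named list (per condition) of optional elements:
#'   `transition_scale` (5x5 multiplicative matrix on transition entries, rows
#'   renormalized) and `band_scale` (named multiplier on EEG band powers,
#'   applied to every stage template).
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_condition, condition_effects = list()) {
  stopifnot(length(n_per_condition) >= 1L, !is.null(names(n_per_condition)))
  structure(list(n_per_condition = n_per_condition,
                 condition_effects = condition_effects),
            class = "cohort_spec")
}

apply_condition_effect <- function(cfg, effect) {
  if (is.null(effect)) return(cfg)
  P <- cfg$transition_matrix
  if (!is.null(effect$transition_scale)) {
    P <- P * effect$transition_scale
    P <- P / rowSums(P)
  }
  tmpl <- cfg$stage_templates
  if (!is.null(effect$band_scale)) {
    for (s in names(tmpl)) {
      bp <- tmpl[[s]]$eeg_band_powers
      for (b in names(effect$band_scale)) bp[[b]] <- bp[[b]] * effect$band_scale[[b]]
      tmpl[[s]]$eeg_band_powers <- bp
    }
  }
  synthetic_config(stage_templates = tmpl, transition_matrix = P,
                   duration_epochs = cfg$duration_epochs, fs = cfg$fs,
                   noise_sd = cfg$noise_sd, initial_stage = cfg$initial_stage,
                   seed = cfg$seed)
}

#' Generate a labeled synthetic cohort
#'
#' Per-subject seeds are `cfg$seed + subject index`, so cohorts are
#' reproducible and extensible; condition effects are applied to the
#' configuration before sampling.
#'
#' @param spec A `cohort_spec`.
#' @param cfg Base `synthetic_config` shared by all subjects.
#' @return List of subjects, each a list with `recording`, `hypnogram`,
#'   `condition` and `subject_id`.
#' @export
generate_cohort <- function(spec, cfg) {
  stopifnot(inherits(spec, "cohort_spec"), inherits(cfg, "synthetic_config"))
  out <- list()
  k <- 0L
  for (cond in names(spec$n_per_condition)) {
    ccfg <- apply_condition_effect(cfg, spec$condition_effects[[cond]])
    for (i in seq_len(spec$n_per_condition[[cond]])) {
      k <- k + 1L
      scfg <- ccfg
      scfg$seed <- cfg$seed + k
      rh <- generate_recording(scfg)
      out[[k]] <- list(recording = rh$recording, hypnogram = rh$hypnogram,
                       condition = cond,
                       subject_id = paste0(cond, "_", i))
    }
  }
  out
}

#' Write a synthetic recording to EDF plus text hypnogram
#'
#' Convenience wrapper so the synthetic path exercises the real EDF reader.
#'
#' @param rh List with `recording` and `hypnogram` (as from
#'   [generate_recording()]).
#' @param dir Output directory.
#' @param name Base file name.
#' @return Named character vector with the `edf` and `hypnogram` paths.
#' @export
write_synthetic_psg <- function(rh, dir, name = "synthetic") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  edf <- file.path(dir, paste0(name, ".edf"))
  hyp <- file.path(dir, paste0(name, ".hyp.txt"))
  write_edf(edf, rh$recording$signals, fs = rh$recording$fs)
  write_hypnogram(hyp, rh$hypnogram$labels)
  c(edf = edf, hypnogram = hyp)
}
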