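# Shared fixtures and independent oracles.

# Two-stage (Wake vs N3) synthetic staging data: beta-rich vs delta-dominant
# epochs with a symmetric transition chain, run through the real pipeline.
two_class_data <- function(duration_epochs = 300L, seed = 5L, L = 5L) {
  P2 <- matrix(0, 5, 5, dimnames = list(stage_levels(), stage_levels()))
  P2["W", "W"] <- 0.7; P2["W", "N3"] <- 0.3
  P2["N3", "N3"] <- 0.7; P2["N3", "W"] <- 0.3
  P2[c("N1", "N2", "R"), ] <- 0.2
  cfg <- synthetic_config(transition_matrix = P2 / rowSums(P2),
                          duration_epochs = duration_epochs, seed = seed)
  rh <- generate_recording(cfg)
  et <- epoch_and_spectrogram(preprocess_signals(rh$recording), rh$hypnogram)
  list(epochs = et, batch = make_sequences(et, L = L))
}

toy_config <- function(seed = 2L, D = 16L, P = 4L, L = 5L, lr = 3e-3,
                       dropout_rate = 0.2, ...) {
  psn_config(L = L, D = D, P = P, seed = seed, lr = lr,
             dropout_rate = dropout_rate, ...)
}

train_toy_model <- function(data, seed = 2L, epochs = 40L, batch_size = 8L,
                            ...) {
  m <- psn_model(toy_config(seed = seed, ...))
  psn_train(m, data$batch, epochs = epochs, batch_size = batch_size)
}

# Memoized trained model + data shared across test files (training is the
# expensive step; every consumer uses the same frozen seed).
.fixture_env <- new.env(parent = emptyenv())

shared_trained_model <- function() {
  if (is.null(.fixture_env$model)) {
    data <- two_class_data()
    .fixture_env$data <- data
    .fixture_env$model <- train_toy_model(data)
  }
  list(model = .fixture_env$model, data = .fixture_env$data)
}

random_epoch_batch <- function(n, seed = 1L, C = 3L, T = 29L, F = 129L) {
  set.seed(seed)
  array(stats::rnorm(n * C * T * F, mean = -5, sd = 6), dim = c(n, C, T, F))
}

# bind two (n, C, T, F) arrays along the first axis
abind_rows <- function(a, b) {
  d <- dim(a)
  out <- array(0, dim = c(d[1] + dim(b)[1], d[-1]))
  out[seq_len(d[1]), , , ] <- a
  out[d[1] + seq_len(dim(b)[1]), , , ] <- b
  out
}

# ---- independent oracles ----

# O(n^2) double-sum squared-MMD with an RBF kernel.
mmd_bruteforce <- function(x, y, bandwidth, biased = FALSE) {
  k <- function(a, b) exp(-sum((a - b)^2) / (2 * bandwidth^2))
  n <- nrow(x); m <- nrow(y)
  kxx <- kyy <- kxy <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (biased || i != j) kxx <- kxx + k(x[i, ], x[j, ])
  }
  for (i in seq_len(m)) for (j in seq_len(m)) {
    if (biased || i != j) kyy <- kyy + k(y[i, ], y[j, ])
  }
  for (i in seq_len(n)) for (j in seq_len(m)) kxy <- kxy + k(x[i, ], y[j, ])
  if (biased) {
    kxx / n^2 + kyy / m^2 - 2 * kxy / (n * m)
  } else {
    kxx / (n * (n - 1)) + kyy / (m * (m - 1)) - 2 * kxy / (n * m)
  }
}

# Cohen's kappa straight from the contingency definition.
kappa_bruteforce <- function(conf) {
  n <- sum(conf)
  po <- sum(diag(conf)) / n
  pe <- 0
  for (k in seq_len(nrow(conf))) pe <- pe + sum(conf[k, ]) * sum(conf[, k]) / n^2
  (po - pe) / (1 - pe)
}

# Brute-force cosine argmax with lowest-index ties.
quantize_bruteforce <- function(cm, LD) {
  best <- integer(nrow(cm))
  for (i in seq_len(nrow(cm))) {
    sims <- apply(LD, 1L, function(p) {
      sum(cm[i, ] * p) / (sqrt(sum(cm[i, ]^2)) * sqrt(sum(p^2)))
    })
    best[i] <- which(sims == max(sims))[1]
  }
  best
}

# Sinusoid amplitude at frequency f by least squares (filter oracle).
sine_amplitude <- function(x, fs, f) {
  t <- seq_along(x) / fs
  fit <- stats::lm(x ~ sin(2 * pi * f * t) + cos(2 * pi * f * t))
  sqrt(sum(stats::coef(fit)[2:3]^2))
}
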