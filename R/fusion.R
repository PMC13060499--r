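# Residual channel mixing and adaptive channel dropout.
#
# EEG/EOG/EMG embeddings are fused by a gated cross-channel attention block
# applied as a residual before averaging across channels, so that with the
# gate at its zero initialization the fusion is exactly the channel mean.
# Channel dropout occludes individually strong channels more often during
# training (probability proportional to recent single-channel accuracy),
# which counters multimodal competition.

#' Mixer parameters
#'
#' @param D Embedding width.
#' @param gamma Residual gate (0 at initialization: mixing inactive).
#' @param seed Seed for the attention weight initialization.
#' @return List with `Wq`, `Wk`, `Wv` `(D, D)` and scalar `gamma`.
#' @export
mixer_params <- function(D, gamma = 0, seed = 1L) {
  with_seed(seed, {
    init <- function() matrix(stats::rnorm(D * D, sd = 1 / sqrt(D)), D, D)
    list(Wq = init(), Wk = init(), Wv = init(), gamma = gamma)
  })
}

#' Mix channels with a gated residual attention block
#'
#' `CH = (1/C) * sum_c [gamma * attn(H) + H]_c`. With `gamma = 0` this is
#' exactly the plain channel mean (residual identity at initialization).
#'
#' @param h Epoch embeddings, array `(..., C, D)` with the channel axis
#'   second-to-last.
#' @param params Mixer parameters from [mixer_params()].
#' @param C Expected channel count (validated; default 3).
#' @return Mixed embeddings `(..., D)`.
#' @export
mix_channels <- function(h, params, C = 3L) {
  d <- dim(h)
  if (d[length(d) - 1L] != C) {
    stop("channel axis has ", d[length(d) - 1L], " channels, expected ", C)
  }
  D <- d[length(d)]
  G <- prod(d[-c(length(d) - 1L, length(d))])
  H3 <- array(h, dim = c(G, C, D))
  out <- channel_attn_fwd(H3, params$Wq, params$Wk, params$Wv, params$gamma)$out
  if (length(d) > 2L) array(out, dim = c(d[-c(length(d) - 1L, length(d))], D)) else out
}

#' Adaptive occlusion probabilities from single-channel accuracies
#'
#' `p_i = acc_i / sum_j acc_j`: channels that perform better alone are
#' occluded more often. All-zero accuracies fall back to uniform with a
#' warning.
#'
#' @param acc Nonnegative per-channel accuracy estimates.
#' @return Object of class `occlusion_schedule`: list with `acc` and `p_occl`.
#' @export
compute_occlusion_probs <- function(acc) {
  if (any(acc < 0)) stop("accuracies must be nonnegative")
  s <- sum(acc)
  if (s == 0) {
    warning("all-zero accuracies; falling back to uniform occlusion")
    p <- rep(1 / length(acc), length(acc))
  } else {
    p <- acc / s
  }
  structure(list(acc = acc, p_occl = p), class = "occlusion_schedule")
}

#' Apply channel dropout to epoch embeddings
#'
#' With overall event rate `rate`, each epoch independently draws one channel
#' from the occlusion schedule and replaces its embedding with the occlusion
#' token (zeros). At most one channel per epoch is occluded, so all channels
#' are never blanked simultaneously. Identity when `rate = 0`.
#'
#' @param h Epoch embeddings `(..., C, D)`.
#' @param sched An `occlusion_schedule`.
#' @param rate Overall dropout event probability per epoch in `[0, 1]`.
#' @param seed Optional seed.
#' @return List with `h` (embeddings after dropout) and `dropped`
#'   (matrix `(G, C)` of 0/1 occlusion indicators, G = number of epochs).
#' @export
apply_channel_dropout <- function(h, sched, rate, seed = NULL) {
  stopifnot(inherits(sched, "occlusion_schedule"), rate >= 0, rate <= 1)
  d <- dim(h)
  C <- d[length(d) - 1L]; D <- d[length(d)]
  G <- prod(d[-c(length(d) - 1L, length(d))])
  dropped <- matrix(0L, nrow = G, ncol = C)
  if (rate > 0) {
    with_seed(seed, {
      ev <- stats::runif(G) < rate
      if (any(ev)) {
        ch <- sample.int(C, sum(ev), replace = TRUE, prob = sched$p_occl)
        dropped[cbind(which(ev), ch)] <- 1L
      }
    })
  }
  H3 <- array(h, dim = c(G, C, D))
  for (c in seq_len(C)) H3[, c, ] <- H3[, c, ] * (1 - dropped[, c])
  list(h = array(H3, dim = d), dropped = dropped)
}

#' Estimate single-channel staging accuracies
#'
#' Evaluates stage accuracy with only one channel visible at a time (the
#' other channel embeddings occluded) on a held-out batch, and exponentially
#' smooths the estimate across calls (`ema <- decay * ema + (1 - decay) * raw`,
#' state kept on the model).
#'
#' @param model A `psn_model`.
#' @param val_batch A labeled `sequence_batch`.
#' @param decay EMA decay (default 0.9).
#' @return Named numeric vector of smoothed per-channel accuracies.
#' @export
estimate_single_channel_accuracy <- function(model, val_batch, decay = 0.9) {
  stopifnot(inherits(model, "psn_model"))
  if (is.null(val_batch$labels) || dim(val_batch$values)[1] == 0L) {
    stop("validation batch must be nonempty and labeled")
  }
  C <- model$config$C
  raw <- numeric(C)
  for (ci in seq_len(C)) {
    fw <- psn_forward(model, val_batch, mode = "eval", visible_channels = ci)
    pred <- max.col(fw$depth_probs[[length(fw$depth_probs)]], ties.method = "first")
    raw[ci] <- mean(pred == as.vector(val_batch$labels))
  }
  prev <- model$state$acc_ema
  ema <- if (is.null(prev)) raw else decay * prev + (1 - decay) * raw
  model$state$acc_ema <- ema
  names(ema) <- val_batch$channel_roles[seq_len(C)]
  ema
}
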