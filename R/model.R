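# The prototype-quantized sequence-to-sequence sleep stager.
#
# Pipeline per forward pass: per-frame projection (linear filterbank over the
# frequency axis + tanh, strictly frame-local) -> time-wise hard-attention
# masking and pooled mean per channel -> [training: adaptive channel dropout]
# -> gated residual channel mixing -> vector quantization onto the prototype
# codebook (straight-through) -> gated bidirectional temporal convolution over
# the sequence axis -> a shared feedforward head producing stage logits at
# each residual depth.
#
# All residual blocks carry a zero-initialized gate, and the quantization
# block is a pass-through during a warm-up phase, so the network is an exact
# identity across depths at initialization. After warm-up the quantizer is a
# pure straight-through replacement: predictions depend on the mixed
# embedding only through the selected codebook rows.

#' Model configuration
#'
#' @param L Sequence length in epochs. @param C Channels. @param T Frames per
#'   epoch. @param F Frequency bins. @param K Stage classes.
#' @param D Embedding width. @param P Prototype count.
#' @param mask_lengths Candidate mask window lengths (frames).
#' @param dropout_rate Channel-dropout event rate per epoch during training.
#' @param commit_weight Commitment-loss weight in the total loss.
#' @param depth_weights Per-depth cross-entropy weights (3 depths).
#' @param tau_start,tau_end Linear Gumbel temperature annealing endpoints.
#' @param vq_warmup_frac Fraction of planned updates during which the
#'   quantization block is a pass-through.
#' @param lr Adam learning rate. @param clip Gradient-norm clip.
#' @param codebook_method `"simvq"` or `"plain"` (see [new_codebook()]).
#' @param se_window Half-width of the temporal convolution over the sequence.
#' @param eps_pool Pooling stabilizer.
#' @param acc_ema_decay EMA decay for single-channel accuracy estimates.
#' @param input_center,input_scale Affine input normalization applied to the
#'   dB spectrogram cells before the filterbank.
#' @param seed Master seed for initialization and training randomness.
#' @return Object of class `psn_config`.
#' @export
psn_config <- function(L = 21L, C = 3L, T = 29L, F = 129L, K = 5L,
                       D = 32L, P = 15L,
                       mask_lengths = c(5L, 9L, 15L, 21L, 29L),
                       dropout_rate = 0.25, commit_weight = 0.25,
                       depth_weights = c(1, 1, 1),
                       tau_start = 1, tau_end = 0.3,
                       vq_warmup_frac = 0.3,
                       lr = 1e-3, clip = 5,
                       codebook_method = "simvq",
                       se_window = 2L, eps_pool = 1e-6,
                       acc_ema_decay = 0.9,
                       input_center = -5, input_scale = 15,
                       seed = 1L) {
  stopifnot(L >= 1, C >= 1, T >= 1, F >= 1, K == 5L, D >= 1, P >= 1)
  mask_lengths <- mask_lengths[mask_lengths <= T]
  structure(as.list(environment()), class = "psn_config")
}

#' Initialize a model
#'
#' @param config A `psn_config`.
#' @return Object of class `psn_model`: parameters, frozen codebook basis,
#'   candidate mask set and a mutable state environment (optimizer step count,
#'   quantizer activation flag, accuracy EMA, training log).
#' @export
psn_model <- function(config = psn_config()) {
  stopifnot(inherits(config, "psn_config"))
  cfg <- config
  mask_set <- build_candidate_masks(cfg$T, lengths = cfg$mask_lengths)
  M <- nrow(mask_set$masks)
  cb <- new_codebook(cfg$P, cfg$D, method = cfg$codebook_method, seed = cfg$seed + 1L)
  params <- with_seed(cfg$seed, {
    rn <- function(nr, nc, sd) matrix(stats::rnorm(nr * nc, sd = sd), nr, nc)
    p <- list(
      Wfb = rn(cfg$F, cfg$D, 1 / sqrt(cfg$F)), bfb = numeric(cfg$D),
      Wmask = matrix(0, cfg$D, M),
      Wq = rn(cfg$D, cfg$D, 1 / sqrt(cfg$D)),
      Wk = rn(cfg$D, cfg$D, 1 / sqrt(cfg$D)),
      Wv = rn(cfg$D, cfg$D, 1 / sqrt(cfg$D)),
      gamma_cm = 0,
      U = lapply(seq_len(2L * cfg$se_window + 1L),
                 function(i) rn(cfg$D, cfg$D, 1 / sqrt(cfg$D * (2 * cfg$se_window + 1)))),
      Wo = rn(cfg$D, cfg$D, 1 / sqrt(cfg$D)),
      gamma_se = 0,
      Wh = rn(cfg$D, cfg$K, 1 / sqrt(cfg$D)), bh = numeric(cfg$K)
    )
    if (cfg$codebook_method == "simvq") p$cbW <- cb$W else p$LD <- cb$LD
    p
  })
  state <- new.env(parent = emptyenv())
  state$updates <- 0L
  state$vq_active <- FALSE
  state$acc_ema <- NULL
  state$recent_indices <- integer(0)
  state$log <- NULL
  structure(list(config = cfg, params = params, mask_set = mask_set,
                 cb_basis = if (cfg$codebook_method == "simvq") cb$basis else NULL,
                 state = state),
            class = "psn_model")
}

#' @export
print.psn_model <- function(x, ...) {
  cfg <- x$config
  cat("<psn_model> D=", cfg$D, " P=", cfg$P, " L=", cfg$L,
      " M=", nrow(x$mask_set$masks),
      " | updates=", x$state$updates,
      " quantizer=", if (x$state$vq_active) "active" else "warm-up", "\n", sep = "")
  invisible(x)
}

#' Current codebook of a model
#'
#' @param model A `psn_model`.
#' @return A `proto_codebook` reflecting the current parameters.
#' @export
psn_codebook <- function(model) {
  cfg <- model$config
  if (cfg$codebook_method == "simvq") {
    structure(list(P = cfg$P, D = cfg$D, method = "simvq",
                   basis = model$cb_basis, W = model$params$cbW),
              class = "proto_codebook")
  } else {
    structure(list(P = cfg$P, D = cfg$D, method = "plain",
                   LD = model$params$LD),
              class = "proto_codebook")
  }
}

#' Per-frame projection of a sequence batch
#'
#' Maps each (epoch, channel, frame) frequency profile independently to a
#' D-vector (linear filterbank over F followed by tanh); no cross-frame or
#' cross-epoch mixing.
#'
#' @param batch A `sequence_batch` (or bare `(B, L, C, T, F)` array).
#' @param model A `psn_model` supplying the filterbank parameters.
#' @return Array `(B, L, C, T, D)` of frame embeddings.
#' @export
project_frames <- function(batch, model) {
  values <- if (inherits(batch, "sequence_batch")) batch$values else batch
  stopifnot_finite(values, "sequence batch")
  d <- dim(values)
  cfg <- model$config
  xn <- (values - cfg$input_center) / cfg$input_scale
  sh <- lin_tanh_fwd(matrix(xn, ncol = d[5]), model$params$Wfb, model$params$bfb)$out
  array(sh, dim = c(d[1:4], cfg$D))
}

occlusion_keep <- function(setup, BL, C, seed = NULL) {
  keep <- matrix(1, BL, C)
  if (setup == "none") return(keep)
  if (setup == "random25" || setup == "random50") {
    p <- if (setup == "random25") 0.25 else 0.5
    with_seed(seed, {
      keep[matrix(stats::runif(BL * C), BL, C) < p] <- 0
    })
  } else if (setup == "eeg") {
    keep[, 1] <- 0
  } else if (setup == "eog_emg") {
    keep[, 2:3] <- 0
  } else {
    stop("unknown occlusion setup: ", setup)
  }
  keep
}

#' Full forward pass
#'
#' @param model A `psn_model`.
#' @param batch A `sequence_batch`.
#' @param mode `"train"` (Gumbel-noise mask selection, channel dropout) or
#'   `"eval"` (greedy hard masks, no dropout; deterministic).
#' @param seed Seed for the stochastic parts in train mode (or for random
#'   occlusion setups in eval).
#' @param occlusion Occlusion setup id applied at the embedding level:
#'   `"none"`, `"random25"`, `"random50"`, `"eeg"`, `"eog_emg"`.
#' @param visible_channels Optional integer vector: keep only these channels
#'   (used for single-channel accuracy estimation).
#' @param collect_cache Keep intermediates for a backward pass.
#' @param temperature Gumbel temperature (train mode).
#' @return List with `depth_logits`, `depth_probs` (3 depths, `(B*L, K)`),
#'   `quant` (a `quantization_result`), `mask` (selector/mask matrices),
#'   `losses` (if the batch is labeled) and optionally `cache`.
#' @export
psn_forward <- function(model, batch, mode = c("eval", "train"), seed = NULL,
                        occlusion = "none", visible_channels = NULL,
                        collect_cache = FALSE, temperature = 1,
                        hard_mask = TRUE) {
  mode <- match.arg(mode)
  cfg <- model$config
  p <- model$params
  values <- batch$values
  d <- dim(values)
  if (d[3] != cfg$C || d[4] != cfg$T || d[5] != cfg$F) {
    stop("batch shape (C,T,F) = (", d[3], ",", d[4], ",", d[5],
         ") does not match config (", cfg$C, ",", cfg$T, ",", cfg$F, ")")
  }
  B <- d[1]; L <- d[2]; C <- cfg$C; Tn <- cfg$T
  G <- B * L * C; BL <- B * L
  masks <- model$mask_set$masks
  M <- nrow(masks)

  with_seed(seed, {
    # 1. frame projection
    xn <- (values - cfg$input_center) / cfg$input_scale
    Xm <- matrix(xn, ncol = cfg$F)
    ft <- lin_tanh_fwd(Xm, p$Wfb, p$bfb)
    SH <- ft$out                                    # (G*T, D), rows g+(t-1)G

    # 2. mask scoring and selection
    mlog <- SH %*% p$Wmask                          # (G*T, M)
    vt <- mask_votes(mlog, G, Tn)
    sel <- gumbel_select(vt$Vn, temperature, hard = hard_mask,
                         gumbel = (mode == "train"))
    maskm <- sel$selector %*% masks                 # (G, T)

    # 3. masked pooling
    mv <- as.vector(maskm)
    grp <- rep(seq_len(G), times = Tn)
    num <- rowsum(SH * mv, group = grp, reorder = FALSE)
    den <- as.vector(rowsum(mv, group = grp, reorder = FALSE)) + cfg$eps_pool
    Hpool <- num / den                              # (G, D), rows b,l fastest then c

    # 4. channel visibility: dropout (train) / occlusion (eval) / single-channel
    keep <- matrix(1, BL, C)
    if (!is.null(visible_channels)) {
      keep[] <- 0; keep[, visible_channels] <- 1
    } else if (mode == "train" && cfg$dropout_rate > 0) {
      acc <- model$state$acc_ema %||% rep(1, C)
      sched <- suppressWarnings(compute_occlusion_probs(acc))
      dr <- apply_channel_dropout(array(Hpool, dim = c(BL, C, cfg$D)), sched,
                                  rate = cfg$dropout_rate)
      keep <- 1 - dr$dropped
    } else if (occlusion != "none") {
      keep <- occlusion_keep(occlusion, BL, C)
    }
    keepv <- as.vector(keep)                        # (G,), rows match Hpool
    Hvis <- Hpool * keepv

    # 5. channel mixing (gated residual attention)
    at <- channel_attn_fwd(array(Hvis, dim = c(BL, C, cfg$D)),
                           p$Wq, p$Wk, p$Wv, p$gamma_cm)
    X1 <- at$out                                    # (BL, D)

    # 6. vector quantization (pass-through during warm-up)
    cb <- psn_codebook(model)
    qz <- quantize(X1, cb)
    X2 <- if (model$state$vq_active) qz$quantized else X1

    # 7. sequence encoder
    se <- temporal_conv_fwd(array(X2, dim = c(B, L, cfg$D)), p$U, p$Wo,
                            p$gamma_se, cfg$se_window)
    X3 <- matrix(se$out, nrow = BL, ncol = cfg$D)

    # 8. shared head at each depth
    depths <- list(X1, X2, X3)
    depth_logits <- lapply(depths, function(X) sweep(X %*% p$Wh, 2L, p$bh, "+"))
    depth_probs <- lapply(depth_logits, softmax_rows)

    losses <- NULL
    if (!is.null(batch$labels)) {
      lab <- as.vector(batch$labels)
      ce <- vapply(depth_probs, function(pr) {
        -mean(log(pr[cbind(seq_along(lab), lab)] + 1e-12))
      }, numeric(1))
      losses <- list(ce = ce, commit = qz$commit_loss,
                     total = sum(cfg$depth_weights * ce) +
                       cfg$commit_weight * qz$commit_loss)
    }

    out <- list(depth_logits = depth_logits, depth_probs = depth_probs,
                quant = qz,
                mask = list(votes = vt$Vn, selector = sel$selector,
                            soft = sel$soft, mask = maskm),
                losses = losses, dims = c(B = B, L = L))
    if (collect_cache) {
      out$cache <- list(ft = ft, SH = SH, vt = vt, sel = sel, maskm = maskm,
                        mv = mv, grp = grp, den = den, Hpool = Hpool,
                        keepv = keepv, at = at, X1 = X1, X2 = X2, se = se,
                        depths = depths, cb = cb, temperature = temperature,
                        d = d)
    }
    out
  })
}

# Backward pass: gradients of the total loss for every trainable parameter.
psn_backward <- function(model, fw, labels) {
  cfg <- model$config
  p <- model$params
  ca <- fw$cache
  if (is.null(ca)) stop("forward pass was run without collect_cache")
  lab <- as.vector(labels)
  B <- fw$dims[["B"]]; L <- fw$dims[["L"]]; C <- cfg$C; Tn <- cfg$T
  G <- B * L * C; BL <- B * L
  masks <- model$mask_set$masks

  # heads
  dWh <- matrix(0, cfg$D, cfg$K); dbh <- numeric(cfg$K)
  dX <- vector("list", 3L)
  for (i in 1:3) {
    dl <- softmax_ce_bwd(fw$depth_probs[[i]], lab, weight = cfg$depth_weights[i])
    dWh <- dWh + t(ca$depths[[i]]) %*% dl
    dbh <- dbh + colSums(dl)
    dX[[i]] <- dl %*% t(p$Wh)
  }

  # sequence encoder
  tb <- temporal_conv_bwd(ca$se$cache, array(dX[[3]], dim = c(B, L, cfg$D)))
  dX2 <- dX[[2]] + matrix(tb$dX, nrow = BL, ncol = cfg$D)

  # quantization: straight-through copies dX2 to the mixed embedding
  dCM <- dX[[1]] + dX2
  LD <- codebook_matrix(ca$cb)
  cg <- commitment_grad(ca$X1, LD, fw$quant$indices, weight = cfg$commit_weight)
  dCM <- dCM + cg$dcm
  dLD <- cg$dLD

  # channel mixing
  ab <- channel_attn_bwd(ca$at$cache, dCM)
  dHvis <- matrix(ab$dH, nrow = G, ncol = cfg$D)
  dHpool <- dHvis * ca$keepv

  # masked pooling
  dnum <- dHpool / ca$den
  dden <- -rowSums(dHpool * ca$Hpool) / ca$den
  dSH <- dnum[ca$grp, , drop = FALSE] * ca$mv
  dmv <- rowSums(ca$SH * dnum[ca$grp, , drop = FALSE]) + dden[ca$grp]
  dmaskm <- matrix(dmv, nrow = G, ncol = Tn)

  # selector (straight-through: gradient via the relaxed probabilities)
  dSel <- dmaskm %*% t(masks)
  y <- ca$sel$soft
  dz <- y * (dSel - rowSums(dSel * y))
  dlogVn <- dz / ca$temperature
  dVn <- dlogVn / (ca$vt$Vn + 1e-20)
  s <- ca$vt$s
  dV <- dVn / s - rowSums(dVn * ca$vt$Vn) / s
  dsm <- dV[ca$grp, , drop = FALSE]
  sm <- ca$vt$sm
  dmlog <- sm * (dsm - rowSums(dsm * sm))
  dWmask <- t(ca$SH) %*% dmlog
  dSH <- dSH + dmlog %*% t(p$Wmask)

  # frame projection
  fb <- lin_tanh_bwd(ca$ft$cache, dSH)

  grads <- list(Wfb = fb$dW, bfb = fb$db, Wmask = dWmask,
                Wq = ab$dWq, Wk = ab$dWk, Wv = ab$dWv, dgamma_cm = ab$dgamma,
                U = tb$dU, Wo = tb$dWo, gamma_se = tb$dgamma,
                Wh = dWh, bh = dbh)
  names(grads)[names(grads) == "dgamma_cm"] <- "gamma_cm"
  if (cfg$codebook_method == "simvq") {
    grads$cbW <- t(model$cb_basis) %*% dLD
  } else {
    grads$LD <- dLD
  }
  grads[names(p)]
}

#' Total training loss
#'
#' Weighted sum of the per-depth cross-entropies plus the weighted commitment
#' loss.
#'
#' @param depth_logits List of `(n, K)` logit matrices (one per depth).
#' @param labels Integer stage labels 1..K of length n.
#' @param commit_loss Scalar commitment loss.
#' @param depth_weights Per-depth CE weights.
#' @param commit_weight Commitment weight.
#' @return List with `ce` (per depth), `commit` and `total`.
#' @export
total_loss <- function(depth_logits, labels, commit_loss = 0,
                       depth_weights = rep(1, length(depth_logits)),
                       commit_weight = 0.25) {
  if (any(labels < 1L | labels > ncol(depth_logits[[1]]))) {
    stop("labels out of range 1..K")
  }
  ce <- vapply(depth_logits, function(lg) softmax_ce_fwd(lg, labels)$loss, numeric(1))
  list(ce = ce, commit = commit_loss,
       total = sum(depth_weights * ce) + commit_weight * commit_loss)
}

#' Train the model
#'
#' Adam with gradient-norm clipping; per training epoch the single-channel
#' accuracy estimates (and hence the occlusion schedule) are refreshed, the
#' Gumbel temperature is annealed linearly, dead prototypes are revived, and
#' all loss components are logged. The quantization block switches from
#' pass-through to straight-through replacement after the configured warm-up
#' fraction of updates. Deterministic given the config seed.
#'
#' @param model A `psn_model`.
#' @param train_data Labeled `sequence_batch`.
#' @param val_data Optional labeled `sequence_batch` for the single-channel
#'   accuracy estimates (defaults to a slice of the training data).
#' @param epochs Training epochs.
#' @param batch_size Sequences per minibatch.
#' @param verbose Print per-epoch progress.
#' @return The trained `psn_model` (training log in `model$state$log`).
#' @export
psn_train <- function(model, train_data, val_data = NULL, epochs = 20L,
                      batch_size = 16L, verbose = FALSE) {
  stopifnot(inherits(model, "psn_model"), inherits(train_data, "sequence_batch"))
  if (is.null(train_data$labels) || dim(train_data$values)[1] == 0L) {
    stop("training data must be nonempty and labeled")
  }
  # clone the mutable state so the caller's model is left untouched
  s2 <- new.env(parent = emptyenv())
  for (nm in ls(model$state)) assign(nm, get(nm, model$state), envir = s2)
  model$state <- s2
  cfg <- model$config
  Btot <- dim(train_data$values)[1]
  nb <- max(1L, ceiling(Btot / batch_size))
  total_updates <- epochs * nb
  warmup <- floor(cfg$vq_warmup_frac * total_updates)
  opt <- adam_init(model$params)
  if (is.null(val_data)) {
    vidx <- seq_len(min(Btot, max(2L, batch_size)))
    val_data <- sequence_batch(train_data$values[vidx, , , , , drop = FALSE],
                               train_data$labels[vidx, , drop = FALSE],
                               train_data$channel_roles)
  }
  log <- NULL
  with_seed(cfg$seed + 1000L, {
    for (ep in seq_len(epochs)) {
      estimate_single_channel_accuracy(model, val_data, decay = cfg$acc_ema_decay)
      ord <- sample.int(Btot)
      ep_losses <- c(total = 0, commit = 0, ce1 = 0, ce2 = 0, ce3 = 0)
      ep_idx <- integer(0)
      for (bi in seq_len(nb)) {
        rows <- ord[((bi - 1L) * batch_size + 1L):min(bi * batch_size, Btot)]
        mb <- sequence_batch(train_data$values[rows, , , , , drop = FALSE],
                             train_data$labels[rows, , drop = FALSE],
                             train_data$channel_roles)
        frac <- model$state$updates / max(1L, total_updates - 1L)
        tau <- cfg$tau_start + (cfg$tau_end - cfg$tau_start) * min(1, frac)
        model$state$vq_active <- model$state$updates >= warmup
        fw <- psn_forward(model, mb, mode = "train", collect_cache = TRUE,
                          temperature = tau)
        if (!is.finite(fw$losses$total)) {
          stop("divergent (non-finite) training loss at update ",
               model$state$updates, "; last components: ",
               paste(signif(c(fw$losses$ce, fw$losses$commit), 4), collapse = ", "))
        }
        grads <- psn_backward(model, fw, mb$labels)
        st <- adam_step(model$params, grads, opt, lr = cfg$lr, clip = cfg$clip)
        model$params <- st$params
        opt <- st$state
        model$state$updates <- model$state$updates + 1L
        ep_losses <- ep_losses + c(fw$losses$total, fw$losses$commit, fw$losses$ce)
        ep_idx <- c(ep_idx, fw$quant$indices)
      }
      # dead-prototype revival at epoch boundaries
      cb <- psn_codebook(model)
      cb2 <- revive_dead_prototypes(cb, ep_idx)
      if (cfg$codebook_method == "simvq") {
        model$cb_basis <- cb2$basis
      } else {
        model$params$LD <- cb2$LD
      }
      model$state$recent_indices <- ep_idx
      usage <- codebook_health(cb, ep_idx)$usage
      row <- data.frame(epoch = ep, t(ep_losses / nb),
                        codebook_used = sum(usage > 0),
                        vq_active = model$state$vq_active)
      log <- rbind(log, row)
      if (verbose) {
        message(sprintf("epoch %d: loss %.4f commit %.3f (codebook %d/%d)",
                        ep, row$total, row$commit, row$codebook_used, cfg$P))
      }
    }
  })
  model$state$log <- log
  model
}

#' Cohen's kappa from a confusion matrix
#'
#' @param conf Square contingency matrix (rows = reference, cols = predicted).
#' @return Chance-corrected agreement in `[-1, 1]` (0 when the predictor is
#'   constant or otherwise at chance level).
#' @export
cohen_kappa <- function(conf) {
  n <- sum(conf)
  po <- sum(diag(conf)) / n
  pe <- sum(rowSums(conf) * colSums(conf)) / n^2
  if (abs(1 - pe) < 1e-12) return(0)
  (po - pe) / (1 - pe)
}

macro_f1 <- function(conf) {
  tp <- diag(conf)
  f1 <- 2 * tp / (2 * tp + (colSums(conf) - tp) + (rowSums(conf) - tp))
  f1[!is.finite(f1)] <- 0
  mean(f1)
}

#' Evaluate staging performance under an occlusion setup
#'
#' @param model A trained `psn_model`.
#' @param data Labeled `sequence_batch`.
#' @param setup Occlusion setup id: `"none"`, `"random25"` (25% independent
#'   per-epoch channel occlusion), `"random50"`, `"eeg"` (EEG blanked for the
#'   whole recording), `"eog_emg"` (both secondary modalities blanked).
#' @param seed Seed for the random occlusion setups.
#' @return Object of class `eval_report`: `accuracy`, `cohen_kappa`,
#'   `macro_f1`, `per_class_f1`, `confusion` (rows = reference stages),
#'   `occlusion_setup`.
#' @export
psn_evaluate <- function(model, data, setup = "none", seed = NULL) {
  stopifnot(inherits(model, "psn_model"))
  if (is.null(data$labels)) stop("evaluation data must be labeled")
  if (!setup %in% c("none", "random25", "random50", "eeg", "eog_emg")) {
    stop("unknown occlusion setup: ", setup)
  }
  fw <- psn_forward(model, data, mode = "eval", occlusion = setup, seed = seed)
  pred <- max.col(fw$depth_probs[[3]], ties.method = "first")
  truth <- as.vector(data$labels)
  K <- model$config$K
  conf <- matrix(0L, K, K, dimnames = list(stage_levels(), stage_levels()))
  for (i in seq_along(truth)) conf[truth[i], pred[i]] <- conf[truth[i], pred[i]] + 1L
  tp <- diag(conf)
  per_f1 <- 2 * tp / (2 * tp + (colSums(conf) - tp) + (rowSums(conf) - tp))
  per_f1[!is.finite(per_f1)] <- 0
  structure(list(accuracy = mean(pred == truth),
                 cohen_kappa = cohen_kappa(conf),
                 macro_f1 = mean(per_f1),
                 per_class_f1 = per_f1,
                 confusion = conf,
                 occlusion_setup = setup),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report> setup=", x$occlusion_setup,
      sprintf(" acc=%.3f kappa=%.3f macroF1=%.3f\n",
              x$accuracy, x$cohen_kappa, x$macro_f1), sep = "")
  invisible(x)
}

#' Prototype-gram of a recording
#'
#' Runs the epoch encoder over a whole recording (as one sequence; the
#' temporal encoder is length-agnostic) and returns the per-epoch selected
#' prototype index.
#'
#' @param model A trained `psn_model`.
#' @param epochs An `epoch_tensor` for the recording.
#' @param subject_id,condition Optional metadata stored on the result.
#' @return Object of class `protogram`: `indices` (1..P, one per epoch),
#'   `P`, `subject_id`, `condition`.
#' @export
compute_protogram <- function(model, epochs, subject_id = NULL, condition = NA) {
  stopifnot(inherits(epochs, "epoch_tensor"))
  d <- dim(epochs$values)
  batch <- sequence_batch(array(epochs$values, dim = c(1L, d)), NULL,
                          epochs$channel_roles)
  fw <- psn_forward(model, batch, mode = "eval")
  structure(list(indices = fw$quant$indices, P = model$config$P,
                 subject_id = subject_id %||% "subject", condition = condition),
            class = "protogram")
}

#' @export
print.protogram <- function(x, ...) {
  cat("<protogram> ", x$subject_id, ": ", length(x$indices),
      " epochs over ", x$P, " prototypes\n", sep = "")
  invisible(x)
}

#' Save / load a model checkpoint
#'
#' Single-file archive with parameters, frozen codebook basis, configuration,
#' optimizer-visible state and the training log.
#'
#' @param model A `psn_model`. @param path File path.
#' @return `path` (save) or the restored `psn_model` (load).
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(list(config = model$config, params = model$params,
               cb_basis = model$cb_basis, mask_set = model$mask_set,
               state = as.list(model$state)), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  x <- readRDS(path)
  state <- new.env(parent = emptyenv())
  for (nm in names(x$state)) assign(nm, x$state[[nm]], envir = state)
  structure(list(config = x$config, params = x$params, mask_set = x$mask_set,
                 cb_basis = x$cb_basis, state = state),
            class = "psn_model")
}
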