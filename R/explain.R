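# Mechanistic explanation of input-to-prototype matching.
#
# Local: integrated-gradient relevance of the cosine similarity between the
# epoch encoding and a prototype, along the straight path from a baseline
# (the center of a reference epoch distribution) to the instance; satisfies
# completeness up to the Riemann discretization. The hard attention mask is
# frozen at the instance's selected mask, which makes the attributed function
# smooth along the path.
#
# Global: prototype reconstructions by three strategies (data-driven nearest
# instances, model-driven gradient ascent from noise, hybrid ascent from
# nearest instances), scored by fidelity (cosine similarity of the
# reconstruction's embedding to the prototype), plausibility (MMD to the
# empirical neighbors) and stability (mean pairwise MMD across datasets),
# plus feature-level occlusion relevance and natural-language rules.

# ---- epoch encoder (input -> mixed embedding) with input gradients ----

# Encode a batch of single epochs (N, C, T, F) -> CM (N, D) using the model's
# per-epoch path (frame projection, greedy hard masking, pooling, mixing).
encode_epochs <- function(model, values) {
  if (length(dim(values)) == 3L) values <- array(values, dim = c(1L, dim(values)))
  d <- dim(values)
  batch <- sequence_batch(array(values, dim = c(1L, d)), NULL)
  fw <- psn_forward(model, batch, mode = "eval", collect_cache = TRUE)
  list(CM = fw$cache$X1, mask = fw$mask$mask, quant = fw$quant)
}

# Single-epoch encoder with cache. s: (C, T, F); fixed_mask: (C, T) or NULL
# (greedy selection from the votes).
epoch_encoder_fwd <- function(model, s, fixed_mask = NULL) {
  cfg <- model$config
  p <- model$params
  C <- cfg$C; Tn <- cfg$T
  xn <- (s - cfg$input_center) / cfg$input_scale
  Xm <- matrix(xn, ncol = cfg$F)                   # rows c + (t-1)C
  ft <- lin_tanh_fwd(Xm, p$Wfb, p$bfb)
  SH <- ft$out
  if (is.null(fixed_mask)) {
    mlog <- SH %*% p$Wmask
    vt <- mask_votes(mlog, C, Tn)
    sel <- gumbel_select(vt$Vn, 1, hard = TRUE, gumbel = FALSE)
    maskm <- sel$selector %*% model$mask_set$masks
  } else {
    maskm <- fixed_mask
  }
  mv <- as.vector(maskm)
  grp <- rep(seq_len(C), times = Tn)
  num <- rowsum(SH * mv, group = grp, reorder = FALSE)
  den <- as.vector(rowsum(mv, group = grp, reorder = FALSE)) + cfg$eps_pool
  Hp <- num / den                                  # (C, D)
  at <- channel_attn_fwd(array(Hp, dim = c(1L, C, cfg$D)),
                         p$Wq, p$Wk, p$Wv, p$gamma_cm)
  list(CM = as.vector(at$out), maskm = maskm,
       cache = list(ft = ft, SH = SH, mv = mv, grp = grp, den = den,
                    Hp = Hp, at = at))
}

# Gradient of a scalar wrt the input epoch, given dCM.
epoch_encoder_bwd <- function(model, cache, dCM) {
  cfg <- model$config
  C <- cfg$C
  ab <- channel_attn_bwd(cache$at$cache, matrix(dCM, nrow = 1L))
  dHp <- matrix(ab$dH, nrow = C, ncol = cfg$D)
  dnum <- dHp / cache$den
  dSH <- dnum[cache$grp, , drop = FALSE] * cache$mv
  fb <- lin_tanh_bwd(cache$ft$cache, dSH)
  array(fb$dX, dim = c(C, cfg$T, cfg$F)) / cfg$input_scale
}

# Cosine similarity to a prototype and its input gradient (mask frozen).
sim_and_grad <- function(model, s, prototype_id, fixed_mask = NULL,
                         grad = TRUE) {
  enc <- epoch_encoder_fwd(model, s, fixed_mask)
  LD <- codebook_matrix(psn_codebook(model))
  v <- LD[prototype_id, ]
  cm <- enc$CM
  ncm <- max(sqrt(sum(cm^2)), 1e-12)
  nv <- max(sqrt(sum(v^2)), 1e-12)
  u <- cm / ncm; vh <- v / nv
  simv <- sum(u * vh)
  out <- list(sim = simv, mask = enc$maskm)
  if (grad) {
    dCM <- (vh - simv * u) / ncm
    out$grad <- epoch_encoder_bwd(model, enc$cache, dCM)
  }
  out
}

#' Baseline epoch (center of a reference distribution)
#'
#' @param epochs An `epoch_tensor` (the reference set, e.g. training epochs).
#' @param source Identifier recorded on the baseline.
#' @return Object of class `psn_baseline`: `values` `(C, T, F)` per-cell mean.
#' @export
compute_baseline <- function(epochs, source = "reference") {
  vals <- if (inherits(epochs, "epoch_tensor")) epochs$values else epochs
  if (length(dim(vals)) != 4L || dim(vals)[1] < 1L) {
    stop("need a nonempty (N, C, T, F) reference set")
  }
  m <- apply(vals, c(2, 3, 4), mean)
  structure(list(values = m, source = source), class = "psn_baseline")
}

#' Integrated-gradient relevance of an epoch to a prototype
#'
#' Midpoint-Riemann integration of the input gradient of the cosine
#' similarity along the straight path from the baseline to the instance,
#' scaled elementwise by the path difference. The hard attention mask is
#' frozen at the instance's selected mask so the attributed function is
#' smooth; the completeness identity
#' `sum(relevance) = sim(instance) - sim(baseline)` then holds up to the
#' integration error, reported as `completeness_gap`.
#'
#' @param model A `psn_model`.
#' @param s Epoch array `(C, T, F)`.
#' @param prototype_id Prototype index (1..P).
#' @param baseline A `psn_baseline`.
#' @param steps Integration steps (>= 2).
#' @return Object of class `relevance_map`: `values` `(C, T, F)`, `steps`,
#'   `completeness_gap`, `sim_instance`, `sim_baseline`.
#' @export
local_relevance <- function(model, s, prototype_id, baseline, steps = 64L) {
  stopifnot(inherits(baseline, "psn_baseline"), steps >= 2L)
  b <- baseline$values
  if (!all(dim(s) == dim(b))) stop("instance and baseline shapes differ")
  frozen <- sim_and_grad(model, s, prototype_id, grad = FALSE)$mask
  diff <- s - b
  acc <- array(0, dim = dim(s))
  for (i in seq_len(steps)) {
    alpha <- (i - 0.5) / steps
    g <- sim_and_grad(model, b + alpha * diff, prototype_id, fixed_mask = frozen)$grad
    if (!all(is.finite(g))) stop("non-finite gradient during path integration")
    acc <- acc + g
  }
  rel <- diff * acc / steps
  s1 <- sim_and_grad(model, s, prototype_id, fixed_mask = frozen, grad = FALSE)$sim
  s0 <- sim_and_grad(model, b, prototype_id, fixed_mask = frozen, grad = FALSE)$sim
  structure(list(values = rel, steps = steps,
                 completeness_gap = abs(sum(rel) - (s1 - s0)),
                 sim_instance = s1, sim_baseline = s0,
                 prototype_id = prototype_id),
            class = "relevance_map")
}

#' @export
print.relevance_map <- function(x, ...) {
  cat("<relevance_map> prototype ", x$prototype_id, ", ", x$steps,
      " steps, completeness gap ", signif(x$completeness_gap, 3), "\n", sep = "")
  invisible(x)
}

new_reconstruction <- function(values, prototype_id, strategy, fidelity,
                               provenance = NULL, converged = TRUE) {
  structure(list(values = values, prototype_id = prototype_id,
                 strategy = strategy, fidelity = fidelity,
                 provenance = provenance, converged = converged),
            class = "reconstruction")
}

#' @export
print.reconstruction <- function(x, ...) {
  cat("<reconstruction> prototype ", x$prototype_id, " (", x$strategy, "), ",
      dim(x$values)[1], " instances, mean fidelity ",
      signif(mean(x$fidelity), 3), "\n", sep = "")
  invisible(x)
}

#' Reconstruction fidelity
#'
#' Cosine similarity between the epoch encoding of each reconstruction
#' instance and the prototype.
#'
#' @param model A `psn_model`.
#' @param r A `reconstruction` or `(n, C, T, F)` array.
#' @param prototype_id Prototype index (taken from `r` when absent).
#' @return Numeric vector of per-instance fidelities in `[-1, 1]`.
#' @export
fidelity <- function(model, r, prototype_id = NULL) {
  if (inherits(r, "reconstruction")) {
    prototype_id <- prototype_id %||% r$prototype_id
    r <- r$values
  }
  enc <- encode_epochs(model, r)
  enc$quant$all_sims[, prototype_id]
}

#' Data-driven prototype reconstruction
#'
#' The `k` reference epochs whose encodings are most cosine-similar to the
#' prototype.
#'
#' @param model A `psn_model`.
#' @param epochs An `epoch_tensor` (reference set).
#' @param prototype_id Prototype index.
#' @param k Number of instances (clipped to the available count with a
#'   warning).
#' @return A `reconstruction` with strategy `"data_driven"`; `provenance`
#'   holds the selected epoch indices.
#' @export
reconstruct_data_driven <- function(model, epochs, prototype_id, k = 16L) {
  vals <- epochs$values
  n <- dim(vals)[1]
  if (n < 1L) stop("empty reference set")
  if (k > n) {
    warning("k > available epochs; returning all ", n)
    k <- n
  }
  enc <- encode_epochs(model, vals)
  sims <- enc$quant$all_sims[, prototype_id]
  top <- order(sims, decreasing = TRUE)[seq_len(k)]
  new_reconstruction(vals[top, , , , drop = FALSE], prototype_id,
                     "data_driven", fidelity = sims[top], provenance = top)
}

#' Noise initialization for model-driven reconstruction
#'
#' @param model A `psn_model`. @param n Instances. @param seed Seed.
#' @return `(n, C, T, F)` array of clipped Gaussian noise in the dB input
#'   domain.
#' @export
noise_init <- function(model, n, seed = 1L) {
  cfg <- model$config
  with_seed(seed, {
    x <- array(stats::rnorm(n * cfg$C * cfg$T * cfg$F, mean = cfg$input_center, sd = 6),
               dim = c(n, cfg$C, cfg$T, cfg$F))
    pmax(x, SPEC_CLIP_DB)
  })
}

#' Gradient-ascent prototype reconstruction
#'
#' Maximizes the cosine similarity of the epoch encoding to the prototype by
#' projected gradient ascent (values kept above the -25 dB input floor) with
#' step-halving: a step is only accepted if fidelity does not decrease, so
#' fidelity is non-decreasing over iterations. Strategy is `"model_driven"`
#' when `init` is noise, `"hybrid"` when seeded with nearest instances.
#'
#' @param model A `psn_model`.
#' @param init `(n, C, T, F)` array or a `reconstruction` (whose values seed
#'   the ascent, giving the hybrid strategy).
#' @param prototype_id Prototype index.
#' @param iters Ascent iterations. @param step_size Initial step size.
#' @param max_halvings Step halvings per iteration before giving up.
#' @param strategy Override the strategy label.
#' @return A `reconstruction`; `converged = FALSE` flags instances that hit
#'   the halving limit.
#' @export
reconstruct_optimized <- function(model, init, prototype_id, iters = 100L,
                                  step_size = 5, max_halvings = 20L,
                                  strategy = NULL) {
  if (inherits(init, "reconstruction")) {
    strategy <- strategy %||% "hybrid"
    init <- init$values
  }
  strategy <- strategy %||% "model_driven"
  if (length(dim(init)) == 3L) init <- array(init, dim = c(1L, dim(init)))
  n <- dim(init)[1]
  out <- init
  fid <- numeric(n)
  conv <- rep(TRUE, n)
  for (i in seq_len(n)) {
    x <- array(init[i, , , ], dim = dim(init)[-1])
    cur <- sim_and_grad(model, x, prototype_id, grad = FALSE)$sim
    step <- step_size
    for (it in seq_len(iters)) {
      g <- sim_and_grad(model, x, prototype_id)$grad
      gn <- sqrt(sum(g^2))
      if (gn < 1e-10) break
      accepted <- FALSE
      st <- step
      for (h in seq_len(max_halvings)) {
        cand <- pmax(x + st * g / gn, SPEC_CLIP_DB)
        s2 <- sim_and_grad(model, cand, prototype_id, grad = FALSE)$sim
        if (s2 >= cur) {
          x <- cand; cur <- s2; accepted <- TRUE
          step <- st * 1.5
          break
        }
        st <- st / 2
      }
      if (!accepted) { conv[i] <- FALSE; break }
    }
    out[i, , , ] <- x
    fid[i] <- cur
  }
  new_reconstruction(out, prototype_id, strategy, fidelity = fid,
                     converged = all(conv))
}

#' Maximum mean discrepancy between two sample sets
#'
#' Squared MMD with a Gaussian RBF kernel; the bandwidth defaults to the
#' median pairwise distance of the pooled sample. The unbiased estimator
#' (default) removes kernel self-terms and can be slightly negative; the
#' biased estimator keeps them, is nonnegative, and is exactly 0 for
#' identical multisets. Singleton sets fall back to the biased estimator
#' with a warning.
#'
#' @param x,y Matrices `(n, d)` and `(m, d)` (arrays are flattened per
#'   instance along the first axis).
#' @param biased Use the biased (V-statistic) estimator.
#' @param bandwidth Optional kernel bandwidth.
#' @return Scalar squared-MMD estimate.
#' @export
mmd <- function(x, y, biased = FALSE, bandwidth = NULL) {
  x <- flatten_instances(x); y <- flatten_instances(y)
  n <- nrow(x); m <- nrow(y)
  if (n < 1L || m < 1L) stop("both sample sets must be nonempty")
  if (!biased && (n < 2L || m < 2L)) {
    warning("singleton set: falling back to the biased estimator")
    biased <- TRUE
  }
  z <- rbind(x, y)
  d2 <- sq_dists(z, z)
  if (is.null(bandwidth)) {
    md <- stats::median(sqrt(d2[upper.tri(d2)]))
    bandwidth <- if (is.finite(md) && md > 0) md else 1
  }
  Kz <- exp(-d2 / (2 * bandwidth^2))
  Kxx <- Kz[seq_len(n), seq_len(n), drop = FALSE]
  Kyy <- Kz[n + seq_len(m), n + seq_len(m), drop = FALSE]
  Kxy <- Kz[seq_len(n), n + seq_len(m), drop = FALSE]
  if (biased) {
    mean(Kxx) + mean(Kyy) - 2 * mean(Kxy)
  } else {
    (sum(Kxx) - n) / (n * (n - 1)) + (sum(Kyy) - m) / (m * (m - 1)) -
      2 * mean(Kxy)
  }
}

flatten_instances <- function(x) {
  if (inherits(x, "reconstruction")) x <- x$values
  if (is.matrix(x)) return(x)
  d <- dim(x)
  matrix(x, nrow = d[1], ncol = prod(d[-1]))
}

sq_dists <- function(a, b) {
  an <- rowSums(a^2); bn <- rowSums(b^2)
  d2 <- outer(an, bn, "+") - 2 * a %*% t(b)
  pmax(d2, 0)
}

#' Plausibility of optimized reconstructions
#'
#' Biased squared MMD between the optimized batch and the empirical-neighbor
#' batch for the same prototype; lower is more plausible, and the data-driven
#' strategy scores exactly 0 against itself.
#'
#' @param r_opt,r_data `reconstruction` objects (or arrays) for one prototype.
#' @return Scalar plausibility (>= 0).
#' @export
plausibility <- function(r_opt, r_data) {
  if (inherits(r_opt, "reconstruction") && inherits(r_data, "reconstruction") &&
      r_opt$prototype_id != r_data$prototype_id) {
    stop("reconstructions refer to different prototypes")
  }
  mmd(r_opt, r_data, biased = TRUE)
}

#' Stability across independent datasets
#'
#' Mean pairwise (biased) squared MMD between reconstruction batches obtained
#' from independent datasets; lower means the reconstructions depend less on
#' the specific dataset.
#'
#' @param batches List of >= 2 `reconstruction` objects or arrays.
#' @return Scalar stability score.
#' @export
stability <- function(batches) {
  k <- length(batches)
  if (k < 2L) stop("need at least 2 reconstruction batches")
  tot <- 0; np <- 0L
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    tot <- tot + mmd(batches[[i]], batches[[j]], biased = TRUE)
    np <- np + 1L
  }
  tot / np
}

#' Physiological feature groups over the time-frequency plane
#'
#' EEG frequency bands (delta 0.5-4, theta 4-8, alpha 8-12, sigma 12-16,
#' beta 16-30, gamma 30-40 Hz), EOG components (SEMs 0.3-1, blinks 0.5-2,
#' REMs 2-5, residual > 5 Hz; SEMs and blinks overlap by construction) and
#' overall EMG tone (all bins).
#'
#' @param fs Sampling rate (Hz). @param nfft FFT length.
#' @return List of groups: `name`, `channel` (1 EEG / 2 EOG / 3 EMG), `band`
#'   (Hz), `bins` (indices into the F axis).
#' @export
feature_groups <- function(fs = 100, nfft = 256) {
  freqs <- (seq_len(nfft / 2 + 1) - 1) * fs / nfft
  g <- function(name, channel, lo, hi) {
    list(name = name, channel = channel, band = c(lo, hi),
         bins = which(freqs >= lo & freqs <= hi))
  }
  c(lapply(names(EEG_BANDS), function(b) {
      g(b, 1L, EEG_BANDS[[b]][1], EEG_BANDS[[b]][2])
    }),
    list(g("SEMs", 2L, 0.3, 1), g("blinks", 2L, 0.5, 2), g("REMs", 2L, 2, 5),
         g("EOG>5Hz", 2L, 5, fs / 2), g("EMG_tone", 3L, 0, fs / 2)))
}

#' Feature-level occlusion relevance
#'
#' For each feature group, the drop in cosine similarity to the prototype
#' when the group's cells are replaced by the baseline (distribution-center)
#' values, averaged over the reconstruction batch.
#'
#' @param model A `psn_model`.
#' @param r A `reconstruction` (or `(n, C, T, F)` array with `prototype_id`).
#' @param groups Feature groups from [feature_groups()].
#' @param baseline A `psn_baseline`.
#' @param prototype_id Needed when `r` is a bare array.
#' @return `data.frame` with `feature`, `channel`, `relevance`.
#' @export
feature_occlusion_relevance <- function(model, r, groups, baseline,
                                        prototype_id = NULL) {
  if (inherits(r, "reconstruction")) {
    prototype_id <- prototype_id %||% r$prototype_id
    vals <- r$values
  } else vals <- r
  if (length(dim(vals)) == 3L) vals <- array(vals, dim = c(1L, dim(vals)))
  n <- dim(vals)[1]
  for (gr in groups) if (length(gr$bins) == 0L) stop("empty feature group mask")
  rel <- matrix(0, n, length(groups))
  for (i in seq_len(n)) {
    x <- array(vals[i, , , ], dim = dim(vals)[-1])
    s0 <- sim_and_grad(model, x, prototype_id, grad = FALSE)$sim
    for (gi in seq_along(groups)) {
      gr <- groups[[gi]]
      xp <- x
      xp[gr$channel, , gr$bins] <- baseline$values[gr$channel, , gr$bins]
      rel[i, gi] <- s0 - sim_and_grad(model, xp, prototype_id, grad = FALSE)$sim
    }
  }
  data.frame(feature = vapply(groups, `[[`, "", "name"),
             channel = vapply(groups, `[[`, 1L, "channel"),
             relevance = colMeans(rel))
}

#' Natural-language matching rule for a prototype
#'
#' Renders, for every feature whose absolute relevance reaches the threshold,
#' a clause with the feature's mean power in the reconstruction (dB), a
#' directional indicator versus the baseline, and the relevance value;
#' clauses are ordered by decreasing absolute relevance.
#'
#' @param relevances Output of [feature_occlusion_relevance()].
#' @param r The `reconstruction` the relevances were computed on.
#' @param baseline A `psn_baseline`.
#' @param groups The feature groups used.
#' @param threshold Minimum absolute relevance for a clause (default 0.05).
#' @return Object of class `proto_rule`: `table` (feature, relevance, power,
#'   baseline power, direction) and `text` (rendered sentences).
#' @export
generate_rules <- function(relevances, r, baseline, groups, threshold = 0.05) {
  vals <- if (inherits(r, "reconstruction")) r$values else r
  if (length(dim(vals)) == 3L) vals <- array(vals, dim = c(1L, dim(vals)))
  power <- base_power <- numeric(length(groups))
  for (gi in seq_along(groups)) {
    gr <- groups[[gi]]
    power[gi] <- mean(vals[, gr$channel, , gr$bins])
    base_power[gi] <- mean(baseline$values[gr$channel, , gr$bins])
  }
  tab <- data.frame(feature = relevances$feature, channel = relevances$channel,
                    relevance = relevances$relevance,
                    power_db = power, baseline_db = base_power,
                    direction = ifelse(power >= base_power, "\u2191", "\u2193"))
  keep <- abs(tab$relevance) >= threshold
  tab <- tab[keep, , drop = FALSE]
  tab <- tab[order(abs(tab$relevance), decreasing = TRUE), , drop = FALSE]
  role <- c("EEG", "EOG", "EMG")
  if (nrow(tab) == 0L) {
    text <- "no salient features above the relevance threshold"
  } else {
    text <- sprintf("%s %s power %.1f dB (%s vs baseline), relevance %.3f",
                    role[tab$channel], tab$feature, tab$power_db,
                    tab$direction, tab$relevance)
  }
  structure(list(table = tab, text = text, threshold = threshold,
                 prototype_id = if (inherits(r, "reconstruction")) r$prototype_id else NA),
            class = "proto_rule")
}

#' @export
print.proto_rule <- function(x, ...) {
  cat("<proto_rule> prototype ", x$prototype_id, ":\n", sep = "")
  cat(paste0("  ", x$text, collapse = "\n"), "\n")
  invisible(x)
}
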