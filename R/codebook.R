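# The learnable prototype dictionary and vector quantization.
#
# Each mixed epoch embedding is snapped to its most cosine-similar prototype.
# The forward value is the selected codebook row exactly; the backward pass
# copies the gradient to the input (straight-through). A commitment loss
# 2 - sim(CM, P) pulls encodings and prototypes together. The codebook is by
# default parameterized as a frozen random basis times a trainable linear map
# so every prototype moves under each gradient step; a directly trainable
# codebook is available via `method = "plain"`.

#' Cosine similarity
#'
#' Scale-invariant, in `[-1, 1]`. Zero vectors are guarded: the similarity is
#' returned as 0 with a warning.
#'
#' @param a,b Numeric vectors of equal length.
#' @return Scalar cosine similarity.
#' @export
cosine_sim <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na < 1e-12 || nb < 1e-12) {
    warning("zero vector in cosine similarity; returning 0")
    return(0)
  }
  sum(a * b) / (na * nb)
}

#' Create a prototype codebook
#'
#' @param P Number of prototypes.
#' @param D Embedding width.
#' @param method `"simvq"` (frozen random basis times trainable map, the
#'   default) or `"plain"` (directly trainable rows).
#' @param seed Initialization seed.
#' @return Object of class `proto_codebook`. Rows of [codebook_matrix()] are
#'   unit-norm at initialization.
#' @export
new_codebook <- function(P, D, method = c("simvq", "plain"), seed = 1L) {
  method <- match.arg(method)
  with_seed(seed, {
    B <- matrix(stats::rnorm(P * D), P, D)
    B <- B / sqrt(rowSums(B^2))
    cb <- list(P = P, D = D, method = method)
    if (method == "simvq") {
      cb$basis <- B            # frozen
      cb$W <- diag(D)          # trainable
    } else {
      cb$LD <- B               # trainable
    }
    structure(cb, class = "proto_codebook")
  })
}

#' Materialized codebook matrix
#'
#' @param cb A `proto_codebook`.
#' @return `(P, D)` matrix of prototype vectors.
#' @export
codebook_matrix <- function(cb) {
  if (cb$method == "simvq") cb$basis %*% cb$W else cb$LD
}

#' @export
print.proto_codebook <- function(x, ...) {
  cat("<proto_codebook> P=", x$P, " D=", x$D, " (", x$method, ")\n", sep = "")
  invisible(x)
}

#' Quantize embeddings onto the codebook
#'
#' For each row of `cm`, selects the prototype with maximal cosine similarity
#' (ties broken by lowest index) and returns that codebook row as the forward
#' value. The straight-through composite `P = CM + sg(P - CM)` means the
#' Jacobian with respect to `cm` is the identity; training code implements
#' this by copying output gradients to `cm` unchanged.
#'
#' @param cm Matrix `(n, D)` of mixed embeddings (a vector is treated as one
#'   row).
#' @param cb A `proto_codebook`.
#' @return Object of class `quantization_result`: `quantized` `(n, D)` rows of
#'   the codebook, `indices` (1..P), `sims` (cosine similarity to the selected
#'   prototype), `commit_loss` (mean of `2 - sim`, in `[1, 3]`).
#' @export
quantize <- function(cm, cb) {
  stopifnot(inherits(cb, "proto_codebook"))
  if (is.null(dim(cm))) cm <- matrix(cm, nrow = 1L)
  if (cb$P < 1L) stop("empty codebook")
  LD <- codebook_matrix(cb)
  sims <- cosine_sim_matrix(cm, LD)
  idx <- max.col(sims, ties.method = "first")
  structure(list(quantized = LD[idx, , drop = FALSE],
                 indices = idx,
                 sims = sims[cbind(seq_len(nrow(cm)), idx)],
                 all_sims = sims,
                 commit_loss = mean(2 - sims[cbind(seq_len(nrow(cm)), idx)])),
            class = "quantization_result")
}

# (n, D) x (P, D) -> (n, P) cosine similarities, epsilon-guarded norms.
cosine_sim_matrix <- function(X, Y) {
  nx <- pmax(sqrt(rowSums(X^2)), 1e-12)
  ny <- pmax(sqrt(rowSums(Y^2)), 1e-12)
  (X %*% t(Y)) / outer(nx, ny)
}

#' Straight-through quantization composite
#'
#' The composite `P = CM + sg(P - CM)`: the forward value is the selected
#' codebook row exactly, while the vector-Jacobian product with respect to
#' `cm` is the identity map. The model's backward pass implements the same
#' contract by copying the output gradient to the mixed embedding unchanged.
#'
#' @param cm Embedding matrix `(n, D)`.
#' @param cb A `proto_codebook`.
#' @return List with `value` (the quantized forward matrix), `quant` (the
#'   full `quantization_result`) and `vjp` (function: output cotangent ->
#'   input cotangent, the identity).
#' @export
quantize_st <- function(cm, cb) {
  q <- quantize(cm, cb)
  list(value = q$quantized, quant = q, vjp = function(dout) dout)
}

#' Commitment loss
#'
#' Mean over epochs of `2 - sim(CM_i, P_{j*(i)})`; equals 1 for perfectly
#' aligned encodings, 2 for orthogonal, 3 for antiparallel.
#'
#' @param cm Embedding matrix the quantization was computed from.
#' @param q The matching `quantization_result`.
#' @return Scalar in `[1, 3]`.
#' @export
commitment_loss <- function(cm, q) {
  stopifnot(inherits(q, "quantization_result"))
  mean(2 - q$sims)
}

# Gradient of mean(2 - sim(cm_i, LD[j_i])) wrt cm and LD (symmetric form,
# assignment fixed). Returns list(dcm, dLD).
commitment_grad <- function(cm, LD, idx, weight = 1) {
  n <- nrow(cm)
  ncm <- pmax(sqrt(rowSums(cm^2)), 1e-12)
  Pm <- LD[idx, , drop = FALSE]
  npm <- pmax(sqrt(rowSums(Pm^2)), 1e-12)
  u <- cm / ncm
  v <- Pm / npm
  s <- rowSums(u * v)
  # d sim / d cm = (v - s*u)/|cm| ; d sim / d P = (u - s*v)/|P|
  dcm <- -(v - s * u) / ncm * (weight / n)
  dP <- -(u - s * v) / npm * (weight / n)
  dLD <- matrix(0, nrow(LD), ncol(LD))
  for (j in unique(idx)) {
    rows <- which(idx == j)
    dLD[j, ] <- colSums(dP[rows, , drop = FALSE])
  }
  list(dcm = dcm, dLD = dLD)
}

#' Codebook usage report
#'
#' @param cb A `proto_codebook`.
#' @param recent_indices Integer vector of prototype assignments collected
#'   over at least one training epoch.
#' @return List with `usage` (per-prototype frequency, sums to 1) and `dead`
#'   (logical flags for prototypes unused in the window).
#' @export
codebook_health <- function(cb, recent_indices) {
  stopifnot(inherits(cb, "proto_codebook"), length(recent_indices) >= 1L)
  counts <- tabulate(recent_indices, nbins = cb$P)
  usage <- counts / sum(counts)
  list(usage = usage, dead = counts == 0L)
}

# Re-initialize dead prototypes near the most used one (called at epoch
# boundaries during training).
revive_dead_prototypes <- function(cb, recent_indices, noise_sd = 0.05, seed = NULL) {
  health <- codebook_health(cb, recent_indices)
  if (!any(health$dead)) return(cb)
  top <- which.max(health$usage)
  with_seed(seed, {
    if (cb$method == "plain") {
      for (j in which(health$dead)) {
        cb$LD[j, ] <- cb$LD[top, ] + stats::rnorm(cb$D, sd = noise_sd)
      }
    } else {
      # move the frozen basis row; the trainable map is shared
      for (j in which(health$dead)) {
        cb$basis[j, ] <- cb$basis[top, ] + stats::rnorm(cb$D, sd = noise_sd)
      }
    }
  })
  cb
}
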