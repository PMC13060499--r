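# Time-wise hard-attention masking.
#
# Each epoch's representation is pooled over a single contiguous window of
# time frames. The window is chosen from a pre-computed candidate set of all
# contiguous masks (stride 1) within a configured length range: per-frame
# logits over the candidates are softmaxed and summed into a vote vector,
# which a Gumbel-softmax turns into a (relaxed or straight-through hard)
# one-hot selector. Multiplying the selector with the candidate matrix yields
# the mask applied in the pooled mean.

#' Enumerate all contiguous candidate masks
#'
#' @param T Number of time frames per epoch.
#' @param min_len,max_len Inclusive window length range.
#' @param lengths Optional explicit vector of window lengths (overrides the
#'   range), e.g. the model default `c(5, 9, 15, 21, 29)`.
#' @return Object of class `candidate_masks`: list with binary `masks`
#'   `(M, T)`, `starts`, `lengths` and `T`.
#' @export
build_candidate_masks <- function(T, min_len = 1L, max_len = T, lengths = NULL) {
  if (is.null(lengths)) {
    if (!(min_len >= 1L && min_len <= max_len && max_len <= T)) {
      stop("need 1 <= min_len <= max_len <= T")
    }
    lengths <- min_len:max_len
  }
  lengths <- sort(unique(as.integer(lengths)))
  if (any(lengths < 1L | lengths > T)) stop("mask lengths must lie in [1, T]")
  starts <- integer(0); lens <- integer(0)
  for (l in lengths) {
    s <- seq_len(T - l + 1L)
    starts <- c(starts, s); lens <- c(lens, rep(l, length(s)))
  }
  M <- length(starts)
  masks <- matrix(0, nrow = M, ncol = T)
  for (m in seq_len(M)) masks[m, starts[m]:(starts[m] + lens[m] - 1L)] <- 1
  structure(list(masks = masks, starts = starts, lengths = lens, T = T),
            class = "candidate_masks")
}

#' @export
print.candidate_masks <- function(x, ...) {
  cat("<candidate_masks> M=", nrow(x$masks), " over T=", x$T,
      " frames, lengths {", paste(sort(unique(x$lengths)), collapse = ","),
      "}\n", sep = "")
  invisible(x)
}

#' Score candidate masks from frame embeddings
#'
#' Linear per-frame logits over the candidate set: `logits = SH . W`.
#'
#' @param sh Frame embeddings, array `(..., D)` or matrix `(n, D)`.
#' @param W Score map `(D, M)`.
#' @return Logits with the embedding axis replaced by the mask axis `M`.
#' @export
score_masks <- function(sh, W) {
  d <- dim(sh) %||% c(length(sh), 1L)
  D <- d[length(d)]
  if (nrow(W) != D) stop("W rows (", nrow(W), ") must equal embedding width (", D, ")")
  stopifnot_finite(sh, "frame embeddings")
  out <- matrix(sh, ncol = D) %*% W
  if (length(d) > 2L) out <- array(out, dim = c(d[-length(d)], ncol(W)))
  out
}

# Internal: votes from per-frame logits. logits (G*T, M) with rows ordered
# group-fastest (row = g + (t-1)*G). Returns normalized votes + softmax cache.
mask_votes <- function(logits, G, T) {
  sm <- softmax_rows(logits)
  V <- rowsum(sm, group = rep(seq_len(G), times = T), reorder = FALSE)
  s <- rowSums(V)
  list(Vn = V / s, V = V, sm = sm, s = s)
}

onehot_rows <- function(idx, M) {
  out <- matrix(0, nrow = length(idx), ncol = M)
  out[cbind(seq_along(idx), idx)] <- 1
  out
}

#' Select a mask per epoch/channel from vote logits
#'
#' Aggregates per-frame softmaxes into a vote distribution over the candidate
#' masks, then draws a selector. In stochastic mode the draw uses the
#' Gumbel-softmax relaxation at the given temperature (straight-through when
#' `hard = TRUE`: the forward selector is exactly one-hot while gradients use
#' the relaxed probabilities); with `gumbel = FALSE` the argmax of the votes
#' is taken deterministically (evaluation).
#'
#' @param logits Array `(..., T, M)` of per-frame mask logits.
#' @param mask_set A `candidate_masks` (its `M` must match).
#' @param temperature Gumbel-softmax temperature (> 0).
#' @param hard Return a one-hot forward selector.
#' @param gumbel Add Gumbel noise (training) or select greedily (evaluation).
#' @param seed Optional integer seed making the draw reproducible.
#' @return Object of class `mask_selection`: `votes` (normalized, `(..., M)`),
#'   `selector` (forward value), `soft` (relaxed probabilities used for
#'   gradients), `mask` `(..., T)`, plus `temperature` and `hard`.
#' @export
select_mask <- function(logits, mask_set, temperature = 1, hard = TRUE,
                        gumbel = TRUE, seed = NULL) {
  stopifnot(inherits(mask_set, "candidate_masks"))
  if (temperature <= 0) stop("temperature must be > 0")
  stopifnot_finite(logits, "mask logits")
  d <- dim(logits)
  if (is.null(d) || length(d) < 2L) stop("logits must have at least (T, M) axes")
  M <- d[length(d)]; T <- d[length(d) - 1L]
  if (M != nrow(mask_set$masks)) stop("logit mask axis does not match candidate set")
  if (T != mask_set$T) stop("logit frame axis does not match candidate set")
  lead <- d[-c(length(d) - 1L, length(d))]
  G <- prod(lead)
  if (G == 0L) stop("empty logits")
  # column-major flattening orders rows with the leading (group) axes fastest,
  # then t: row = g + (t-1)*G, so the group pattern is rep(1:G, times = T)
  vt <- mask_votes(matrix(logits, ncol = M), G, T)
  sel <- with_seed(seed, gumbel_select(vt$Vn, temperature, hard, gumbel))
  mask <- sel$selector %*% mask_set$masks
  reshape_back <- function(x, last) {
    if (length(d) > 2L) array(x, dim = c(lead, last)) else x
  }
  structure(list(votes = reshape_back(vt$Vn, M),
                 selector = reshape_back(sel$selector, M),
                 soft = reshape_back(sel$soft, M),
                 mask = reshape_back(mask, T),
                 temperature = temperature, hard = hard),
            class = "mask_selection")
}

gumbel_select <- function(Vn, temperature, hard, gumbel) {
  eps <- 1e-20
  z <- log(Vn + eps)
  if (gumbel) {
    u <- matrix(stats::runif(length(Vn)), nrow = nrow(Vn))
    z <- z + (-log(-log(u + eps) + eps))
  }
  soft <- softmax_rows(z / temperature)
  if (hard) {
    selector <- onehot_rows(max.col(soft, ties.method = "first"), ncol(Vn))
  } else {
    selector <- soft
  }
  list(selector = selector, soft = soft)
}

#' Masked mean pooling of frame embeddings
#'
#' `H = sum_t M_t * SH_t / (sum_t M_t + eps)`: the mean over retained frames,
#' with a small stabilizer so an all-zero mask yields (near-)zero output.
#'
#' @param sh Frame embeddings `(..., T, D)`.
#' @param mask Mask values `(..., T)` in `[0, 1]` (e.g. from [select_mask()]).
#' @param eps Pooling stabilizer (default 1e-6).
#' @return Pooled embeddings `(..., D)`.
#' @export
masked_pool <- function(sh, mask, eps = 1e-6) {
  if (inherits(mask, "mask_selection")) mask <- mask$mask
  d <- dim(sh)
  D <- d[length(d)]; T <- d[length(d) - 1L]
  lead <- d[-c(length(d) - 1L, length(d))]
  G <- prod(lead)
  shm <- matrix(sh, ncol = D)           # rows ordered g-fastest, then t
  mv <- as.vector(mask)                 # same order
  if (length(mv) != nrow(shm)) stop("mask shape does not match embeddings")
  grp <- rep(seq_len(G), times = T)
  num <- rowsum(shm * mv, group = grp, reorder = FALSE)
  den <- as.vector(rowsum(mv, group = grp, reorder = FALSE)) + eps
  out <- num / den
  if (length(d) > 2L) array(out, dim = c(lead, D)) else out
}
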