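# Differentiable building blocks with analytic forward/backward pairs and an
# Adam optimizer. Everything operates on plain matrices/arrays; caches carry
# the intermediates each backward pass needs. Gradients are verified against
# central finite differences in the test suite.

lin_tanh_fwd <- function(X, W, b) {
  Z <- X %*% W
  Z <- sweep(Z, 2L, b, "+")
  A <- tanh(Z)
  list(out = A, cache = list(X = X, W = W, A = A))
}

lin_tanh_bwd <- function(cache, dout) {
  dZ <- dout * (1 - cache$A^2)
  list(dX = dZ %*% t(cache$W),
       dW = t(cache$X) %*% dZ,
       db = colSums(dZ))
}

# Softmax cross-entropy over K classes; labels are 1..K integers.
softmax_ce_fwd <- function(logits, labels) {
  p <- softmax_rows(logits)
  n <- nrow(logits)
  eps <- 1e-12
  loss <- -mean(log(p[cbind(seq_len(n), labels)] + eps))
  list(loss = loss, probs = p)
}

softmax_ce_bwd <- function(probs, labels, weight = 1) {
  n <- nrow(probs)
  d <- probs
  d[cbind(seq_len(n), labels)] <- d[cbind(seq_len(n), labels)] - 1
  d * (weight / n)
}

# Single-head dot-product attention across the channel axis, gated residual.
# H: array (G, C, D). Output CH: (G, D) = mean_c(gamma * (A V) + H)_c.
channel_attn_fwd <- function(H, Wq, Wk, Wv, gamma) {
  dg <- dim(H); G <- dg[1]; C <- dg[2]; D <- dg[3]
  Hm <- matrix(H, nrow = G * C, ncol = D)   # rows ordered G-fastest per channel
  # reorder to (g,c) with c fastest for per-group blocks
  Q <- array(Hm %*% Wq, dim = dg)
  K <- array(Hm %*% Wk, dim = dg)
  V <- array(Hm %*% Wv, dim = dg)
  S <- array(0, dim = c(G, C, C))
  for (i in seq_len(C)) for (j in seq_len(C)) {
    S[, i, j] <- rowSums(Q[, i, , drop = FALSE] * K[, j, , drop = FALSE]) / sqrt(D)
  }
  A <- array(0, dim = c(G, C, C))
  for (i in seq_len(C)) {
    A[, i, ] <- softmax_rows(matrix(S[, i, ], nrow = G, ncol = C))
  }
  O <- array(0, dim = dg)
  for (i in seq_len(C)) {
    acc <- matrix(0, G, D)
    for (j in seq_len(C)) acc <- acc + A[, i, j] * matrix(V[, j, ], G, D)
    O[, i, ] <- acc
  }
  CH <- matrix(0, G, D)
  for (c in seq_len(C)) CH <- CH + gamma * matrix(O[, c, ], G, D) + matrix(H[, c, ], G, D)
  CH <- CH / C
  list(out = CH, cache = list(H = H, Q = Q, K = K, V = V, A = A, O = O,
                              gamma = gamma, Wq = Wq, Wk = Wk, Wv = Wv))
}

channel_attn_bwd <- function(cache, dCH) {
  H <- cache$H; dg <- dim(H); G <- dg[1]; C <- dg[2]; D <- dg[3]
  gamma <- cache$gamma
  A <- cache$A; Q <- cache$Q; K <- cache$K; V <- cache$V
  dH <- array(0, dim = dg)
  dO <- array(0, dim = dg)
  for (c in seq_len(C)) {
    dH[, c, ] <- dCH / C
    dO[, c, ] <- gamma * dCH / C
  }
  dgamma <- sum(dCH * apply(cache$O, c(1, 3), sum)) / C
  dA <- array(0, dim = c(G, C, C))
  dV <- array(0, dim = dg)
  for (i in seq_len(C)) for (j in seq_len(C)) {
    dA[, i, j] <- rowSums(matrix(dO[, i, ], G, D) * matrix(V[, j, ], G, D))
  }
  for (j in seq_len(C)) {
    acc <- matrix(0, G, D)
    for (i in seq_len(C)) acc <- acc + A[, i, j] * matrix(dO[, i, ], G, D)
    dV[, j, ] <- acc
  }
  dS <- array(0, dim = c(G, C, C))
  for (i in seq_len(C)) {
    Ai <- matrix(A[, i, ], G, C)
    dAi <- matrix(dA[, i, ], G, C)
    dS[, i, ] <- Ai * (dAi - rowSums(dAi * Ai))
  }
  dQ <- array(0, dim = dg); dK <- array(0, dim = dg)
  for (i in seq_len(C)) for (j in seq_len(C)) {
    s <- dS[, i, j] / sqrt(D)
    dQ[, i, ] <- dQ[, i, ] + s * matrix(K[, j, ], G, D)
    dK[, j, ] <- dK[, j, ] + s * matrix(Q[, i, ], G, D)
  }
  Hm <- matrix(H, nrow = G * C, ncol = D)
  dQm <- matrix(dQ, nrow = G * C, ncol = D)
  dKm <- matrix(dK, nrow = G * C, ncol = D)
  dVm <- matrix(dV, nrow = G * C, ncol = D)
  dWq <- t(Hm) %*% dQm; dWk <- t(Hm) %*% dKm; dWv <- t(Hm) %*% dVm
  dHm <- dQm %*% t(cache$Wq) + dKm %*% t(cache$Wk) + dVm %*% t(cache$Wv)
  dH <- dH + array(dHm, dim = dg)
  list(dH = dH, dWq = dWq, dWk = dWk, dWv = dWv, dgamma = dgamma)
}

# Gated bidirectional temporal convolution over the sequence axis.
# X: array (B, L, D); Z_l = sum_k X_{l+k} U_k (zero padded), out = X + gamma tanh(Z) Wo.
temporal_conv_fwd <- function(X, U, Wo, gamma, w) {
  dB <- dim(X); B <- dB[1]; L <- dB[2]; D <- dB[3]
  Z <- array(0, dim = dB)
  for (k in -w:w) {
    src <- seq_len(L) + k
    ok <- src >= 1L & src <= L
    if (!any(ok)) next
    Xs <- matrix(X[, src[ok], ], nrow = B * sum(ok), ncol = D)
    Z[, which(ok), ] <- Z[, which(ok), , drop = FALSE] +
      array(Xs %*% U[[k + w + 1L]], dim = c(B, sum(ok), D))
  }
  Aa <- tanh(Z)
  Gm <- matrix(Aa, nrow = B * L, ncol = D) %*% Wo
  out <- X + gamma * array(Gm, dim = dB)
  list(out = out, cache = list(X = X, A = Aa, Gm = Gm, U = U, Wo = Wo,
                               gamma = gamma, w = w))
}

temporal_conv_bwd <- function(cache, dout) {
  X <- cache$X; dB <- dim(X); B <- dB[1]; L <- dB[2]; D <- dB[3]
  w <- cache$w
  dX <- dout
  dgamma <- sum(dout * array(cache$Gm, dim = dB))
  dGm <- cache$gamma * matrix(dout, nrow = B * L, ncol = D)
  Am <- matrix(cache$A, nrow = B * L, ncol = D)
  dWo <- t(Am) %*% dGm
  dA <- dGm %*% t(cache$Wo)
  dZ <- array(dA, dim = dB) * (1 - cache$A^2)
  dU <- vector("list", 2L * w + 1L)
  for (k in -w:w) {
    src <- seq_len(L) + k
    ok <- src >= 1L & src <= L
    ki <- k + w + 1L
    if (!any(ok)) { dU[[ki]] <- matrix(0, D, D); next }
    Xs <- matrix(X[, src[ok], ], nrow = B * sum(ok), ncol = D)
    dZs <- matrix(dZ[, which(ok), ], nrow = B * sum(ok), ncol = D)
    dU[[ki]] <- t(Xs) %*% dZs
    dX[, src[ok], ] <- dX[, src[ok], , drop = FALSE] +
      array(dZs %*% t(cache$U[[ki]]), dim = c(B, sum(ok), D))
  }
  list(dX = dX, dU = dU, dWo = dWo, dgamma = dgamma)
}

# ---- Adam ----

adam_init <- function(params) {
  zeros <- rapply(params, function(x) x * 0, how = "replace")
  list(m = zeros, v = zeros, t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8, clip = 5) {
  gn <- sqrt(sum(unlist(rapply(grads, function(g) sum(g^2), how = "unlist"))))
  scale <- if (is.finite(gn) && gn > clip) clip / gn else 1
  state$t <- state$t + 1L
  t <- state$t
  walk <- function(p, g, m, v) {
    g <- g * scale
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    mh <- m / (1 - beta1^t)
    vh <- v / (1 - beta2^t)
    list(p = p - lr * mh / (sqrt(vh) + eps), m = m, v = v)
  }
  for (nm in names(params)) {
    if (is.list(params[[nm]])) {
      for (i in seq_along(params[[nm]])) {
        r <- walk(params[[nm]][[i]], grads[[nm]][[i]], state$m[[nm]][[i]], state$v[[nm]][[i]])
        params[[nm]][[i]] <- r$p; state$m[[nm]][[i]] <- r$m; state$v[[nm]][[i]] <- r$v
      }
    } else {
      r <- walk(params[[nm]], grads[[nm]], state$m[[nm]], state$v[[nm]])
      params[[nm]] <- r$p; state$m[[nm]] <- r$m; state$v[[nm]] <- r$v
    }
  }
  list(params = params, state = state)
}
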