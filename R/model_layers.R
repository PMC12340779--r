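# Layer primitives with hand-derived reverse-mode gradients.
#
# The encoders are small enough at desk scale to run on BLAS matrix ops; each
# primitive returns its output plus the cache its backward pass needs.
# Gradients are propagated through activations everywhere; parameter
# gradients are only materialized for tensors marked trainable under the
# model's tuning mode (frozen tensors report NULL gradients).

ln_fwd <- function(X, g, b, eps = 1e-5) {
  n <- nrow(X); d <- ncol(X)
  mu <- .rowMeans(X, n, d)
  xc <- X - mu
  inv <- 1 / sqrt(.rowMeans(xc * xc, n, d) + eps)
  xhat <- xc * inv
  list(out = xhat * rep(g, each = n) + rep(b, each = n),
       xhat = xhat, inv = inv)
}

ln_bwd <- function(dY, cache, g, want_param_grads) {
  xhat <- cache$xhat
  n <- nrow(dY); d <- ncol(dY)
  dxhat <- dY * rep(g, each = n)
  m1 <- .rowMeans(dxhat, n, d)
  m2 <- .rowMeans(dxhat * xhat, n, d)
  dX <- (dxhat - m1 - xhat * m2) * cache$inv
  out <- list(dX = dX)
  if (want_param_grads) {
    out$dg <- .colSums(dY * xhat, n, d)
    out$db <- .colSums(dY, n, d)
  }
  out
}

quickgelu_fwd <- function(X) {
  s <- 1 / (1 + exp(-1.702 * X))
  list(out = X * s, s = s)
}

quickgelu_bwd <- function(dY, X, s) {
  dY * (s + X * 1.702 * s * (1 - s))
}

l2norm_rows_fwd <- function(X, eps = 1e-12) {
  nrm <- sqrt(rowSums(X * X)) + eps
  list(out = X / nrm, nrm = nrm, Y = X / nrm)
}

l2norm_rows_bwd <- function(dY, cache) {
  Y <- cache$Y
  (dY - Y * rowSums(dY * Y)) / cache$nrm
}

# Linear projection with optional low-rank adapter path:
# Y = X W + b + (alpha/r) * drop(X) A' B'
lora_lin_fwd <- function(X, W, b, A = NULL, B = NULL, scale = 0,
                         dropout = 0, train = FALSE) {
  Y <- X %*% W
  if (!is.null(b)) Y <- Y + rep(b, each = nrow(X))
  cache <- list(X = X)
  if (!is.null(A) && scale != 0) {
    Z <- X
    if (train && dropout > 0) {
      mask <- matrix(stats::runif(length(X)) >= dropout, nrow(X)) /
        (1 - dropout)
      Z <- X * mask
      cache$mask <- mask
    }
    U <- Z %*% t(A)
    Y <- Y + scale * (U %*% t(B))
    cache$Z <- Z
    cache$U <- U
  }
  list(out = Y, cache = cache)
}

lora_lin_bwd <- function(dY, cache, W, A = NULL, B = NULL, scale = 0,
                         want_W = FALSE, want_adapter = FALSE) {
  out <- list(dX = dY %*% t(W))
  if (want_W) {
    out$dW <- crossprod(cache$X, dY)
    out$db <- colSums(dY)
  }
  if (!is.null(A) && scale != 0) {
    dU <- scale * (dY %*% B)
    dZ <- dU %*% A
    if (!is.null(cache$mask)) dZ <- dZ * cache$mask
    out$dX <- out$dX + dZ
    if (want_adapter) {
      out$dB <- scale * crossprod(dY, cache$U)
      out$dA <- crossprod(dU, cache$Z)
    }
  }
  out
}

# Multi-head self-attention over `nb` blocks of `Tn` tokens each.
# Q, K, V are (nb*Tn) x width with block-major rows. Rather than looping
# over blocks, the block-diagonal score matrix is built column-by-column
# (one vectorized pass per key position), which keeps every operation a
# full-height elementwise op or rowsum.
mha_fwd <- function(Q, K, V, heads, nb, Tn, causal = FALSE) {
  w <- ncol(Q)
  dh <- w %/% heads
  scl <- 1 / sqrt(dh)
  n <- nrow(Q)
  pos <- rep(seq_len(Tn), nb)              # token position of each row
  exp_ix <- rep(seq(0L, (nb - 1L) * Tn, by = Tn), each = Tn)  # block offset
  O <- matrix(0, n, w)
  P <- vector("list", heads)               # n x Tn attention per head
  for (h in seq_len(heads)) {
    hc <- ((h - 1L) * dh + 1L):(h * dh)
    Qh <- Q[, hc, drop = FALSE]
    Kh <- K[, hc, drop = FALSE]
    Vh <- V[, hc, drop = FALSE]
    S <- matrix(0, n, Tn)
    for (t in seq_len(Tn)) {
      S[, t] <- .rowSums(Qh * Kh[exp_ix + t, , drop = FALSE], n, dh) * scl
    }
    if (causal) S[outer(pos, seq_len(Tn), "<")] <- -Inf
    Ph <- softmax_rows(S)
    Oh <- matrix(0, n, dh)
    for (t in seq_len(Tn)) {
      Oh <- Oh + Ph[, t] * Vh[exp_ix + t, , drop = FALSE]
    }
    O[, hc] <- Oh
    P[[h]] <- Ph
  }
  list(out = O, P = P, scl = scl, exp_ix = exp_ix)
}

mha_bwd <- function(dO, cache, Q, K, V, heads, nb, Tn) {
  w <- ncol(Q)
  dh <- w %/% heads
  scl <- cache$scl
  exp_ix <- cache$exp_ix
  n <- nrow(Q)
  # rows are block-major, so summing a (n x dh) matrix over query positions
  # within each block is a column-sum of its (Tn, nb*dh) reshape
  block_sum <- function(X) {
    matrix(.colSums(matrix(X, Tn, nb * dh), Tn, nb * dh), nb, dh)
  }
  dQ <- matrix(0, n, w)
  dK <- matrix(0, n, w)
  dV <- matrix(0, n, w)
  for (h in seq_len(heads)) {
    hc <- ((h - 1L) * dh + 1L):(h * dh)
    Qh <- Q[, hc, drop = FALSE]
    Kh <- K[, hc, drop = FALSE]
    Vh <- V[, hc, drop = FALSE]
    Ph <- cache$P[[h]]
    dOh <- dO[, hc, drop = FALSE]
    dP <- matrix(0, n, Tn)
    dVh <- matrix(0, n, dh)
    for (t in seq_len(Tn)) {
      dP[, t] <- .rowSums(dOh * Vh[exp_ix + t, , drop = FALSE], n, dh)
      # dV at key position t: per block, sum over query rows of P[, t] * dO
      dVh[seq(t, n, by = Tn), ] <- block_sum(Ph[, t] * dOh)
    }
    dS <- Ph * (dP - .rowSums(dP * Ph, n, Tn))
    dQh <- matrix(0, n, dh)
    dKh <- matrix(0, n, dh)
    for (t in seq_len(Tn)) {
      dQh <- dQh + dS[, t] * Kh[exp_ix + t, , drop = FALSE]
      dKh[seq(t, n, by = Tn), ] <- block_sum(dS[, t] * Qh)
    }
    dQ[, hc] <- dQh * scl
    dK[, hc] <- dKh * scl
    dV[, hc] <- dVh
  }
  list(dQ = dQ, dK = dK, dV = dV)
}

# One residual transformer block (pre-norm attention + pre-norm MLP).
block_fwd <- function(X, p, pre, heads, nb, Tn, causal, lora, train,
                      grads_for) {
  g <- function(nm) p[[paste0(pre, "_", nm)]]
  scale <- if (lora$rank > 0) lora$alpha / lora$rank else 0
  ln1 <- ln_fwd(X, g("ln1_g"), g("ln1_b"))
  qkv <- lapply(c("q", "k", "v"), function(s) {
    lora_lin_fwd(ln1$out, g(paste0("W", s)), g(paste0("b", s)),
                 g(paste0("A", s)), g(paste0("B", s)),
                 scale = scale, dropout = lora$dropout, train = train)
  })
  att <- mha_fwd(qkv[[1]]$out, qkv[[2]]$out, qkv[[3]]$out, heads, nb, Tn,
                 causal)
  o <- lora_lin_fwd(att$out, g("Wo"), g("bo"))
  X1 <- X + o$out
  ln2 <- ln_fwd(X1, g("ln2_g"), g("ln2_b"))
  fc <- lora_lin_fwd(ln2$out, g("Wfc"), g("bfc"))
  gl <- quickgelu_fwd(fc$out)
  pr <- lora_lin_fwd(gl$out, g("Wpr"), g("bpr"))
  list(out = X1 + pr$out,
       cache = list(ln1 = ln1, qkv = qkv, att = att, o = o, X1 = X1,
                    ln2 = ln2, fc = fc, gl = gl, pr = pr))
}

block_bwd <- function(dY, cache, p, pre, heads, nb, Tn, lora, grads_for,
                      grads) {
  g <- function(nm) p[[paste0(pre, "_", nm)]]
  nm_full <- function(nm) paste0(pre, "_", nm)
  want <- function(nm) nm_full(nm) %in% grads_for
  acc <- function(nm, val) {
    key <- nm_full(nm)
    grads[[key]] <<- if (is.null(grads[[key]])) val else grads[[key]] + val
  }
  scale <- if (lora$rank > 0) lora$alpha / lora$rank else 0

  # mlp branch
  prb <- lora_lin_bwd(dY, cache$pr$cache, g("Wpr"), want_W = want("Wpr"))
  if (want("Wpr")) { acc("Wpr", prb$dW); acc("bpr", prb$db) }
  dG <- quickgelu_bwd(prb$dX, cache$fc$out, cache$gl$s)
  fcb <- lora_lin_bwd(dG, cache$fc$cache, g("Wfc"), want_W = want("Wfc"))
  if (want("Wfc")) { acc("Wfc", fcb$dW); acc("bfc", fcb$db) }
  ln2b <- ln_bwd(fcb$dX, cache$ln2, g("ln2_g"), want("ln2_g"))
  if (want("ln2_g")) { acc("ln2_g", ln2b$dg); acc("ln2_b", ln2b$db) }
  dX1 <- dY + ln2b$dX

  # attention branch
  ob <- lora_lin_bwd(dX1, cache$o$cache, g("Wo"), want_W = want("Wo"))
  if (want("Wo")) { acc("Wo", ob$dW); acc("bo", ob$db) }
  mb <- mha_bwd(ob$dX, cache$att, cache$qkv[[1]]$out, cache$qkv[[2]]$out,
                cache$qkv[[3]]$out, heads, nb, Tn)
  dh1 <- 0
  dqkv <- list(mb$dQ, mb$dK, mb$dV)
  for (i in seq_len(3)) {
    s <- c("q", "k", "v")[i]
    lb <- lora_lin_bwd(dqkv[[i]], cache$qkv[[i]]$cache, g(paste0("W", s)),
                       g(paste0("A", s)), g(paste0("B", s)), scale = scale,
                       want_W = want(paste0("W", s)),
                       want_adapter = want(paste0("A", s)))
    if (want(paste0("W", s))) {
      acc(paste0("W", s), lb$dW); acc(paste0("b", s), lb$db)
    }
    if (want(paste0("A", s)) && !is.null(lb$dA)) {
      acc(paste0("A", s), lb$dA); acc(paste0("B", s), lb$dB)
    }
    dh1 <- dh1 + lb$dX
  }
  ln1b <- ln_bwd(dh1, cache$ln1, g("ln1_g"), want("ln1_g"))
  if (want("ln1_g")) { acc("ln1_g", ln1b$dg); acc("ln1_b", ln1b$db) }
  list(dX = dX1 + ln1b$dX, grads = grads)
}
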