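# Batched training engine.
#
# The user-facing forward pass (har_forward) processes one window at a
# time and keeps attention records. Training uses this engine instead: a
# whole minibatch is stacked row-wise into an (B*T) x d matrix so every
# position-wise operation is a single BLAS call, and only the attention
# softmax loops over windows and heads. The backward pass mirrors the
# forward caches exactly; its correctness is pinned by a central-difference
# gradient check in the test suite.
#
# RNG: dropout masks draw from the session RNG; train() seeds it once.

stack_batch <- function(windows, normalizer) {
  X <- do.call(rbind, lapply(windows, function(w)
    apply_normalizer(normalizer, w)))
  labels <- unlist(lapply(windows, `[[`, "labels"), use.names = FALSE)
  list(X = X, labels = as.integer(labels))
}

drop_mask <- function(nr, nc, rate) {
  matrix((stats::runif(nr * nc) >= rate) / (1 - rate), nr, nc)
}

ln_fwd <- function(x, g, b, eps = 1e-6) {
  mu <- rowMeans(x)
  xc <- x - mu
  inv <- 1 / sqrt(rowMeans(xc^2) + eps)
  xhat <- xc * inv
  list(y = sweep(xhat, 2L, g, "*") + rep(b, each = nrow(x)),
       xhat = xhat, inv = inv, g = g)
}

ln_bwd <- function(dY, cache) {
  dxhat <- sweep(dY, 2L, cache$g, "*")
  list(dx = cache$inv *
         (dxhat - rowMeans(dxhat) - cache$xhat * rowMeans(dxhat * cache$xhat)),
       dg = colSums(dY * cache$xhat),
       db = colSums(dY))
}

# Forward over a stacked batch, returning logits and (optionally) the
# caches needed by engine_backward.
engine_forward <- function(params, config, X, training = FALSE,
                           keep_cache = FALSE) {
  T <- config$T; d <- config$d_model
  M <- nrow(X); B <- M %/% T
  h_heads <- config$n_heads; dk <- head_dim(d, h_heads)
  drop <- config$dropout_rate
  adrop <- config$attention_dropout_rate
  cache <- if (keep_cache) list(X = X, blocks = vector("list", config$n_layers))

  H <- X %*% params$Win + rep(params$bin, each = M)
  H <- H + params$P[rep(seq_len(T), B), ]
  mask0 <- NULL
  if (training && drop > 0) {
    mask0 <- drop_mask(M, d, drop)
    H <- H * mask0
  }
  if (keep_cache) cache$mask0 <- mask0

  for (l in seq_len(config$n_layers)) {
    blk <- params$blocks[[l]]
    x_in <- H
    ln1 <- ln_fwd(x_in, blk$ln1_g, blk$ln1_b)
    Q <- ln1$y %*% blk$Wq + rep(blk$bq, each = M)
    Kp <- ln1$y %*% blk$Wk + rep(blk$bk, each = M)
    V <- ln1$y %*% blk$Wv + rep(blk$bv, each = M)
    O <- matrix(0, M, h_heads * dk)
    A_soft <- if (keep_cache) array(0, c(T, T, h_heads, B))
    A_mask <- if (keep_cache && training && adrop > 0) array(0, c(T, T, h_heads, B))
    for (w in seq_len(B)) {
      rows <- (w - 1L) * T + seq_len(T)
      for (i in seq_len(h_heads)) {
        cols <- (i - 1L) * dk + seq_len(dk)
        A <- row_softmax(tcrossprod(Q[rows, cols, drop = FALSE],
                                    Kp[rows, cols, drop = FALSE]) / sqrt(dk))
        if (keep_cache) A_soft[, , i, w] <- A
        if (training && adrop > 0) {
          mk <- drop_mask(T, T, adrop)
          if (keep_cache) A_mask[, , i, w] <- mk
          A <- A * mk
        }
        O[rows, cols] <- A %*% V[rows, cols, drop = FALSE]
      }
    }
    Y <- O %*% blk$Wo + rep(blk$bo, each = M)
    mask1 <- NULL
    if (training && drop > 0) {
      mask1 <- drop_mask(M, d, drop)
      Y <- Y * mask1
    }
    U <- x_in + Y
    ln2 <- ln_fwd(U, blk$ln2_g, blk$ln2_b)
    Z1 <- ln2$y %*% blk$W1 + rep(blk$b1, each = M)
    Ag <- if (config$activation == "relu") pmax(Z1, 0) else gelu(Z1)
    Fo <- Ag %*% blk$W2 + rep(blk$b2, each = M)
    mask2 <- NULL
    if (training && drop > 0) {
      mask2 <- drop_mask(M, d, drop)
      Fo <- Fo * mask2
    }
    H <- U + Fo
    if (keep_cache)
      cache$blocks[[l]] <- list(x_in = x_in, ln1 = ln1, Q = Q, K = Kp, V = V,
                                A_soft = A_soft, A_mask = A_mask, O = O,
                                mask1 = mask1, U = U, ln2 = ln2, Z1 = Z1,
                                Ag = Ag, mask2 = mask2)
  }
  lnf <- ln_fwd(H, params$lnf_g, params$lnf_b)
  logits <- lnf$y %*% params$Wh + rep(params$bh, each = M)
  if (keep_cache) {
    cache$lnf <- lnf
    cache$B <- B
  }
  list(logits = logits, cache = cache)
}

# Smoothed cross-entropy over stacked logits; returns loss and dlogits.
ce_loss_grad <- function(logits, labels, smoothing) {
  M <- nrow(logits); K <- ncol(logits)
  if (any(labels < 0L | labels >= K)) stop("label out of range 0..", K - 1L)
  mx <- apply(logits, 1L, max)
  Z <- exp(logits - mx)
  sz <- rowSums(Z)
  logp <- logits - mx - log(sz)
  idx <- cbind(seq_len(M), labels + 1L)
  loss <- -mean((1 - smoothing) * logp[idx] + (smoothing / K) * rowSums(logp))
  P <- Z / sz
  dlogits <- P
  dlogits[idx] <- dlogits[idx] - (1 - smoothing)
  dlogits <- (dlogits - smoothing / K) / M
  list(loss = loss, dlogits = dlogits)
}

engine_backward <- function(params, config, cache, dlogits) {
  T <- config$T; d <- config$d_model
  M <- nrow(dlogits); B <- cache$B
  h_heads <- config$n_heads; dk <- head_dim(d, h_heads)
  g <- list()

  g$Wh <- crossprod(cache$lnf$y, dlogits)
  g$bh <- colSums(dlogits)
  lb <- ln_bwd(dlogits %*% t(params$Wh), cache$lnf)
  g$lnf_g <- lb$dg; g$lnf_b <- lb$db
  dH <- lb$dx

  g$blocks <- vector("list", config$n_layers)
  for (l in rev(seq_len(config$n_layers))) {
    blk <- params$blocks[[l]]
    cc <- cache$blocks[[l]]
    gb <- list()
    dFo <- if (is.null(cc$mask2)) dH else dH * cc$mask2
    gb$W2 <- crossprod(cc$Ag, dFo)
    gb$b2 <- colSums(dFo)
    dAg <- dFo %*% t(blk$W2)
    dZ1 <- if (config$activation == "relu") dAg * (cc$Z1 > 0)
           else dAg * gelu_grad(cc$Z1)
    gb$W1 <- crossprod(cc$ln2$y, dZ1)
    gb$b1 <- colSums(dZ1)
    lb2 <- ln_bwd(dZ1 %*% t(blk$W1), cc$ln2)
    gb$ln2_g <- lb2$dg; gb$ln2_b <- lb2$db
    dU <- dH + lb2$dx

    dY <- if (is.null(cc$mask1)) dU else dU * cc$mask1
    gb$Wo <- crossprod(cc$O, dY)
    gb$bo <- colSums(dY)
    dO <- dY %*% t(blk$Wo)
    hd <- h_heads * dk
    dQ <- matrix(0, M, hd); dK <- matrix(0, M, hd); dV <- matrix(0, M, hd)
    for (w in seq_len(B)) {
      rows <- (w - 1L) * T + seq_len(T)
      for (i in seq_len(h_heads)) {
        cols <- (i - 1L) * dk + seq_len(dk)
        A <- cc$A_soft[, , i, w]
        Adrop <- if (is.null(cc$A_mask)) A else A * cc$A_mask[, , i, w]
        dO_wi <- dO[rows, cols, drop = FALSE]
        V_wi <- cc$V[rows, cols, drop = FALSE]
        dAdrop <- tcrossprod(dO_wi, V_wi)
        dV[rows, cols] <- crossprod(Adrop, dO_wi)
        dA <- if (is.null(cc$A_mask)) dAdrop
              else dAdrop * cc$A_mask[, , i, w]
        dS <- A * (dA - rowSums(A * dA))
        dQ[rows, cols] <- dS %*% cc$K[rows, cols, drop = FALSE] / sqrt(dk)
        dK[rows, cols] <- crossprod(dS, cc$Q[rows, cols, drop = FALSE]) / sqrt(dk)
      }
    }
    gb$Wq <- crossprod(cc$ln1$y, dQ); gb$bq <- colSums(dQ)
    gb$Wk <- crossprod(cc$ln1$y, dK); gb$bk <- colSums(dK)
    gb$Wv <- crossprod(cc$ln1$y, dV); gb$bv <- colSums(dV)
    dxn1 <- dQ %*% t(blk$Wq) + dK %*% t(blk$Wk) + dV %*% t(blk$Wv)
    lb1 <- ln_bwd(dxn1, cc$ln1)
    gb$ln1_g <- lb1$dg; gb$ln1_b <- lb1$db
    dH <- dU + lb1$dx
    # leaf order must match the parameter tree for tree_map2
    g$blocks[[l]] <- gb[c("ln1_g", "ln1_b", "Wq", "bq", "Wk", "bk",
                          "Wv", "bv", "Wo", "bo", "ln2_g", "ln2_b",
                          "W1", "b1", "W2", "b2")]
  }

  dH0 <- if (is.null(cache$mask0)) dH else dH * cache$mask0
  g$P <- rowsum(dH0, rep(seq_len(T), B), reorder = TRUE)
  dimnames(g$P) <- NULL
  g$Win <- crossprod(cache$X, dH0)
  g$bin <- colSums(dH0)
  g[c("Win", "bin", "P", "blocks", "lnf_g", "lnf_b", "Wh", "bh")]
}

# One loss + gradient evaluation on a stacked batch.
engine_loss_grads <- function(params, config, X, labels, smoothing,
                              training = TRUE) {
  fwd <- engine_forward(params, config, X, training = training,
                        keep_cache = TRUE)
  lg <- ce_loss_grad(fwd$logits, labels, smoothing)
  list(loss = lg$loss,
       grads = engine_backward(params, config, fwd$cache, lg$dlogits),
       logits = fwd$logits)
}

# ---- parameter-tree helpers (nested lists of numeric arrays) ----

tree_map <- function(f, tree) {
  if (is.list(tree)) lapply(tree, function(x) tree_map(f, x)) else f(tree)
}

tree_map2 <- function(f, a, b) {
  if (is.list(a)) mapply(function(x, y) tree_map2(f, x, y), a, b,
                         SIMPLIFY = FALSE)
  else f(a, b)
}

tree_sumsq <- function(tree) {
  if (is.list(tree)) sum(vapply(tree, tree_sumsq, numeric(1)))
  else sum(tree^2)
}
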