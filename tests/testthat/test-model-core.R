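test_that("normalizer matches a two-pass oracle and standardizes training data", {
  # two-point channel: {1, 3} -> mu 2, sigma 1, values map to -1/+1
  w <- signal_window(matrix(c(1, 3, 5, 5), 2, 2), 0L)
  ds <- window_dataset(list(w), activity_manifest("a", 1L))
  st <- fit_normalizer(ds)
  expect_equal(st$mean, c(2, 5))
  expect_equal(st$std, c(1, 0))
  out <- apply_normalizer(st, w)
  expect_equal(out[, 1], c(-1, 1), tolerance = 1e-6)
  expect_true(all(abs(out[, 2]) < 1e-9))   # constant channel -> 0, no blow-up

  set.seed(11)
  ws <- lapply(1:4, function(i)
    signal_window(matrix(rnorm(30, mean = i, sd = i), 10, 3), 0L, i))
  ds2 <- window_dataset(ws, activity_manifest("a", 4L))
  st2 <- fit_normalizer(ds2)
  pooled <- do.call(rbind, lapply(ws, `[[`, "values"))
  # independent two-pass mean/sd
  mu <- apply(pooled, 2, function(v) sum(v) / length(v))
  sdv <- sqrt(apply(pooled, 2, function(v) sum((v - sum(v) / length(v))^2) / length(v)))
  expect_equal(st2$mean, mu, tolerance = 1e-9)
  expect_equal(st2$std, sdv, tolerance = 1e-9)
  z <- apply_normalizer(st2, pooled)
  expect_true(all(abs(colMeans(z)) < 1e-6))
  expect_true(all(abs(apply(z, 2, function(v) sqrt(mean((v - mean(v))^2))) - 1) < 1e-4))
  expect_error(fit_normalizer(window_dataset(list(), activity_manifest("a"))),
               "empty")
  expect_error(apply_normalizer(st2, matrix(0, 2, 5)), "mismatch")
})

test_that("scaled dot-product attention matches hand and brute-force oracles", {
  # singleton: softmax of one score is 1
  one <- scaled_dot_product_attention(matrix(1), matrix(2), matrix(5))
  expect_equal(one$weights, matrix(1))
  expect_equal(one$output, matrix(5))

  # identical keys -> uniform weights, output = column mean of V
  Q <- matrix(rnorm(6), 3, 2)
  K <- matrix(rep(c(1, 2), each = 3), 3, 2)
  V <- matrix(rnorm(9), 3, 3)
  att <- scaled_dot_product_attention(Q, K, V)
  expect_equal(att$weights, matrix(1 / 3, 3, 3), tolerance = 1e-12)
  expect_equal(att$output[1, ], colMeans(V), tolerance = 1e-12)

  # d_k = 1 hand-computed case
  att2 <- scaled_dot_product_attention(matrix(c(1, 0)), matrix(c(1, 0)),
                                       matrix(c(2, 4)))
  expect_equal(att2$weights[1, ], c(0.7311, 0.2689), tolerance = 1e-4)
  expect_equal(att2$output[1, 1], 2.5378, tolerance = 1e-4)

  # random instances vs nested-loop oracle
  set.seed(21)
  for (i in 1:10) {
    T <- sample(2:8, 1); dk <- sample(1:8, 1)
    Q <- matrix(rnorm(T * dk), T, dk); K <- matrix(rnorm(T * dk), T, dk)
    V <- matrix(rnorm(T * 3), T, 3)
    got <- scaled_dot_product_attention(Q, K, V)
    ref <- oracle_attention(Q, K, V)
    expect_lt(max(abs(got$weights - ref$weights)), 1e-6)
    expect_lt(max(abs(got$output - ref$output)), 1e-6)
    expect_equal(rowSums(got$weights), rep(1, T), tolerance = 1e-12)
  }
  expect_error(scaled_dot_product_attention(matrix(0, 2, 2), matrix(0, 2, 3),
                                            matrix(0, 2, 2)), "d_k")
})

test_that("multi-head attention reduces to single-head and matches a per-head loop", {
  d <- 4L
  x <- matrix(rnorm(5 * d), 5, d)
  ident <- list(Wq = diag(d), bq = rep(0, d), Wk = diag(d), bk = rep(0, d),
                Wv = diag(d), bv = rep(0, d), Wo = diag(d), bo = rep(0, d))
  got <- multi_head_attention(x, ident, n_heads = 1L)
  ref <- scaled_dot_product_attention(x, x, x)
  expect_equal(got$output, ref$output, tolerance = 1e-12)
  expect_identical(dim(got$output), dim(x))

  set.seed(31)
  p <- list(Wq = matrix(rnorm(16), 4, 4) * 0.3, bq = rnorm(4) * 0.1,
            Wk = matrix(rnorm(16), 4, 4) * 0.3, bk = rnorm(4) * 0.1,
            Wv = matrix(rnorm(16), 4, 4) * 0.3, bv = rnorm(4) * 0.1,
            Wo = matrix(rnorm(16), 4, 4) * 0.3, bo = rnorm(4) * 0.1)
  got2 <- multi_head_attention(x, p, n_heads = 2L)
  # brute-force per-head composition
  Q <- x %*% p$Wq + rep(p$bq, each = 5); K <- x %*% p$Wk + rep(p$bk, each = 5)
  V <- x %*% p$Wv + rep(p$bv, each = 5)
  O <- matrix(0, 5, 4)
  for (h in 1:2) {
    cols <- (h - 1) * 2 + 1:2
    O[, cols] <- oracle_attention(Q[, cols], K[, cols], V[, cols])$output
  }
  expect_lt(max(abs(got2$output - (O %*% p$Wo + rep(p$bo, each = 5)))), 1e-6)
  expect_length(got2$records, 2L)
  for (r in got2$records)
    expect_equal(rowSums(r$matrix), rep(1, 5), tolerance = 1e-6)
  # non-divisible head count: d_k = floor(d/h), output still T x d
  p3h <- list(Wq = matrix(rnorm(12), 4, 3) * 0.3, bq = rnorm(3) * 0.1,
              Wk = matrix(rnorm(12), 4, 3) * 0.3, bk = rnorm(3) * 0.1,
              Wv = matrix(rnorm(12), 4, 3) * 0.3, bv = rnorm(3) * 0.1,
              Wo = matrix(rnorm(12), 3, 4) * 0.3, bo = rnorm(4) * 0.1)
  got3 <- multi_head_attention(x, p3h, n_heads = 3L)
  expect_identical(dim(got3$output), c(5L, 4L))
  expect_error(multi_head_attention(x, p, n_heads = 5L), "exceed")
})

test_that("position-wise FFN is per-timestep and honors both activations", {
  prm <- list(W1 = matrix(0, 3, 5), b1 = rep(0, 5),
              W2 = matrix(0, 5, 3), b2 = c(1, 2, 3))
  out <- position_wise_ffn(matrix(rnorm(12), 4, 3), prm)
  expect_equal(out, matrix(rep(c(1, 2, 3), each = 4), 4, 3))

  # relu hand case: pre-activations (-1, 2) pass through max(0, .)
  prm2 <- list(W1 = diag(2), b1 = c(0, 0), W2 = diag(2), b2 = c(0, 0))
  out2 <- position_wise_ffn(matrix(c(-1, 2), 1, 2), prm2, activation = "relu")
  expect_equal(out2, matrix(c(0, 2), 1, 2))

  set.seed(5)
  x <- matrix(rnorm(15), 5, 3)
  prm3 <- list(W1 = matrix(rnorm(12), 3, 4), b1 = rnorm(4),
               W2 = matrix(rnorm(12), 4, 3), b2 = rnorm(3))
  perm <- c(3, 1, 5, 2, 4)
  expect_equal(position_wise_ffn(x[perm, ], prm3),
               position_wise_ffn(x, prm3)[perm, ], tolerance = 1e-12)
})

test_that("pre-norm encoder block is the identity when sublayers are zeroed", {
  cfg <- tiny_config(n_layers = 1L)
  p <- init_params(cfg, seed = 2)
  blk <- p$blocks[[1]]
  blk$Wo[] <- 0; blk$bo[] <- 0; blk$W2[] <- 0; blk$b2[] <- 0
  x <- matrix(rnorm(cfg$T * cfg$d_model), cfg$T, cfg$d_model)
  out <- encoder_block(x, blk, cfg)
  expect_identical(out$output, x)

  # straight-line composition oracle
  blk2 <- p$blocks[[1]]
  ref <- {
    u <- x + multi_head_attention(harformer:::layer_norm(x, blk2$ln1_g, blk2$ln1_b),
                                  blk2, cfg$n_heads)$output
    u + position_wise_ffn(harformer:::layer_norm(u, blk2$ln2_g, blk2$ln2_b),
                          blk2, cfg$activation)
  }
  got <- encoder_block(x, blk2, cfg)
  expect_equal(got$output, ref, tolerance = 1e-12)
  expect_identical(dim(got$output), dim(x))
})

test_that("initialization is seeded, truncated, and has the closed-form sd", {
  cfg <- tiny_config()
  expect_identical(init_params(cfg, seed = 9), init_params(cfg, seed = 9))
  expect_false(identical(init_params(cfg, seed = 9), init_params(cfg, seed = 10)))
  p <- init_params(cfg, seed = 9)
  ws <- unlist(lapply(c(p["Win"], p["P"], p["Wh"]), as.vector))
  expect_true(all(abs(ws) <= 0.04 + 1e-12))     # truncation at 2 sd of 0.02
  set.seed(1)
  draws <- harformer:::rtruncnorm2(1e5, sd = 0.02)
  sd_closed <- 0.02 * sqrt(1 - 4 * dnorm(2) / (pnorm(2) - pnorm(-2)))
  expect_lt(abs(sd(draws) - sd_closed) / sd_closed, 0.05)
  expect_lt(max(abs(draws)), 0.04 + 1e-12)
})

test_that("parameter count matches shape arithmetic", {
  cfg <- tiny_config(d_model = 4L, d_ff = 8L, n_heads = 2L, n_layers = 1L,
                     T = 6L, C = 2L, K = 3L)
  p <- init_params(cfg, seed = 1)
  per_block <- 4 * (4 * 4 + 4) +      # q, k, v, o projections + biases
    2 * (4 + 4) +                     # two layer norms
    (4 * 8 + 8) + (8 * 4 + 4)         # ffn
  expected <- (2 * 4 + 4) +           # input projection
    6 * 4 +                           # position embedding
    per_block +
    (4 + 4) +                         # final layer norm
    (4 * 3 + 3)                       # head
  expect_identical(count_parameters(p), as.integer(expected))
  p2 <- init_params(tiny_config(n_layers = 3L), seed = 1)
  expect_gt(count_parameters(p2), count_parameters(p))
  # doubling d_ff changes only the ffn term by the predicted amount
  p3 <- init_params(tiny_config(d_ff = 16L, n_layers = 1L), seed = 1)
  expect_identical(count_parameters(p3) - count_parameters(p),
                   as.integer((4 * 16 + 16 + 16 * 4) - (4 * 8 + 8 + 8 * 4)))
})

test_that("forward pass has the contracted shape, determinism and row sums", {
  cfg <- model_config()       # reference architecture: 300 x 6 -> 18
  p <- init_params(cfg, seed = 1)
  w <- signal_window(matrix(rnorm(300 * 6), 300, 6), 0L)
  out <- har_forward(w, p, cfg)
  expect_identical(dim(out$logits), c(300L, 18L))
  expect_length(out$records, cfg$n_layers * cfg$n_heads)
  for (r in out$records[c(1, 9, 18)])
    expect_true(all(abs(rowSums(r$matrix) - 1) < 1e-5))
  out2 <- har_forward(w, p, cfg)
  expect_identical(out$logits, out2$logits)
  expect_error(har_forward(signal_window(matrix(0, 10, 6), 0L), p, cfg),
               "does not match")
})

test_that("position embedding breaks permutation equivariance; P = 0 restores it", {
  cfg <- tiny_config(T = 5L, K = 2L, n_layers = 1L)
  p <- init_params(cfg, seed = 6)
  p$P <- p$P * 50            # make position information non-degenerate
  w <- random_window(5, 2, 2, seed = 8)
  perm <- c(4, 2, 5, 1, 3)
  wp <- signal_window(w$values[perm, ], w$labels[perm], "p")
  with_P <- har_forward(w, p, cfg)$logits
  with_P_perm <- har_forward(wp, p, cfg)$logits
  expect_gt(max(abs(with_P_perm - with_P[perm, ])), 1e-4)
  p0 <- p; p0$P[] <- 0
  no_P <- har_forward(w, p0, cfg)$logits
  no_P_perm <- har_forward(wp, p0, cfg)$logits
  expect_lt(max(abs(no_P_perm - no_P[perm, ])), 1e-8)
})

test_that("batched engine agrees with the per-window forward", {
  cfg <- tiny_config(T = 7L, C = 3L, K = 4L, d_model = 6L, n_heads = 3L)
  p <- init_params(cfg, seed = 4)
  set.seed(14)
  ws <- lapply(1:3, function(i) random_window(7, 3, 4, seed = i))
  st <- harformer:::stack_batch(ws, p$normalizer)
  eng <- harformer:::engine_forward(p, cfg, st$X)$logits
  for (i in 1:3) {
    ref <- har_forward(ws[[i]], p, cfg)$logits
    expect_lt(max(abs(eng[(i - 1) * 7 + 1:7, ] - ref)), 1e-12)
  }
})

test_that("analytic gradients match central differences", {
  cfg <- tiny_config()
  p <- init_params(cfg, seed = 3)
  p$normalizer <- normalizer_state(c(0.5, -0.2), c(1.2, 0.8))
  set.seed(42)
  ws <- lapply(1:2, function(i) random_window(6, 2, 3, seed = i))
  st <- harformer:::stack_batch(ws, p$normalizer)
  lg <- harformer:::engine_loss_grads(p, cfg, st$X, st$labels, 0.1,
                                      training = FALSE)
  tr <- harformer:::learnable_tree(p)
  p_flat <- unlist(tr, use.names = FALSE)
  g_an <- unlist(lg$grads, use.names = FALSE)
  restore <- function(a, b)
    if (is.list(a)) mapply(restore, a, b, SIMPLIFY = FALSE)
    else { dim(b) <- dim(a); b }
  loss_at <- function(pf) {
    p2 <- p
    p2[names(tr)] <- restore(tr, utils::relist(pf, tr))
    harformer:::engine_loss_grads(p2, cfg, st$X, st$labels, 0.1,
                                  training = FALSE)$loss
  }
  set.seed(1)
  idx <- sample(length(p_flat), 50)
  eps <- 1e-6
  for (j in idx) {
    up <- p_flat; up[j] <- up[j] + eps
    dn <- p_flat; dn[j] <- dn[j] - eps
    expect_lt(abs((loss_at(up) - loss_at(dn)) / (2 * eps) - g_an[j]), 1e-6)
  }
})

test_that("checkpoints round-trip bit-exactly with their config sidecar", {
  cfg <- tiny_config()
  p <- init_params(cfg, seed = 12)
  path <- withr::local_tempfile(fileext = ".ckpt")
  save_checkpoint(p, cfg, path)
  back <- load_checkpoint(path)
  expect_identical(back$params, p)
  expect_identical(back$config, cfg)
  expect_error(load_checkpoint("missing.ckpt"), "not found")
})
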