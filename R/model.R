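#' Transformer model configuration
#'
#' Defaults follow the optimized hyperparameters of the reference study:
#' 300-step windows of 6 channels, 18 classes, embedding size 128, first
#' feed-forward layer 256, 6 heads, 3 encoder blocks, dropout 0.1 both
#' between layers and on the attention matrix.
#'
#' @param T Window length in timesteps.
#' @param C Input channels.
#' @param K Number of classes.
#' @param d_model Embedding size. Each head works in
#'   `d_k = floor(d_model / n_heads)` dimensions and the concatenated head
#'   outputs are projected back to `d_model`, so `d_model` need not be a
#'   multiple of `n_heads`.
#' @param d_ff Size of the first feed-forward layer.
#' @param n_heads Number of attention heads.
#' @param n_layers Number of encoder blocks.
#' @param dropout_rate Dropout between layers.
#' @param attention_dropout_rate Dropout on attention weights.
#' @param activation `"gelu"` (default) or `"relu"` for the feed-forward
#'   nonlinearity.
#' @return A list of class `har_model_config`.
#' @export
model_config <- function(T = 300L, C = 6L, K = 18L, d_model = 128L,
                         d_ff = 256L, n_heads = 6L, n_layers = 3L,
                         dropout_rate = 0.1, attention_dropout_rate = 0.1,
                         activation = c("gelu", "relu")) {
  activation <- match.arg(activation)
  sizes <- c(T = T, C = C, K = K, d_model = d_model, d_ff = d_ff,
             n_heads = n_heads, n_layers = n_layers)
  if (any(sizes < 1)) stop("all sizes must be positive")
  if (n_heads > d_model)
    stop("n_heads (", n_heads, ") must not exceed d_model (", d_model, ")")
  structure(list(T = as.integer(T), C = as.integer(C), K = as.integer(K),
                 d_model = as.integer(d_model), d_ff = as.integer(d_ff),
                 n_heads = as.integer(n_heads),
                 n_layers = as.integer(n_layers),
                 dropout_rate = as.numeric(dropout_rate),
                 attention_dropout_rate = as.numeric(attention_dropout_rate),
                 activation = activation),
            class = "har_model_config")
}

# Truncated normal on [-2 sd, +2 sd] via inverse-CDF sampling.
# Per-head width: floor(d_model / n_heads), as in the usual framework
# multi-head layer; the output projection maps h*d_k back to d_model.
head_dim <- function(d_model, n_heads) d_model %/% n_heads

rtruncnorm2 <- function(n, sd = 0.02) {
  lo <- stats::pnorm(-2); hi <- stats::pnorm(2)
  stats::qnorm(lo + stats::runif(n) * (hi - lo)) * sd
}

tn_mat <- function(nr, nc, sd = 0.02) matrix(rtruncnorm2(nr * nc, sd), nr, nc)

#' Channel standardization state
#'
#' Stores the per-channel mean and standard deviation estimated from the
#' training data; the same calibration is applied unchanged at inference.
#'
#' @param mean,std Length-C numeric vectors.
#' @param epsilon Small positive guard added to `std` (keeps constant
#'   channels from dividing by zero).
#' @return A list of class `normalizer_state`.
#' @export
normalizer_state <- function(mean, std, epsilon = 1e-6) {
  stopifnot(length(mean) == length(std), all(std >= 0), epsilon > 0)
  structure(list(mean = as.numeric(mean), std = as.numeric(std),
                 epsilon = epsilon),
            class = "normalizer_state")
}

#' Fit the channel normalizer on training data
#'
#' Pools every timestep of every training window and computes the
#' per-channel mean and (population) standard deviation.
#'
#' @param train A non-empty [window_dataset()].
#' @param epsilon Guard added to the standard deviation when applying.
#' @return A [normalizer_state()].
#' @export
fit_normalizer <- function(train, epsilon = 1e-6) {
  if (!length(train$windows)) stop("cannot fit a normalizer on an empty dataset")
  pooled <- do.call(rbind, lapply(train$windows, `[[`, "values"))
  mu <- colMeans(pooled)
  sdv <- sqrt(colMeans(sweep(pooled, 2L, mu)^2))
  normalizer_state(mu, sdv, epsilon)
}

#' Apply a fitted normalizer
#'
#' `out[t, c] = (in[t, c] - mean_c) / (std_c + epsilon)`.
#'
#' @param state A [normalizer_state()].
#' @param window A [signal_window()] or a plain T x C matrix.
#' @return A T x C numeric matrix.
#' @export
apply_normalizer <- function(state, window) {
  x <- if (inherits(window, "signal_window")) window$values else as.matrix(window)
  if (ncol(x) != length(state$mean))
    stop("channel count mismatch: window has ", ncol(x),
         ", normalizer has ", length(state$mean))
  sweep(sweep(x, 2L, state$mean), 2L, state$std + state$epsilon, "/")
}

#' Initialize model parameters
#'
#' All dense weights and the position embedding are drawn from a normal
#' distribution with standard deviation 0.02 truncated at +/- 2 sd;
#' biases start at 0, layer-norm gains at 1.
#'
#' @param config A [model_config()].
#' @param seed Integer seed; the same seed gives bit-identical parameters.
#' @return A nested list of class `har_params` holding `normalizer`
#'   (identity until [fit_normalizer()] output is attached), `Win`/`bin`
#'   (input projection), `P` (T x d_model position embedding), `blocks`
#'   (per encoder block: two layer norms, query/key/value/output
#'   projections, feed-forward weights), `lnf_g`/`lnf_b` (final layer
#'   norm) and `Wh`/`bh` (per-timestep classification head).
#' @export
init_params <- function(config, seed = 1L) {
  rng <- local_rng(seed)
  d <- config$d_model
  hd <- head_dim(d, config$n_heads) * config$n_heads
  draw <- function(nr, nc) matrix(rng$with(rtruncnorm2(nr * nc)), nr, nc)
  blocks <- lapply(seq_len(config$n_layers), function(l) {
    list(
      ln1_g = rep(1, d), ln1_b = rep(0, d),
      Wq = draw(d, hd), bq = rep(0, hd),
      Wk = draw(d, hd), bk = rep(0, hd),
      Wv = draw(d, hd), bv = rep(0, hd),
      Wo = draw(hd, d), bo = rep(0, d),
      ln2_g = rep(1, d), ln2_b = rep(0, d),
      W1 = draw(d, config$d_ff), b1 = rep(0, config$d_ff),
      W2 = draw(config$d_ff, d), b2 = rep(0, d)
    )
  })
  structure(list(
    normalizer = normalizer_state(rep(0, config$C), rep(1, config$C),
                                  epsilon = 1e-6),
    Win = draw(config$C, d), bin = rep(0, d),
    P = draw(config$T, d),
    blocks = blocks,
    lnf_g = rep(1, d), lnf_b = rep(0, d),
    Wh = draw(d, config$K), bh = rep(0, config$K)
  ), class = "har_params")
}

#' Count the scalar learnable parameters
#'
#' The normalizer calibration is excluded: it is estimated from data but
#' not updated by gradient descent.
#'
#' @param params A `har_params` object.
#' @return Integer count.
#' @export
count_parameters <- function(params) {
  sum(vapply(unlist(learnable_tree(params), recursive = TRUE,
                    use.names = FALSE), length, integer(1)))
}

learnable_tree <- function(params) params[setdiff(names(params), "normalizer")]

row_softmax <- function(S) {
  E <- exp(S - apply(S, 1L, max))
  E / rowSums(E)
}

gelu <- function(x) x * stats::pnorm(x)
gelu_grad <- function(x) stats::pnorm(x) + x * stats::dnorm(x)

layer_norm <- function(x, g, b, eps = 1e-6) {
  mu <- rowMeans(x)
  xc <- x - mu
  inv <- 1 / sqrt(rowMeans(xc^2) + eps)
  xhat <- xc * inv
  sweep(xhat, 2L, g, "*") + rep(b, each = nrow(x))
}

#' Scaled dot-product attention
#'
#' `weights = softmax(Q K' / sqrt(d_k))` row-wise; `output = weights V`.
#'
#' @param Q,K,V Numeric matrices; `Q` and `K` share their column dimension
#'   `d_k`, `K` and `V` share their row count.
#' @return A list with `output` (nrow(Q) x ncol(V)) and `weights`
#'   (nrow(Q) x nrow(K), each row summing to 1).
#' @export
scaled_dot_product_attention <- function(Q, K, V) {
  Q <- as.matrix(Q); K <- as.matrix(K); V <- as.matrix(V)
  if (ncol(Q) != ncol(K)) stop("Q and K must share d_k")
  if (nrow(K) != nrow(V)) stop("K and V must have the same length")
  A <- row_softmax(tcrossprod(Q, K) / sqrt(ncol(Q)))
  list(output = A %*% V, weights = A)
}

#' Multi-head self-attention
#'
#' Each head projects the input with its own query/key/value maps (stored
#' as column blocks of `Wq`/`Wk`/`Wv`), applies scaled dot-product
#' attention, and the concatenated head outputs are mixed by `Wo`.
#' Dropout is applied to the attention weights only when `training`.
#'
#' @param x T x d_model input matrix.
#' @param params List with `Wq`, `bq`, `Wk`, `bk`, `Wv`, `bv`, `Wo`, `bo`.
#' @param n_heads Number of heads (d_model must be divisible by it).
#' @param attention_dropout Dropout rate on the attention weights.
#' @param training Logical; enables attention dropout.
#' @param rng Internal seeded generator (required when `training`).
#' @return List with `output` (T x d_model) and `records` — one
#'   `attention_record` (layer/head/matrix) per head.
#' @export
multi_head_attention <- function(x, params, n_heads,
                                 attention_dropout = 0, training = FALSE,
                                 rng = NULL) {
  d <- ncol(x)
  if (n_heads > d)
    stop("n_heads (", n_heads, ") must not exceed d_model (", d, ")")
  dk <- head_dim(d, n_heads)
  Q <- x %*% params$Wq + rep(params$bq, each = nrow(x))
  K <- x %*% params$Wk + rep(params$bk, each = nrow(x))
  V <- x %*% params$Wv + rep(params$bv, each = nrow(x))
  O <- matrix(0, nrow(x), n_heads * dk)
  records <- vector("list", n_heads)
  for (i in seq_len(n_heads)) {
    cols <- (i - 1L) * dk + seq_len(dk)
    att <- scaled_dot_product_attention(Q[, cols, drop = FALSE],
                                        K[, cols, drop = FALSE],
                                        V[, cols, drop = FALSE])
    A <- att$weights
    records[[i]] <- structure(list(head = i, matrix = A),
                              class = "attention_record")
    if (training && attention_dropout > 0) {
      mask <- matrix(rng$rbern(length(A), 1 - attention_dropout),
                     nrow(A), ncol(A)) / (1 - attention_dropout)
      A <- A * mask
    }
    O[, cols] <- A %*% V[, cols, drop = FALSE]
  }
  list(output = O %*% params$Wo + rep(params$bo, each = nrow(x)),
       records = records)
}

#' Position-wise feed-forward network
#'
#' `out = act(x W1 + b1) W2 + b2`, applied independently at each timestep.
#'
#' @param x T x d_model matrix.
#' @param params List with `W1`, `b1`, `W2`, `b2`.
#' @param activation `"gelu"` or `"relu"`.
#' @return T x d_model matrix.
#' @export
position_wise_ffn <- function(x, params, activation = "gelu") {
  z <- x %*% params$W1 + rep(params$b1, each = nrow(x))
  a <- if (activation == "relu") pmax(z, 0) else gelu(z)
  a %*% params$W2 + rep(params$b2, each = nrow(x))
}

#' Pre-norm transformer encoder block
#'
#' `u = x + Dropout(MHA(LN(x)))`; `y = u + Dropout(FFN(LN(u)))` — layer
#' normalization before each sublayer, residual connection after.
#'
#' @param x T x d_model input.
#' @param block Parameter list for one block (see [init_params()]).
#' @param config A [model_config()].
#' @param training Logical; enables dropout.
#' @param rng Internal seeded generator (required when `training`).
#' @return List with `output` (T x d_model) and `records` (per-head
#'   attention records).
#' @export
encoder_block <- function(x, block, config, training = FALSE, rng = NULL) {
  site_drop <- function(m) {
    if (training && config$dropout_rate > 0) {
      mask <- matrix(rng$rbern(length(m), 1 - config$dropout_rate),
                     nrow(m), ncol(m)) / (1 - config$dropout_rate)
      m * mask
    } else m
  }
  mha <- multi_head_attention(layer_norm(x, block$ln1_g, block$ln1_b),
                              block, config$n_heads,
                              config$attention_dropout_rate, training, rng)
  u <- x + site_drop(mha$output)
  f <- position_wise_ffn(layer_norm(u, block$ln2_g, block$ln2_b), block,
                         config$activation)
  list(output = u + site_drop(f), records = mha$records)
}

#' Forward pass of the activity-recognition transformer
#'
#' Pipeline: channel standardization, per-timestep input projection
#' (C to d_model), addition of the learned position embedding, dropout,
#' `n_layers` pre-norm encoder blocks, a final layer norm, and a linear
#' per-timestep head. Logits are raw scores (no softmax).
#'
#' @param window A [signal_window()] or T x C matrix.
#' @param params A `har_params` object.
#' @param config The matching [model_config()].
#' @param training Logical; enables dropout (the map is deterministic when
#'   `FALSE`).
#' @param rng Internal seeded generator (required when `training`).
#' @return List with `logits` (T x K) and `records`, a list of
#'   `attention_record`s with fields `layer`, `head`, `matrix` (T x T).
#' @export
har_forward <- function(window, params, config, training = FALSE,
                        rng = NULL) {
  x <- apply_normalizer(params$normalizer, window)
  if (nrow(x) != config$T || ncol(x) != config$C)
    stop("window shape ", nrow(x), " x ", ncol(x),
         " does not match config ", config$T, " x ", config$C)
  h <- x %*% params$Win + rep(params$bin, each = config$T)
  h <- h + params$P
  if (training && config$dropout_rate > 0) {
    mask <- matrix(rng$rbern(length(h), 1 - config$dropout_rate),
                   nrow(h), ncol(h)) / (1 - config$dropout_rate)
    h <- h * mask
  }
  records <- list()
  for (l in seq_len(config$n_layers)) {
    blk <- encoder_block(h, params$blocks[[l]], config, training, rng)
    h <- blk$output
    for (r in blk$records) {
      r$layer <- l
      records[[length(records) + 1L]] <- r
    }
  }
  h <- layer_norm(h, params$lnf_g, params$lnf_b)
  list(logits = h %*% params$Wh + rep(params$bh, each = config$T),
       records = records)
}

#' Save / load a parameter checkpoint
#'
#' Parameters are serialized with R's portable binary serialization and a
#' JSON sidecar (`<path>.json`) records the model configuration; the
#' round trip is bit-exact.
#'
#' @param params A `har_params` object.
#' @param config The matching [model_config()].
#' @param path Checkpoint file path.
#' @return `path`, invisibly (for `save_checkpoint`); a list with
#'   `params` and `config` (for `load_checkpoint`).
#' @export
save_checkpoint <- function(params, config, path) {
  saveRDS(params, path, version = 3)
  jsonlite::write_json(unclass(config), paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stop("checkpoint not found: ", path)
  cfgfile <- paste0(path, ".json")
  if (!file.exists(cfgfile)) stop("checkpoint sidecar not found: ", cfgfile)
  cfg <- jsonlite::read_json(cfgfile, simplifyVector = TRUE)
  list(params = readRDS(path), config = do.call(model_config, cfg))
}
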