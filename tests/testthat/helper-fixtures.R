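# Shared fixtures. The trained demo pipeline is expensive (~2 min) and is
# built lazily, once per test run.

tiny_config <- function(...) {
  args <- utils::modifyList(
    list(T = 6L, C = 2L, K = 3L, d_model = 4L, d_ff = 8L, n_heads = 2L,
         n_layers = 2L, dropout_rate = 0, attention_dropout_rate = 0),
    list(...))
  do.call(model_config, args)
}

random_window <- function(T = 6L, C = 2L, K = 3L, seed = 1L, id = "w") {
  set.seed(seed)
  signal_window(matrix(rnorm(T * C), T, C), sample(0:(K - 1L), T, TRUE), id)
}

# Small single-label dataset: `counts[k]` windows of class k-1, values
# deterministic per window.
toy_dataset <- function(counts, T = 4L, C = 2L, seed = 1L) {
  set.seed(seed)
  windows <- list()
  for (k in seq_along(counts))
    for (i in seq_len(counts[k]))
      windows[[length(windows) + 1L]] <-
        signal_window(matrix(rnorm(T * C, mean = k), T, C), k - 1L,
                      sprintf("c%d-%d", k - 1L, i))
  window_dataset(windows,
                 activity_manifest(paste0("class", seq_along(counts) - 1L),
                                   counts))
}

# Straight-line nested-loop attention oracle (independent of the package
# implementation path).
oracle_attention <- function(Q, K, V) {
  Tq <- nrow(Q); Tk <- nrow(K); dk <- ncol(Q)
  W <- matrix(0, Tq, Tk)
  for (i in seq_len(Tq)) {
    s <- numeric(Tk)
    for (j in seq_len(Tk)) s[j] <- sum(Q[i, ] * K[j, ]) / sqrt(dk)
    e <- exp(s - max(s))
    W[i, ] <- e / sum(e)
  }
  out <- matrix(0, Tq, ncol(V))
  for (i in seq_len(Tq))
    for (c in seq_len(ncol(V)))
      out[i, c] <- sum(W[i, ] * V[, c])
  list(output = out, weights = W)
}

demo_cache <- new.env(parent = emptyenv())

# Desk-scale end-to-end pipeline: synthetic generation, pair
# augmentation, stratified split, training of a small model.
get_demo <- function() {
  if (!is.null(demo_cache$fit)) return(as.list(demo_cache))
  ds <- generate_dataset(synth_preset("desk"))
  cls <- ds$manifest$name
  pairs <- expand.grid(first = cls, second = cls,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$first != pairs$second, ]
  rules <- pair_rules(pairs$first, pairs$second)
  plan <- plan_counts(rules, ds$manifest)
  aug <- build_augmented_dataset(ds, plan, seed = 2)
  parts <- stratified_split(aug, seed = 3)
  config <- model_config(T = 50L, C = 6L, K = 4L, d_model = 32L,
                         d_ff = 64L, n_heads = 2L, n_layers = 2L)
  fit <- har_transformer(parts$train, parts$validation, config = config,
                         tconfig = train_config(epochs = 8L,
                                                batch_size = 64L,
                                                seed = 4L),
                         seed = 5L)
  demo_cache$dataset <- ds
  demo_cache$rules <- rules
  demo_cache$plan <- plan
  demo_cache$augmented <- aug
  demo_cache$parts <- parts
  demo_cache$config <- config
  demo_cache$fit <- fit
  as.list(demo_cache)
}
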