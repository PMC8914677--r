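#' Training configuration
#'
#' Defaults follow the reference recipe: 50 epochs, batch size 64, Adam
#' with a linear warmup over 10 update steps to a 0.001 peak followed by
#' cosine decay to zero, global gradient-norm clipping at 3.0, and label
#' smoothing 0.1.
#'
#' @param epochs Number of passes over the training set.
#' @param batch_size Windows per update step.
#' @param max_lr Peak learning rate reached after warmup.
#' @param warmup_steps Optimizer update steps of linear warmup.
#' @param global_clipnorm Global gradient-norm ceiling.
#' @param label_smoothing Smoothing mass spread over all classes.
#' @param adam_beta1,adam_beta2,adam_epsilon Adam moment decay rates and
#'   denominator guard (canonical defaults).
#' @param seed Integer seed for shuffling and dropout.
#' @return A list of class `har_train_config`.
#' @export
train_config <- function(epochs = 50L, batch_size = 64L, max_lr = 1e-3,
                         warmup_steps = 10L, global_clipnorm = 3.0,
                         label_smoothing = 0.1, adam_beta1 = 0.9,
                         adam_beta2 = 0.999, adam_epsilon = 1e-8,
                         seed = 1L) {
  stopifnot(epochs >= 0, batch_size >= 1, max_lr > 0, warmup_steps >= 0,
            global_clipnorm > 0, label_smoothing >= 0, label_smoothing < 1)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), max_lr = max_lr,
                 warmup_steps = as.integer(warmup_steps),
                 global_clipnorm = global_clipnorm,
                 label_smoothing = label_smoothing,
                 adam_beta1 = adam_beta1, adam_beta2 = adam_beta2,
                 adam_epsilon = adam_epsilon, seed = as.integer(seed)),
            class = "har_train_config")
}

#' Warmup-cosine learning rate
#'
#' Linear ramp from 0 to `max_lr` over `warmup_steps`, then cosine decay
#' `max_lr * 0.5 * (1 + cos(pi * (step - w) / (total - w)))` reaching 0 at
#' `total_steps`.
#'
#' @param step Update step, `0 <= step <= total_steps`.
#' @param config A [train_config()].
#' @param total_steps Total number of update steps in the run
#'   (`warmup_steps < total_steps`).
#' @return The learning rate at `step`.
#' @export
lr_at_step <- function(step, config, total_steps) {
  w <- config$warmup_steps
  if (any(step < 0 | step > total_steps)) stop("step outside 0..total_steps")
  if (w >= total_steps) stop("warmup_steps must be below total_steps")
  ifelse(step < w,
         config$max_lr * step / w,
         config$max_lr * 0.5 * (1 + cos(pi * (step - w) / (total_steps - w))))
}

#' Label-smoothed per-timestep cross-entropy
#'
#' Each timestep's target distribution is
#' `(1 - smoothing) * onehot + smoothing / K`; the loss is the mean over
#' timesteps of the cross-entropy against log-softmax logits.
#'
#' @param logits T x K matrix of raw scores.
#' @param labels Length-T integer vector of 0-based classes.
#' @param smoothing Smoothing mass in `[0, 1)`.
#' @return Scalar loss.
#' @export
smoothed_cross_entropy <- function(logits, labels, smoothing = 0.1) {
  ce_loss_grad(as.matrix(logits), as.integer(labels), smoothing)$loss
}

#' Per-timestep classification accuracy
#'
#' Fraction of timesteps whose argmax logit matches the label; argmax ties
#' break toward the lowest class index.
#'
#' @param logits T x K matrix (or stacked (B*T) x K).
#' @param labels Integer vector of 0-based classes, length nrow(logits).
#' @return Fraction in `[0, 1]`.
#' @export
per_timestep_accuracy <- function(logits, labels) {
  pred <- max.col(as.matrix(logits), ties.method = "first") - 1L
  mean(pred == as.integer(labels))
}

clip_global_norm <- function(grads, clipnorm) {
  gn <- sqrt(tree_sumsq(grads))
  if (is.finite(gn) && gn > clipnorm)
    grads <- tree_map(function(x) x * (clipnorm / gn), grads)
  list(grads = grads, norm = min(gn, clipnorm))
}

adam_init <- function(params) {
  zeros <- tree_map(function(x) x * 0, learnable_tree(params))
  list(m = zeros, v = zeros, t = 0L)
}

adam_step <- function(params, grads, state, lr, cfg) {
  state$t <- state$t + 1L
  state$m <- tree_map2(function(m, g) cfg$adam_beta1 * m + (1 - cfg$adam_beta1) * g,
                       state$m, grads)
  state$v <- tree_map2(function(v, g) cfg$adam_beta2 * v + (1 - cfg$adam_beta2) * g^2,
                       state$v, grads)
  bc1 <- 1 - cfg$adam_beta1^state$t
  bc2 <- 1 - cfg$adam_beta2^state$t
  upd <- tree_map2(function(m, v) lr * (m / bc1) / (sqrt(v / bc2) + cfg$adam_epsilon),
                   state$m, state$v)
  learn <- tree_map2(`-`, learnable_tree(params), upd)
  params[names(learn)] <- learn
  list(params = params, state = state)
}

# Stacked forward over a dataset in evaluation batches.
predict_logits <- function(params, config, dataset, batch_size = 64L) {
  n <- length(dataset$windows)
  out_logits <- vector("list", ceiling(n / batch_size))
  labels <- vector("list", length(out_logits))
  for (b in seq_along(out_logits)) {
    idx <- ((b - 1L) * batch_size + 1L):min(b * batch_size, n)
    st <- stack_batch(dataset$windows[idx], params$normalizer)
    out_logits[[b]] <- engine_forward(params, config, st$X)$logits
    labels[[b]] <- st$labels
  }
  list(logits = do.call(rbind, out_logits),
       labels = unlist(labels, use.names = FALSE))
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  set.seed(as.integer(seed))
  on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
          else assign(".Random.seed", old, globalenv()))
  expr
}

#' Train the transformer
#'
#' Runs the full recipe: seeded minibatch shuffling, warmup-cosine
#' learning rate, label-smoothed per-timestep cross-entropy, global
#' gradient-norm clipping before every Adam step, and per-epoch validation
#' accuracy with best-checkpoint tracking. The channel normalizer is
#' fitted on the training split before the first update and stored inside
#' the parameters.
#'
#' @param params Initial `har_params` (from [init_params()]).
#' @param train,validation [window_dataset()]s.
#' @param config A [model_config()].
#' @param tconfig A [train_config()].
#' @param log_path Optional path; per-epoch metrics are appended as CSV.
#' @param quiet Suppress per-epoch console logging.
#' @return A list of class `har_train_state`: `best_params` (parameters at
#'   the best validation accuracy), `best_validation_accuracy`,
#'   `best_epoch`, `history` (data.frame epoch/train_loss/
#'   val_accuracy/best_val_accuracy), `grad_norms` (post-clip global norm
#'   per step), `final_params`.
#' @export
har_train <- function(params, train, validation, config, tconfig,
                      log_path = NULL, quiet = TRUE) {
  if (!length(train$windows)) stop("empty training dataset")
  if (!length(validation$windows)) stop("empty validation dataset")
  params$normalizer <- fit_normalizer(train)
  if (tconfig$epochs == 0L)
    return(structure(list(best_params = params,
                          best_validation_accuracy = NA_real_,
                          best_epoch = NA_integer_,
                          history = data.frame(), grad_norms = numeric(0),
                          final_params = params),
                     class = "har_train_state"))
  n <- length(train$windows)
  steps_per_epoch <- ceiling(n / tconfig$batch_size)
  total_steps <- tconfig$epochs * steps_per_epoch
  # runs shorter than the warmup keep a valid (all-ramp) schedule
  tconfig$warmup_steps <- min(tconfig$warmup_steps, total_steps - 1L)
  opt <- adam_init(params)
  best_acc <- -Inf; best_params <- params; best_epoch <- NA_integer_
  hist <- vector("list", tconfig$epochs)
  grad_norms <- numeric(total_steps)
  step <- 0L
  with_seed(tconfig$seed, {
    for (epoch in seq_len(tconfig$epochs)) {
      ord <- sample.int(n)
      losses <- numeric(steps_per_epoch)
      for (b in seq_len(steps_per_epoch)) {
        idx <- ord[((b - 1L) * tconfig$batch_size + 1L):
                     min(b * tconfig$batch_size, n)]
        st <- stack_batch(train$windows[idx], params$normalizer)
        lg <- engine_loss_grads(params, config, st$X, st$labels,
                                tconfig$label_smoothing, training = TRUE)
        if (!is.finite(lg$loss))
          stop("divergent loss (", lg$loss, ") at epoch ", epoch,
               ", step ", step, "; lower the learning rate or check inputs")
        cl <- clip_global_norm(lg$grads, tconfig$global_clipnorm)
        step <- step + 1L
        grad_norms[step] <- cl$norm
        lr <- lr_at_step(step, tconfig, total_steps)
        up <- adam_step(params, cl$grads, opt, lr, tconfig)
        params <- up$params; opt <- up$state
        losses[b] <- lg$loss
      }
      pv <- predict_logits(params, config, validation, tconfig$batch_size)
      acc <- per_timestep_accuracy(pv$logits, pv$labels)
      if (acc > best_acc) {
        best_acc <- acc; best_params <- params; best_epoch <- epoch
      }
      hist[[epoch]] <- data.frame(epoch = epoch,
                                  train_loss = mean(losses),
                                  val_accuracy = acc,
                                  best_val_accuracy = best_acc)
      if (!quiet)
        message(sprintf("epoch %d/%d  loss %.4f  val acc %.4f (best %.4f)",
                        epoch, tconfig$epochs, mean(losses), acc, best_acc))
    }
  })
  history <- do.call(rbind, hist)
  if (!is.null(log_path))
    utils::write.csv(history, log_path, row.names = FALSE)
  structure(list(best_params = best_params,
                 best_validation_accuracy = best_acc,
                 best_epoch = best_epoch, history = history,
                 grad_norms = grad_norms, final_params = params),
            class = "har_train_state")
}

#' @export
print.har_train_state <- function(x, ...) {
  cat("har_train_state:", nrow(x$history), "epochs, best validation",
      "accuracy", round(x$best_validation_accuracy, 4), "at epoch",
      x$best_epoch, "\n")
  invisible(x)
}
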