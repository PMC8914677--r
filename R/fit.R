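#' Fit an activity-recognition transformer
#'
#' High-level fitting interface in the usual R modelling style: give it a
#' training and a validation [window_dataset()] and it initializes the
#' parameters, fits the channel normalizer, runs the training recipe and
#' returns a fitted-model object carrying the best-validation checkpoint.
#'
#' @param train,validation [window_dataset()]s (e.g. from
#'   [stratified_split()]).
#' @param config A [model_config()]; defaults to the reference
#'   architecture sized to the data (`T`, `C`, `K` taken from `train`).
#' @param tconfig A [train_config()].
#' @param seed Integer seed used for parameter initialization (training
#'   randomness is governed by `tconfig$seed`).
#' @param quiet Suppress per-epoch logging.
#' @return An object of class `har_transformer` with components `params`
#'   (best checkpoint), `config`, `tconfig`, `state` (the full
#'   [har_train()] result) and `n_parameters`.
#' @examples
#' \donttest{
#' ds <- generate_dataset(synth_preset("desk", windows_per_class = 12))
#' parts <- stratified_split(ds, seed = 1)
#' fit <- har_transformer(parts$train, parts$validation,
#'                        config = model_config(T = 50, C = 6, K = 4,
#'                                              d_model = 16, d_ff = 32,
#'                                              n_heads = 2, n_layers = 1),
#'                        tconfig = train_config(epochs = 2, batch_size = 16))
#' predict(fit, parts$test)[1, 1:5]
#' }
#' @export
har_transformer <- function(train, validation,
                            config = NULL, tconfig = train_config(),
                            seed = 1L, quiet = TRUE) {
  if (is.null(config))
    config <- model_config(T = dataset_T(train), C = dataset_C(train),
                           K = nrow(train$manifest))
  params <- init_params(config, seed = seed)
  state <- har_train(params, train, validation, config, tconfig,
                     quiet = quiet)
  structure(list(params = state$best_params, config = config,
                 tconfig = tconfig, state = state,
                 n_parameters = count_parameters(state$best_params),
                 manifest = train$manifest),
            class = "har_transformer")
}

#' @export
print.har_transformer <- function(x, ...) {
  cat("Activity-recognition transformer\n")
  cat(sprintf("  %d encoder blocks, %d heads, d_model %d, d_ff %d (%s)\n",
              x$config$n_layers, x$config$n_heads, x$config$d_model,
              x$config$d_ff, x$config$activation))
  cat(sprintf("  window %d x %d -> %d classes; %d learnable parameters\n",
              x$config$T, x$config$C, x$config$K, x$n_parameters))
  if (is.finite(x$state$best_validation_accuracy))
    cat(sprintf("  best validation accuracy %.4f (epoch %d/%d)\n",
                x$state$best_validation_accuracy, x$state$best_epoch,
                nrow(x$state$history)))
  invisible(x)
}

#' @export
summary.har_transformer <- function(object, ...) {
  out <- list(config = object$config, tconfig = object$tconfig,
              n_parameters = object$n_parameters,
              history = object$state$history,
              best_validation_accuracy = object$state$best_validation_accuracy,
              best_epoch = object$state$best_epoch)
  class(out) <- "summary.har_transformer"
  out
}

#' @export
print.summary.har_transformer <- function(x, ...) {
  cat("Activity-recognition transformer -- training summary\n")
  cat(sprintf("  learnable parameters: %d\n", x$n_parameters))
  if (nrow(x$history)) {
    cat(sprintf("  epochs: %d; best validation accuracy %.4f at epoch %d\n",
                nrow(x$history), x$best_validation_accuracy, x$best_epoch))
    utils::tail(x$history, 5L) |> print(row.names = FALSE)
  }
  invisible(x)
}

#' Predict per-timestep activity classes
#'
#' @param object A fitted `har_transformer`.
#' @param newdata A [window_dataset()] or a single [signal_window()].
#' @param type `"class"` for 0-based predicted class ids, `"logits"` for
#'   raw scores, `"prob"` for softmax probabilities.
#' @param ... Unused.
#' @return For `"class"`: an n_windows x T integer matrix. Otherwise a
#'   list of T x K matrices, one per window.
#' @export
predict.har_transformer <- function(object, newdata,
                                    type = c("class", "logits", "prob"),
                                    ...) {
  type <- match.arg(type)
  if (inherits(newdata, "signal_window"))
    newdata <- window_dataset(list(newdata), object$manifest)
  pl <- predict_logits(object$params, object$config, newdata)
  T <- object$config$T
  n <- length(newdata$windows)
  if (type == "class") {
    pred <- max.col(pl$logits, ties.method = "first") - 1L
    return(matrix(pred, nrow = n, ncol = T, byrow = TRUE))
  }
  out <- vector("list", n)
  for (i in seq_len(n)) {
    m <- pl$logits[(i - 1L) * T + seq_len(T), , drop = FALSE]
    out[[i]] <- if (type == "prob") row_softmax(m) else m
  }
  out
}

#' Plot training history
#'
#' Training loss and validation accuracy against epoch.
#'
#' @param x A fitted `har_transformer`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.har_transformer <- function(x, ...) {
  h <- x$state$history
  if (!nrow(h)) stop("no training history to plot")
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::plot(h$epoch, h$train_loss, type = "l", xlab = "epoch",
                 ylab = "training loss", ...)
  graphics::plot(h$epoch, h$val_accuracy, type = "l", xlab = "epoch",
                 ylab = "validation accuracy", ylim = c(0, 1), ...)
  graphics::lines(h$epoch, h$best_val_accuracy, lty = 2)
  invisible(x)
}
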