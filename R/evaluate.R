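#' Confusion matrix over per-timestep predictions
#'
#' @param predictions,labels Integer vectors of 0-based classes, equal
#'   length.
#' @param K Number of classes.
#' @return K x K integer matrix; entry (i, j) counts timesteps with true
#'   class i-1 predicted as j-1. Rows are true classes, columns predicted.
#' @export
confusion_matrix <- function(predictions, labels, K) {
  predictions <- as.integer(predictions); labels <- as.integer(labels)
  if (length(predictions) != length(labels))
    stop("predictions and labels must have equal length")
  if (any(c(predictions, labels) < 0L) || any(c(predictions, labels) >= K))
    stop("class out of range 0..", K - 1L)
  m <- matrix(0L, K, K)
  tab <- table(factor(labels, levels = 0:(K - 1L)),
               factor(predictions, levels = 0:(K - 1L)))
  m[] <- as.integer(tab)
  dimnames(m) <- list(true = 0:(K - 1L), predicted = 0:(K - 1L))
  m
}

#' Class-wise precision, recall, F1 and support
#'
#' `precision_k = diag_k / colsum_k`, `recall_k = diag_k / rowsum_k`, F1
#' their harmonic mean; a zero denominator yields 0 with a warning.
#' Support is the row sum (true instances, counted per timestep).
#'
#' @param confusion K x K non-negative count matrix (rows true, columns
#'   predicted).
#' @return data.frame with columns `class_id`, `precision`, `recall`,
#'   `f1`, `support`.
#' @export
classwise_metrics <- function(confusion) {
  confusion <- as.matrix(confusion)
  K <- nrow(confusion)
  d <- diag(confusion)
  cs <- colSums(confusion); rs <- rowSums(confusion)
  if (any(cs == 0) || any(rs == 0))
    warning("zero-denominator precision/recall reported as 0 for class(es): ",
            paste(sort(unique(c(which(cs == 0), which(rs == 0)))) - 1L,
                  collapse = ", "))
  precision <- ifelse(cs > 0, d / cs, 0)
  recall <- ifelse(rs > 0, d / rs, 0)
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  data.frame(class_id = 0:(K - 1L), precision = precision, recall = recall,
             f1 = f1, support = as.integer(rs), row.names = NULL)
}

#' Evaluate a fitted model on a dataset
#'
#' Produces the timestep-level evaluation report: confusion matrix,
#' class-wise precision/recall/F1/support, overall per-timestep accuracy,
#' and a secondary window-level accuracy by majority vote over each
#' window's predicted timesteps.
#'
#' @param fit A `har_transformer` (or a list with `params` and `config`).
#' @param dataset A [window_dataset()].
#' @return A list of class `har_eval_report`.
#' @export
evaluate_model <- function(fit, dataset) {
  pl <- predict_logits(fit$params, fit$config, dataset)
  pred <- max.col(pl$logits, ties.method = "first") - 1L
  K <- fit$config$K
  conf <- confusion_matrix(pred, pl$labels, K)
  T <- fit$config$T
  n <- length(dataset$windows)
  majority <- function(v) as.integer(names(which.max(table(v))))
  win_pred <- vapply(seq_len(n), function(i)
    majority(pred[(i - 1L) * T + seq_len(T)]), integer(1))
  win_true <- vapply(dataset$windows, function(w) majority(w$labels),
                     integer(1))
  structure(list(
    confusion = conf,
    metrics = suppressWarnings(classwise_metrics(conf)),
    accuracy = mean(pred == pl$labels),
    window_accuracy = mean(win_pred == win_true),
    n_timesteps = length(pred),
    n_windows = n
  ), class = "har_eval_report")
}

#' @export
print.har_eval_report <- function(x, ...) {
  cat(sprintf("Evaluation over %d windows (%d timesteps)\n", x$n_windows,
              x$n_timesteps))
  cat(sprintf("  per-timestep accuracy: %.4f\n", x$accuracy))
  cat(sprintf("  window-majority accuracy: %.4f\n", x$window_accuracy))
  print(x$metrics, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Serialize an evaluation report to JSON
#'
#' @param report A `har_eval_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_eval_report_json <- function(report, path) {
  jsonlite::write_json(
    list(accuracy = report$accuracy,
         window_accuracy = report$window_accuracy,
         n_timesteps = report$n_timesteps,
         n_windows = report$n_windows,
         confusion = unname(as.matrix(report$confusion)),
         metrics = report$metrics),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Extract an attention heatmap
#'
#' Returns the recorded T x T attention matrix of one layer/head
#' unmodified, optionally rendering it to PNG with higher weights mapped
#' to paler intensity.
#'
#' @param records Attention records from [har_forward()].
#' @param layer,head 1-based layer and head indices.
#' @param png_path Optional path; when given, the heatmap is rendered.
#' @return The T x T attention matrix.
#' @export
attention_heatmap <- function(records, layer, head, png_path = NULL) {
  hit <- Filter(function(r) r$layer == layer && r$head == head, records)
  if (!length(hit))
    stop("no attention record for layer ", layer, ", head ", head)
  m <- hit[[1L]]$matrix
  if (!is.null(png_path)) {
    grDevices::png(png_path, width = 600, height = 600)
    on.exit(grDevices::dev.off())
    graphics::image(t(m)[, nrow(m):1], col = grDevices::gray.colors(256),
                    axes = FALSE,
                    main = sprintf("attention layer %d head %d", layer, head))
  }
  m
}

#' Cosine similarity of position-embedding rows
#'
#' @param P T x d matrix of learned position embeddings. All-zero rows get
#'   similarity 0 with a warning.
#' @return T x T symmetric matrix of class `position_similarity` with unit
#'   diagonal (for nonzero rows), entries in `[-1, 1]`.
#' @export
position_embedding_similarity <- function(P) {
  P <- as.matrix(P)
  nrm <- sqrt(rowSums(P^2))
  zero <- nrm == 0
  if (any(zero)) {
    warning("all-zero position-embedding row(s): similarity reported as 0")
    nrm[zero] <- 1
  }
  S <- tcrossprod(P / nrm)
  S[zero, ] <- 0; S[, zero] <- 0
  S <- (S + t(S)) / 2           # kill asymmetric rounding residue
  d <- diag(S); d[!zero] <- 1; diag(S) <- d
  structure(S, class = c("position_similarity", "matrix"))
}

#' Within-half versus cross-half attention mass
#'
#' For two-activity windows built by pair augmentation the label changes
#' at T/2; a model that has learned this structure concentrates attention
#' inside each half. The statistic is the ratio of the mean attention
#' weight inside the two diagonal T/2 x T/2 blocks to the mean weight in
#' the off-diagonal blocks; about 1 for an untrained (near-uniform)
#' attention map, above 1 for half-window block structure.
#'
#' @param A T x T attention matrix (rows sum to 1), or a list of
#'   attention records whose matrices are averaged.
#' @return List with `within`, `cross` (mean masses) and `ratio`.
#' @export
attention_block_mass <- function(A) {
  if (is.list(A) && !is.matrix(A))
    A <- Reduce(`+`, lapply(A, `[[`, "matrix")) / length(A)
  T <- nrow(A)
  half <- T %/% 2L
  i1 <- seq_len(half); i2 <- (half + 1L):T
  within <- mean(c(A[i1, i1], A[i2, i2]))
  cross <- mean(c(A[i1, i2], A[i2, i1]))
  list(within = within, cross = cross, ratio = within / cross)
}

#' Estimate the label change point of a predicted sequence
#'
#' Fits the best two-segment step function to a per-timestep class
#' sequence: for every cut position the first-segment and second-segment
#' majority classes are compared with the predictions, and the cut with
#' the fewest disagreements wins (earliest cut on ties).
#'
#' @param pred Integer vector of per-timestep predicted classes.
#' @return 0-based index of the first timestep of the second segment.
#' @export
predicted_change_point <- function(pred) {
  T <- length(pred)
  majority <- function(v) as.integer(names(which.max(table(v))))
  best_cut <- 1L; best_err <- Inf
  for (cut in seq_len(T - 1L)) {
    a <- majority(pred[1:cut]); b <- majority(pred[(cut + 1L):T])
    err <- sum(pred[1:cut] != a) + sum(pred[(cut + 1L):T] != b)
    if (err < best_err) { best_err <- err; best_cut <- cut }
  }
  best_cut
}

#' Write a numeric matrix as CSV (for heatmaps/similarity matrices)
#'
#' @param m Numeric matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_matrix_csv <- function(m, path) {
  utils::write.table(as.matrix(m), path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
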