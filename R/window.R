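#' A windowed multichannel signal with per-timestep labels
#'
#' A `signal_window` holds a T x C matrix of sensor values (columns are
#' channels: by convention accelerometer x/y/z in m/s^2 then gyroscope
#' x/y/z in rad/s) together with a length-T integer label track. Windows
#' cut from a single activity have a constant label track; augmented
#' two-activity windows change label at T/2.
#'
#' @param values Numeric T x C matrix, all values finite.
#' @param labels Integer vector of length T (0-based class ids), or a single
#'   class id to broadcast to every timestep.
#' @param window_id Opaque identifier (coerced to character).
#' @return An object of class `signal_window`.
#' @export
signal_window <- function(values, labels, window_id = "w0") {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (!all(is.finite(values)))
    stop("window values must all be finite")
  if (length(labels) == 1L) labels <- rep(labels, nrow(values))
  labels <- as.integer(labels)
  if (length(labels) != nrow(values))
    stop("labels length (", length(labels), ") must equal T (",
         nrow(values), ")")
  if (any(is.na(labels)) || any(labels < 0L))
    stop("labels must be non-negative integers")
  structure(
    list(values = values, labels = labels, window_id = as.character(window_id)),
    class = "signal_window"
  )
}

#' @export
print.signal_window <- function(x, ...) {
  lab <- unique(x$labels)
  cat("signal_window '", x$window_id, "': ", nrow(x$values), " x ",
      ncol(x$values), ", label(s) ", paste(lab, collapse = ","), "\n",
      sep = "")
  invisible(x)
}

window_is_single_label <- function(w) length(unique(w$labels)) == 1L

#' A collection of signal windows with its class manifest
#'
#' @param windows List of [signal_window()] objects, all with the same
#'   dimensions.
#' @param manifest An [activity_manifest()] covering every label used.
#' @param sampling_rate Sampling frequency in Hz (default 100).
#' @return An object of class `window_dataset`.
#' @export
window_dataset <- function(windows, manifest, sampling_rate = 100) {
  stopifnot(is.list(windows))
  validate_manifest(manifest)
  if (length(windows) > 0L) {
    dims <- vapply(windows, function(w) dim(w$values), integer(2))
    if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
      stop("all windows must share the same T x C shape")
    labs <- unique(unlist(lapply(windows, `[[`, "labels")))
    if (length(labs) && any(!labs %in% manifest$class_id))
      stop("labels not present in manifest: ",
           paste(setdiff(labs, manifest$class_id), collapse = ", "))
  }
  structure(
    list(windows = windows, manifest = manifest,
         sampling_rate = sampling_rate),
    class = "window_dataset"
  )
}

#' @export
print.window_dataset <- function(x, ...) {
  cat("window_dataset:", length(x$windows), "windows",
      if (length(x$windows)) paste0("(", nrow(x$windows[[1]]$values), " x ",
                                    ncol(x$windows[[1]]$values), ")"),
      "@", x$sampling_rate, "Hz,", nrow(x$manifest), "classes\n")
  invisible(x)
}

#' @export
length.window_dataset <- function(x) length(x$windows)

dataset_T <- function(d) if (length(d$windows)) nrow(d$windows[[1]]$values) else NA_integer_
dataset_C <- function(d) if (length(d$windows)) ncol(d$windows[[1]]$values) else NA_integer_

#' Per-class observed window counts of a dataset
#'
#' Counts windows by their (single) label; mixed-label windows are counted
#' under the label of their first timestep.
#'
#' @param dataset A [window_dataset()].
#' @return Integer vector indexed by class id (0-based), length K.
#' @export
observed_counts <- function(dataset) {
  K <- nrow(dataset$manifest)
  counts <- integer(K)
  for (w in dataset$windows) {
    k <- w$labels[1L] + 1L
    counts[k] <- counts[k] + 1L
  }
  names(counts) <- dataset$manifest$name
  counts
}

#' Recompute a dataset manifest from observed single-label window counts
#'
#' @param dataset A [window_dataset()].
#' @return The dataset with `manifest$count` set to observed counts.
#' @export
refresh_manifest <- function(dataset) {
  dataset$manifest$count <- as.integer(observed_counts(dataset))
  dataset
}

dataset_equal <- function(a, b) {
  if (length(a$windows) != length(b$windows)) return(FALSE)
  for (i in seq_along(a$windows)) {
    wa <- a$windows[[i]]; wb <- b$windows[[i]]
    if (!identical(unname(wa$values), unname(wb$values))) return(FALSE)
    if (!identical(wa$labels, wb$labels)) return(FALSE)
  }
  identical(a$manifest$name, b$manifest$name) &&
    identical(a$manifest$count, b$manifest$count)
}

subset_dataset <- function(dataset, idx) {
  out <- dataset
  out$windows <- dataset$windows[idx]
  refresh_manifest(out)
}
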