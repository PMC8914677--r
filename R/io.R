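#' CSV layout for windowed-signal datasets
#'
#' One row per window: `T * C` value columns in timestep-major,
#' channel-minor order (flat index `t * C + c`, 0-based), followed by
#' either a single class column (single-activity windows, broadcast to all
#' timesteps on read) or `T` label columns (per-timestep labels, as
#' produced by augmentation).
#'
#' @param T Window length in timesteps (default 300).
#' @param C Number of channels (default 6).
#' @param label_mode `"window"` (one label column) or `"timestep"`
#'   (`T` label columns).
#' @param header Logical; write/expect a header row.
#' @return A list of class `csv_layout`.
#' @export
csv_layout <- function(T = 300L, C = 6L, label_mode = c("window", "timestep"),
                       header = TRUE) {
  label_mode <- match.arg(label_mode)
  stopifnot(T >= 1, C >= 1)
  structure(list(T = as.integer(T), C = as.integer(C),
                 label_mode = label_mode, header = isTRUE(header)),
            class = "csv_layout")
}

#' Read a CSV layout from a YAML or JSON config file
#'
#' Recognized keys: `T`, `C`, `label_mode`, `header`.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A [csv_layout()].
#' @export
read_csv_layout <- function(path) {
  if (!file.exists(path)) stop("layout config not found: ", path)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  do.call(csv_layout, cfg[intersect(names(cfg), c("T", "C", "label_mode", "header"))])
}

layout_colnames <- function(layout) {
  vals <- paste0(
    "t", rep(seq_len(layout$T) - 1L, each = layout$C),
    "c", rep(seq_len(layout$C) - 1L, times = layout$T)
  )
  labs <- if (layout$label_mode == "window") "class"
          else paste0("label", seq_len(layout$T) - 1L)
  c(vals, labs)
}

#' Write a window dataset as CSV
#'
#' Values are formatted with 17 significant digits so that
#' [read_dataset_csv()] recovers them bit-for-bit.
#'
#' @param dataset A [window_dataset()].
#' @param path Output file path.
#' @param layout A [csv_layout()] matching the dataset dimensions; defaults
#'   to the dataset's own shape with per-timestep labels when any window is
#'   mixed-label.
#' @return `path`, invisibly.
#' @export
write_dataset_csv <- function(dataset, path, layout = NULL) {
  if (is.null(layout)) {
    single <- all(vapply(dataset$windows, window_is_single_label, logical(1)))
    layout <- csv_layout(T = dataset_T(dataset), C = dataset_C(dataset),
                         label_mode = if (single) "window" else "timestep")
  }
  if (length(dataset$windows) &&
      (dataset_T(dataset) != layout$T || dataset_C(dataset) != layout$C))
    stop("layout dimensions do not match dataset windows")
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (layout$header)
    writeLines(paste(layout_colnames(layout), collapse = ","), con)
  for (w in dataset$windows) {
    vals <- sprintf("%.17g", as.vector(t(w$values)))  # flat index t*C + c
    labs <- if (layout$label_mode == "window") {
      if (!window_is_single_label(w))
        stop("window '", w$window_id,
             "' has per-timestep labels; use label_mode = 'timestep'")
      as.character(w$labels[1L])
    } else as.character(w$labels)
    writeLines(paste(c(vals, labs), collapse = ","), con)
  }
  invisible(path)
}

#' Read a window dataset from CSV
#'
#' @param path Input file path.
#' @param layout A [csv_layout()] describing the file.
#' @param manifest An [activity_manifest()] giving the label space. If
#'   `NULL`, a manifest with anonymous class names `class0..classK-1` is
#'   built from the largest label seen.
#' @param sampling_rate Sampling frequency in Hz.
#' @return A [window_dataset()].
#' @export
read_dataset_csv <- function(path, layout, manifest = NULL,
                             sampling_rate = 100) {
  if (!file.exists(path)) stop("dataset file not found: ", path)
  stopifnot(inherits(layout, "csv_layout"))
  n_vals <- layout$T * layout$C
  n_labs <- if (layout$label_mode == "window") 1L else layout$T
  nf <- utils::count.fields(path, sep = ",")
  if (layout$header && length(nf)) nf <- nf[-1L]
  bad_row <- which(nf != n_vals + n_labs)
  if (length(bad_row))
    stop("row ", bad_row[1L], ": expected ", n_vals + n_labs, " fields (",
         n_vals, " values + ", n_labs, " label(s)), found ", nf[bad_row[1L]])
  dt <- suppressWarnings(
    data.table::fread(path, header = layout$header, sep = ",",
                      colClasses = "numeric", data.table = FALSE)
  )
  vals <- as.matrix(dt[, seq_len(n_vals), drop = FALSE])
  labs <- as.matrix(dt[, n_vals + seq_len(n_labs), drop = FALSE])
  if (any(!is.finite(vals)))
    stop("non-numeric or non-finite value at row ",
         which(rowSums(!is.finite(vals)) > 0)[1L])
  if (any(labs != floor(labs)) || any(!is.finite(labs)))
    stop("non-integer label at row ",
         which(rowSums(labs != floor(labs) | !is.finite(labs)) > 0)[1L])
  K_seen <- if (nrow(dt)) max(labs) + 1L else 0L
  if (is.null(manifest))
    manifest <- activity_manifest(paste0("class", seq_len(max(K_seen, 1L)) - 1L))
  bad <- labs < 0 | labs >= nrow(manifest)
  if (any(bad))
    stop("label outside 0..", nrow(manifest) - 1L, " at row ",
         which(rowSums(bad) > 0)[1L])
  windows <- vector("list", nrow(dt))
  for (i in seq_len(nrow(dt))) {
    m <- matrix(vals[i, ], nrow = layout$T, ncol = layout$C, byrow = TRUE)
    lab <- if (n_labs == 1L) rep(as.integer(labs[i, 1L]), layout$T)
           else as.integer(labs[i, ])
    windows[[i]] <- signal_window(m, lab, window_id = paste0("row", i - 1L))
  }
  ds <- window_dataset(windows, manifest, sampling_rate)
  if (all(vapply(windows, window_is_single_label, logical(1))))
    ds <- refresh_manifest(ds)
  ds
}
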