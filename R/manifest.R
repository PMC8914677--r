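#' Activity class manifest
#'
#' An `activity_manifest` records the label space of a windowed-signal
#' dataset: consecutive integer class ids starting at 0, unique class names,
#' and the number of examples per class.
#'
#' @param names Character vector of unique class names, in class-id order
#'   (the first name gets id 0).
#' @param counts Non-negative integer vector of per-class example counts,
#'   same length as `names`.
#' @return A data.frame of class `activity_manifest` with columns
#'   `class_id`, `name`, `count`.
#' @examples
#' m <- activity_manifest(c("still", "walk"), c(10, 20))
#' manifest_total(m)
#' @export
activity_manifest <- function(names, counts = rep(0L, length(names))) {
  names <- as.character(names)
  counts <- as.integer(counts)
  if (length(names) != length(counts))
    stop("'names' and 'counts' must have the same length")
  if (anyDuplicated(names))
    stop("class names must be unique: ", names[duplicated(names)][1L])
  if (any(is.na(counts)) || any(counts < 0))
    stop("counts must be non-negative integers")
  m <- data.frame(
    class_id = seq_along(names) - 1L,
    name = names,
    count = counts,
    stringsAsFactors = FALSE
  )
  class(m) <- c("activity_manifest", "data.frame")
  m
}

#' @export
print.activity_manifest <- function(x, ...) {
  cat("Activity manifest:", nrow(x), "classes,", manifest_total(x),
      "examples\n")
  print.data.frame(x, row.names = FALSE, ...)
  invisible(x)
}

#' Total number of examples in a manifest
#'
#' @param manifest An [activity_manifest()].
#' @return Sum of the per-class counts (0 for an empty manifest).
#' @export
manifest_total <- function(manifest) {
  stopifnot(inherits(manifest, "activity_manifest"))
  if (nrow(manifest) == 0L) return(0L)
  sum(manifest$count)
}

validate_manifest <- function(manifest) {
  stopifnot(inherits(manifest, "activity_manifest"))
  if (nrow(manifest) > 0L &&
      !identical(manifest$class_id, seq_len(nrow(manifest)) - 1L))
    stop("class ids must be consecutive integers starting at 0")
  if (anyDuplicated(manifest$name))
    stop("class names must be unique")
  if (any(manifest$count < 0))
    stop("counts must be non-negative")
  invisible(manifest)
}

#' Reference manifest of the 18-class smartphone inertial benchmark
#'
#' The 18 activity classes of the KU-HAR benchmark (90 participants,
#' 3-second windows at 100 Hz) with the published per-class subsample
#' counts; the counts sum to 20,750.
#'
#' @return An [activity_manifest()] with 18 rows.
#' @examples
#' manifest_total(kuhar_manifest())  # 20750
#' @export
kuhar_manifest <- function() {
  activity_manifest(
    names = c("Stand", "Sit", "Talk-sit", "Talk-stand", "Stand-sit", "Lay",
              "Lay-stand", "Pick", "Jump", "Push-up", "Sit-up", "Walk",
              "Walk-backward", "Walk-circle", "Run", "Stair-up",
              "Stair-down", "Table-tennis"),
    counts = c(1886L, 1874L, 1797L, 1866L, 2178L, 1813L,
               1762L, 1333L, 666L, 480L, 1005L, 882L,
               317L, 259L, 595L, 798L, 781L, 458L)
  )
}

class_id_for <- function(manifest, name) {
  i <- match(name, manifest$name)
  if (anyNA(i))
    stop("unknown class name(s): ", paste(name[is.na(i)], collapse = ", "))
  manifest$class_id[i]
}

#' Read a manifest from a JSON report
#'
#' Inverse of [write_manifest_json()].
#'
#' @param path Path to the JSON file.
#' @return An [activity_manifest()].
#' @export
read_manifest_json <- function(path) {
  if (!file.exists(path)) stop("manifest file not found: ", path)
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  activity_manifest(j$classes$name, j$classes$count)
}

#' Write a manifest report as JSON
#'
#' @param manifest An [activity_manifest()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_manifest_json <- function(manifest, path) {
  validate_manifest(manifest)
  jsonlite::write_json(
    list(
      n_classes = nrow(manifest),
      total = manifest_total(manifest),
      classes = manifest
    ),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}
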