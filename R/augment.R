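#' Ordered activity-pair rules
#'
#' A pair rule names an ordered couple of activities whose windows are
#' concatenated (first then second) into a new two-activity window. A rule
#' never pairs a class with itself, and transition activities composed of
#' two postures (and classes with no plausible neighbour) are excluded
#' from pairing altogether.
#'
#' @param first,second Character vectors of class names (recycled to equal
#'   length).
#' @return A data.frame of class `pair_rules` with columns `first`,
#'   `second`.
#' @export
pair_rules <- function(first, second) {
  r <- data.frame(first = as.character(first),
                  second = as.character(second),
                  stringsAsFactors = FALSE)
  if (any(r$first == r$second))
    stop("a pair rule must not pair a class with itself: ",
         r$first[r$first == r$second][1L])
  class(r) <- c("pair_rules", "data.frame")
  r
}

#' Classes excluded from pairing in the reference rule table
#' @return Character vector of class names.
#' @export
excluded_pair_classes <- function() c("Lay-stand", "Stand-sit", "Push-up")

#' Load the default pair-rule table
#'
#' The 100 ordered activity couples for the 18-class benchmark, shipped as
#' an editable CSV (`extdata/kuhar_pair_rules.csv`) so the transcription
#' can be corrected without code changes. Every rule is validated against
#' the manifest and against the excluded-class list.
#'
#' @param manifest An [activity_manifest()] naming at least the classes
#'   used by the rules (default [kuhar_manifest()]).
#' @param path Optional path to an alternative rules CSV with columns
#'   `first,second`.
#' @return A [pair_rules()] data.frame.
#' @export
default_pair_rules <- function(manifest = kuhar_manifest(), path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "kuhar_pair_rules.csv",
                        package = "harformer", mustWork = TRUE)
  r <- utils::read.csv(path, stringsAsFactors = FALSE)
  rules <- pair_rules(r$first, r$second)
  missing <- setdiff(unique(c(rules$first, rules$second)), manifest$name)
  if (length(missing))
    stop("manifest is missing class(es) named in the rules file: ",
         paste(missing, collapse = ", "))
  banned <- intersect(unique(c(rules$first, rules$second)),
                      excluded_pair_classes())
  if (length(banned))
    stop("rules file names excluded class(es): ",
         paste(banned, collapse = ", "))
  rules
}

#' Per-rule generation counts under the min-count rule
#'
#' Each ordered pair generates `min(n_first, n_second)` combined windows,
#' where `n_k` are the manifest counts, so no example of the rarer class
#' is ever duplicated within a rule.
#'
#' @param rules A [pair_rules()] data.frame.
#' @param manifest An [activity_manifest()] containing every rule class.
#' @return A list of class `augmentation_plan` with elements `rules`
#'   (the input, plus a `count` column) and `total` (sum of counts).
#' @export
plan_counts <- function(rules, manifest) {
  validate_manifest(manifest)
  n <- stats::setNames(manifest$count, manifest$name)
  missing <- setdiff(unique(c(rules$first, rules$second)), manifest$name)
  if (length(missing))
    stop("manifest is missing class(es): ", paste(missing, collapse = ", "))
  rules$count <- as.integer(pmin(n[rules$first], n[rules$second]))
  structure(list(rules = rules, total = sum(rules$count)),
            class = "augmentation_plan")
}

#' @export
print.augmentation_plan <- function(x, ...) {
  cat("Augmentation plan:", nrow(x$rules), "pair rules,", x$total,
      "windows to generate\n")
  invisible(x)
}

#' Concatenate two windows and downsample back to length T
#'
#' The two T-step windows are concatenated into a 2T-step series, then
#' every second step is omitted: the output keeps the even indices
#' 0, 2, ..., 2T-2 of the concatenation, so `out[t, c] == concat[2t, c]`
#' (0-based). The label track is `label_a` for steps 0..T/2-1 and
#' `label_b` for steps T/2..T-1: one change point, exactly at half the
#' window.
#'
#' @param a,b [signal_window()]s of identical shape with even T.
#' @param label_a,label_b Class ids for the two halves; default to each
#'   window's own (single) label.
#' @param window_id Identifier for the combined window.
#' @return A [signal_window()] of the same T x C shape.
#' @export
combine_pair <- function(a, b, label_a = a$labels[1L], label_b = b$labels[1L],
                         window_id = paste0(a$window_id, "+", b$window_id)) {
  if (!identical(dim(a$values), dim(b$values)))
    stop("windows must have identical T x C shapes")
  T <- nrow(a$values)
  if (T %% 2L != 0L) stop("window length T must be even, got ", T)
  # even rows (0-based) of rbind(a, b): 1-based rows 1,3,...,2T-1
  keep <- seq(1L, 2L * T, by = 2L)
  vals <- rbind(a$values, b$values)[keep, , drop = FALSE]
  labels <- c(rep(as.integer(label_a), T %/% 2L),
              rep(as.integer(label_b), T %/% 2L))
  signal_window(vals, labels, window_id)
}

#' Build the augmented dataset
#'
#' Keeps every original window unchanged and appends, for each rule,
#' `min(n_first, n_second)` combined windows. Within a rule each window of
#' the smaller class is used exactly once; its partner from the larger
#' class is drawn without replacement by a seeded shuffle. The original
#' single-activity examples of both classes also remain in the output, as
#' in the source augmentation scheme.
#'
#' @param dataset A [window_dataset()] of single-activity windows.
#' @param plan An [plan_counts()] result valid for the dataset manifest.
#' @param seed Integer seed controlling partner selection.
#' @return A [window_dataset()] with
#'   `length(dataset) + plan$total` windows; the manifest keeps the
#'   original single-activity counts.
#' @export
build_augmented_dataset <- function(dataset, plan, seed = 1L) {
  stopifnot(inherits(plan, "augmentation_plan"))
  if (!all(vapply(dataset$windows, window_is_single_label, logical(1))))
    stop("augmentation input must contain single-activity windows only")
  strata <- vapply(dataset$windows, function(w) w$labels[1L], integer(1))
  by_class <- split(seq_along(dataset$windows), strata)
  name_of <- stats::setNames(dataset$manifest$name, dataset$manifest$class_id)
  id_of <- stats::setNames(dataset$manifest$class_id, dataset$manifest$name)
  avail <- vapply(by_class, length, integer(1))
  names(avail) <- name_of[names(avail)]
  rng <- local_rng(seed)
  new_windows <- vector("list", plan$total)
  pos <- 0L
  for (r in seq_len(nrow(plan$rules))) {
    f <- plan$rules$first[r]; s <- plan$rules$second[r]
    m <- plan$rules$count[r]
    if (m == 0L) next
    ia <- by_class[[as.character(id_of[[f]])]]
    ib <- by_class[[as.character(id_of[[s]])]]
    if (is.null(ia) || m > length(ia) || is.null(ib) || m > length(ib))
      stop("rule (", f, ", ", s, ") needs ", m,
           " examples of each class but the dataset has fewer")
    # the smaller class contributes every example once; the larger class
    # contributes a seeded sample without replacement
    if (length(ia) <= length(ib)) {
      ja <- ia[seq_len(m)]
      jb <- ib[rng$sample_int(length(ib), m)]
    } else {
      jb <- ib[seq_len(m)]
      ja <- ia[rng$sample_int(length(ia), m)]
    }
    for (i in seq_len(m)) {
      pos <- pos + 1L
      wa <- dataset$windows[[ja[i]]]; wb <- dataset$windows[[jb[i]]]
      new_windows[[pos]] <- combine_pair(
        wa, wb,
        window_id = paste0("aug", pos - 1L, ":", wa$window_id, "+",
                           wb$window_id))
    }
  }
  out <- dataset
  out$windows <- c(dataset$windows, new_windows[seq_len(pos)])
  out
}

#' Augmentation bookkeeping report
#'
#' Tallies the per-pair generation counts under the min-count rule and
#' compares the implied final dataset size with an expected total (for the
#' 18-class reference manifest, the published figure of 83,129). Any
#' difference is reported explicitly rather than silently absorbed.
#'
#' @param manifest An [activity_manifest()] with per-class counts.
#' @param rules A [pair_rules()] table (default the shipped reference
#'   table).
#' @param expected_total Optional expected final size (original + new).
#' @return A list with `per_pair` (data.frame first/second/count),
#'   `original`, `new`, `total`, and — when `expected_total` is given —
#'   `expected_total` and `discrepancy` (total - expected).
#' @export
augmentation_report <- function(manifest,
                                rules = default_pair_rules(manifest),
                                expected_total = NULL) {
  plan <- plan_counts(rules, manifest)
  out <- list(
    per_pair = plan$rules,
    original = manifest_total(manifest),
    new = plan$total,
    total = manifest_total(manifest) + plan$total
  )
  if (!is.null(expected_total)) {
    out$expected_total <- expected_total
    out$discrepancy <- out$total - expected_total
  }
  class(out) <- "augmentation_report"
  out
}

#' @export
print.augmentation_report <- function(x, ...) {
  cat("Augmentation report\n")
  cat("  original windows:", x$original, "\n")
  cat("  pair rules:      ", nrow(x$per_pair), "\n")
  cat("  new windows:     ", x$new, "\n")
  cat("  final total:     ", x$total, "\n")
  if (!is.null(x$expected_total))
    cat("  expected total:  ", x$expected_total,
        sprintf("(discrepancy %+d)", x$discrepancy), "\n")
  invisible(x)
}
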