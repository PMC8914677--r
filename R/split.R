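#' Stratified train/validation/test split
#'
#' Splits a dataset class by class so that every partition receives its
#' share of each class to within one window. Within each class the windows
#' are shuffled with a seeded generator and sliced contiguously; remainder
#' windows are assigned train-first (train, then validation, then test).
#'
#' @param dataset A [window_dataset()]. Windows are stratified by the label
#'   of their first timestep, so augmented two-activity windows are grouped
#'   under their opening activity.
#' @param ratios Numeric triple of non-negative proportions summing to 1
#'   (default `c(0.70, 0.15, 0.15)`).
#' @param seed Integer seed; the same seed reproduces the same partition.
#' @return A named list of three [window_dataset()]s: `train`,
#'   `validation`, `test`.
#' @export
stratified_split <- function(dataset, ratios = c(0.70, 0.15, 0.15),
                             seed = 1L) {
  stopifnot(length(ratios) == 3L, all(ratios >= 0))
  if (abs(sum(ratios) - 1) > 1e-9)
    stop("ratios must sum to 1 (got ", sum(ratios), ")")
  n_parts <- sum(ratios > 0)
  strata <- vapply(dataset$windows, function(w) w$labels[1L], integer(1))
  idx_parts <- list(integer(0), integer(0), integer(0))
  rng <- local_rng(seed)
  for (k in sort(unique(strata))) {
    idx <- which(strata == k)
    if (length(idx) < n_parts)
      stop("class id ", k, " has ", length(idx),
           " window(s), fewer than the ", n_parts,
           " non-empty partitions requested")
    idx <- idx[rng$sample_int(length(idx))]
    base <- floor(length(idx) * ratios)
    rem <- length(idx) - sum(base)
    add <- rep(0L, 3L)
    p <- 1L
    while (rem > 0L) {            # leftover windows go train-first
      if (ratios[p] > 0) { add[p] <- add[p] + 1L; rem <- rem - 1L }
      p <- if (p == 3L) 1L else p + 1L
    }
    sizes <- base + add
    ends <- cumsum(sizes)
    starts <- c(1L, ends[-3L] + 1L)
    for (p in 1:3)
      if (sizes[p] > 0)
        idx_parts[[p]] <- c(idx_parts[[p]], idx[starts[p]:ends[p]])
  }
  list(
    train = subset_dataset(dataset, sort(idx_parts[[1L]])),
    validation = subset_dataset(dataset, sort(idx_parts[[2L]])),
    test = subset_dataset(dataset, sort(idx_parts[[3L]]))
  )
}

# Seeded RNG scoped to a closure so package functions do not disturb the
# caller's .Random.seed.
local_rng <- function(seed) {
  state <- NULL
  with_state <- function(expr) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    if (is.null(state)) set.seed(as.integer(seed)) else assign(".Random.seed", state, globalenv())
    on.exit({
      state <<- get(".Random.seed", globalenv())
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, globalenv())
    })
    expr
  }
  list(
    with = function(expr) with_state(expr),
    sample_int = function(n, size = n) with_state(sample.int(n, size)),
    runif = function(n) with_state(stats::runif(n)),
    rnorm = function(n, mean = 0, sd = 1) with_state(stats::rnorm(n, mean, sd)),
    rbern = function(n, p) with_state(stats::runif(n) < p)
  )
}
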