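#' Synthetic activity class specification
#'
#' Describes one synthetic activity: static classes are a constant
#' per-channel baseline plus Gaussian noise (a posture held against
#' gravity); dynamic classes add a per-channel sinusoid with a
#' class-specific frequency and random per-window phase (a rhythmic
#' movement such as walking or jumping).
#'
#' @param name Class name.
#' @param kind `"static"` or `"dynamic"`.
#' @param offset Length-C per-channel baseline (m/s^2 for accelerometer
#'   channels, rad/s for gyroscope channels).
#' @param frequency Oscillation frequency in Hz (dynamic only); must lie
#'   in `(0, sampling_rate / 2)`.
#' @param amplitude Length-C per-channel oscillation amplitude (dynamic
#'   only).
#' @param noise_sd Standard deviation of i.i.d. Gaussian sample noise.
#' @return A list of class `synth_class_spec`.
#' @export
synth_class_spec <- function(name, kind = c("static", "dynamic"), offset,
                             frequency = NULL, amplitude = NULL,
                             noise_sd = 0.3) {
  kind <- match.arg(kind)
  if (kind == "dynamic") {
    if (is.null(frequency) || is.null(amplitude))
      stop("dynamic classes need a frequency and an amplitude")
    if (frequency <= 0) stop("frequency must be positive")
  }
  stopifnot(noise_sd >= 0)
  structure(list(name = name, kind = kind, offset = as.numeric(offset),
                 frequency = frequency,
                 amplitude = if (!is.null(amplitude)) as.numeric(amplitude),
                 noise_sd = noise_sd),
            class = "synth_class_spec")
}

#' Synthetic dataset specification
#'
#' @param classes List of [synth_class_spec()]s (class ids follow list
#'   order, starting at 0).
#' @param counts Integer vector of windows per class.
#' @param T Window length (timesteps).
#' @param C Channels.
#' @param sampling_rate Hz.
#' @param seed Integer seed.
#' @return A list of class `synth_dataset_spec`.
#' @export
synth_dataset_spec <- function(classes, counts, T = 50L, C = 6L,
                               sampling_rate = 100, seed = 1L) {
  stopifnot(length(classes) == length(counts), all(counts >= 1))
  for (s in classes)
    if (s$kind == "dynamic" && s$frequency >= sampling_rate / 2)
      stop("class '", s$name, "': frequency ", s$frequency,
           " Hz is not below the Nyquist limit ", sampling_rate / 2, " Hz")
  structure(list(classes = classes, counts = as.integer(counts),
                 T = as.integer(T), C = as.integer(C),
                 sampling_rate = sampling_rate, seed = as.integer(seed)),
            class = "synth_dataset_spec")
}

#' Generate one synthetic window
#'
#' Static: `value[t, c] = offset_c + noise`. Dynamic:
#' `offset_c + amplitude_c * sin(2 pi f t / rate + phase) + noise` with a
#' seeded random phase per window.
#'
#' @param spec A [synth_class_spec()].
#' @param class_id 0-based class id to stamp on every timestep.
#' @param T,C,sampling_rate Window geometry.
#' @param seed Integer seed (same seed, same window).
#' @param window_id Identifier.
#' @return A [signal_window()].
#' @export
generate_window <- function(spec, class_id, T = 50L, C = 6L,
                            sampling_rate = 100, seed = 1L,
                            window_id = "synth0") {
  if (spec$kind == "dynamic" && spec$frequency >= sampling_rate / 2)
    stop("frequency ", spec$frequency, " Hz is not below the Nyquist limit")
  rng <- local_rng(seed)
  base <- matrix(rep(spec$offset, each = T), T, C)
  if (spec$kind == "dynamic") {
    phase <- rng$runif(1) * 2 * pi
    t0 <- seq_len(T) - 1L
    osc <- sin(2 * pi * spec$frequency * t0 / sampling_rate + phase)
    base <- base + outer(osc, spec$amplitude)
  }
  if (spec$noise_sd > 0)
    base <- base + matrix(rng$rnorm(T * C, sd = spec$noise_sd), T, C)
  signal_window(base, class_id, window_id)
}

#' Generate a synthetic dataset
#'
#' @param spec A [synth_dataset_spec()].
#' @return A [window_dataset()] with exactly the per-class counts of the
#'   spec and a populated manifest.
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "synth_dataset_spec"))
  manifest <- activity_manifest(vapply(spec$classes, `[[`, "", "name"),
                                spec$counts)
  windows <- vector("list", sum(spec$counts))
  pos <- 0L
  for (k in seq_along(spec$classes)) {
    for (i in seq_len(spec$counts[k])) {
      pos <- pos + 1L
      windows[[pos]] <- generate_window(
        spec$classes[[k]], class_id = k - 1L, T = spec$T, C = spec$C,
        sampling_rate = spec$sampling_rate,
        seed = spec$seed + 7919L * (k - 1L) + i,
        window_id = sprintf("%s-%d", spec$classes[[k]]$name, i - 1L))
    }
  }
  window_dataset(windows, manifest, spec$sampling_rate)
}

#' Built-in synthetic dataset presets
#'
#' `"desk"`: the default desk-scale preset — 50-step, 6-channel windows at
#' 100 Hz, four classes (two static postures with distinct baselines, two
#' dynamic movements at 3 and 5 Hz with distinct amplitudes), 200 windows
#' per class; small enough for minutes-scale CPU training.
#' `"kuhar-manifest"`: the same four signal archetypes cycled over the 18
#' reference class names with the published per-class counts (total
#' 20,750) — intended for augmentation bookkeeping, not for training.
#'
#' @param name Preset name.
#' @param windows_per_class Override for the per-class count of the
#'   `"desk"` preset.
#' @param seed Integer seed.
#' @return A [synth_dataset_spec()].
#' @export
synth_preset <- function(name = c("desk", "kuhar-manifest"),
                         windows_per_class = 200L, seed = 1L) {
  name <- match.arg(name)
  g <- 9.81
  archetypes <- list(
    function(nm) synth_class_spec(nm, "static",
                                  offset = c(0, 0, g, 0, 0, 0),
                                  noise_sd = 0.3),
    function(nm) synth_class_spec(nm, "static",
                                  offset = c(g, 0, 0, 0.5, 0, 0),
                                  noise_sd = 0.3),
    function(nm) synth_class_spec(nm, "dynamic",
                                  offset = c(0, 0, g, 0, 0, 0) + 1.5,
                                  frequency = 3,
                                  amplitude = c(2, 1, 2, 0.5, 0.5, 0.5),
                                  noise_sd = 0.3),
    function(nm) synth_class_spec(nm, "dynamic",
                                  offset = c(0, g, 0, 0, 0, -0.5) - 1.5,
                                  frequency = 5,
                                  amplitude = c(4, 2, 1, 1, 0.3, 1),
                                  noise_sd = 0.3)
  )
  if (name == "desk") {
    classes <- list(archetypes[[1]]("still"), archetypes[[2]]("posture"),
                    archetypes[[3]]("walk-like"), archetypes[[4]]("jump-like"))
    return(synth_dataset_spec(classes,
                              counts = rep(windows_per_class, 4L),
                              T = 50L, C = 6L, sampling_rate = 100,
                              seed = seed))
  }
  ref <- kuhar_manifest()
  classes <- lapply(seq_len(nrow(ref)), function(k) {
    arch <- archetypes[[(k - 1L) %% 4L + 1L]]
    sp <- arch(ref$name[k])
    sp$offset <- sp$offset + 0.05 * k   # keep specs pairwise distinct
    sp
  })
  synth_dataset_spec(classes, counts = ref$count, T = 50L, C = 6L,
                     sampling_rate = 100, seed = seed)
}

#' Read a synthetic dataset spec from YAML
#'
#' Expected structure: top-level `T`, `C`, `sampling_rate`, `seed`, and a
#' `classes` list whose entries have `name`, `kind`, `offset`, `count`,
#' and for dynamic classes `frequency` and `amplitude`; `noise_sd`
#' optional.
#'
#' @param path Path to the YAML file.
#' @return A [synth_dataset_spec()].
#' @export
read_synth_spec_yaml <- function(path) {
  if (!file.exists(path)) stop("spec file not found: ", path)
  y <- yaml::read_yaml(path)
  classes <- lapply(y$classes, function(cl)
    synth_class_spec(cl$name, cl$kind, unlist(cl$offset),
                     frequency = cl$frequency,
                     amplitude = if (!is.null(cl$amplitude)) unlist(cl$amplitude),
                     noise_sd = if (!is.null(cl$noise_sd)) cl$noise_sd else 0.3))
  synth_dataset_spec(classes,
                     counts = vapply(y$classes, function(cl) as.integer(cl$count), integer(1)),
                     T = if (!is.null(y$T)) y$T else 50L,
                     C = if (!is.null(y$C)) y$C else 6L,
                     sampling_rate = if (!is.null(y$sampling_rate)) y$sampling_rate else 100,
                     seed = if (!is.null(y$seed)) y$seed else 1L)
}
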