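#' Protocol specification
#'
#' A PEEP-step protocol: an ordered sequence of PEEP levels, each held for a
#' fixed number of breaths, optionally in isolated-lung mode, run in
#' (seeded) triplicate when sensor noise is enabled.
#'
#' @param peep_sequence ordered numeric vector of PEEP levels, cmH2O.
#' @param breaths_per_level breaths delivered at each level; at least 21 (15
#'   summation breaths + 5 offset breaths + 1 margin).
#' @param isolated_lung logical.
#' @param repetitions number of repeated runs (identical when noise-free).
#' @param noise optional [noise_settings()]; repetition `r` uses
#'   `noise$seed + r`.
#' @param seed base seed recorded in outputs.
#' @return a list of class `protocol_spec`.
#' @export
protocol_spec <- function(peep_sequence, breaths_per_level = 25,
                          isolated_lung = FALSE, repetitions = 3,
                          noise = NULL, seed = 0) {
  if (breaths_per_level < 21)
    stop("breaths_per_level must be >= 21 (15 summation + 5 offset + 1 margin)",
         call. = FALSE)
  if (repetitions < 1) stop("repetitions must be >= 1", call. = FALSE)
  structure(list(peep_sequence = as.numeric(peep_sequence),
                 breaths_per_level = as.integer(breaths_per_level),
                 isolated_lung = isTRUE(isolated_lung),
                 repetitions = as.integer(repetitions), noise = noise,
                 seed = as.integer(seed)),
            class = "protocol_spec")
}

#' Run a PEEP-step protocol
#'
#' Simulates the full level sequence, annotating every PEEP transition with
#' its breath and sample index. If a level would push the lung above its
#' capacity the simulation raises a capacity error; the level is recorded as
#' omitted (mirroring the bench practice of skipping steps that exceed test
#' lung capacity) and the run is truncated before it.
#'
#' @param config a `model_config`.
#' @param spec a [protocol_spec()].
#' @return list of class `protocol_run` with elements `reps` (one list per
#'   repetition: `waveforms`, `breaths`, `annotations`, `seed`),
#'   `omitted_levels` (numeric vector of omitted PEEP levels),
#'   `levels_run`, `spec` and `config`.
#' @export
run_protocol <- function(config, spec) {
  stopifnot(inherits(config, "model_config"), inherits(spec, "protocol_spec"))
  if (spec$isolated_lung) config <- isolated_lung_mode(config)
  levels <- spec$peep_sequence
  omitted <- numeric()
  repeat {
    peep_per_breath <- rep(levels, each = spec$breaths_per_level)
    wf <- tryCatch(simulate_breaths(config, peep_per_breath),
                   peepstep_capacity_error = function(e) e)
    if (!inherits(wf, "peepstep_capacity_error")) break
    bad_level <- ceiling(wf$breath / spec$breaths_per_level)
    omitted <- c(omitted, levels[bad_level])
    levels <- levels[seq_len(bad_level - 1)]
    if (length(levels) == 0)
      stop("capacity error at the first protocol level; nothing to run",
           call. = FALSE)
  }
  first_breath <- (seq_along(levels) - 1) * spec$breaths_per_level + 1
  trans <- which(diff(levels) != 0)
  annotations <- data.frame(
    breath = first_breath[trans + 1],
    sample = (first_breath[trans + 1] - 1) *
      (attr(wf, "sample_rate") * config$ventilator$t_cycle) + 1,
    peep_old = levels[trans], peep_new = levels[trans + 1])
  reps <- lapply(seq_len(spec$repetitions), function(r) {
    wfr <- wf
    if (!is.null(spec$noise)) {
      ns <- spec$noise
      ns$seed <- ns$seed + r
      wfr <- add_noise(wf, ns)
    }
    list(waveforms = wfr, breaths = segment_breaths(wfr),
         annotations = annotations, seed = spec$seed + r)
  })
  structure(list(reps = reps, omitted_levels = omitted, levels_run = levels,
                 spec = spec, config = config),
            class = "protocol_run")
}

#' The bench's six experimental arms
#'
#' One, two or three parallel test lungs crossed with normal or stiff
#' (strapped) chest wall.
#'
#' @return a `data.frame` with columns `arm`, `n_lungs`, `chest_wall_mode`.
#' @export
arm_presets <- function() {
  arms <- expand.grid(n_lungs = 1:3,
                      chest_wall_mode = c("normal", "stiff"),
                      stringsAsFactors = FALSE)
  arms$arm <- paste0(arms$n_lungs, "_lung", ifelse(arms$n_lungs > 1, "s", ""),
                     "_", arms$chest_wall_mode)
  arms[, c("arm", "n_lungs", "chest_wall_mode")]
}

#' Load a preset arm configuration shipped with the package
#'
#' Presets are YAML configuration files under `inst/extdata/presets`, one
#' per experimental arm (see [arm_presets()] for the names).
#'
#' @param name preset name, e.g. `"2_lungs_normal"`.
#' @return a `model_config`.
#' @export
load_preset <- function(name) {
  path <- system.file("extdata", "presets", paste0(name, ".yaml"),
                      package = "peepstep")
  if (path == "")
    stop("unknown preset: ", name, "; see arm_presets()", call. = FALSE)
  read_model_config(path)
}
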