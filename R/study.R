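#' Measure every PEEP step of a protocol run
#'
#' Applies the full measurement pipeline to each repetition of a
#' [run_protocol()] result: breath segmentation, measured PEEP per level
#' (mean end-expiratory airway pressure of the last equilibrated breaths),
#' the 15+5-breath spirometric `dEELV`, ground-truth `dEELV` from the lung
#' volume channel, end-expiratory pleural and transpulmonary pressure
#' changes, and tidal elastances at the pre-step level.
#'
#' @param run a `protocol_run`.
#' @param last_n breaths averaged at each level for equilibrated values.
#' @return data.frame, one row per (repetition, transition): `rep`,
#'   `transition`, `peep_from`, `peep_to`, `direction`, `dpeep`, `deelv`,
#'   `deelv_true`, `dppl_ee`, `dptp_ee`, `el_tidal`, `ecw_tidal`,
#'   `etot_tidal` (tidal values at the baseline level of the run), `vt`,
#'   `el_peepstep`, `ecw_ee`.
#' @export
measure_peep_steps <- function(run, last_n = 5) {
  stopifnot(inherits(run, "protocol_run"))
  bpl <- run$spec$breaths_per_level
  out <- lapply(seq_along(run$reps), function(r) {
    rep_ <- run$reps[[r]]
    br <- rep_$breaths
    ann <- rep_$annotations
    if (nrow(ann) == 0) return(NULL)
    base5 <- utils::tail(1:bpl, last_n)   # equilibrated baseline breaths
    tid <- lapply(base5, function(i) tidal_elastances(br[i, ]))
    el_tid <- mean(vapply(tid, `[[`, 0, "el"))
    ecw_tid <- mean(vapply(tid, `[[`, 0, "ecw"))
    etot_tid <- mean(vapply(tid, `[[`, 0, "etot"))
    vt <- mean(br$vti[base5])
    rows <- lapply(seq_len(nrow(ann)), function(k) {
      b <- ann$breath[k]
      old5 <- (b - last_n):(b - 1)
      new5 <- (b + bpl - last_n):(b + bpl - 1)
      dpeep <- mean(br$paw_ee[new5]) - mean(br$paw_ee[old5])
      dppl <- mean(br$ppl_ee[new5]) - mean(br$ppl_ee[old5])
      deelv <- delta_eelv(rep_$waveforms, b, br)
      data.frame(rep = r, transition = k,
                 peep_from = ann$peep_old[k], peep_to = ann$peep_new[k],
                 direction = if (ann$peep_new[k] > ann$peep_old[k]) "up" else "down",
                 dpeep = dpeep, deelv = deelv,
                 deelv_true = mean(br$vlung_ee[new5]) - mean(br$vlung_ee[old5]),
                 dppl_ee = dppl, dptp_ee = dpeep - dppl,
                 el_tidal = el_tid, ecw_tidal = ecw_tid, etot_tidal = etot_tid,
                 vt = vt,
                 el_peepstep = dpeep / deelv * 1000,
                 ecw_ee = dppl / deelv * 1000)
    })
    do.call(rbind, rows)
  })
  do.call(rbind, out)
}

#' Run the full PEEP-step study over the experimental arms
#'
#' For every arm (lungs x chest-wall stiffness) and every PEEP step, runs
#' the `0-step-0` protocol, measures all transitions, and averages the
#' repetitions. Steps that exceed the capacity of the connected test lungs
#' are omitted, as at the bench.
#'
#' @param arms data.frame as returned by [arm_presets()] (subset allowed).
#' @param steps PEEP step sizes from ZEEP, cmH2O. Defaults to the measured
#'   bench levels 4.4, 8.4 and 12.2.
#' @param breaths_per_level breaths per PEEP level.
#' @param repetitions runs per step procedure (identical when noise-free).
#' @param noise optional [noise_settings()].
#' @param seed base seed.
#' @param configs optional named list of `model_config`s keyed by arm name;
#'   defaults to [make_default_config()] per arm.
#' @return data.frame with one row per (arm, step, direction), averaged
#'   over repetitions, plus an `omitted` attribute listing skipped (arm,
#'   step) pairs.
#' @export
run_peep_step_study <- function(arms = arm_presets(),
                                steps = c(4.4, 8.4, 12.2),
                                breaths_per_level = 25, repetitions = 1,
                                noise = NULL, seed = 0, configs = NULL) {
  omitted <- data.frame(arm = character(), step = numeric())
  rows <- list()
  for (i in seq_len(nrow(arms))) {
    arm <- arms$arm[i]
    cfg <- if (!is.null(configs)) configs[[arm]] else
      make_default_config(arms$n_lungs[i], arms$chest_wall_mode[i])
    for (s in steps) {
      spec <- protocol_spec(c(0, s, 0), breaths_per_level = breaths_per_level,
                            repetitions = repetitions, noise = noise,
                            seed = seed)
      run <- run_protocol(cfg, spec)
      if (length(run$omitted_levels)) {
        omitted <- rbind(omitted, data.frame(arm = arm, step = s))
        next
      }
      m <- measure_peep_steps(run)
      # triplicate averaging: mean over repetitions per transition
      agg <- stats::aggregate(m[, !(names(m) %in% c("rep", "direction"))],
                              by = list(transition = m$transition), FUN = mean)
      agg$direction <- m$direction[match(agg$transition, m$transition)]
      agg$arm <- arm
      agg$n_lungs <- arms$n_lungs[i]
      agg$chest_wall_mode <- arms$chest_wall_mode[i]
      agg$step_nominal <- s
      rows[[length(rows) + 1]] <- agg
    }
  }
  res <- do.call(rbind, rows)
  res$transition.1 <- NULL
  attr(res, "omitted") <- omitted
  res
}

#' Incremental PEEP sequence study
#'
#' Runs an incremental staircase (default 0-4.1-8.2-12.3 cmH2O, i.e. steps
#' of 4.1) on every arm and measures the per-step changes in end-expiratory
#' transpulmonary and pleural pressure. Arms whose lungs cannot accommodate
#' the top level are truncated at their capacity, as at the bench.
#'
#' @inheritParams run_peep_step_study
#' @param levels the staircase PEEP levels, cmH2O.
#' @return data.frame, one row per (arm, step), with the
#'   [measure_peep_steps()] columns.
#' @export
incremental_peep_study <- function(arms = arm_presets(),
                                   levels = c(0, 4.1, 8.2, 12.3),
                                   breaths_per_level = 25, seed = 0,
                                   configs = NULL) {
  rows <- list()
  for (i in seq_len(nrow(arms))) {
    arm <- arms$arm[i]
    cfg <- if (!is.null(configs)) configs[[arm]] else
      make_default_config(arms$n_lungs[i], arms$chest_wall_mode[i])
    spec <- protocol_spec(levels, breaths_per_level = breaths_per_level,
                          repetitions = 1, seed = seed)
    run <- run_protocol(cfg, spec)
    m <- measure_peep_steps(run)
    if (is.null(m)) next
    m$arm <- arm
    m$n_lungs <- arms$n_lungs[i]
    m$chest_wall_mode <- arms$chest_wall_mode[i]
    m$omitted_levels <- paste(run$omitted_levels, collapse = ",")
    rows[[length(rows) + 1]] <- m
  }
  do.call(rbind, rows)
}

#' Pooled study summary
#'
#' Means and standard deviations across arms, mirroring how the bench study
#' pooled its six procedures: per PEEP step the measured step size,
#' end-expiratory transpulmonary increase and end-expiratory pleural
#' increase; plus tidal chest-wall elastance by stiffness mode and the
#' pooled end-expiratory chest-wall elastance/compliance over the largest
#' step.
#'
#' @param study result of [run_peep_step_study()].
#' @param incremental optional result of [incremental_peep_study()].
#' @return list of data.frames: `steps`, `tidal_ecw`, `ee_chest_wall`, and
#'   (if `incremental` given) `incremental`.
#' @export
summarize_study <- function(study, incremental = NULL) {
  up <- study[study$direction == "up", ]
  steps <- do.call(rbind, lapply(split(up, up$step_nominal), function(d)
    data.frame(step = d$step_nominal[1], n_arms = nrow(d),
               dpeep_mean = mean(d$dpeep), dpeep_sd = stats::sd(d$dpeep),
               dptp_ee_mean = mean(d$dptp_ee), dptp_ee_sd = stats::sd(d$dptp_ee),
               dppl_ee_mean = mean(d$dppl_ee), dppl_ee_sd = stats::sd(d$dppl_ee),
               deelv_mean = mean(d$deelv), deelv_sd = stats::sd(d$deelv))))
  tidal <- do.call(rbind, lapply(split(study, study$chest_wall_mode), function(d)
    data.frame(chest_wall_mode = d$chest_wall_mode[1],
               ecw_tidal_mean = mean(d$ecw_tidal),
               ecw_tidal_sd = stats::sd(d$ecw_tidal))))
  top <- up[up$step_nominal == max(up$step_nominal), ]
  ee <- data.frame(step = max(up$step_nominal), n_arms = nrow(top),
                   ecw_ee_mean = mean(top$ecw_ee),
                   ecw_ee_sd = stats::sd(top$ecw_ee),
                   ccw_ee_mean = mean(1000 / top$ecw_ee),
                   ccw_ee_sd = stats::sd(1000 / top$ecw_ee))
  out <- list(steps = steps, tidal_ecw = tidal, ee_chest_wall = ee)
  if (!is.null(incremental)) {
    inc_up <- incremental[incremental$direction == "up", ]
    out$incremental <- data.frame(
      n_steps = nrow(inc_up),
      dpeep_mean = mean(inc_up$dpeep), dpeep_sd = stats::sd(inc_up$dpeep),
      dptp_ee_mean = mean(inc_up$dptp_ee), dptp_ee_sd = stats::sd(inc_up$dptp_ee),
      dppl_ee_mean = mean(inc_up$dppl_ee), dppl_ee_sd = stats::sd(inc_up$dppl_ee))
  }
  out
}

#' Worked example: conventional vs PEEP-step transpulmonary pressure
#'
#' The two routes to the end-inspiratory transpulmonary pressure of one
#' recorded tidal breath of the two-test-lung arm: conventionally as
#' `dPAW - dPPL`, and esophageal-free from a PEEP step as
#' `(dPEEP/dEELV) * VT`. Defaults are the reference bench recording (tidal
#' volume 297 ml, tidal `dPAW` 14.1 and `dPPL` 5.3 cmH2O; PEEP step 8.4
#' cmH2O with `dEELV` 281 ml).
#'
#' @param dpaw,dppl tidal airway / pleural driving pressure, cmH2O.
#' @param vt tidal volume, ml.
#' @param dpeep measured PEEP change, cmH2O.
#' @param deelv measured end-expiratory volume change, ml.
#' @return two-row data.frame with `method` and `ptp_ei` (cmH2O).
#' @export
tidal_vs_peepstep_example <- function(dpaw = 14.1, dppl = 5.3, vt = 297,
                                      dpeep = 8.4, deelv = 281) {
  data.frame(
    method = c("conventional dPAW - dPPL", "PEEP-step (dPEEP/dEELV) x VT"),
    ptp_ei = c(dpaw - dppl, ptp_from_peepstep(dpeep, deelv, vt)))
}

#' Regenerate a study-level results table from scratch
#'
#' Convenience reproduction entry point: runs whatever simulations the
#' requested table needs and returns it.
#'
#' * `"results_summary"`: pooled PEEP-step and incremental summary
#'   ([summarize_study()]) over all six arms.
#' * `"regression"`: the measured-vs-predicted `dEELV` regression
#'   ([eelv_regression()]) over all arms and steps.
#' * `"worked_example"`: [tidal_vs_peepstep_example()].
#'
#' @param table one of `"results_summary"`, `"regression"`,
#'   `"worked_example"`.
#' @param breaths_per_level breaths per PEEP level for the simulations.
#' @param seed base seed.
#' @return the requested table (data.frame or list of data.frames).
#' @export
reproduce_table <- function(table = c("results_summary", "regression",
                                      "worked_example"),
                            breaths_per_level = 25, seed = 0) {
  table <- match.arg(table)
  if (table == "worked_example") return(tidal_vs_peepstep_example())
  study <- run_peep_step_study(breaths_per_level = breaths_per_level,
                               seed = seed)
  if (table == "regression") {
    reg <- eelv_regression(study)
    return(data.frame(slope = reg$slope, r2 = reg$r2,
                      slope_reverse = reg$slope_reverse,
                      free_intercept = reg$free_fit$intercept,
                      free_slope = reg$free_fit$slope, n = reg$n))
  }
  inc <- incremental_peep_study(seed = seed)
  summarize_study(study, inc)
}
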