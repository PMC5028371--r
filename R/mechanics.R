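#' Tidal elastances of one breath
#'
#' Total respiratory system, chest wall and lung elastance from one breath:
#' `ETOT = dPAW/VT`, `ECW = dPPL/VT`, `EL = (dPAW - dPPL)/VT`, where the
#' pressure deltas are end-inspiratory (pause plateau) minus end-expiratory
#' values and the volume is the inspired tidal volume. By construction
#' `ETOT = ECW + EL` exactly.
#'
#' @param breath one row of a [segment_breaths()] table (or any list with
#'   `paw_ee`, `paw_ei`, `ppl_ee`, `ppl_ei`, `vti`).
#' @return list with `etot`, `ecw`, `el` (cmH2O/L), `dpaw`, `dppl`, `dptp`
#'   (cmH2O) and `vt` (ml).
#' @export
tidal_elastances <- function(breath) {
  vt <- breath$vti
  if (is.null(vt) || !is.finite(vt) || vt <= 0)
    stop("undefined elastance: tidal volume must be positive", call. = FALSE)
  dpaw <- breath$paw_ei - breath$paw_ee
  dppl <- breath$ppl_ei - breath$ppl_ee
  list(etot = dpaw / vt * 1000, ecw = dppl / vt * 1000,
       el = (dpaw - dppl) / vt * 1000,
       dpaw = dpaw, dppl = dppl, dptp = dpaw - dppl, vt = vt)
}

#' Summary of one PEEP step
#'
#' Derived quantities of a PEEP step: lung elastance by the PEEP-step method
#' `EL = dPEEP/dEELV`, the end-expiratory transpulmonary pressure change
#' `dPTP_EE = dPEEP - dPPL_EE` and the end-expiratory chest-wall elastance
#' `ECW_EE = dPPL_EE/dEELV`.
#'
#' @param dpeep measured PEEP change, cmH2O.
#' @param deelv measured change in end-expiratory lung volume, ml (non-zero).
#' @param dppl_ee change in end-expiratory pleural pressure, cmH2O.
#' @param arm optional arm identifier.
#' @return list of class `peepstep_result` with fields `arm`, `dpeep`,
#'   `deelv`, `el_peepstep` (cmH2O/L), `dppl_ee`, `dptp_ee` (cmH2O),
#'   `ecw_ee` (cmH2O/L).
#' @export
peepstep_result <- function(dpeep, deelv, dppl_ee, arm = NA_character_) {
  if (!is.finite(deelv) || deelv == 0)
    stop("division error: dEELV must be non-zero", call. = FALSE)
  structure(list(arm = arm, dpeep = dpeep, deelv = deelv,
                 el_peepstep = dpeep / deelv * 1000,
                 dppl_ee = dppl_ee, dptp_ee = dpeep - dppl_ee,
                 ecw_ee = dppl_ee / deelv * 1000),
            class = "peepstep_result")
}

#' Transpulmonary driving pressure without pleural measurement
#'
#' The PEEP-step route to the lung (transpulmonary) driving pressure of a
#' tidal volume: total respiratory-system driving pressure minus the
#' chest-wall contribution, `dPAW - ECW * VT`. Because tidal chest-wall
#' elastance is essentially PEEP-independent, `ECW` determined once (e.g.
#' as `ETOT - dPEEP/dEELV` from a single PEEP step) gives the lung driving
#' pressure at any PEEP level without pleural or esophageal measurements.
#'
#' @param dpaw tidal airway driving pressure (plateau minus end-expiratory),
#'   cmH2O.
#' @param ecw tidal chest-wall elastance, cmH2O/L.
#' @param vt tidal volume, ml.
#' @return `dPAW - ECW * VT`, cmH2O.
#' @export
driving_ptp_via_peepstep <- function(dpaw, ecw, vt) {
  stopifnot(is.finite(dpaw), is.finite(ecw), is.finite(vt))
  dpaw - ecw * vt / 1000
}

#' End-inspiratory transpulmonary pressure by the PEEP-step method
#'
#' `(dPEEP / dEELV) * VT`: the PEEP-step lung elastance applied to the tidal
#' volume, the esophageal-free estimate of the conventional tidal
#' `dPAW - dPPL`.
#'
#' @param dpeep measured PEEP change, cmH2O.
#' @param deelv measured end-expiratory lung volume change, ml (non-zero).
#' @param vt tidal volume, ml.
#' @return transpulmonary pressure estimate, cmH2O.
#' @export
ptp_from_peepstep <- function(dpeep, deelv, vt) {
  if (!is.finite(deelv) || deelv == 0)
    stop("division error: dEELV must be non-zero", call. = FALSE)
  dpeep / deelv * vt
}

#' End-expiratory and end-inspiratory pressure/volume points
#'
#' Extracts per-breath end-expiratory and end-inspiratory airway and
#' transpulmonary P/V pairs from a waveform record and fits the lung P/V
#' line through the end-expiratory airway points (least squares of pressure
#' on volume across PEEP levels).
#'
#' @param waveforms a `peep_waveforms` record.
#' @param breaths optional precomputed [segment_breaths()] table.
#' @param last_n use only the last `last_n` (equilibrated) breaths at each
#'   PEEP level for the fit; default 5.
#' @return list with `points` (data.frame: `breath`, `peep`, `paw_ee`,
#'   `ptp_ee`, `vol_ee`, `paw_ei`, `ptp_ei`, `vol_ei`), `slope` (fitted
#'   end-expiratory elastance, cmH2O/L), `intercept` (cmH2O) and
#'   `max_residual` (cmH2O).
#' @export
pv_points <- function(waveforms, breaths = NULL, last_n = 5) {
  if (is.null(breaths)) breaths <- segment_breaths(waveforms)
  peep_lab <- round(breaths$paw_ee, 1)
  pts <- data.frame(breath = breaths$breath, peep = peep_lab,
                    paw_ee = breaths$paw_ee,
                    ptp_ee = breaths$paw_ee - breaths$ppl_ee,
                    vol_ee = breaths$vlung_ee,
                    paw_ei = breaths$paw_ei,
                    ptp_ei = breaths$paw_ei - breaths$ppl_ei,
                    vol_ei = breaths$vlung_ei)
  # equilibrated points: last last_n breaths of each constant-PEEP stretch
  changes <- detect_peep_changes(waveforms, breaths)
  seg_start <- c(1, changes$breath)
  seg_end <- c(changes$breath - 1, nrow(breaths))
  keep <- unlist(lapply(seq_along(seg_start), function(i)
    utils::tail(seg_start[i]:seg_end[i], last_n)))
  fitpts <- pts[keep, ]
  if (length(unique(round(fitpts$paw_ee))) < 2)
    stop("fit error: need at least two distinct PEEP levels", call. = FALSE)
  fit <- stats::lm(paw_ee ~ vol_ee, data = fitpts)
  list(points = pts, fit_points = fitpts,
       slope = unname(stats::coef(fit)[2]) * 1000,
       intercept = unname(stats::coef(fit)[1]),
       max_residual = max(abs(stats::residuals(fit))))
}

#' Regression of elastance-predicted on measured end-expiratory volume change
#'
#' The study-level check that the change in end-expiratory lung volume after
#' a PEEP step equals the PEEP change divided by lung elastance: a
#' zero-intercept least-squares fit of `Y = dPEEP / EL_tidal` (in ml, with
#' `EL_tidal` from the tidal airway-minus-pleural driving pressure) on the
#' spirometrically measured `X = dEELV`, reported as slope and r-squared.
#' The reverse-direction slope (measured on predicted) and a free-intercept
#' fit are also returned for transparency.
#'
#' @param data a data.frame with columns `deelv` (measured, ml), `dpeep`
#'   (cmH2O) and `el_tidal` (cmH2O/L), e.g. from [run_peep_step_study()];
#'   at least 3 steps.
#' @return list with `slope` (zero-intercept, predicted-on-measured), `r2`,
#'   `slope_reverse`, `free_fit` (intercept and slope of the ordinary fit)
#'   and `n`.
#' @export
eelv_regression <- function(data) {
  stopifnot(all(c("deelv", "dpeep", "el_tidal") %in% names(data)))
  x <- data$deelv
  y <- data$dpeep / data$el_tidal * 1000
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 PEEP steps", call. = FALSE)
  if (sum(x^2) == 0) stop("regression error: degenerate measured values",
                          call. = FALSE)
  slope <- sum(x * y) / sum(x^2)
  r2 <- sum(x * y)^2 / (sum(x^2) * sum(y^2))
  free <- stats::lm(y ~ x)
  list(slope = slope, r2 = r2,
       slope_reverse = sum(x * y) / sum(y^2),
       free_fit = list(intercept = unname(stats::coef(free)[1]),
                       slope = unname(stats::coef(free)[2])),
       n = length(x))
}
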