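#' Model state at functional residual capacity
#'
#' The apneic resting state after evacuating the pleural space: pleural
#' pressure equals the evacuation target (default -5 cmH2O), airway pressure
#' is zero, the lung sits at the volume where its recoil balances the
#' transpulmonary pressure `0 - evacuation_pressure`, no water has been
#' displaced, and the container water level exceeds the sack level by
#' exactly the head that balances the evacuated pleural pressure at the
#' valve.
#'
#' @param config a `model_config`.
#' @return a list of class `model_state` with fields `time`, `lung_volume`
#'   (ml above residual), `displaced_water` (ml), `pleural_pressure`,
#'   `airway_pressure` (cmH2O gauge) and `ventilator_phase`.
#' @export
initial_state_at_frc <- function(config) {
  stopifnot(inherits(config, "model_config"))
  pev <- if (config$isolated_lung) 0 else config$chest_wall$evacuation_pressure
  v0 <- .v_of_ptp(config, -pev)
  structure(list(time = 0, lung_volume = v0, displaced_water = 0,
                 pleural_pressure = pev, airway_pressure = 0,
                 ventilator_phase = "expiration"),
            class = "model_state")
}

#' Instantaneous pleural pressure from the gas law
#'
#' Solves the isothermal gas-conservation relation of the sealed pleural
#' space for the pleural pressure at a given lung volume and displaced water
#' volume. Used by [derivatives()] and by conservation checks.
#'
#' @param config a `model_config`.
#' @param lung_volume total lung volume above residual, ml.
#' @param displaced_water water moved container-to-sack, ml.
#' @return pleural pressure, cmH2O gauge.
#' @export
pleural_pressure <- function(config, lung_volume, displaced_water) {
  .solve_ppl_cpp(.core_par(config), lung_volume, displaced_water)
}

#' Time derivatives of the model state
#'
#' The governing equations: lung volume follows the airway flow prescribed
#' by the ventilator drive; displaced water follows the hydraulic driving
#' pressure across the valve, `Ppl - Pev - (k_head + k_rec) * W`, divided by
#' the valve resistance, where `k_head = f * (1/A_container + 1/A_sack)` is
#' the geometric head stiffness; pleural pressure is algebraic (isothermal
#' gas law on the pleural gas volume, which changes with lung expansion,
#' water displacement and wall bulging).
#'
#' @param state a `model_state` (or list with `lung_volume`,
#'   `displaced_water`).
#' @param config a `model_config`.
#' @param drive list with `phase` (`"inspiration"`, `"pause"` or
#'   `"expiration"`) and `peep` (cmH2O; used during expiration).
#' @return list with `d_lung_volume` and `d_displaced_water` (ml/s) plus the
#'   instantaneous `pleural_pressure`, `alveolar_pressure` and `flow`.
#' @export
derivatives <- function(state, config, drive = list(phase = "expiration", peep = 0)) {
  v <- state$lung_volume; w <- state$displaced_water
  cap <- config$lung$n_units * config$lung$capacity_per_unit
  if (v < config$lung$residual_volume - 1e-6 || v > cap + 1e-6)
    stop("state outside physical bounds: lung_volume must lie in [residual, capacity]",
         call. = FALSE)
  cwp <- config$chest_wall; vs <- config$ventilator
  ppl <- if (config$isolated_lung) 0 else pleural_pressure(config, v, w)
  palv <- ppl + .ptp_of_v(config, v)
  flow <- switch(drive$phase,
    inspiration = vs$tidal_volume / vs$t_flow,
    pause = 0,
    expiration = -max(0, (palv - drive$peep) /
                        (config$lung$airway_resistance + vs$expiratory_resistance)),
    stop("unknown ventilator phase: ", drive$phase, call. = FALSE))
  dw <- if (config$isolated_lung) 0 else
    (ppl - cwp$evacuation_pressure -
       (.k_head(config) + cwp$static_recoil_elastance) * w) /
      config$abdomen$valve_resistance
  list(d_lung_volume = flow, d_displaced_water = dw,
       pleural_pressure = ppl, alveolar_pressure = palv, flow = flow)
}

#' Advance the model state by one integrator step
#'
#' Classical fixed-step 4th-order Runge-Kutta on (lung volume, displaced
#' water), with pleural pressure solved algebraically at every stage so the
#' pleural gas amount is conserved exactly. Intended for unit-scale checks;
#' long simulations use the compiled core via [simulate_breaths()].
#'
#' @inheritParams derivatives
#' @param dt step length, s; must not exceed `config$integrator_dt`.
#' @return the advanced `model_state`.
#' @export
step_state <- function(state, config, dt = config$integrator_dt,
                       drive = list(phase = "expiration", peep = 0)) {
  if (dt > config$integrator_dt + 1e-12)
    stop("dt must not exceed integrator_dt", call. = FALSE)
  v <- state$lung_volume; w <- state$displaced_water
  f <- function(v, w) {
    d <- derivatives(list(lung_volume = v, displaced_water = w), config, drive)
    c(d$d_lung_volume, d$d_displaced_water)
  }
  k1 <- f(v, w)
  k2 <- f(v + dt / 2 * k1[1], w + dt / 2 * k1[2])
  k3 <- f(v + dt / 2 * k2[1], w + dt / 2 * k2[2])
  k4 <- f(v + dt * k3[1], w + dt * k3[2])
  v2 <- v + dt / 6 * (k1[1] + 2 * k2[1] + 2 * k3[1] + k4[1])
  w2 <- w + dt / 6 * (k1[2] + 2 * k2[2] + 2 * k3[2] + k4[2])
  cap <- config$lung$n_units * config$lung$capacity_per_unit
  if (v2 > cap)
    stop("capacity error: lung volume ", round(v2, 1), " ml exceeds ", cap,
         " ml", call. = FALSE)
  d <- derivatives(list(lung_volume = v2, displaced_water = w2), config, drive)
  structure(list(time = state$time + dt, lung_volume = v2,
                 displaced_water = w2, pleural_pressure = d$pleural_pressure,
                 airway_pressure = d$alveolar_pressure,
                 ventilator_phase = drive$phase),
            class = "model_state")
}

#' Simulate ventilated breaths
#'
#' Runs the compiled fixed-step model for one PEEP value per breath and
#' returns the 100 Hz multi-channel record. The flow channel is the
#' interval-averaged airway flow over each 10 ms sample interval
#' (inspiratory positive); pressures and lung volume are instantaneous.
#'
#' @param config a `model_config`.
#' @param peep_per_breath numeric vector, one commanded PEEP (cmH2O) per
#'   breath.
#' @param init optional `model_state` to start from; default
#'   [initial_state_at_frc()].
#' @param keep_state keep the internal displaced-water channel (`w`) in the
#'   output (used by conservation checks).
#' @return a `data.frame` of class `peep_waveforms` with columns `time`,
#'   `paw`, `ppl`, `flow`, `vlung`, `phase` (1 inspiration, 2 pause,
#'   3 expiration), `breath` and attributes `sample_rate`, `config`,
#'   `final_state`, `peep_per_breath`.  If the lung capacity is exceeded the
#'   function throws a condition of class `peepstep_capacity_error` whose
#'   `breath` field names the offending breath.
#' @export
simulate_breaths <- function(config, peep_per_breath, init = NULL,
                             keep_state = FALSE) {
  stopifnot(inherits(config, "model_config"), length(peep_per_breath) >= 1)
  if (is.null(init)) init <- initial_state_at_frc(config)
  res <- .sim_breaths_cpp(.core_par(config), as.numeric(peep_per_breath),
                          init$lung_volume, init$displaced_water)
  if (isTRUE(res$capacity_error)) {
    cond <- structure(class = c("peepstep_capacity_error", "error", "condition"),
                      list(message = paste0("capacity error: lung volume exceeded ",
                                            config$lung$n_units *
                                              config$lung$capacity_per_unit,
                                            " ml in breath ", res$capacity_breath),
                           call = sys.call(-1), breath = res$capacity_breath))
    stop(cond)
  }
  wf <- data.frame(time = res$time, paw = res$paw, ppl = res$ppl,
                   flow = res$flow, vlung = res$vlung, phase = res$phase,
                   breath = res$breath)
  if (keep_state) wf$w <- res$w
  structure(wf,
            class = c("peep_waveforms", "data.frame"),
            sample_rate = 100, config = config,
            peep_per_breath = as.numeric(peep_per_breath),
            final_state = structure(list(
              time = max(res$time) + 0.01, lung_volume = res$v_final,
              displaced_water = res$w_final,
              pleural_pressure = pleural_pressure(config, res$v_final, res$w_final),
              airway_pressure = NA_real_, ventilator_phase = "expiration"),
              class = "model_state"))
}

#' Apneic hold at constant airway pressure
#'
#' Holds the airway at a constant pressure with no tidal ventilation (CPAP),
#' letting the lung and the hydraulic abdomen settle. The long-time limit of
#' this run is the static equilibrium computed by [equilibrium_solver()].
#'
#' @param config a `model_config`.
#' @param pressure airway pressure, cmH2O.
#' @param duration hold time, s.
#' @param init optional starting `model_state`.
#' @return list with `trace` (100 Hz data.frame: `time`, `ppl`, `vlung`,
#'   `w`) and `state` (final `model_state`).
#' @export
hold_at_pressure <- function(config, pressure, duration = 120, init = NULL) {
  stopifnot(inherits(config, "model_config"))
  if (is.null(init)) init <- initial_state_at_frc(config)
  res <- .sim_hold_cpp(.core_par(config), pressure, duration,
                       init$lung_volume, init$displaced_water)
  list(trace = data.frame(time = res$time, ppl = res$ppl, vlung = res$vlung,
                          w = res$w),
       state = structure(list(time = duration, lung_volume = res$v_final,
                              displaced_water = res$w_final,
                              pleural_pressure = if (config$isolated_lung) 0 else
                                pleural_pressure(config, res$v_final, res$w_final),
                              airway_pressure = pressure,
                              ventilator_phase = "pause"),
                         class = "model_state"))
}

#' Static equilibrium at a PEEP level
#'
#' Closed-form statics of the model held at a constant airway pressure: the
#' lung recoil, the hydraulic head across the open valve and the pleural gas
#' law are solved simultaneously. In the linear-lung case this reduces to
#' `dEELV = dPEEP / (EL + Ecw_stat)` with `Ecw_stat` the effective static
#' chest-wall elastance (geometric head stiffness plus residual recoil,
#' shunted by gas and wall storage compliance).
#'
#' @param config a `model_config`.
#' @param peep airway pressure, cmH2O (>= 0).
#' @return list with `delta_eelv` (ml above the apneic FRC), `lung_volume`
#'   (ml above residual), `pleural_pressure`, `transpulmonary_pressure`
#'   (cmH2O) and `displaced_water` (ml).
#' @export
equilibrium_solver <- function(config, peep) {
  stopifnot(inherits(config, "model_config"), peep >= 0)
  cwp <- config$chest_wall
  v0 <- .v_of_ptp(config, -cwp$evacuation_pressure)
  if (config$isolated_lung) {
    v <- .v_of_ptp(config, peep)
    return(list(delta_eelv = v - .v_of_ptp(config, 0), lung_volume = v,
                pleural_pressure = 0, transpulmonary_pressure = peep,
                displaced_water = 0))
  }
  kappa <- .k_head(config) + cwp$static_recoil_elastance
  patm <- cwp$atmospheric_pressure
  ngas <- (patm + cwp$evacuation_pressure) * cwp$pleural_gas_volume
  # residual of the coupled statics as a function of pleural pressure
  resid <- function(ppl) {
    v <- .v_of_ptp(config, peep - ppl)
    w <- (ppl - cwp$evacuation_pressure) / kappa    # zero valve flow
    vg <- ngas / (patm + ppl)                        # gas law
    # gas volume bookkeeping must close
    vg - (cwp$pleural_gas_volume - (v - v0) + w +
            cwp$wall_compliance * (ppl - cwp$evacuation_pressure))
  }
  ppl <- stats::uniroot(resid, lower = cwp$evacuation_pressure - 1,
                        upper = max(peep, 0) + 1, tol = 1e-10)$root
  v <- .v_of_ptp(config, peep - ppl)
  cap <- config$lung$n_units * config$lung$capacity_per_unit
  if (v > cap)
    stop("capacity error: equilibrium lung volume ", round(v, 1),
         " ml exceeds ", cap, " ml", call. = FALSE)
  list(delta_eelv = v - v0, lung_volume = v, pleural_pressure = ppl,
       transpulmonary_pressure = peep - ppl,
       displaced_water = (ppl - cwp$evacuation_pressure) / kappa)
}

#' Calibrate wall compliance against a tidal chest-wall elastance target
#'
#' Adjusts the container wall (bulging) compliance by bisection until the
#' simulated tidal chest-wall elastance `dPPL/VT` at ZEEP matches the
#' target. Valve resistance is held fixed. Deterministic: fixed bracket,
#' noise-free simulation, converges when the simulated value is within
#' `tol` of the target.
#'
#' @param config a `model_config`.
#' @param target_tidal_ecw target `dPPL/VT` at ZEEP, cmH2O/L.
#' @param tol acceptance tolerance, cmH2O/L.
#' @param n_breaths breaths simulated per evaluation (the last breath is
#'   measured; the default reaches periodic steady state).
#' @return the calibrated `model_config`.
#' @export
calibrate_chest_wall <- function(config, target_tidal_ecw, tol = 0.2,
                                 n_breaths = 12) {
  stopifnot(inherits(config, "model_config"))
  e_stat <- 1000 * effective_static_elastance(config)
  if (target_tidal_ecw <= e_stat)
    stop("target must exceed the static chest-wall elastance (",
         round(e_stat, 2), " cmH2O/L)", call. = FALSE)
  measure <- function(cw) {
    cfg <- config
    cfg$chest_wall$wall_compliance <- cw
    wf <- simulate_breaths(cfg, rep(0, n_breaths))
    br <- segment_breaths(wf)
    b <- br[nrow(br), ]
    (b$ppl_ei - b$ppl_ee) / b$vti * 1000
  }
  lo <- 1; hi <- 300
  f_lo <- measure(lo); f_hi <- measure(hi)
  # dPPL/VT decreases as the wall gets more compliant
  if ((f_lo - target_tidal_ecw) * (f_hi - target_tidal_ecw) > 0)
    stop("calibration error: target ", target_tidal_ecw,
         " cmH2O/L not attainable within the wall-compliance bracket",
         call. = FALSE)
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    f_mid <- measure(mid)
    if (abs(f_mid - target_tidal_ecw) < tol / 4 || (hi - lo) < 1e-3) break
    if ((f_lo - target_tidal_ecw) * (f_mid - target_tidal_ecw) <= 0) {
      hi <- mid
    } else {
      lo <- mid; f_lo <- f_mid
    }
  }
  config$chest_wall$wall_compliance <- mid
  config
}

#' Effective static end-expiratory chest-wall elastance
#'
#' The elastance relating a sustained end-expiratory lung volume change to
#' the end-expiratory pleural pressure change once the hydraulic abdomen has
#' equilibrated: `kappa / (1 + kappa * (G + Cw))`, in cmH2O/ml.
#'
#' @param config a `model_config`.
#' @return elastance in cmH2O/ml (multiply by 1000 for cmH2O/L).
#' @export
effective_static_elastance <- function(config) {
  kappa <- .k_head(config) + config$chest_wall$static_recoil_elastance
  storage <- .gas_compliance(config) + config$chest_wall$wall_compliance
  kappa / (1 + kappa * storage)
}
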