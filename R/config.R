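#' Test-lung parameters
#'
#' Parameters of the parallel elastic test lungs used as the recoiling lung
#' in the bench model. One, two or three units in parallel give a nominal
#' total compliance of 19, 38 or 57 ml/cmH2O.
#'
#' @param n_units number of parallel test lungs (1, 2 or 3).
#' @param compliance_per_unit nominal compliance of one unit, ml/cmH2O.
#' @param residual_volume lung volume at zero transpulmonary pressure, ml.
#'   Volumes elsewhere in the package are reported above this residual.
#' @param capacity_per_unit hard volume ceiling of one test lung, ml. A
#'   simulated breath that would exceed `n_units * capacity_per_unit` raises a
#'   capacity error, which protocol runners convert into step omission.
#' @param airway_resistance resistance of the airway/tubing between the
#'   ventilator Y-piece and the lungs, cmH2O·s/ml.
#' @param pv_table optional two-column matrix/data.frame (`ptp`, `volume`)
#'   giving a measured total lung pressure/volume curve (volume above
#'   residual, ml, vs transpulmonary pressure, cmH2O). Default `NULL` uses
#'   the nominal linear curve `V = n_units * compliance_per_unit * PTP`.
#' @return a list of class `lung_params`.
#' @export
lung_params <- function(n_units = 2, compliance_per_unit = 19,
                        residual_volume = 0, capacity_per_unit = 600,
                        airway_resistance = 0.003, pv_table = NULL) {
  if (!n_units %in% 1:3)
    stop("n_units must be 1, 2 or 3", call. = FALSE)
  if (compliance_per_unit <= 0) stop("compliance_per_unit must be > 0", call. = FALSE)
  if (capacity_per_unit <= 0) stop("capacity_per_unit must be > 0", call. = FALSE)
  if (!is.null(pv_table)) {
    pv_table <- as.data.frame(pv_table)
    names(pv_table) <- c("ptp", "volume")
    if (any(diff(pv_table$ptp) <= 0) || any(diff(pv_table$volume) <= 0))
      stop("pv_table must be strictly increasing in both columns", call. = FALSE)
  }
  structure(list(n_units = as.integer(n_units),
                 compliance_per_unit = compliance_per_unit,
                 residual_volume = residual_volume,
                 capacity_per_unit = capacity_per_unit,
                 airway_resistance = airway_resistance,
                 pv_table = pv_table),
            class = "lung_params")
}

#' Pleural-space / chest-wall parameters
#'
#' The "chest wall" of the bench model is the sealed gas space above the
#' water in the semi-stiff plastic container plus the lung box and tubing.
#' Evacuating it to `evacuation_pressure` creates the contra-directional
#' recoil/spring-out forces. Its tidal stiffness comes from compressing this
#' gas (and slightly bulging the container walls); its end-expiratory
#' stiffness is hydraulic and set by the abdomen geometry plus
#' `static_recoil_elastance`.
#'
#' @param pleural_gas_volume gas volume of the pleural space at baseline, ml.
#' @param wall_compliance bulging compliance of the container walls,
#'   ml/cmH2O; reduced by strapping (stiff chest wall).
#' @param strapped logical; `TRUE` for the strapped, stiff chest wall.
#' @param atmospheric_pressure absolute ambient pressure, cmH2O.
#' @param evacuation_pressure pleural pressure after suction, cmH2O gauge.
#' @param static_recoil_elastance residual static recoil term, cmH2O/ml,
#'   added to the purely geometric hydraulic head stiffness so that the
#'   model's end-expiratory chest-wall elastance matches the bench (see
#'   [calibrate_static_recoil()]).
#' @return a list of class `chest_wall_params`.
#' @export
chest_wall_params <- function(pleural_gas_volume = 15000, wall_compliance = 35,
                              strapped = FALSE, atmospheric_pressure = 1033,
                              evacuation_pressure = -5,
                              static_recoil_elastance = 0) {
  if (pleural_gas_volume <= 0) stop("pleural_gas_volume must be > 0", call. = FALSE)
  if (wall_compliance < 0) stop("wall_compliance must be >= 0", call. = FALSE)
  structure(list(pleural_gas_volume = pleural_gas_volume,
                 wall_compliance = wall_compliance,
                 strapped = isTRUE(strapped),
                 atmospheric_pressure = atmospheric_pressure,
                 evacuation_pressure = evacuation_pressure,
                 static_recoil_elastance = static_recoil_elastance),
            class = "chest_wall_params")
}

#' Hydraulic abdomen parameters
#'
#' A water-filled container (the "diaphragm", area 1500 cm2) drains through a
#' resistive valve into a plastic 10 l sack (upper surface 1800 cm2)
#' representing the abdomen. Because the sack walls are plastic, the pressure
#' at its surface is atmospheric, and moving water container-to-sack lowers
#' the hydraulic head by `fluid_column_factor * (1/container_area +
#' 1/sack_area)` cmH2O per ml; this geometric term is the rib-cage spring-out
#' analogue and dominates the static end-expiratory chest-wall elastance.
#'
#' @param container_area water surface area in the container, cm2.
#' @param sack_area upper surface area of the abdominal sack, cm2.
#' @param sack_volume volume of the sack, ml (bookkeeping only).
#' @param valve_resistance hydraulic resistance of the connecting valve,
#'   cmH2O·s/ml. Sets the slow time constant of the post-PEEP-step pleural
#'   relaxation (default gives ~10 s, i.e. equilibration within 10-15
#'   breaths).
#' @param fluid_column_factor cmH2O per cm of water column (1 for water).
#' @return a list of class `abdomen_params`.
#' @export
abdomen_params <- function(container_area = 1500, sack_area = 1800,
                           sack_volume = 10000, valve_resistance = 0.1,
                           fluid_column_factor = 1) {
  if (container_area <= 0 || sack_area <= 0 || valve_resistance <= 0)
    stop("container_area, sack_area and valve_resistance must be > 0",
         call. = FALSE)
  structure(list(container_area = container_area, sack_area = sack_area,
                 sack_volume = sack_volume,
                 valve_resistance = valve_resistance,
                 fluid_column_factor = fluid_column_factor),
            class = "abdomen_params")
}

#' Volume-controlled ventilator settings
#'
#' Square inspiratory flow delivering `tidal_volume` over the flow portion of
#' inspiration, an end-inspiratory pause, and passive expiration through a
#' one-way PEEP-regulated valve. Phase durations are rounded to the 10 ms
#' record grid: at the default 15/min and I:E 1:2 the 4 s cycle splits into
#' 0.93 s flow + 0.40 s pause + 2.67 s expiration.
#'
#' @param tidal_volume ml.
#' @param respiratory_rate breaths/min.
#' @param ie_ratio expiratory-to-inspiratory time ratio (2 means I:E = 1:2).
#' @param pause_fraction end-inspiratory pause as a fraction of the cycle.
#' @param peep end-expiratory pressure target of the expiratory valve, cmH2O.
#' @param expiratory_resistance resistance of the expiratory limb + valve,
#'   cmH2O·s/ml.
#' @return a list of class `ventilator_settings` with derived phase durations
#'   `t_flow`, `t_pause`, `t_exp` (s).
#' @export
ventilator_settings <- function(tidal_volume = 300, respiratory_rate = 15,
                                ie_ratio = 2, pause_fraction = 0.10, peep = 0,
                                expiratory_resistance = 0.007) {
  if (tidal_volume <= 0) stop("tidal_volume must be > 0", call. = FALSE)
  t_cycle <- 60 / respiratory_rate
  t_insp <- t_cycle / (1 + ie_ratio)
  t_pause <- pause_fraction * t_cycle
  if (t_pause >= t_insp)
    stop("pause_fraction must leave a positive inspiratory flow phase",
         call. = FALSE)
  # align phase boundaries with the 10 ms sampling grid
  grid <- function(x) round(x / 0.01) * 0.01
  t_insp <- grid(t_insp); t_pause <- grid(t_pause); t_cycle <- grid(t_cycle)
  structure(list(tidal_volume = tidal_volume,
                 respiratory_rate = respiratory_rate,
                 ie_ratio = ie_ratio, pause_fraction = pause_fraction,
                 peep = peep, expiratory_resistance = expiratory_resistance,
                 t_cycle = t_cycle, t_flow = t_insp - t_pause,
                 t_pause = t_pause, t_exp = t_cycle - t_insp),
            class = "ventilator_settings")
}

#' Full model configuration
#'
#' @param lung a [lung_params()] object.
#' @param chest_wall a [chest_wall_params()] object.
#' @param abdomen an [abdomen_params()] object.
#' @param ventilator a [ventilator_settings()] object.
#' @param integrator_dt fixed integrator step, s (must divide 10 ms).
#' @param record_rate sampling rate of recorded waveforms, Hz.
#' @param isolated_lung logical; `TRUE` ventilates the lung open to
#'   atmosphere (pleural pressure identically zero, airway pressure equals
#'   transpulmonary pressure).
#' @return a list of class `model_config`.
#' @export
model_config <- function(lung = lung_params(), chest_wall = chest_wall_params(),
                         abdomen = abdomen_params(),
                         ventilator = ventilator_settings(),
                         integrator_dt = 0.001, record_rate = 100,
                         isolated_lung = FALSE) {
  stopifnot(inherits(lung, "lung_params"),
            inherits(chest_wall, "chest_wall_params"),
            inherits(abdomen, "abdomen_params"),
            inherits(ventilator, "ventilator_settings"))
  if (integrator_dt > 0.01) stop("integrator_dt must be <= 0.01 s", call. = FALSE)
  n_sub <- 0.01 / integrator_dt
  if (abs(n_sub - round(n_sub)) > 1e-9)
    stop("integrator_dt must divide the 10 ms record interval", call. = FALSE)
  if (record_rate != 100)
    stop("record_rate is fixed at 100 Hz in this implementation", call. = FALSE)
  structure(list(lung = lung, chest_wall = chest_wall, abdomen = abdomen,
                 ventilator = ventilator, integrator_dt = integrator_dt,
                 record_rate = record_rate, isolated_lung = isTRUE(isolated_lung)),
            class = "model_config")
}

# Frozen calibrated wall compliances (ml/cmH2O), obtained once by running
# calibrate_chest_wall() on the two-test-lung arm at ZEEP against the bench
# tidal chest-wall elastance targets of 18 (normal) and 24 (strapped) cmH2O/L.
.default_wall_compliance <- function(mode) {
  switch(mode, normal = 35.747, stiff = 21.585,
         stop("unknown chest wall mode: ", mode, call. = FALSE))
}

#' Default calibrated configuration of one experimental arm
#'
#' Returns the fully populated configuration for `n_lungs` parallel test
#' lungs with a normal or strapped (stiff) chest wall. Wall compliance is
#' pre-calibrated so that simulated tidal chest-wall elastance at ZEEP is 18
#' (normal) or 24 (stiff) cmH2O/L, and the residual static recoil term is
#' set analytically (see [calibrate_static_recoil()]) so that the
#' end-expiratory chest-wall elastance is 1.5 cmH2O/L (compliance ~667
#' ml/cmH2O).
#'
#' @param n_lungs 1, 2 or 3 parallel test lungs (nominal total compliance
#'   19, 38 or 57 ml/cmH2O).
#' @param chest_wall_mode `"normal"` or `"stiff"`.
#' @return a `model_config`.
#' @export
make_default_config <- function(n_lungs, chest_wall_mode = c("normal", "stiff")) {
  if (length(chest_wall_mode) != 1 || !chest_wall_mode %in% c("normal", "stiff"))
    chest_wall_mode <- match.arg(chest_wall_mode)
  cw <- .default_wall_compliance(chest_wall_mode)
  cfg <- model_config(
    lung = lung_params(n_units = n_lungs),
    chest_wall = chest_wall_params(wall_compliance = cw,
                                   strapped = chest_wall_mode == "stiff"),
    abdomen = abdomen_params(),
    ventilator = ventilator_settings())
  calibrate_static_recoil(cfg, target_ee_ecw = 1.5)
}

#' Switch a configuration to isolated-lung ventilation
#'
#' The test lungs are disconnected from the pleural/abdominal compartments
#' and ventilated open to atmosphere, so pleural pressure is identically
#' zero and airway pressure equals transpulmonary pressure.
#'
#' @param config a `model_config`.
#' @return the configuration with `isolated_lung = TRUE`.
#' @export
isolated_lung_mode <- function(config) {
  stopifnot(inherits(config, "model_config"))
  config$isolated_lung <- TRUE
  config
}

# geometric hydraulic-head stiffness, cmH2O per ml of displaced water
.k_head <- function(config) {
  ab <- config$abdomen
  ab$fluid_column_factor * (1 / ab$container_area + 1 / ab$sack_area)
}

# gas storage compliance of the pleural space at baseline, ml/cmH2O
.gas_compliance <- function(config) {
  cwp <- config$chest_wall
  cwp$pleural_gas_volume /
    (cwp$atmospheric_pressure + cwp$evacuation_pressure)
}

#' Calibrate the residual static recoil term
#'
#' The purely geometric hydraulic stiffness of the abdomen is
#' `1/1500 + 1/1800 = 1.22` cmH2O/L of displaced water, but part of any
#' end-expiratory volume change is absorbed by pleural gas compression and
#' container-wall bulging, so the effective end-expiratory chest-wall
#' elastance seen at the lung is `kappa / (1 + kappa * (G + Cw))` with
#' `kappa` the total hydraulic stiffness, `G` the pleural gas compliance and
#' `Cw` the wall compliance. This function solves that relation for the
#' residual recoil term so the effective elastance matches `target_ee_ecw`
#' (the bench measured ~1.5 cmH2O/L). Use `target_ee_ecw = NULL` for the
#' geometric-only model (residual term zero).
#'
#' @param config a `model_config`.
#' @param target_ee_ecw target effective end-expiratory chest-wall
#'   elastance, cmH2O/L, or `NULL`.
#' @return the configuration with `static_recoil_elastance` set.
#' @export
calibrate_static_recoil <- function(config, target_ee_ecw = 1.5) {
  stopifnot(inherits(config, "model_config"))
  if (is.null(target_ee_ecw)) {
    config$chest_wall$static_recoil_elastance <- 0
    return(config)
  }
  et <- target_ee_ecw / 1000              # cmH2O/ml
  storage <- .gas_compliance(config) + config$chest_wall$wall_compliance
  if (et * storage >= 1)
    stop("target end-expiratory elastance unattainable with this storage compliance",
         call. = FALSE)
  kappa <- et / (1 - et * storage)
  krec <- kappa - .k_head(config)
  if (krec < 0)
    stop("target end-expiratory elastance below the geometric minimum", call. = FALSE)
  config$chest_wall$static_recoil_elastance <- krec
  config
}

# lung P/V interpolation tables (total volume above residual vs PTP)
.lung_tables <- function(config) {
  lp <- config$lung
  if (is.null(lp$pv_table)) {
    cl <- lp$n_units * lp$compliance_per_unit
    list(ptab = c(0, 50), vtab = c(0, 50 * cl))
  } else {
    list(ptab = lp$pv_table$ptp, vtab = lp$pv_table$volume)
  }
}

# flat parameter list handed to the C++ core
.core_par <- function(config) {
  lp <- config$lung; cwp <- config$chest_wall; ab <- config$abdomen
  vs <- config$ventilator; tabs <- .lung_tables(config)
  list(n_units = lp$n_units, cap_per_unit = lp$capacity_per_unit,
       r_aw = lp$airway_resistance, ptab = tabs$ptab, vtab = tabs$vtab,
       vg0 = cwp$pleural_gas_volume, cw = cwp$wall_compliance,
       patm = cwp$atmospheric_pressure, pev = cwp$evacuation_pressure,
       krec = cwp$static_recoil_elastance, k_head = .k_head(config),
       r_valve = ab$valve_resistance, isolated = config$isolated_lung,
       vt = vs$tidal_volume, t_flow = vs$t_flow, t_pause = vs$t_pause,
       t_exp = vs$t_exp, r_exp = vs$expiratory_resistance,
       dt = config$integrator_dt)
}

# total lung volume above residual at a transpulmonary pressure (vector ok)
.v_of_ptp <- function(config, ptp) {
  tabs <- .lung_tables(config)
  .interp_extrap(tabs$ptab, tabs$vtab, ptp)
}

# transpulmonary pressure at a total lung volume above residual
.ptp_of_v <- function(config, v) {
  tabs <- .lung_tables(config)
  .interp_extrap(tabs$vtab, tabs$ptab, v)
}

.interp_extrap <- function(x, y, xq) {
  n <- length(x)
  out <- stats::approx(x, y, xout = xq, rule = 2)$y
  lo <- xq < x[1]
  hi <- xq > x[n]
  if (any(lo)) out[lo] <- y[1] + (y[2] - y[1]) / (x[2] - x[1]) * (xq[lo] - x[1])
  if (any(hi)) out[hi] <- y[n] + (y[n] - y[n - 1]) / (x[n] - x[n - 1]) * (xq[hi] - x[n])
  out
}

#' Write / read a model configuration as YAML
#'
#' The YAML schema mirrors the constructor arguments section by section
#' (`lung`, `chest_wall`, `abdomen`, `ventilator`, plus `integrator_dt`,
#' `isolated_lung`).
#'
#' @param config a `model_config`.
#' @param path file path.
#' @return `read_model_config` returns a `model_config`;
#'   `write_model_config` returns `path` invisibly.
#' @export
write_model_config <- function(config, path) {
  stopifnot(inherits(config, "model_config"))
  x <- lapply(config[c("lung", "chest_wall", "abdomen", "ventilator")],
              function(s) {
                s <- unclass(s)
                s[!vapply(s, is.null, logical(1))]
              })
  x$lung$pv_table <- if (!is.null(config$lung$pv_table))
    as.list(config$lung$pv_table)
  x$lung <- x$lung[!vapply(x$lung, is.null, logical(1))]
  x$ventilator <- x$ventilator[setdiff(names(x$ventilator),
                                       c("t_cycle", "t_flow", "t_pause", "t_exp"))]
  x$integrator_dt <- config$integrator_dt
  x$record_rate <- config$record_rate
  x$isolated_lung <- config$isolated_lung
  yaml::write_yaml(x, path, precision = 12)
  invisible(path)
}

#' @rdname write_model_config
#' @export
read_model_config <- function(path) {
  x <- yaml::read_yaml(path)
  need <- c("lung", "chest_wall", "abdomen", "ventilator")
  missing <- setdiff(need, names(x))
  if (length(missing))
    stop("config file is missing sections: ", paste(missing, collapse = ", "),
         call. = FALSE)
  lung <- x$lung
  if (!is.null(lung$pv_table)) lung$pv_table <- as.data.frame(lung$pv_table)
  model_config(
    lung = do.call(lung_params, lung),
    chest_wall = do.call(chest_wall_params, x$chest_wall),
    abdomen = do.call(abdomen_params, x$abdomen),
    ventilator = do.call(ventilator_settings, x$ventilator),
    integrator_dt = x$integrator_dt %||% 0.001,
    record_rate = x$record_rate %||% 100,
    isolated_lung = isTRUE(x$isolated_lung))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
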