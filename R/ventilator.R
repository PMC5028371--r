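#' Ventilator phase and prescribed flow at a time within the cycle
#'
#' Volume-controlled ventilation: constant (square) inspiratory flow
#' delivering the tidal volume over the flow portion of inspiration, an
#' end-inspiratory pause occupying the terminal part of the inspiratory
#' time, and passive expiration through the PEEP-regulated valve.
#'
#' @param settings a [ventilator_settings()] object.
#' @param t_in_cycle time since the start of the breath, s (in
#'   `[0, t_cycle)`).
#' @return list with `phase` (`"inspiration"`, `"pause"`, `"expiration"`)
#'   and `flow` (prescribed inspiratory flow, ml/s; 0 outside the flow
#'   phase).
#' @export
breath_phase <- function(settings, t_in_cycle) {
  stopifnot(inherits(settings, "ventilator_settings"))
  if (t_in_cycle < 0 || t_in_cycle >= settings$t_cycle)
    stop("t_in_cycle must lie in [0, cycle time)", call. = FALSE)
  if (t_in_cycle < settings$t_flow) {
    list(phase = "inspiration", flow = settings$tidal_volume / settings$t_flow)
  } else if (t_in_cycle < settings$t_flow + settings$t_pause) {
    list(phase = "pause", flow = 0)
  } else {
    list(phase = "expiration", flow = 0)
  }
}

#' Expiratory valve flow
#'
#' Passive expiration through a one-way valve regulated at the PEEP target:
#' flow is `(Paw - PEEP) / expiratory_resistance` when airway pressure
#' exceeds PEEP and zero otherwise, so the valve never lets airway pressure
#' fall below PEEP.
#'
#' @param airway_pressure cmH2O at the valve.
#' @param settings a [ventilator_settings()] object.
#' @return expired flow, ml/s (>= 0).
#' @export
expiratory_valve_flow <- function(airway_pressure, settings) {
  stopifnot(inherits(settings, "ventilator_settings"))
  pmax(0, (airway_pressure - settings$peep) / settings$expiratory_resistance)
}
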