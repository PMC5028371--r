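#' Segment a waveform record into breaths
#'
#' Breaths are delimited at inspiration onsets. In noise-free records the
#' phase annotation is used directly; with `method = "threshold"` onsets are
#' detected as the flow crossing +25 ml/s sustained for 100 ms, as a
#' pneumotachograph-based system would do without a phase channel.
#'
#' For every breath the inspired and expired tidal volumes are the
#' summations of flow samples over the inspiratory (flow + pause) and
#' expiratory phases, and the end-expiratory / end-inspiratory pressures are
#' means over the final 100 ms of expiration and of the pause plateau.
#'
#' @param waveforms a `peep_waveforms` record.
#' @param method `"phase"` (default) or `"threshold"`.
#' @param threshold flow threshold, ml/s (threshold method).
#' @param hold_ms required hold above threshold, ms (threshold method).
#' @return a `data.frame`, one row per complete breath: `breath`,
#'   `start_sample`, `end_sample`, `vti`, `vte` (ml), `paw_ee`, `ppl_ee`,
#'   `paw_ei`, `ppl_ei` (cmH2O) and ground-truth end-expiratory /
#'   end-inspiratory lung volumes `vlung_ee`, `vlung_ei` (ml). Returns zero
#'   rows if no complete breath is present.
#' @export
segment_breaths <- function(waveforms, method = c("phase", "threshold"),
                            threshold = 25, hold_ms = 100) {
  method <- match.arg(method)
  wf <- waveforms
  dt <- 1 / attr(wf, "sample_rate")
  if (method == "phase") {
    onsets <- which(wf$phase == 1 & c(TRUE, wf$phase[-nrow(wf)] != 1))
  } else {
    hold_n <- round(hold_ms / 1000 / dt)
    above <- wf$flow > threshold
    run <- stats::filter(as.numeric(above), rep(1, hold_n), sides = 1)
    sustained <- !is.na(run) & run == hold_n
    # onset = first sample of each sustained crossing
    starts <- which(sustained & !c(FALSE, sustained[-length(sustained)]))
    onsets <- starts - hold_n + 1
    onsets <- onsets[c(TRUE, diff(onsets) > hold_n)]
  }
  if (length(onsets) < 2) {
    return(data.frame(breath = integer(), start_sample = integer(),
                      end_sample = integer(), vti = numeric(), vte = numeric(),
                      paw_ee = numeric(), ppl_ee = numeric(),
                      paw_ei = numeric(), ppl_ei = numeric(),
                      vlung_ee = numeric(), vlung_ei = numeric()))
  }
  ends <- c(onsets[-1] - 1, nrow(wf))
  win <- round(0.1 / dt)                   # 100 ms read-out windows
  # a breath is complete when it contains a pause and a full end-expiratory
  # read-out window of expiration
  complete <- Filter(function(i) {
    ph <- wf$phase[onsets[i]:ends[i]]
    any(ph == 2) && sum(ph == 3) >= win && utils::tail(ph, 1) == 3
  }, seq_along(onsets))
  out <- lapply(as.integer(complete), function(i) {
    idx <- onsets[i]:ends[i]
    ph <- wf$phase[idx]
    insp <- idx[ph %in% c(1, 2)]
    pause <- idx[ph == 2]
    expn <- idx[ph == 3]
    ee <- utils::tail(expn, win)
    ei <- utils::tail(pause, win)
    data.frame(breath = i, start_sample = onsets[i], end_sample = ends[i],
               vti = sum(wf$flow[insp]) * dt,
               vte = -sum(wf$flow[expn]) * dt,
               paw_ee = mean(wf$paw[ee]), ppl_ee = mean(wf$ppl[ee]),
               paw_ei = mean(wf$paw[ei]), ppl_ei = mean(wf$ppl[ei]),
               vlung_ee = mean(wf$vlung[ee]), vlung_ei = mean(wf$vlung[ei]))
  })
  out <- do.call(rbind, out)
  out$breath <- seq_len(nrow(out))
  out
}

#' Detect PEEP changes breath by breath
#'
#' The measured PEEP of a breath is the mean airway pressure over the final
#' 100 ms of its expiration. A change is flagged between consecutive
#' breaths whose measured PEEP differs by more than `min_step`.
#'
#' @param waveforms a `peep_waveforms` record.
#' @param breaths optional precomputed [segment_breaths()] table.
#' @param min_step flag threshold, cmH2O.
#' @return `data.frame` with one row per detected change: `breath` (first
#'   breath at the new level), `peep_old`, `peep_new` (cmH2O).
#' @export
detect_peep_changes <- function(waveforms, breaths = NULL, min_step = 1) {
  if (is.null(breaths)) breaths <- segment_breaths(waveforms)
  if (nrow(breaths) < 2)
    return(data.frame(breath = integer(), peep_old = numeric(),
                      peep_new = numeric()))
  peep <- breaths$paw_ee
  j <- which(abs(diff(peep)) > min_step) + 1
  data.frame(breath = breaths$breath[j], peep_old = peep[j - 1],
             peep_new = peep[j])
}

#' Change in end-expiratory lung volume after a PEEP change
#'
#' The bench estimator: the cumulative difference between inspired and
#' expired tidal volume over the first 15 breaths following the PEEP
#' change, compensated for a constant flow-sensor offset estimated as the
#' mean `VTi - VTe` of the five breaths (16-20) that follow the summation
#' window at the new level:
#' `dEELV = sum_{1..15}(VTi - VTe) - 15 * mean_{16..20}(VTi - VTe)`.
#' Positive for PEEP increases.
#'
#' @param waveforms a `peep_waveforms` record.
#' @param change breath index of the first breath at the new level (e.g.
#'   from [detect_peep_changes()]).
#' @param breaths optional precomputed [segment_breaths()] table.
#' @param offset_comp logical; disable to obtain the raw 15-breath sum
#'   (used to demonstrate the offset sensitivity).
#' @return the estimated change in end-expiratory lung volume, ml.
#' @export
delta_eelv <- function(waveforms, change, breaths = NULL, offset_comp = TRUE) {
  if (is.null(breaths)) breaths <- segment_breaths(waveforms)
  need <- change + 19
  if (nrow(breaths) < need)
    stop("estimation error: need 20 breaths after the PEEP change (have ",
         nrow(breaths) - change + 1, ")", call. = FALSE)
  d <- breaths$vti - breaths$vte
  s <- sum(d[change:(change + 14)])
  if (offset_comp) s <- s - 15 * mean(d[(change + 15):(change + 19)])
  s
}

#' Sensor noise settings
#'
#' @param flow_noise_sd per-sample Gaussian noise on the flow channel, ml/s.
#' @param pressure_noise_sd per-sample Gaussian noise on both pressure
#'   channels, cmH2O.
#' @param flow_offset constant flow-sensor bias, ml/s.
#' @param seed integer RNG seed; the same settings and seed always produce
#'   identical noise.
#' @return a list of class `noise_settings`.
#' @export
noise_settings <- function(flow_noise_sd = 2, pressure_noise_sd = 0.1,
                           flow_offset = 0, seed = 0) {
  if (flow_noise_sd < 0 || pressure_noise_sd < 0)
    stop("noise standard deviations must be >= 0", call. = FALSE)
  structure(list(flow_noise_sd = flow_noise_sd,
                 pressure_noise_sd = pressure_noise_sd,
                 flow_offset = flow_offset, seed = as.integer(seed)),
            class = "noise_settings")
}

#' Add sensor noise to a waveform record
#'
#' Independent Gaussian noise per sample on the flow and pressure channels
#' plus a constant flow offset, deterministic under a fixed seed. The
#' ground-truth lung volume channel is left untouched.
#'
#' @param waveforms a `peep_waveforms` record.
#' @param noise a [noise_settings()] object.
#' @return the noisy `peep_waveforms`.
#' @export
add_noise <- function(waveforms, noise) {
  stopifnot(inherits(noise, "noise_settings"))
  wf <- waveforms
  n <- nrow(wf)
  rng <- local({
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(noise$seed)
    list(flow = stats::rnorm(n, 0, max(noise$flow_noise_sd, 0)),
         paw = stats::rnorm(n, 0, max(noise$pressure_noise_sd, 0)),
         ppl = stats::rnorm(n, 0, max(noise$pressure_noise_sd, 0)))
  })
  if (noise$flow_noise_sd > 0) wf$flow <- wf$flow + rng$flow
  if (noise$pressure_noise_sd > 0) {
    wf$paw <- wf$paw + rng$paw
    wf$ppl <- wf$ppl + rng$ppl
  }
  wf$flow <- wf$flow + noise$flow_offset
  wf
}

#' Write / read a waveform record as CSV
#'
#' Plain CSV with one header line and columns `time_s`, `paw_cmH2O`,
#' `ppl_cmH2O`, `flow_ml_s`, `vlung_ml`, `phase`.
#'
#' @param waveforms a `peep_waveforms` record.
#' @param path file path.
#' @return `read_waveforms_csv` returns a `peep_waveforms` data.frame
#'   (without config/final-state attributes); `write_waveforms_csv` returns
#'   `path` invisibly.
#' @export
write_waveforms_csv <- function(waveforms, path) {
  out <- data.frame(time_s = waveforms$time, paw_cmH2O = waveforms$paw,
                    ppl_cmH2O = waveforms$ppl, flow_ml_s = waveforms$flow,
                    vlung_ml = waveforms$vlung, phase = waveforms$phase)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_waveforms_csv
#' @export
read_waveforms_csv <- function(path) {
  x <- utils::read.csv(path)
  wf <- data.frame(time = x$time_s, paw = x$paw_cmH2O, ppl = x$ppl_cmH2O,
                   flow = x$flow_ml_s, vlung = x$vlung_ml, phase = x$phase)
  rate <- 1 / stats::median(diff(wf$time))
  wf$breath <- cumsum(wf$phase == 1 & c(TRUE, wf$phase[-nrow(wf)] != 1))
  structure(wf, class = c("peep_waveforms", "data.frame"),
            sample_rate = round(rate))
}
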