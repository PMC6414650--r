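#' Stimulus parameter set for an amplitude-modulated laser pulse train
#'
#' Bundles the carrier and envelope parameters of one optical stimulation
#' unit: a train of laser pulses at the laser pulse rate (LPR, the carrier)
#' whose per-pulse energy follows a raised sinusoid at the laser modulation
#' rate (LMR, the target acoustic frequency).
#'
#' @param lpr Laser pulse rate (carrier), kHz. The experiments use 32 or 50.
#' @param lmr Laser modulation rate (envelope), kHz; must be below `lpr`.
#' @param duration Unit duration, ms. Default 100.
#' @param ramp Rise and fall ramp time, ms. Default 0.5. A raised-cosine
#'   (Hann half-window) gate is applied over the first and last `ramp` ms.
#' @param peak_power Averaged maximal peak power at the envelope maximum, mW.
#' @param unit_rate Stimulation units per second (5 for the vibration
#'   protocol, 1.86 for the neural protocol). Metadata only.
#'
#' @return An object of class `stim_params` (a named list).
#' @examples
#' stimulus_params(lpr = 50, lmr = 8, peak_power = 200)
#' @export
stimulus_params <- function(lpr, lmr, duration = 100, ramp = 0.5,
                            peak_power = 80, unit_rate = 5) {
  for (nm in c("lpr", "lmr", "duration", "ramp", "peak_power", "unit_rate")) {
    stopifnot_scalar(get(nm), nm)
  }
  if (lpr <= 0 || lmr <= 0) abort("`lpr` and `lmr` must be positive.")
  if (lmr >= lpr) abort("`lmr` must be smaller than `lpr` (carrier above envelope).")
  if (ramp < 0) abort("`ramp` must be non-negative.")
  if (duration <= 2 * ramp) abort("`duration` must exceed twice the ramp time.")
  if (peak_power < 0) abort("`peak_power` must be non-negative.")
  structure(
    list(lpr = lpr, lmr = lmr, duration = duration, ramp = ramp,
         peak_power = peak_power, unit_rate = unit_rate),
    class = "stim_params"
  )
}

#' @export
print.stim_params <- function(x, ...) {
  cat(sprintf(
    "<stim_params> LPR %g kHz, LMR %g kHz, %g ms (ramp %g ms), %g mW peak, %g units/s\n",
    x$lpr, x$lmr, x$duration, x$ramp, x$peak_power, x$unit_rate))
  invisible(x)
}

#' Number of laser pulses per modulation period
#'
#' With the carrier held fixed across modulation rates, the number of pulses
#' under one period of the sinusoidal envelope is the ratio of the two rates
#' and may be fractional (e.g. 3.2 pulses for 32 kHz LPR / 10 kHz LMR).
#'
#' @param lpr Laser pulse rate, kHz.
#' @param lmr Laser modulation rate, kHz.
#' @return `lpr / lmr`, possibly fractional.
#' @examples
#' pulses_per_period(50, 1)  # 50
#' pulses_per_period(32, 10) # 3.2
#' @export
pulses_per_period <- function(lpr, lmr) {
  if (any(!is.finite(lpr)) || any(!is.finite(lmr)) || any(lpr <= 0) || any(lmr <= 0)) {
    abort("`lpr` and `lmr` must be positive.")
  }
  lpr / lmr
}

#' Energy per laser pulse
#'
#' Peak power divided by the pulse rate: mW / kHz = uJ. This reproduces the
#' published power-to-energy bookkeeping for both carriers (e.g. 320 mW at
#' 32 kHz gives 10 uJ per pulse).
#'
#' @param peak_power Averaged maximal peak power, mW.
#' @param lpr Laser pulse rate, kHz.
#' @return Energy per pulse at the envelope maximum, uJ.
#' @examples
#' energy_per_pulse(320, 32) # 10
#' energy_per_pulse(20, 50)  # 0.4
#' @export
energy_per_pulse <- function(peak_power, lpr) {
  if (any(!is.finite(lpr)) || any(lpr <= 0)) abort("`lpr` must be positive.")
  if (any(!is.finite(peak_power)) || any(peak_power < 0)) {
    abort("`peak_power` must be non-negative.")
  }
  peak_power / lpr
}

#' Sinusoidal modulation envelope with on/off ramps
#'
#' The envelope weight `sin(2 * pi * LMR * t) + 1` (range 0..2, starting at 1
#' at onset), multiplied by a raised-cosine (Hann half-window) gate over the
#' first and last `ramp` ms of the unit. Zero outside the unit.
#'
#' @param params A [stimulus_params()] object.
#' @param t Time from unit onset, seconds (vectorised).
#' @return Envelope weights in `[0, 2]`.
#' @export
modulation_envelope <- function(params, t) {
  stopifnot(inherits(params, "stim_params"))
  dur <- params$duration / 1000
  ramp <- params$ramp / 1000
  base <- sin(2 * pi * params$lmr * 1000 * t) + 1
  gate <- rep(1, length(t))
  if (ramp > 0) {
    rise <- t < ramp
    fall <- t > dur - ramp
    gate[rise] <- 0.5 * (1 - cos(pi * t[rise] / ramp))
    gate[fall] <- 0.5 * (1 - cos(pi * (dur - t[fall]) / ramp))
  }
  gate[t < 0 | t > dur] <- 0
  base * gate
}

#' Synthesise an amplitude-modulated pulse train
#'
#' Places pulses on the carrier grid `t_k = k / LPR` for the full unit
#' duration and assigns each the ramped envelope weight and the corresponding
#' pulse energy. The envelope maximum (weight 2) carries the stated peak
#' power, i.e. `energy_k = weight_k / 2 * peak_power / LPR`.
#'
#' @param params A [stimulus_params()] object.
#' @return A tibble of class `pulse_train` with columns `time_s`, `amplitude`
#'   (envelope weight in `[0, 2]`) and `energy_uj`; the parameter set is kept
#'   in the `params` attribute.
#' @examples
#' train <- make_pulse_train(stimulus_params(50, 1, peak_power = 200))
#' nrow(train) # 5000 pulses in 100 ms
#' @export
make_pulse_train <- function(params) {
  stopifnot(inherits(params, "stim_params"))
  lpr_hz <- params$lpr * 1000
  dur <- params$duration / 1000
  k <- seq_len(floor(dur * lpr_hz)) - 1
  time_s <- k / lpr_hz
  amplitude <- modulation_envelope(params, time_s)
  energy_uj <- amplitude / 2 * energy_per_pulse(params$peak_power, params$lpr)
  out <- tibble(time_s = time_s, amplitude = amplitude, energy_uj = energy_uj)
  attr(out, "params") <- params
  class(out) <- c("pulse_train", class(out))
  out
}

#' Render a pulse train onto a dense sample grid
#'
#' Each pulse becomes a single-sample impulse at the nearest grid sample.
#' Sample values follow the energy-preserving convention
#' `amplitude = energy / dt`, so the waveform integrates back to the total
#' train energy. The default rate, 800 kHz, is the least common multiple of
#' the 32 and 50 kHz carriers, placing every pulse exactly on-grid.
#'
#' @param train A [make_pulse_train()] result.
#' @param fs Sampling rate, Hz; must be at least four times the carrier.
#' @return A tibble of class `dense_waveform` with columns `time_s` and
#'   `amplitude` (uJ/s); attributes `fs` and `t0`.
#' @export
render_dense <- function(train, fs = 8e5) {
  stopifnot(inherits(train, "pulse_train"))
  params <- attr(train, "params")
  lpr_hz <- params$lpr * 1000
  if (fs < 4 * lpr_hz) {
    abort(sprintf("fs = %g Hz would alias the %g kHz carrier; need fs >= %g Hz.",
                  fs, params$lpr, 4 * lpr_hz))
  }
  dt <- 1 / fs
  n <- ceiling(params$duration / 1000 * fs)
  samples <- numeric(n)
  if (nrow(train) > 0) {
    idx <- pmin(pmax(round(train$time_s * fs) + 1L, 1L), n)
    for (i in seq_along(idx)) {
      samples[idx[i]] <- samples[idx[i]] + train$energy_uj[i] / dt
    }
  }
  out <- tibble(time_s = (seq_len(n) - 1) / fs, amplitude = samples)
  attr(out, "fs") <- fs
  attr(out, "t0") <- 0
  attr(out, "params") <- params
  class(out) <- c("dense_waveform", class(out))
  out
}
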