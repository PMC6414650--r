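#' Synthetic tonotopic gradient of a 16-channel penetration
#'
#' Best frequencies are log-spaced between `f_lo` and `f_hi` (inclusive),
#' emulating a single-shank electrode placed along the tonotopic gradient of
#' the central nucleus of the inferior colliculus with 100 um inter-channel
#' spacing. Each channel carries a Gaussian tuning curve on the log2
#' frequency axis and an acoustic threshold.
#'
#' @param f_lo,f_hi Best-frequency range, Hz (defaults 1000 and 22000, the
#'   low-frequency electrode position).
#' @param n_channels Number of channels. Default 16.
#' @param tuning_bw Gaussian tuning standard deviation, octaves. Default 0.3.
#' @param acoustic_threshold Acoustic threshold per channel, dB SPL; recycled.
#'   Default 20.
#' @return A tibble of class `tonotopy` with columns `channel`, `bf_hz`,
#'   `threshold_db`; attributes `tuning_bw` and `spacing_um`.
#' @export
synth_tonotopy <- function(f_lo = 1000, f_hi = 22000, n_channels = 16,
                           tuning_bw = 0.3, acoustic_threshold = 20) {
  if (f_lo <= 0 || f_hi <= f_lo) abort("Need 0 < f_lo < f_hi.")
  thr <- rep_len(acoustic_threshold, n_channels)
  if (any(thr < 0 | thr > 80)) abort("Thresholds must lie within 0-80 dB SPL.")
  out <- tibble(
    channel = seq_len(n_channels),
    bf_hz = exp(seq(log(f_lo), log(f_hi), length.out = n_channels)),
    threshold_db = thr
  )
  attr(out, "tuning_bw") <- tuning_bw
  attr(out, "spacing_um") <- 100
  class(out) <- c("tonotopy", class(out))
  out
}

#' Neural response model parameters
#'
#' Governs how the synthetic multi-unit sites respond to stimulation:
#' spontaneous rate, a linear rate-versus-level growth above threshold,
#' saturation of the driven increment, onset latency, and the optical gain
#' mapping laser peak power to an acoustic-equivalent level. The optical
#' gain default anchors 80 mW to 41 dB SPL, the midpoint of the reported
#' 34.6-47.8 dB SPL equivalent-level range.
#'
#' @param spont_rate Spontaneous multi-unit rate, spikes/s. Default 40.
#' @param max_driven_rate Saturation of the driven rate increment, spikes/s.
#'   Default 100.
#' @param rate_growth Driven-rate growth, spikes/s per dB above threshold.
#'   Default 3.
#' @param onset_latency Response latency, ms. Default 5.
#' @param optical_gain Acoustic-equivalent level per unit laser peak power,
#'   dB SPL per mW (linear map through zero). Default `41 / 80`.
#' @return An object of class `response_model`.
#' @export
response_model <- function(spont_rate = 40, max_driven_rate = 100,
                           rate_growth = 3, onset_latency = 5,
                           optical_gain = 41 / 80) {
  if (spont_rate < 0) abort("`spont_rate` must be non-negative.")
  if (max_driven_rate <= 0 || rate_growth < 0) {
    abort("`max_driven_rate` must be positive and `rate_growth` non-negative.")
  }
  structure(list(spont_rate = spont_rate, max_driven_rate = max_driven_rate,
                 rate_growth = rate_growth, onset_latency = onset_latency,
                 optical_gain = optical_gain),
            class = "response_model")
}

#' Stimulus descriptors
#'
#' `acoustic_stim()` describes a pure tone at a sound pressure level;
#' `optical_stim()` describes an amplitude-modulated laser pulse train whose
#' target frequency is the modulation rate and whose level is the peak power.
#' Both default to the 100 ms unit duration and the in-vivo presentation
#' rate of 1.86 stimulation units/s.
#'
#' @param freq Tone frequency, Hz.
#' @param level Sound pressure level, dB SPL.
#' @param lmr Laser modulation rate, kHz.
#' @param lpr Laser pulse rate, kHz. Default 50.
#' @param power Averaged maximal peak power, mW. Default 80.
#' @param duration Stimulus duration, s. Default 0.1.
#' @param rate Stimulation units per second. Default 1.86.
#' @return A list of class `stim_descriptor`.
#' @export
acoustic_stim <- function(freq, level, duration = 0.1, rate = 1.86) {
  stopifnot_scalar(freq, "freq"); stopifnot_scalar(level, "level")
  structure(list(modality = "acoustic", freq_hz = freq, level_db = level,
                 duration = duration, rate = rate),
            class = "stim_descriptor")
}

#' @rdname acoustic_stim
#' @export
optical_stim <- function(lmr, lpr = 50, power = 80, duration = 0.1, rate = 1.86) {
  stopifnot_scalar(lmr, "lmr"); stopifnot_scalar(power, "power")
  structure(list(modality = "optical", freq_hz = lmr * 1000, lmr_khz = lmr,
                 lpr_khz = lpr, power_mw = power, duration = duration,
                 rate = rate),
            class = "stim_descriptor")
}

# Acoustic-equivalent level of a stimulus, dB SPL.
effective_level <- function(model, stim) {
  if (stim$modality == "acoustic") stim$level_db else model$optical_gain * stim$power_mw
}

#' Driven firing rate of a channel for a stimulus
#'
#' During the stimulus a channel fires at the spontaneous rate plus a driven
#' increment: a Gaussian tuning factor in log2 frequency distance from the
#' channel's best frequency, times the rate growth, times the level above
#' the channel threshold, saturated at `max_driven_rate`. Optical stimuli
#' are first mapped to an acoustic-equivalent level via the optical gain,
#' with the modulation rate as the effective frequency.
#'
#' @param model A [response_model()].
#' @param tono A [synth_tonotopy()] result.
#' @param ch Channel index.
#' @param stim A stimulus descriptor.
#' @return Firing rate during the stimulus, spikes/s.
#' @export
driven_rate <- function(model, tono, ch, stim) {
  stopifnot(inherits(model, "response_model"), inherits(tono, "tonotopy"),
            inherits(stim, "stim_descriptor"))
  if (!ch %in% tono$channel) abort("Invalid channel index.")
  bw <- attr(tono, "tuning_bw")
  d <- log2(stim$freq_hz / tono$bf_hz[tono$channel == ch])
  tune <- exp(-d^2 / (2 * bw^2))
  lvl <- effective_level(model, stim)
  incr <- tune * model$rate_growth * max(0, lvl - tono$threshold_db[tono$channel == ch])
  model$spont_rate + min(incr, model$max_driven_rate)
}

# Poisson event times on [t0, t1) at constant `rate`, then a 1 ms refractory
# period applied jointly with `after` (previously accepted, earlier times).
draw_poisson_window <- function(rate, t0, t1) {
  if (rate <= 0 || t1 <= t0) return(numeric(0))
  n <- rpois(1, rate * (t1 - t0))
  sort(runif(n, t0, t1))
}

apply_refractory <- function(times, refractory = 0.001) {
  # greedy keep-first thinning: iteratively drop the first event of every
  # run of too-close successors, until all gaps respect the dead time
  while (length(times) > 1) {
    bad <- which(diff(times) < refractory) + 1L
    if (length(bad) == 0) break
    drop <- bad[c(TRUE, diff(bad) > 1L)]
    times <- times[-drop]
  }
  times
}

# Biphasic spike template: negative-leading, `dur_s` long, scaled so the
# negative extremum equals -amp. Returns the waveform and the index of its
# negative peak.
spike_template <- function(fs, amp, dur_s = 8e-4) {
  n <- max(4L, round(dur_s * fs))
  n1 <- floor(n / 2)
  w <- c(-sin(pi * seq_len(n1) / (n1 + 1)),
         0.5 * sin(pi * seq_len(n - n1) / (n - n1 + 1)))
  w <- w / max(abs(w)) * amp
  list(wave = w, peak = which.min(w))
}

#' Simulate one multi-channel extracellular trial
#'
#' Per channel: white Gaussian background noise plus a biphasic spike
#' waveform (0.8 ms, negative-leading, amplitude `template_sd` times the
#' noise SD) inserted at inhomogeneous-Poisson times -- the spontaneous rate
#' outside the stimulus and [driven_rate()] during the stimulus window
#' (onset latency to latency + 100 ms after the trigger), with a 1 ms
#' refractory period. Deterministic given `seed`; the inserted ground-truth
#' spike times (at the template's negative peak) are retained for scoring.
#'
#' @param model A [response_model()].
#' @param tono A [synth_tonotopy()] result.
#' @param stim A stimulus descriptor, or `NULL` for a no-stimulus trial.
#' @param seed RNG seed.
#' @param fs Sampling rate, Hz. Default 25000.
#' @param pre,post Pre- and post-trigger context, s. Defaults 0.010, 0.250.
#' @param noise_sd Background noise SD, uV. Default 10.
#' @param template_sd Spike amplitude in units of the noise SD. Default 6.
#' @return A list of class `neural_recording`: `traces` (samples x channels
#'   matrix, uV), `fs`, `t0` (=-`pre`), `descriptor`, `spikes` (tibble
#'   `channel`, `time_s` of ground-truth negative-peak times), `seed`.
#' @export
synth_trial <- function(model, tono, stim, seed, fs = 25000,
                        pre = 0.010, post = 0.250,
                        noise_sd = 10, template_sd = 6) {
  stopifnot(inherits(model, "response_model"), inherits(tono, "tonotopy"))
  if (pre < 0.010 || post < 0.250) {
    abort("Trials need at least 10 ms pre-trigger and 250 ms post-trigger context.")
  }
  n_ch <- nrow(tono)
  n <- round((pre + post) * fs)
  t0 <- -pre
  lat <- model$onset_latency / 1000
  tmpl <- spike_template(fs, template_sd * noise_sd)
  len <- length(tmpl$wave)
  with_seed(seed, {
    traces <- matrix(rnorm(n * n_ch, sd = noise_sd), n, n_ch)
    ch_vec <- integer(0)
    time_vec <- numeric(0)
    for (ch in seq_len(n_ch)) {
      rate_on <- if (is.null(stim)) model$spont_rate else driven_rate(model, tono, ch, stim)
      times <- c(
        draw_poisson_window(model$spont_rate, t0, lat),
        draw_poisson_window(rate_on, lat, lat + 0.1),
        draw_poisson_window(model$spont_rate, lat + 0.1, post)
      )
      times <- apply_refractory(sort(times))
      times <- times[times >= t0 & times < post]
      if (length(times) > 0) {
        # refractory (1 ms) exceeds the template length, so insertions of
        # one channel never overlap and flat-index addition is safe;
        # templates at the record edges are clipped, not dropped, so the
        # spike rate is unbiased across the whole record
        ip <- round((times - t0) * fs) + 1L
        i0 <- ip - tmpl$peak + 1L
        off <- as.vector(outer(0:(len - 1L), i0, `+`))
        wave_rep <- rep(tmpl$wave, times = length(i0))
        ok <- off >= 1L & off <= n
        flat <- off[ok] + (ch - 1L) * n
        traces[flat] <- traces[flat] + wave_rep[ok]
      }
      ch_vec <- c(ch_vec, rep.int(ch, length(times)))
      time_vec <- c(time_vec, times)
    }
  })
  structure(list(traces = traces, fs = fs, t0 = t0, descriptor = stim,
                 spikes = tibble(channel = ch_vec, time_s = time_vec),
                 seed = seed),
            class = "neural_recording")
}

#' Simulate a block-structured recording session
#'
#' One block of `trials_per_stim` trials per protocol entry, with
#' reproducible, disjoint per-trial sub-seeds derived from the master seed
#' and the stimulus position.
#'
#' @param protocol A list of stimulus descriptors.
#' @param trials_per_stim Trials per stimulus. The in-vivo histograms use
#'   at least 100.
#' @param seed Master seed.
#' @param ... Passed to [synth_trial()].
#' @return A list of `neural_recording` objects (stimulus-major order), with
#'   a `protocol_index` attribute mapping each trial to its protocol entry.
#' @export
synth_session <- function(protocol, trials_per_stim = 100, seed = 1, ...) {
  if (length(protocol) == 0) abort("Protocol must contain at least one stimulus.")
  args <- list(...)
  model <- args$model %||% response_model()
  recs <- list()
  index <- integer(0)
  k <- 0L
  for (si in seq_along(protocol)) {
    for (tr in seq_len(trials_per_stim)) {
      k <- k + 1L
      recs[[k]] <- synth_trial(
        model = model,
        tono = args$tono %||% synth_tonotopy(),
        stim = protocol[[si]],
        seed = derive_seed(seed, (si - 1) * trials_per_stim + tr),
        fs = args$fs %||% 25000,
        pre = args$pre %||% 0.010, post = args$post %||% 0.250,
        noise_sd = args$noise_sd %||% 10,
        template_sd = args$template_sd %||% 6
      )
      index[k] <- si
    }
  }
  attr(recs, "protocol_index") <- index
  recs
}

`%||%` <- function(a, b) if (is.null(a)) b else a
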