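#' Offline analysis of a set of umbo vibration runs
#'
#' The offline vibrometry chain: zero-phase 300-12000 Hz band-pass on every
#' run, pointwise averaging over runs, numerical integration of velocity to
#' displacement (with linear detrend), single-sided amplitude spectra of the
#' averaged stimulated and no-stimulus records, peak extraction at the
#' fundamental, second harmonic, carrier and sidebands, and SNR-based
#' quality control.
#'
#' @param session A [synth_vibration_runs()] result, or any list with
#'   `signal` and `noise` sample-by-run matrices, `fs` and `params`.
#' @param min_runs Minimum expected run count. Default 17.
#' @param window Spectral taper, see [single_sided_spectrum()]. The
#'   default, `"hann"`, suppresses the broadband leakage skirt of the
#'   onset transient so weak carrier-region peaks are resolved.
#' @return A list of class `vibration_analysis`: `peaks`
#'   (a [extract_peaks()] tibble), `qc`, `spectrum`, `noise_spectrum`,
#'   `params`.
#' @export
analyze_vibration <- function(session, min_runs = 17, window = "hann") {
  fs <- session$fs
  params <- session$params
  sig <- average_runs(bandpass_vibration(session$signal, fs), min_runs)
  noi <- average_runs(bandpass_vibration(session$noise, fs), min_runs)
  spec <- single_sided_spectrum(integrate_velocity(sig, fs), fs, window)
  nspec <- single_sided_spectrum(integrate_velocity(noi, fs), fs, window)
  peaks <- extract_peaks(spec, nspec, lmr = params$lmr, lpr = params$lpr)
  structure(list(peaks = peaks, qc = qc_measurement(peaks), spectrum = spec,
                 noise_spectrum = nspec, params = params),
            class = "vibration_analysis")
}

# Cumulative trapezoidal integration + linear detrend.
integrate_velocity <- function(v, fs) {
  t <- (seq_along(v) - 1) / fs
  d <- pracma::cumtrapz(t, v)[, 1]
  fit <- stats::lm.fit(cbind(1, t), d)
  d - fit$fitted.values
}

#' @export
print.vibration_analysis <- function(x, ...) {
  cat(sprintf("<vibration_analysis> LPR %g kHz / LMR %g kHz: %s\n",
              x$params$lpr, x$params$lmr,
              if (x$qc$accepted) "accepted" else "rejected"))
  print(as_tibble(x$peaks))
  invisible(x)
}

#' Vibration study over a grid of carrier and modulation rates
#'
#' For each LPR/LMR combination, runs the forward model ([convolve_model()]
#' and [predict_spectrum()]) and the synthetic measurement pipeline
#' ([synth_vibration_runs()] and [analyze_vibration()]), and summarises the
#' recovered peaks.
#'
#' @param lprs Carrier rates, kHz. Default `c(32, 50)`.
#' @param lmrs Modulation rates, kHz. Default `c(1, 2, 4, 8, 10)`.
#' @param ir Velocity impulse response. Default [synth_impulse_response()].
#' @param peak_power Peak power, mW. Default 200 (the level used for the
#'   pooled SNR comparisons).
#' @param runs Runs per measurement. Default 17.
#' @param seed Master seed.
#' @return A tibble with one row per combination: modelled fundamental
#'   (`model_f0_hz`), measured peaks and SNRs, and the QC flag.
#' @export
run_vibration_study <- function(lprs = c(32, 50), lmrs = c(1, 2, 4, 8, 10),
                                ir = synth_impulse_response(),
                                peak_power = 200, runs = 17, seed = 1) {
  ir <- velocity_to_displacement(ir)
  combos <- tidyr::expand_grid(lpr = lprs, lmr = lmrs)
  purrr::pmap(combos, function(lpr, lmr) {
    params <- stimulus_params(lpr = lpr, lmr = lmr, peak_power = peak_power)
    pred <- predict_spectrum(convolve_model(build_input_sequence(params), ir))
    session <- synth_vibration_runs(
      params, ir, runs = runs,
      seed = derive_seed(seed, lpr * 100 + lmr))
    an <- analyze_vibration(session)
    pk <- function(p, col) an$peaks[[col]][an$peaks$peak == p]
    tibble(
      lpr_khz = lpr, lmr_khz = lmr,
      pulses_per_period = pulses_per_period(lpr, lmr),
      model_f0_hz = attr(pred, "f0_hz"),
      f0_hz = pk("f0", "freq_hz"),
      snr_f0_db = pk("f0", "snr_db"),
      snr_h2_db = pk("h2", "snr_db"),
      snr_lpr_db = pk("lpr", "snr_db"),
      sideband_lo_hz = pk("sideband_lo", "freq_hz"),
      sideband_hi_hz = pk("sideband_hi", "freq_hz"),
      accepted = an$qc$accepted
    )
  }) |> dplyr::bind_rows()
}

#' Simulate and spike-detect one block of trials
#'
#' Generates `n_trials` trials of one stimulus with [synth_trial()]
#' (per-trial sub-seeds derived from `seed`), band-pass filters all traces,
#' pools the filtered pre-trigger segments per channel for a robust (MAD)
#' background-SD estimate, and detects spikes on every channel of every
#' trial at 3.5 background SDs.
#'
#' @param model A [response_model()].
#' @param tono A [synth_tonotopy()] result.
#' @param stim A stimulus descriptor (or `NULL` for no-stimulus trials).
#' @param n_trials Trials in the block.
#' @param seed Block seed.
#' @param fs,pre,post,noise_sd,template_sd Passed to [synth_trial()].
#' @param threshold Detection threshold in background SDs. Default 3.5.
#' @return A list of class `detected_block`: `detections` and `truth`
#'   (tibbles `trial`, `channel`, `time_s`), `noise_sd` (per channel),
#'   `n_trials`, `pre`, `stim`.
#' @export
detect_block <- function(model, tono, stim, n_trials, seed,
                         fs = 25000, pre = 0.010, post = 0.250,
                         noise_sd = 10, template_sd = 6, threshold = 3.5) {
  n <- round((pre + post) * fs)
  n_ch <- nrow(tono)
  big <- matrix(0, n, n_ch * n_trials)
  truth <- vector("list", n_trials)
  for (tr in seq_len(n_trials)) {
    rec <- synth_trial(model, tono, stim, seed = derive_seed(seed, tr),
                       fs = fs, pre = pre, post = post,
                       noise_sd = noise_sd, template_sd = template_sd)
    big[, ((tr - 1) * n_ch + 1):(tr * n_ch)] <- rec$traces
    truth[[tr]] <- mutate(rec$spikes, trial = tr)
  }
  filt <- filter_spike_band(big, fs)
  n_pre <- floor(pre * fs)
  sds <- vapply(seq_len(n_ch), function(ch) {
    cols <- ch + (seq_len(n_trials) - 1) * n_ch
    mad(as.vector(filt[seq_len(n_pre), cols]))
  }, numeric(1))
  gap <- round(0.001 * fs)
  idx_list <- vector("list", n_trials * n_ch)
  n_ev <- integer(n_trials * n_ch)
  k <- 0L
  for (tr in seq_len(n_trials)) {
    for (ch in seq_len(n_ch)) {
      ev <- detect_spikes_core(filt[, (tr - 1) * n_ch + ch],
                               threshold * sds[ch], gap)
      k <- k + 1L
      idx_list[[k]] <- ev$idx
      n_ev[k] <- length(ev$idx)
    }
  }
  detections <- tibble(
    trial = rep(rep(seq_len(n_trials), each = n_ch), times = n_ev),
    channel = rep(rep(seq_len(n_ch), times = n_trials), times = n_ev),
    time_s = -pre + (unlist(idx_list) - 1) / fs
  )
  structure(list(detections = detections,
                 truth = dplyr::bind_rows(truth),
                 noise_sd = sds, n_trials = n_trials, pre = pre, stim = stim),
            class = "detected_block")
}

#' Per-trial rate summaries of a detected block
#'
#' The spontaneous rate is estimated per channel from the pooled
#' spontaneous-activity windows of the block -- the pre-trigger segment
#' together with the late post-stimulus segment (150-250 ms after the
#' trigger, well after stimulus offset), which stabilises the estimate on
#' short blocks; each trial's total and driven spike rates follow
#' [rate_summary()].
#'
#' @param block A [detect_block()] result.
#' @param ssr_late Late spontaneous window, s. Default `c(0.150, 0.250)`;
#'   set `NULL` to use the pre-trigger segment alone.
#' @param ssr Optional per-channel spontaneous rates (spikes/s) to use
#'   instead of the block's own estimate, e.g. pooled over a whole session.
#' @return A tibble with columns `trial`, `channel`, `tsr`, `ssr`, `dsr`.
#' @export
block_rates <- function(block, ssr_late = c(0.150, 0.250), ssr = NULL) {
  stopifnot(inherits(block, "detected_block"))
  n_ch <- length(block$noise_sd)
  d <- block$detections
  if (is.null(ssr)) {
    sc <- block_spont_counts(block, ssr_late)
    ssr <- sc$count / sc$duration
  }
  ssr <- rep_len(ssr, n_ch)
  grid <- tidyr::expand_grid(trial = seq_len(block$n_trials),
                             channel = seq_len(n_ch))
  counts <- summarise(
    group_by(filter(d, .data$time_s >= 0.005, .data$time_s < 0.105),
             .data$trial, .data$channel),
    n_spk = dplyr::n(), .groups = "drop")
  out <- left_join(grid, counts, by = c("trial", "channel"))
  out$n_spk[is.na(out$n_spk)] <- 0L
  mutate(out,
         tsr = .data$n_spk / 0.1,
         ssr = ssr[.data$channel],
         dsr = .data$tsr - .data$ssr,
         n_spk = NULL)
}

#' Spontaneous-window detection counts of a block
#'
#' Counts detections per channel in the block's spontaneous windows (the
#' pre-trigger segment plus, by default, the late 150-250 ms post-stimulus
#' segment) together with the total window duration, so spontaneous rates
#' can be pooled across blocks.
#'
#' @inheritParams block_rates
#' @return A tibble with columns `channel`, `count`, `duration` (s).
#' @export
block_spont_counts <- function(block, ssr_late = c(0.150, 0.250)) {
  stopifnot(inherits(block, "detected_block"))
  n_ch <- length(block$noise_sd)
  d <- block$detections
  in_spont <- d$time_s < 0
  spont_dur <- block$pre
  if (!is.null(ssr_late)) {
    in_spont <- in_spont | (d$time_s >= ssr_late[1] & d$time_s < ssr_late[2])
    spont_dur <- spont_dur + diff(ssr_late)
  }
  tibble(
    channel = seq_len(n_ch),
    count = vapply(seq_len(n_ch), function(ch) {
      sum(d$channel == ch & in_spont)
    }, numeric(1)),
    duration = block$n_trials * spont_dur
  )
}

#' Frequency grid with six steps per octave
#'
#' @param f_lo,f_hi Range, Hz; the grid starts at `f_lo` and extends to the
#'   first grid point at or above `f_hi`.
#' @param per_octave Steps per octave. Default 6.
#' @return Frequencies, Hz.
#' @export
frm_frequencies <- function(f_lo = 1000, f_hi = 22000, per_octave = 6) {
  k <- 0:ceiling(per_octave * log2(f_hi / f_lo))
  f_lo * 2^(k / per_octave)
}

#' Measure an acoustic frequency response map from synthetic recordings
#'
#' Runs a block of trials for every frequency-level cell of the acoustic
#' protocol (pure tones, six frequencies per octave, 10 dB level steps),
#' detects spikes, computes per-run driven rates and assembles the
#' normalised frequency response map. The spontaneous rate entering the
#' driven-rate subtraction is pooled per channel over the spontaneous
#' windows of the whole session, since the spontaneous rate is a property
#' of the site, not of a stimulus cell.
#'
#' @param model A [response_model()].
#' @param tono A [synth_tonotopy()] result.
#' @param freqs Tone frequencies, Hz. Default [frm_frequencies()] over the
#'   tonotopy span.
#' @param levels Levels, dB SPL. Default 0-80 in 10 dB steps.
#' @param runs_per_cell Runs per cell. Default 12 (the protocol minimum
#'   is 7).
#' @param seed Seed.
#' @param ... Passed to [detect_block()].
#' @return A [build_frm()] tibble.
#' @export
measure_frm <- function(model, tono,
                        freqs = frm_frequencies(min(tono$bf_hz), max(tono$bf_hz)),
                        levels = seq(0, 80, by = 10),
                        runs_per_cell = 12, seed = 1, ...) {
  cells <- tidyr::expand_grid(freq_hz = freqs, level_db = levels)
  pieces <- purrr::pmap(
    mutate(cells, .ci = dplyr::row_number()),
    function(freq_hz, level_db, .ci) {
      block <- detect_block(model, tono, acoustic_stim(freq_hz, level_db),
                            n_trials = runs_per_cell,
                            seed = derive_seed(seed, .ci), ...)
      list(rates = mutate(block_rates(block), freq_hz = freq_hz,
                          level_db = level_db),
           spont = block_spont_counts(block))
    })
  spont <- dplyr::bind_rows(purrr::map(pieces, "spont"))
  ssr_pooled <- summarise(group_by(spont, .data$channel),
                          ssr = sum(.data$count) / sum(.data$duration),
                          .groups = "drop")
  rates <- dplyr::bind_rows(purrr::map(pieces, "rates"))
  rates <- mutate(rates,
                  ssr = ssr_pooled$ssr[match(.data$channel,
                                             ssr_pooled$channel)],
                  dsr = .data$tsr - .data$ssr)
  build_frm(rates)
}

#' Best frequencies of all channels of a frequency response map
#'
#' @param frm A [build_frm()] result.
#' @param criterion Threshold criterion, see [estimate_threshold()].
#' @return A tibble with one row per channel: `channel`, `bf_hz`,
#'   `threshold_db` (`NA` where no threshold was reached).
#' @export
frm_best_frequencies <- function(frm, criterion = 0.25) {
  purrr::map(sort(unique(frm$channel)), function(ch) {
    tryCatch(as_tibble(best_frequency(frm, ch, criterion)),
             error = function(e) tibble(channel = ch, bf_hz = NA_real_,
                                        threshold_db = NA_real_))
  }) |> dplyr::bind_rows()
}

#' Modulation-rate to best-frequency mapping for one synthetic subject
#'
#' Builds the subject's acoustic frequency response map, derives per-channel
#' best frequencies at threshold, then presents each optical stimulus and
#' pairs its modulation rate with the best frequency of the most activated
#' channel (largest mean driven rate).
#'
#' @param model,tono Response model and tonotopy of the subject.
#' @param lmrs Modulation rates, kHz. Default `c(1, 2, 4, 8, 10)`.
#' @param lpr Carrier, kHz. Default 50.
#' @param power Optical peak power, mW. Default 80.
#' @param trials_per_stim Optical trials per modulation rate. Default 100.
#' @param runs_per_cell Acoustic runs per map cell. Default 12.
#' @param seed Subject seed.
#' @return A tibble with one row per modulation rate: `lmr_khz`, `channel`
#'   (most activated), `bf_hz`, `threshold_db`, `mean_dsr`.
#' @export
subject_lmr_bf <- function(model = response_model(), tono = synth_tonotopy(),
                           lmrs = c(1, 2, 4, 8, 10), lpr = 50, power = 80,
                           trials_per_stim = 100, runs_per_cell = 12,
                           seed = 1) {
  frm <- measure_frm(model, tono, runs_per_cell = runs_per_cell,
                     seed = derive_seed(seed, 500000))
  bfs <- frm_best_frequencies(frm)
  purrr::imap(lmrs, function(lmr, i) {
    block <- detect_block(model, tono, optical_stim(lmr, lpr, power),
                          n_trials = trials_per_stim,
                          seed = derive_seed(seed, 600000 + i))
    by_ch <- summarise(group_by(block_rates(block), .data$channel),
                       mean_dsr = mean(.data$dsr), .groups = "drop")
    best <- by_ch$channel[which.max(by_ch$mean_dsr)]
    tibble(lmr_khz = lmr, channel = best,
           bf_hz = bfs$bf_hz[bfs$channel == best],
           threshold_db = bfs$threshold_db[bfs$channel == best],
           mean_dsr = max(by_ch$mean_dsr))
  }) |> dplyr::bind_rows()
}

#' Multi-subject modulation-rate / best-frequency study
#'
#' Repeats [subject_lmr_bf()] over several synthetic subjects (independent
#' sub-seeds from the master seed) and correlates the applied modulation
#' rate with the recovered best frequency at threshold.
#'
#' @param n_subjects Number of synthetic subjects. Default 4.
#' @param lmrs,lpr,power,trials_per_stim,runs_per_cell See
#'   [subject_lmr_bf()].
#' @param seed Master seed. Default 42.
#' @param model,tono Shared response model and tonotopy.
#' @return A list of class `lmr_bf_study`: `pairs` (tibble with `subject`
#'   prepended) and `correlation` (a [lmr_bf_correlation()] object).
#' @export
lmr_bf_study <- function(n_subjects = 4, lmrs = c(1, 2, 4, 8, 10), lpr = 50,
                         power = 80, trials_per_stim = 100,
                         runs_per_cell = 12, seed = 42,
                         model = response_model(), tono = synth_tonotopy()) {
  pairs <- purrr::map(seq_len(n_subjects), function(s) {
    mutate(subject_lmr_bf(model, tono, lmrs, lpr, power, trials_per_stim,
                          runs_per_cell, seed = derive_seed(seed, s)),
           subject = s)
  }) |> dplyr::bind_rows()
  structure(list(pairs = pairs, correlation = lmr_bf_correlation(pairs)),
            class = "lmr_bf_study")
}

#' @export
print.lmr_bf_study <- function(x, ...) {
  cat(sprintf("<lmr_bf_study> %d subjects x %d modulation rates\n",
              length(unique(x$pairs$subject)),
              length(unique(x$pairs$lmr_khz))))
  print(x$correlation)
  invisible(x)
}

#' Acoustic equivalent level of optical stimulation, one synthetic session
#'
#' Presents the optical stimulus at `power`, finds the most activated
#' channel, measures the acoustic rate-level curve of that channel at the
#' grid frequency nearest its generator best frequency, and interpolates
#' the acoustic level whose driven rate matches the optical one
#' ([equivalent_level()]).
#'
#' @param lmr,lpr Optical stimulus rates, kHz.
#' @param power Optical peak power, mW. Default 80.
#' @param seed Session seed.
#' @param model,tono Response model and tonotopy.
#' @param levels Acoustic levels, dB SPL. Default 0-80 in 10 dB steps.
#' @param optical_trials Optical trials. Default 20.
#' @param runs Acoustic runs per level. Default 7.
#' @return A one-row [equivalent_level()] tibble with an added
#'   `optical_dsr` column.
#' @export
run_equivalent_level_session <- function(lmr = 1, lpr = 50, power = 80,
                                         seed = 1,
                                         model = response_model(),
                                         tono = synth_tonotopy(),
                                         levels = seq(0, 80, by = 10),
                                         optical_trials = 20, runs = 7) {
  opt <- detect_block(model, tono, optical_stim(lmr, lpr, power),
                      n_trials = optical_trials, seed = derive_seed(seed, 1))
  opt_by_ch <- summarise(group_by(block_rates(opt), .data$channel),
                         dsr = mean(.data$dsr), .groups = "drop")
  best <- opt_by_ch$channel[which.max(opt_by_ch$dsr)]
  optical_dsr <- max(opt_by_ch$dsr)
  grid <- frm_frequencies(min(tono$bf_hz), max(tono$bf_hz))
  freq <- grid[which.min(abs(log(grid) - log(tono$bf_hz[tono$channel == best])))]
  pieces <- purrr::imap(levels, function(lvl, i) {
    blk <- detect_block(model, tono, acoustic_stim(freq, lvl),
                        n_trials = runs, seed = derive_seed(seed, 100 + i))
    list(rates = mutate(block_rates(blk), level_db = lvl),
         spont = block_spont_counts(blk))
  })
  spont <- dplyr::bind_rows(purrr::map(pieces, "spont"))
  ssr_pooled <- summarise(group_by(spont, .data$channel),
                          ssr = sum(.data$count) / sum(.data$duration),
                          .groups = "drop")
  sweep <- dplyr::bind_rows(purrr::map(pieces, "rates")) |>
    mutate(dsr = .data$tsr - ssr_pooled$ssr[match(.data$channel,
                                                  ssr_pooled$channel)]) |>
    group_by(.data$channel, .data$level_db) |>
    summarise(dsr = mean(.data$dsr), .groups = "drop")
  curve <- filter(sweep, .data$channel == best)
  top <- filter(sweep, .data$level_db == max(levels))
  bf_at_max <- top$channel[which.max(top$dsr)]
  by_level <- summarise(group_by(sweep, .data$level_db),
                        m = max(.data$dsr), .groups = "drop")
  resp_levels <- by_level$level_db[by_level$m >= 0.25 * max(by_level$m)]
  thr_level <- if (length(resp_levels) > 0) min(resp_levels) else max(levels)
  at_thr <- filter(sweep, .data$level_db == thr_level)
  bf_at_thr <- at_thr$channel[which.max(at_thr$dsr)]
  out <- equivalent_level(optical_dsr, select(curve, "level_db", "dsr"),
                          bf_at_max, bf_at_thr, lmr = lmr, lpr = lpr)
  mutate(out, optical_dsr = optical_dsr)
}

#' Run the full synthetic pipeline and write its artifacts
#'
#' Orchestrates the two stages end to end: the stimulus synthesis, forward
#' model and vibrometry pipeline over the configured LPR/LMR grid, and the
#' synthetic neural study. Deterministic given the seeds in the config.
#'
#' @param config A named list: `lprs`, `lmrs` (kHz), `peak_power` (mW),
#'   `runs` (vibration runs), `seed`, and optional `neural` (list with
#'   `n_subjects`, `trials_per_stim`, `runs_per_cell`) and `out_dir`.
#'   Defaults via [default_config()].
#' @return A list of class `pipeline_report`: `vibration` (the
#'   [run_vibration_study()] table), `neural` (the [lmr_bf_study()] result
#'   or `NULL` when disabled) and the paths of written artifacts.
#' @export
run_pipeline <- function(config = default_config()) {
  if (length(config$lmrs) == 0) abort("Config has an empty LMR list.")
  if (is.null(config$seed)) abort("Config must carry an explicit seed.")
  for (lmr in config$lmrs) {
    stimulus_params(lpr = max(config$lprs), lmr = lmr,
                    peak_power = config$peak_power)  # validation
  }
  vib <- run_vibration_study(config$lprs, config$lmrs,
                             peak_power = config$peak_power,
                             runs = config$runs, seed = config$seed)
  neural <- NULL
  if (!is.null(config$neural)) {
    neural <- lmr_bf_study(
      n_subjects = config$neural$n_subjects,
      lmrs = config$lmrs, lpr = max(config$lprs),
      trials_per_stim = config$neural$trials_per_stim,
      runs_per_cell = config$neural$runs_per_cell,
      seed = config$seed)
  }
  paths <- character(0)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    p1 <- file.path(config$out_dir, "vibration_summary.csv")
    readr::write_csv(vib, p1)
    paths <- p1
    if (!is.null(neural)) {
      p2 <- file.path(config$out_dir, "lmr_bf_pairs.csv")
      readr::write_csv(neural$pairs, p2)
      paths <- c(paths, p2)
    }
  }
  structure(list(vibration = vib, neural = neural, paths = paths,
                 config = config),
            class = "pipeline_report")
}

#' @rdname run_pipeline
#' @export
default_config <- function() {
  list(lprs = c(32, 50), lmrs = c(1, 2, 4, 8, 10), peak_power = 200,
       runs = 17, seed = 1, neural = NULL, out_dir = NULL)
}

#' Generate the bundled small fixture set
#'
#' Writes a small, regenerable dataset used by examples and tests: a
#' synthetic impulse response, the ground-truth spike table of a 10-trial
#' neural mini-session, and a no-stimulus vibration noise record. All files
#' are plain columnar text with metadata headers and are byte-identical
#' across calls with the same seed.
#'
#' @param seed Seed. Default 1.
#' @param dir Output directory. Default `tempdir()`.
#' @return Named character vector of the written paths.
#' @export
make_fixtures <- function(seed = 1, dir = tempdir()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ir <- synth_impulse_response(fs = 1e5, duration = 0.02)
  p_ir <- file.path(dir, "impulse_response.csv")
  write_impulse_response(ir, p_ir)
  session <- synth_session(list(optical_stim(8)), trials_per_stim = 10,
                           seed = seed)
  truth <- purrr::imap(session, function(rec, i) {
    mutate(rec$spikes, trial = i)
  }) |> dplyr::bind_rows()
  p_truth <- file.path(dir, "mini_session_truth.csv")
  write_columnar(truth[, c("trial", "channel", "time_s")], p_truth,
                 meta = list(seed = seed, trials = 10, stimulus = "optical LMR 8 kHz"))
  noise <- with_seed(seed, rnorm(10000, sd = 3e-7))
  p_noise <- file.path(dir, "noise_record.csv")
  write_columnar(tibble(time_s = (seq_along(noise) - 1) / 1e5,
                        velocity = noise),
                 p_noise, meta = list(fs = 1e5, stimulus = "none", seed = seed))
  c(impulse_response = p_ir, mini_session_truth = p_truth,
    noise_record = p_noise)
}
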