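#' Detect multi-unit spikes by amplitude threshold
#'
#' Events are negative-going excursions of the band-pass filtered trace
#' beyond 3.5 times the background noise standard deviation; the timestamp
#' of each event is the time of its largest negative deflection, and events
#' closer than 1 ms are merged into one. The background SD is estimated
#' robustly (median absolute deviation scaled to SD) from the pre-trigger
#' segment unless supplied.
#'
#' @param trace A single filtered channel trace (numeric vector).
#' @param fs Sampling rate, Hz.
#' @param t0 Time of the first sample relative to the trigger, s.
#'   Default -0.010.
#' @param noise_sd Background noise SD; if `NULL`, estimated from the
#'   pre-trigger samples (`t < 0`), which must exist.
#' @param threshold Threshold in noise SDs. Default 3.5.
#' @param min_separation Merge window, s. Default 0.001.
#' @return A tibble with columns `time_s` (negative-peak times relative to
#'   the trigger) and `peak` (trace value at the peak).
#' @export
detect_spikes <- function(trace, fs, t0 = -0.010, noise_sd = NULL,
                          threshold = 3.5, min_separation = 0.001) {
  if (is.null(noise_sd)) {
    n_pre <- floor(-t0 * fs)
    if (n_pre < 2) {
      abort("No pre-trigger background segment available; supply `noise_sd`.")
    }
    noise_sd <- mad(trace[seq_len(n_pre)])
  }
  ev <- detect_spikes_core(trace, threshold * noise_sd,
                           gap = round(min_separation * fs))
  tibble(time_s = t0 + (ev$idx - 1) / fs, peak = ev$peak)
}

# Cluster suprathreshold (negative) samples separated by less than `gap`
# samples; report the minimum-value sample of each cluster.
detect_spikes_core <- function(x, thr, gap) {
  below <- which(x < -thr)
  if (length(below) == 0) {
    return(list(idx = integer(0), peak = numeric(0)))
  }
  grp <- cumsum(c(1L, as.integer(diff(below) > gap)))
  idx <- vapply(split(below, grp), function(ii) ii[which.min(x[ii])], integer(1))
  idx <- unname(idx)
  list(idx = idx, peak = x[idx])
}

#' Score detected spikes against ground truth
#'
#' Greedy one-to-one matching of detected timestamps to ground-truth spike
#' times within a tolerance; reports precision, recall and counts.
#'
#' @param detected Detected spike times, s.
#' @param truth Ground-truth spike times, s.
#' @param tol Matching tolerance, s. Default 0.001.
#' @return A one-row tibble: `n_detected`, `n_truth`, `n_matched`,
#'   `precision`, `recall`.
#' @export
score_detection <- function(detected, truth, tol = 0.001) {
  detected <- sort(detected)
  truth <- sort(truth)
  used <- logical(length(truth))
  matched <- 0L
  for (d in detected) {
    cand <- which(!used & abs(truth - d) <= tol)
    if (length(cand) > 0) {
      hit <- cand[which.min(abs(truth[cand] - d))]
      used[hit] <- TRUE
      matched <- matched + 1L
    }
  }
  tibble(
    n_detected = length(detected), n_truth = length(truth), n_matched = matched,
    precision = if (length(detected) > 0) matched / length(detected) else NA_real_,
    recall = if (length(truth) > 0) matched / length(truth) else NA_real_
  )
}

#' Local field potential estimate
#'
#' Band-pass filters each trial between 20 and 3000 Hz and averages the
#' first 20 trials pointwise, per channel.
#'
#' @param trials List of samples-by-channels matrices (or vectors), all the
#'   same shape; at least 20.
#' @param fs Sampling rate, Hz.
#' @return Averaged filtered trace, same shape as one trial.
#' @export
compute_lfp <- function(trials, fs) {
  if (length(trials) < 20) abort("LFP averaging requires at least 20 trials.")
  trials <- trials[seq_len(20)]
  filtered <- lapply(trials, zero_phase_bandpass, fs = fs, lo = 20, hi = 3000)
  Reduce(`+`, filtered) / 20
}

#' Peri-stimulus time histogram
#'
#' Bins spike timestamps into 1 ms bins over a -10 to 250 ms window around
#' the trigger, per channel, with half-open bins `[t, t + 1 ms)`.
#'
#' @param spikes Tibble with columns `channel` and `time_s` (and optionally
#'   `trial`), pooled over trials.
#' @param n_trials Number of trials the timestamps came from (used for the
#'   `n_trials` attribute and the 100-trial warning).
#' @param channels Channel set for the output. Default: channels present.
#' @param window Analysis window, s. Default `c(-0.010, 0.250)`.
#' @param binwidth Bin width, s. Default 0.001.
#' @return A tibble of class `psth` with columns `channel`, `time_ms` (bin
#'   left edge) and `count`; attributes `n_trials`, `binwidth`.
#' @export
build_psth <- function(spikes, n_trials, channels = NULL,
                       window = c(-0.010, 0.250), binwidth = 0.001) {
  if (n_trials < 100) {
    warn(sprintf("PSTH built from %d trials; the protocol uses at least 100.",
                 n_trials))
  }
  if (is.null(channels)) {
    channels <- if (nrow(spikes) > 0) sort(unique(spikes$channel)) else 1L
  }
  edges <- seq(window[1], window[2], by = binwidth)
  grid <- tidyr::expand_grid(channel = channels,
                             time_ms = head(edges, -1) * 1000)
  if (nrow(spikes) == 0) {
    out <- mutate(grid, count = 0L)
  } else {
    sp <- filter(spikes, .data$time_s >= window[1], .data$time_s < window[2])
    sp <- mutate(sp,
                 time_ms = (window[1] + floor((sp$time_s - window[1]) / binwidth) *
                              binwidth) * 1000)
    counts <- summarise(group_by(sp, .data$channel, .data$time_ms),
                        count = dplyr::n(), .groups = "drop")
    out <- left_join(grid, counts, by = c("channel", "time_ms"))
    out$count[is.na(out$count)] <- 0L
  }
  out$time_ms <- round(out$time_ms, 6)
  attr(out, "n_trials") <- n_trials
  attr(out, "binwidth") <- binwidth
  class(out) <- c("psth", class(out))
  out
}

#' Total, spontaneous and driven spike rate of one trial
#'
#' The total spike rate (TSR) is the spike count in the 5-105 ms window
#' after the trigger divided by 100 ms; the driven spike rate (DSR) is the
#' TSR minus the spontaneous rate (SSR). If no SSR is supplied it is
#' estimated from the pre-trigger timestamps.
#'
#' @param times Spike timestamps of one trial (one channel), s.
#' @param ssr Spontaneous rate, spikes/s; if `NULL`, estimated from
#'   timestamps in `[-pre, 0)`.
#' @param window TSR window, s. Default `c(0.005, 0.105)`.
#' @param pre Pre-trigger duration used for the SSR estimate, s. Default 0.01.
#' @return A one-row tibble: `tsr`, `ssr`, `dsr` (spikes/s).
#' @export
rate_summary <- function(times, ssr = NULL, window = c(0.005, 0.105), pre = 0.010) {
  tsr <- sum(times >= window[1] & times < window[2]) / diff(window)
  if (is.null(ssr)) {
    ssr <- sum(times >= -pre & times < 0) / pre
  }
  tibble(tsr = tsr, ssr = ssr, dsr = tsr - ssr)
}

#' Frequency response map
#'
#' Averages the driven spike rate over runs for every frequency-level cell,
#' then normalises per channel by the channel's maximum mean rate; negative
#' normalised values are floored at 0. The grid must be complete.
#'
#' @param summaries Tibble with columns `channel`, `freq_hz`, `level_db`,
#'   `dsr` (one row per run and cell).
#' @param min_runs Minimum runs per cell before a warning. Default 7.
#' @return A tibble of class `frm` with columns `channel`, `freq_hz`,
#'   `level_db`, `dsr` (mean) and `ndsr` (normalised, in `[0, 1]`);
#'   attributes `freqs`, `levels`.
#' @export
build_frm <- function(summaries, min_runs = 7) {
  needed <- c("channel", "freq_hz", "level_db", "dsr")
  if (!all(needed %in% names(summaries))) {
    abort("`summaries` needs columns channel, freq_hz, level_db, dsr.")
  }
  freqs <- sort(unique(summaries$freq_hz))
  levels <- sort(unique(summaries$level_db))
  channels <- sort(unique(summaries$channel))
  grid <- tidyr::expand_grid(channel = channels, freq_hz = freqs,
                             level_db = levels)
  cells <- summarise(group_by(summaries, .data$channel, .data$freq_hz,
                              .data$level_db),
                     dsr = mean(.data$dsr), runs = dplyr::n(),
                     .groups = "drop")
  merged <- left_join(grid, cells, by = c("channel", "freq_hz", "level_db"))
  if (anyNA(merged$dsr)) {
    miss <- filter(merged, is.na(.data$dsr))
    abort(paste0(
      "Incomplete frequency x level grid; missing cells: ",
      paste(sprintf("(ch %d, %g Hz, %g dB)", miss$channel, miss$freq_hz,
                    miss$level_db)[seq_len(min(5, nrow(miss)))],
            collapse = ", "),
      if (nrow(miss) > 5) sprintf(" and %d more", nrow(miss) - 5) else ""))
  }
  if (any(merged$runs < min_runs)) {
    warn(sprintf("%d cell(s) have fewer than %d runs.",
                 sum(merged$runs < min_runs), min_runs))
  }
  out <- merged |>
    group_by(.data$channel) |>
    mutate(ndsr = {
      m <- max(.data$dsr)
      if (m > 0) pmax(.data$dsr, 0) / m else rep(0, dplyr::n())
    }) |>
    ungroup() |>
    select("channel", "freq_hz", "level_db", "dsr", "ndsr")
  attr(out, "freqs") <- freqs
  attr(out, "levels") <- levels
  class(out) <- c("frm", class(out))
  out
}

#' Acoustic threshold of a channel from its frequency response map
#'
#' A reproducible surrogate for the visually determined threshold: the
#' lowest tested level at which the channel's maximum normalised driven
#' rate over frequency reaches `criterion` (default 0.25). By default the
#' criterion must also hold at the next higher tested level (as a human
#' rater would demand a response that persists with increasing level),
#' which suppresses false triggers from single noisy map cells.
#'
#' @param frm A [build_frm()] result.
#' @param ch Channel index.
#' @param criterion Normalised-rate criterion. Default 0.25.
#' @param confirm Require the criterion at the following level as well
#'   (when one exists). Default `TRUE`.
#' @return Threshold level, dB SPL, or `NA` if never reached.
#' @export
estimate_threshold <- function(frm, ch, criterion = 0.25, confirm = TRUE) {
  stopifnot(inherits(frm, "frm"))
  sub <- filter(frm, .data$channel == ch)
  if (nrow(sub) == 0) abort("Invalid channel index.")
  by_level <- arrange(summarise(group_by(sub, .data$level_db),
                                m = max(.data$ndsr), .groups = "drop"),
                      .data$level_db)
  ok <- by_level$m >= criterion
  if (confirm && length(ok) > 1) {
    ok <- ok & c(ok[-1], TRUE)
  }
  hit <- by_level$level_db[ok]
  if (length(hit) == 0) NA_real_ else min(hit)
}

#' Best frequency of a channel
#'
#' The frequency with the maximum activation at 10 dB above the channel's
#' estimated acoustic threshold. Ties are resolved deterministically by the
#' geometric mean of the tied frequencies, snapped to the nearest grid
#' frequency.
#'
#' @param frm A [build_frm()] result.
#' @param ch Channel index.
#' @param criterion Passed to [estimate_threshold()].
#' @return A one-row tibble of class `bf_result`: `channel`, `bf_hz`,
#'   `threshold_db`.
#' @export
best_frequency <- function(frm, ch, criterion = 0.25) {
  thr <- estimate_threshold(frm, ch, criterion = criterion)
  if (is.na(thr)) {
    abort(sprintf("Channel %d has no threshold; best frequency undefined.", ch))
  }
  lvl <- thr + 10
  levels <- attr(frm, "levels")
  if (!any(abs(levels - lvl) < 1e-9)) {
    abort(sprintf("Level %g dB (threshold + 10) was not tested.", lvl))
  }
  sub <- filter(frm, .data$channel == ch, abs(.data$level_db - lvl) < 1e-9)
  mx <- max(sub$ndsr)
  tied <- sub$freq_hz[sub$ndsr >= mx - 1e-12]
  bf <- if (length(tied) > 1) {
    gm <- exp(mean(log(tied)))
    grid <- attr(frm, "freqs")
    grid[which.min(abs(log(grid) - log(gm)))]
  } else {
    tied
  }
  out <- tibble(channel = ch, bf_hz = bf, threshold_db = thr)
  class(out) <- c("bf_result", class(out))
  out
}

#' Correlation between modulation rate and best frequency
#'
#' Pearson product-moment correlation (with two-sided p-value) between the
#' applied laser modulation rate and the best frequency at threshold of the
#' most activated channel, pooled over stimuli and subjects.
#'
#' @param pairs Tibble with columns `lmr_khz` and `bf_hz` (>= 3 rows).
#' @return An object of class `lmr_bf_cor` wrapping the `cor.test` result;
#'   see [tidy()] and [glance()] methods.
#' @export
lmr_bf_correlation <- function(pairs) {
  if (!all(c("lmr_khz", "bf_hz") %in% names(pairs))) {
    abort("`pairs` needs columns lmr_khz and bf_hz.")
  }
  if (nrow(pairs) < 3) abort("Need at least 3 (LMR, BF) pairs.")
  if (stats::sd(pairs$lmr_khz) == 0 || stats::sd(pairs$bf_hz) == 0) {
    abort("Correlation undefined: one of the variables has zero variance.")
  }
  ct <- cor.test(pairs$lmr_khz, pairs$bf_hz, method = "pearson")
  structure(list(test = ct, data = pairs), class = "lmr_bf_cor")
}

#' @export
print.lmr_bf_cor <- function(x, ...) {
  cat(sprintf("<lmr_bf_cor> n = %d pairs, r = %.3f, p = %.3g\n",
              nrow(x$data), unname(x$test$estimate), x$test$p.value))
  invisible(x)
}

#' Acoustic equivalent level of an optical response
#'
#' Linearly interpolates (in dB) the acoustic level at which the acoustic
#' driven-rate curve of the best-frequency channel equals the driven rate
#' evoked optically at 80 mW. The estimate is discarded when the
#' best-frequency channel at maximal acoustic stimulation differs by more
#' than one channel from the best-frequency channel at threshold, and
#' flagged extrapolated when the optical rate exceeds the whole curve.
#'
#' @param optical_dsr Driven spike rate under optical stimulation, spikes/s.
#' @param acoustic_curve Tibble with columns `level_db` and `dsr`: the
#'   acoustic rate-level curve of the channel at its best frequency.
#' @param bf_at_max_acoustic,bf_at_threshold Channel indices of the most
#'   activated site at maximal acoustic level and at threshold.
#' @param lmr,lpr Stimulus rates, kHz (annotation).
#' @return A one-row tibble of class `equivalent_level`: `lmr_khz`,
#'   `lpr_khz`, `level_db_spl`, `discarded`, `extrapolated`.
#' @export
equivalent_level <- function(optical_dsr, acoustic_curve,
                             bf_at_max_acoustic, bf_at_threshold,
                             lmr = NA_real_, lpr = NA_real_) {
  if (!all(c("level_db", "dsr") %in% names(acoustic_curve))) {
    abort("`acoustic_curve` needs columns level_db and dsr.")
  }
  curve <- arrange(acoustic_curve, .data$level_db)
  # monotone increasing region up to the curve maximum
  i_max <- which.max(curve$dsr)
  curve <- curve[seq_len(i_max), , drop = FALSE]
  keep <- c(TRUE, diff(cummax(curve$dsr)) > 0)
  curve <- curve[keep | seq_len(nrow(curve)) == 1, , drop = FALSE]
  if (nrow(curve) < 2) abort("Acoustic curve has no increasing region.")
  discarded <- abs(bf_at_max_acoustic - bf_at_threshold) > 1
  extrapolated <- optical_dsr > max(curve$dsr)
  level <- if (extrapolated) {
    NA_real_
  } else if (optical_dsr < min(curve$dsr)) {
    min(curve$level_db)
  } else {
    approx(curve$dsr, curve$level_db, xout = optical_dsr, ties = "ordered")$y
  }
  out <- tibble(lmr_khz = lmr, lpr_khz = lpr, level_db_spl = level,
                discarded = discarded, extrapolated = extrapolated)
  class(out) <- c("equivalent_level", class(out))
  out
}
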