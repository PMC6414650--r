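test_that("spike-band filter passes 1 kHz, rejects DC and 5 kHz", {
  fs <- 25000
  t <- (0:6499) / fs
  mid <- 1000:5500
  tone <- sin(2 * pi * 1000 * t)
  expect_equal(max(abs(filter_spike_band(tone, fs)[mid])), 1,
               tolerance = 0.01)
  expect_lt(max(abs(filter_spike_band(rep(1, length(t)), fs))), 1e-3)
  atten <- max(abs(filter_spike_band(sin(2 * pi * 5000 * t), fs)[mid]))
  expect_lt(20 * log10(atten), -30)
  # matrix input filters channel-wise
  m <- cbind(tone, rep(1, length(t)))
  fm <- filter_spike_band(m, fs)
  expect_equal(fm[, 1], filter_spike_band(tone, fs))
  expect_error(filter_spike_band(tone, fs = 5000), "too low")
})

test_that("threshold detection finds inserted spikes at their negative peak", {
  fs <- 25000
  set.seed(21)
  model <- response_model(spont_rate = 0, rate_growth = 0)
  tono <- synth_tonotopy()
  rec <- synth_trial(model, tono, NULL, seed = 2)  # pure noise
  trace <- filter_spike_band(rec$traces[, 1], fs)
  sd_bg <- mad(trace[1:250])
  # inject one 6-sigma biphasic template mid-record
  tmpl <- optopulse:::spike_template(fs, 6 * 10)
  at <- 3000
  trace2 <- trace
  idx <- at:(at + length(tmpl$wave) - 1)
  trace2[idx] <- trace2[idx] + filter_spike_band(
    c(rep(0, at - 1), tmpl$wave,
      rep(0, length(trace) - at + 1 - length(tmpl$wave))), fs)[idx]
  det <- detect_spikes(trace2, fs, noise_sd = sd_bg)
  base <- detect_spikes(trace, fs, noise_sd = sd_bg)
  new_t <- setdiff(round(det$time_s * fs), round(base$time_s * fs))
  # sample index of the template's negative peak, relative to the trigger
  peak_t <- (at + tmpl$peak - 1) - 1 - 0.010 * fs
  expect_true(any(abs(new_t - peak_t) <= 1))
  # events within 1 ms merge into one
  two <- numeric(6500)
  for (s in c(3000, 3012)) {
    two[s:(s + length(tmpl$wave) - 1)] <- two[s:(s + length(tmpl$wave) - 1)] +
      tmpl$wave
  }
  expect_equal(nrow(detect_spikes(two, fs, noise_sd = 10)), 1)
  # a background estimate is mandatory
  expect_error(detect_spikes(trace, fs, t0 = 0), "background")
})

test_that("false-positive rate on pure noise matches the crossing-rate
           oracle", {
  fs <- 25000
  dur <- 0.26
  n <- round(dur * fs)
  set.seed(77)
  events <- vapply(1:200, function(i) {
    x <- filter_spike_band(rnorm(n, sd = 10), fs)
    nrow(detect_spikes(x, fs, noise_sd = stats::sd(x[200:(n - 200)])))
  }, numeric(1))
  observed_rate <- sum(events) / (200 * dur)
  predicted <- rice_crossing_rate(3.5, 300, 3000)
  expect_gt(observed_rate, 0.5 * predicted)
  expect_lt(observed_rate, 1.5 * predicted)
})

test_that("detection scores on generator ground truth exceed 0.9", {
  blk <- detect_block(response_model(), synth_tonotopy(), optical_stim(4),
                      n_trials = 10, seed = 19)
  sc <- score_block(blk)
  expect_gt(sum(sc$n_matched) / sum(sc$n_detected), 0.9)
  expect_gt(sum(sc$n_matched) / sum(sc$n_truth), 0.9)
})

test_that("LFP averaging reduces independent noise about sqrt(20)-fold", {
  fs <- 25000
  n <- 2000
  set.seed(8)
  evoked <- 5 * sin(2 * pi * 200 * (0:(n - 1)) / fs)
  trials <- lapply(1:20, function(i) evoked + rnorm(n, sd = 10))
  lfp <- compute_lfp(trials, fs)
  resid <- lfp - filter_spike_band(evoked, fs, lo = 20, hi = 3000)
  noise1 <- stats::sd(filter_spike_band(trials[[1]] - evoked, fs,
                                        lo = 20, hi = 3000))
  expect_equal(stats::sd(resid), noise1 / sqrt(20), tolerance = 0.25)
  # identical trials pass through as the filtered single trial
  same <- lapply(1:20, function(i) evoked)
  expect_equal(compute_lfp(same, fs),
               zero_phase_bandpass(evoked, fs, 20, 3000))
  expect_true(all(compute_lfp(lapply(1:20, function(i) numeric(n)), fs) == 0))
  expect_error(compute_lfp(trials[1:19], fs), "at least 20")
})

test_that("PSTHs bin timestamps into half-open 1 ms bins", {
  empty <- suppressWarnings(
    build_psth(tibble::tibble(channel = integer(0), time_s = numeric(0)),
               n_trials = 10, channels = 1:2))
  expect_equal(sum(empty$count), 0)
  expect_equal(nrow(empty), 2 * 260)

  one <- suppressWarnings(
    build_psth(tibble::tibble(channel = 1L, time_s = 0.0123), n_trials = 10))
  expect_equal(one$time_ms[one$count == 1], 12)
  expect_warning(build_psth(tibble::tibble(channel = 1L, time_s = 0.0123),
                            n_trials = 10), "100")

  # homogeneous Poisson: mean bin count near rate * binwidth, counts conserved
  set.seed(14)
  r <- 200
  n_tr <- 150
  ts <- sort(runif(rpois(1, r * 0.26 * n_tr), -0.01, 0.25))
  sp <- tibble::tibble(channel = 1L, time_s = ts)
  psth <- build_psth(sp, n_trials = n_tr)
  expect_equal(sum(psth$count), length(ts))
  # mean count per 1 ms bin within 3 sd of rate * binwidth * trials
  expect_lt(abs(mean(psth$count) - r * 0.001 * n_tr),
            3 * sqrt(r * 0.001 * n_tr / 260))
})

test_that("rate summaries implement TSR, SSR and DSR", {
  times <- c(-0.008, 0.006, 0.02, 0.04, 0.05, 0.06, 0.08, 0.104, 0.2)
  rs <- rate_summary(times, ssr = 30)
  expect_equal(rs$tsr, 70)
  expect_equal(rs$dsr, 40)
  expect_equal(rate_summary(times, ssr = 70)$dsr, 0)
  # SSR estimated from the pre-trigger window when not supplied
  rs2 <- rate_summary(times)
  expect_equal(rs2$ssr, 1 / 0.010)
})

test_that("frequency response maps normalise per channel and demand a
           complete grid", {
  grid <- tidyr::expand_grid(channel = 1:2, freq_hz = c(1000, 2000, 4000),
                             level_db = c(20, 40), run = 1:7)
  sums <- dplyr::mutate(grid,
                        dsr = ifelse(channel == 1 & freq_hz == 2000 &
                                       level_db == 40, 50,
                                     ifelse(channel == 1, -2, 0)))
  frm <- build_frm(dplyr::select(sums, -run))
  expect_equal(frm$ndsr[frm$channel == 1 & frm$freq_hz == 2000 &
                          frm$level_db == 40], 1)
  expect_true(all(frm$ndsr[frm$channel == 1 & frm$freq_hz != 2000] == 0))
  # an unresponsive channel yields an all-zero map, not NaN
  expect_true(all(frm$ndsr[frm$channel == 2] == 0))
  expect_error(build_frm(dplyr::filter(dplyr::select(sums, -run),
                                       !(channel == 2 & freq_hz == 4000))),
               "missing cells")
  expect_warning(build_frm(dplyr::select(sums[sums$run <= 3 |
                                                sums$channel == 1, ], -run)),
                 "fewer than")
})

test_that("threshold and best frequency follow the map", {
  mk_frm <- function(vals) {
    df <- tidyr::expand_grid(channel = 1L, freq_hz = c(1000, 2000, 4000),
                             level_db = c(10, 20, 30))
    df$dsr <- vals
    build_frm(dplyr::bind_rows(df, df, df, df, df, df, df), min_runs = 7)
  }
  # response only at the top level (rows 3, 6, 9 are the 30 dB cells)
  v <- rep(0, 9); v[6] <- 60  # freq 2000 at level 30
  frm <- mk_frm(v)
  expect_equal(estimate_threshold(frm, 1), 30)
  # no response at all
  expect_true(is.na(estimate_threshold(mk_frm(rep(0, 9)), 1)))
  expect_error(best_frequency(mk_frm(rep(0, 9)), 1), "no threshold")
  # single-peaked map: BF at the peak frequency, 10 dB above threshold
  df <- tidyr::expand_grid(channel = 1L, freq_hz = c(1000, 2000, 4000),
                           level_db = c(10, 20, 30))
  df$dsr <- c(0, 10, 20,   0, 30, 60,   0, 12, 25)
  frm3 <- build_frm(do.call(dplyr::bind_rows, rep(list(df), 7)))
  expect_equal(estimate_threshold(frm3, 1), 20)
  bf <- best_frequency(frm3, 1)
  expect_equal(bf$bf_hz, 2000)
  expect_equal(bf$threshold_db, 20)
  # flat map at the BF level: deterministic geometric-mean tie rule
  df$dsr <- c(0, 10, 5,   0, 10, 5,   0, 10, 5)
  frm4 <- build_frm(do.call(dplyr::bind_rows, rep(list(df), 7)))
  bf4a <- best_frequency(frm4, 1)
  bf4b <- best_frequency(frm4, 1)
  expect_identical(bf4a$bf_hz, bf4b$bf_hz)
  expect_equal(bf4a$bf_hz, 2000)  # geometric mean of 1,2,4 kHz
})

test_that("modulation-rate/best-frequency correlation is Pearson's r", {
  pairs <- tibble::tibble(lmr_khz = c(1, 2, 4, 8, 10),
                          bf_hz = c(1, 2, 4, 8, 10) * 1000)
  res <- lmr_bf_correlation(pairs)
  expect_equal(unname(res$test$estimate), 1)
  td <- tidy(res)
  expect_equal(td$estimate, 1)
  expect_equal(glance(res)$n, 5)
  expect_error(lmr_bf_correlation(
    tibble::tibble(lmr_khz = c(1, 2, 4), bf_hz = c(5, 5, 5))), "variance")
  expect_error(lmr_bf_correlation(pairs[1:2, ]), "at least 3")
})

test_that("equivalent level interpolates the acoustic rate-level curve", {
  curve <- tibble::tibble(level_db = seq(0, 80, 10),
                          dsr = c(0, 0, 0, 10, 25, 40, 55, 70, 85))
  hit <- equivalent_level(55, curve, 8, 8, lmr = 1, lpr = 50)
  expect_equal(hit$level_db_spl, 60)
  expect_false(hit$discarded)
  mid <- equivalent_level(47.5, curve, 8, 8)
  expect_equal(mid$level_db_spl, 55)
  # best-frequency channel mismatch beyond one channel discards the value
  expect_true(equivalent_level(55, curve, 8, 6)$discarded)
  expect_false(equivalent_level(55, curve, 8, 7)$discarded)
  # optical rate above the whole curve flags extrapolation
  ex <- equivalent_level(120, curve, 8, 8)
  expect_true(ex$extrapolated)
  expect_true(is.na(ex$level_db_spl))
})

test_that("no-stimulus driven rate is centred on zero", {
  blk <- detect_block(response_model(), synth_tonotopy(), NULL,
                      n_trials = 100, seed = 55)
  rates <- block_rates(blk)
  dsr_bar <- mean(rates$dsr)
  # 3-sd bound from the per-trial Poisson variability of the mean
  se <- stats::sd(rates$dsr) / sqrt(nrow(rates))
  expect_lt(abs(dsr_bar), 3 * se + 0.5)
})
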