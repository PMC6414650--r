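test_that("run averaging is a pointwise mean with run-count policing", {
  x <- sin(2 * pi * 5 * (0:99) / 100)
  runs <- matrix(rep(x, 20), ncol = 20)
  expect_silent(avg <- average_runs(runs))
  expect_equal(avg, x)
  expect_warning(average_runs(matrix(x, ncol = 1)), "at least 17")
  expect_equal(suppressWarnings(average_runs(matrix(x, ncol = 1),
                                             min_runs = 1)), x)
  expect_silent(average_runs(matrix(x, ncol = 1), min_runs = 1))
  expect_error(average_runs(list(1:3, 1:4)), "same length")
})

test_that("averaging N noise runs shrinks the noise as 1/sqrt(N)", {
  set.seed(99)
  ratio <- replicate(100, {
    runs <- matrix(rnorm(200 * 17), ncol = 17)
    stats::sd(rowMeans(runs))
  })
  expect_equal(mean(ratio), 1 / sqrt(17), tolerance = 0.2)
})

test_that("single-sided spectrum is amplitude calibrated", {
  fs <- 1000
  t <- (0:499) / fs
  # bin-centred unit sinusoid -> amplitude 1 at its bin
  spec <- single_sided_spectrum(sin(2 * pi * 10 * t), fs)
  expect_equal(spec$amplitude[spec$freq_hz == 10], 1, tolerance = 1e-6)
  expect_equal(attr(spec, "df"), 2)
  # zero signal -> zero spectrum
  expect_true(all(single_sided_spectrum(numeric(64), fs)$amplitude == 0))
  # linearity: two tones at different amplitudes
  two <- sin(2 * pi * 10 * t) + 0.5 * sin(2 * pi * 50 * t)
  spec2 <- single_sided_spectrum(two, fs)
  expect_equal(spec2$amplitude[spec2$freq_hz == 10], 1, tolerance = 1e-6)
  expect_equal(spec2$amplitude[spec2$freq_hz == 50], 0.5, tolerance = 1e-6)
  # Hann taper keeps bin-centred amplitudes calibrated
  spec3 <- single_sided_spectrum(two, fs, window = "hann")
  expect_equal(spec3$amplitude[spec3$freq_hz == 50], 0.5, tolerance = 1e-3)
  expect_error(single_sided_spectrum(1, fs), "two samples")
})

test_that("time and frequency domain power agree (Parseval)", {
  set.seed(4)
  for (n in c(256, 255)) {
    x <- rnorm(n)
    spec <- single_sided_spectrum(x, 1000)
    a <- spec$amplitude
    half <- rep(0.5, length(a))
    half[1] <- 1                       # DC unpaired
    if (n %% 2 == 0) half[length(a)] <- 1  # Nyquist unpaired for even n
    expect_equal(sum(a^2 * half), mean(x^2), tolerance = 1e-6)
  }
})

test_that("SNR follows the 20 log10 amplitude-ratio form", {
  expect_equal(snr_db(3, 3), 0)
  expect_equal(snr_db(10, 1), 20)
  expect_equal(snr_db(2, 1), 6.0206, tolerance = 1e-4)
  expect_error(snr_db(1, 0), "positive")
  expect_error(snr_db(1, -2), "positive")
})

test_that("peak extraction reads f0, h2, carrier and sidebands", {
  fs <- 2e5
  t <- (0:19999) / fs  # 100 ms -> 10 Hz bins
  x <- 1.0 * sin(2 * pi * 4000 * t) + 0.2 * sin(2 * pi * 8000 * t) +
    0.5 * sin(2 * pi * 50000 * t) + 0.25 * sin(2 * pi * 46000 * t) +
    0.25 * sin(2 * pi * 54000 * t)
  set.seed(12)
  noise <- rnorm(length(t), sd = 0.001)
  spec <- single_sided_spectrum(x + noise, fs)
  nspec <- single_sided_spectrum(rnorm(length(t), sd = 0.001), fs)
  pk <- extract_peaks(spec, nspec, lmr = 4, lpr = 50)
  expect_equal(pk$freq_hz[pk$peak == "f0"], 4000)
  expect_equal(pk$freq_hz[pk$peak == "h2"], 8000)
  expect_equal(pk$freq_hz[pk$peak == "lpr"], 50000)
  expect_equal(pk$freq_hz[pk$peak == "sideband_lo"], 46000)
  expect_equal(pk$freq_hz[pk$peak == "sideband_hi"], 54000)
  expect_equal(pk$amplitude[pk$peak == "f0"], 1, tolerance = 0.01)
  expect_true(all(pk$snr_db > 20))

  # the carrier is unavailable beyond Nyquist
  lo <- single_sided_spectrum((x + noise)[1:2000], 2e4)
  lon <- single_sided_spectrum(noise[1:2000], 2e4)
  pk2 <- extract_peaks(lo, lon, lmr = 4, lpr = 50)
  expect_false(pk2$available[pk2$peak == "lpr"])
  expect_true(is.na(pk2$snr_db[pk2$peak == "lpr"]))

  # a spectrum against itself: all SNRs collapse to 0 dB (single-bin noise)
  pk3 <- extract_peaks(spec, spec, lmr = 4, lpr = 50, noise_avg_bins = 0)
  expect_true(all(abs(pk3$snr_db) < 1e-9))
  expect_false(any(pk3$clamped))

  # h2/carrier/sideband SNRs clamp at 0 dB when below the noise
  weak <- single_sided_spectrum(1.0 * sin(2 * pi * 4000 * t) +
                                  noise * 0.001, fs)
  pk4 <- extract_peaks(weak, nspec, lmr = 4, lpr = 50)
  expect_true(all(pk4$snr_db[pk4$peak != "f0"] == 0))
  expect_true(all(pk4$clamped[pk4$peak != "f0"]))

  # mismatched noise record is refused
  expect_error(extract_peaks(spec, lon, 4, 50), "match")
})

test_that("quality control applies the 6 dB fundamental-SNR rule", {
  mk <- function(snr) {
    pk <- tibble::tibble(peak = "f0", freq_hz = 1000, amplitude = 1,
                         noise_amplitude = 10^(-snr / 20), snr_db = snr,
                         clamped = FALSE, available = TRUE)
    class(pk) <- c("spectral_peaks", class(pk))
    pk
  }
  expect_false(qc_measurement(mk(5.9))$accepted)
  expect_true(qc_measurement(mk(6.0))$accepted)
  expect_true(qc_measurement(mk(25))$accepted)
})

test_that("vibration band-pass preserves the passband and rejects DC", {
  fs <- 1e5
  t <- (0:9999) / fs
  mid <- 2000:8000
  tone5k <- sin(2 * pi * 5000 * t)
  expect_equal(max(abs(bandpass_vibration(tone5k, fs)[mid])), 1,
               tolerance = 0.01)
  expect_lt(max(abs(bandpass_vibration(rep(1, length(t)), fs))), 1e-3)
  # 20 kHz: the designed zero-phase response gives 1/(1+(20/12)^8)
  atten <- max(abs(bandpass_vibration(sin(2 * pi * 20000 * t), fs)[mid]))
  expect_equal(20 * log10(atten), 20 * log10(1 / (1 + (20 / 12)^8)),
               tolerance = 0.05)
  expect_lt(20 * log10(atten), -30)
  expect_error(bandpass_vibration(tone5k, fs = 20000), "too low")
})
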