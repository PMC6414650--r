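#' Average repeated measurement runs
#'
#' Pointwise mean over runs. The offline vibrometry protocol averages a
#' minimum of 17 runs; fewer runs produce a warning, not an error.
#'
#' @param runs A samples-by-runs matrix, or a list of equal-length vectors.
#' @param min_runs Minimum expected run count. Default 17.
#' @return The averaged record (numeric vector).
#' @export
average_runs <- function(runs, min_runs = 17) {
  if (is.list(runs) && !is.data.frame(runs)) {
    lens <- lengths(runs)
    if (length(unique(lens)) != 1L) {
      abort("All runs must have the same length.")
    }
    runs <- do.call(cbind, runs)
  }
  if (!is.matrix(runs)) runs <- matrix(runs, ncol = 1)
  if (ncol(runs) < min_runs) {
    warn(sprintf("Only %d run(s) averaged; the protocol expects at least %d.",
                 ncol(runs), min_runs))
  }
  rowMeans(runs)
}

#' Single-sided amplitude spectrum
#'
#' Discrete Fourier amplitude spectrum with the single-sided convention:
#' `A(f) = 2 |X(f)| / N` for `0 < f < ` Nyquist, `|X(0)| / N` at DC (and
#' `|X| / N` at the unpaired Nyquist bin for even record lengths). A
#' unit-amplitude sinusoid centred on a bin yields amplitude 1 at that bin.
#'
#' @param x Real-valued record.
#' @param fs Sampling rate, Hz.
#' @param window `"none"` (default) or `"hann"`. The Hann taper suppresses
#'   leakage skirts from non-stationary components (e.g. onset transients);
#'   amplitudes are corrected for the window's coherent gain, so
#'   bin-centred sinusoid amplitudes stay calibrated.
#' @return A tibble of class `amplitude_spectrum` with columns `freq_hz` and
#'   `amplitude`; attributes `df` (bin width, Hz = 1/record duration), `fs`
#'   and `n`.
#' @export
single_sided_spectrum <- function(x, fs, window = c("none", "hann")) {
  window <- match.arg(window)
  n <- length(x)
  if (n < 2) abort("Need at least two samples.")
  if (window == "hann") {
    w <- 0.5 * (1 - cos(2 * pi * (seq_len(n) - 1) / n))
    x <- x * w / mean(w)
  }
  X <- fft(x)
  half <- floor(n / 2) + 1L
  amp <- Mod(X[seq_len(half)]) / n
  scale2 <- rep(2, half)
  scale2[1] <- 1
  if (n %% 2 == 0) scale2[half] <- 1
  out <- tibble(freq_hz = (seq_len(half) - 1) * fs / n,
                amplitude = amp * scale2)
  attr(out, "df") <- fs / n
  attr(out, "fs") <- fs
  attr(out, "n") <- n
  class(out) <- c("amplitude_spectrum", class(out))
  out
}

#' Signal-to-noise ratio in dB
#'
#' `SNR = 20 * log10(peak_signal / peak_noise)`, comparing a spectral peak
#' amplitude against the amplitude of the no-stimulus noise spectrum at the
#' same frequency.
#'
#' @param peak_signal Signal peak amplitude (> 0 for a finite result).
#' @param peak_noise Noise amplitude at the same frequency; must be positive.
#' @return SNR in dB.
#' @examples
#' snr_db(10, 1) # 20
#' @export
snr_db <- function(peak_signal, peak_noise) {
  if (any(!is.finite(peak_noise)) || any(peak_noise <= 0)) {
    abort("`peak_noise` must be positive.")
  }
  20 * log10(peak_signal / peak_noise)
}

#' Extract fundamental, harmonic, carrier and sideband peaks
#'
#' Reads the displacement spectrum at the bins nearest the modulation rate
#' (f0), its second harmonic (h2), the carrier (LPR) and the two carrier
#' sidebands (LPR +/- LMR), refining each location by a local-maximum search
#' within +/-2 bins. SNRs follow [snr_db()] against the no-stimulus noise
#' spectrum at the matching bin; the h2, LPR and sideband SNRs are clamped
#' at 0 dB. Peaks at or above the Nyquist frequency are marked unavailable.
#'
#' @param spec Amplitude spectrum of the stimulated measurement.
#' @param noise_spec Amplitude spectrum of a no-stimulus record of identical
#'   length and sampling rate.
#' @param lmr,lpr Modulation and carrier rates, kHz.
#' @param search_bins Half-width of the local-maximum search. Default 2.
#' @param noise_avg_bins Half-width (in bins) of the neighbourhood over
#'   which the noise spectrum is averaged to estimate the noise value at a
#'   frequency. Averaging stabilises the per-bin Rayleigh fluctuation of a
#'   finite noise record; 0 uses the single bin. Default 3.
#' @return A tibble of class `spectral_peaks` with one row per peak
#'   (`peak`, `freq_hz`, `amplitude`, `noise_amplitude`, `snr_db`,
#'   `clamped`, `available`); attributes `lmr`, `lpr`, `df`.
#' @export
extract_peaks <- function(spec, noise_spec, lmr, lpr, search_bins = 2,
                          noise_avg_bins = 3) {
  stopifnot(inherits(spec, "amplitude_spectrum"),
            inherits(noise_spec, "amplitude_spectrum"))
  if (nrow(spec) != nrow(noise_spec) ||
      !isTRUE(all.equal(attr(spec, "df"), attr(noise_spec, "df")))) {
    abort("Noise spectrum must match the signal spectrum in length and bin width.")
  }
  nyquist <- attr(spec, "fs") / 2
  targets <- tibble(
    peak = c("f0", "h2", "lpr", "sideband_lo", "sideband_hi"),
    target_hz = c(lmr, 2 * lmr, lpr, lpr - lmr, lpr + lmr) * 1000,
    clamp = c(FALSE, TRUE, TRUE, TRUE, TRUE)
  )
  rows <- purrr::pmap(targets, function(peak, target_hz, clamp) {
    if (target_hz >= nyquist || target_hz <= 0) {
      return(tibble(peak = peak, freq_hz = NA_real_, amplitude = NA_real_,
                    noise_amplitude = NA_real_, snr_db = NA_real_,
                    clamped = FALSE, available = FALSE))
    }
    i0 <- which.min(abs(spec$freq_hz - target_hz))
    win <- max(2L, i0 - search_bins):min(nrow(spec), i0 + search_bins)
    i <- win[which.max(spec$amplitude[win])]
    s <- spec$amplitude[i]
    nwin <- max(2L, i - noise_avg_bins):min(nrow(spec), i + noise_avg_bins)
    nz <- mean(noise_spec$amplitude[nwin])
    snr <- if (nz > 0) snr_db(s, nz) else Inf
    clamped <- FALSE
    if (clamp && snr < 0) {
      snr <- 0
      clamped <- TRUE
    }
    tibble(peak = peak, freq_hz = spec$freq_hz[i], amplitude = s,
           noise_amplitude = nz, snr_db = snr, clamped = clamped,
           available = TRUE)
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "lmr") <- lmr
  attr(out, "lpr") <- lpr
  attr(out, "df") <- attr(spec, "df")
  class(out) <- c("spectral_peaks", class(out))
  out
}

#' Quality control of a vibration measurement
#'
#' A measurement is accepted when the fundamental-peak SNR is at least 6 dB
#' (the discard rule is "below 6 dB"; the boundary is inclusive).
#'
#' @param peaks A [extract_peaks()] result.
#' @return A one-row tibble with `accepted` and `reason`.
#' @export
qc_measurement <- function(peaks) {
  stopifnot(inherits(peaks, "spectral_peaks"))
  snr_f0 <- peaks$snr_db[peaks$peak == "f0"]
  if (length(snr_f0) != 1 || is.na(snr_f0)) {
    return(tibble(accepted = FALSE, reason = "fundamental peak unavailable"))
  }
  if (snr_f0 >= 6) {
    tibble(accepted = TRUE, reason = sprintf("f0 SNR %.1f dB >= 6 dB", snr_f0))
  } else {
    tibble(accepted = FALSE, reason = sprintf("f0 SNR %.1f dB below 6 dB", snr_f0))
  }
}
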