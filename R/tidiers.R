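#' Tidy and summarise spectral peak tables
#'
#' `tidy()` returns the per-peak table; `glance()` a one-row summary with
#' the fundamental location, the three SNRs and the quality-control flag.
#'
#' @param x A [extract_peaks()] result.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.spectral_peaks <- function(x, ...) {
  as_tibble(x)
}

#' @rdname tidy.spectral_peaks
#' @export
glance.spectral_peaks <- function(x, ...) {
  pk <- function(p, col) x[[col]][x$peak == p]
  tibble(
    lpr_khz = attr(x, "lpr"), lmr_khz = attr(x, "lmr"),
    f0_hz = pk("f0", "freq_hz"),
    snr_f0_db = pk("f0", "snr_db"),
    snr_h2_db = pk("h2", "snr_db"),
    snr_lpr_db = pk("lpr", "snr_db"),
    accepted = qc_measurement(x)$accepted
  )
}

#' Tidy and summarise modulation-rate/best-frequency correlations
#'
#' `tidy()` reports the Pearson estimate with its confidence interval and
#' p-value; `glance()` adds the pair count.
#'
#' @param x A [lmr_bf_correlation()] result.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.lmr_bf_cor <- function(x, ...) {
  ct <- x$test
  tibble(
    estimate = unname(ct$estimate),
    statistic = unname(ct$statistic),
    p.value = ct$p.value,
    parameter = unname(ct$parameter),
    conf.low = ct$conf.int[1],
    conf.high = ct$conf.int[2],
    method = ct$method,
    alternative = ct$alternative
  )
}

#' @rdname tidy.lmr_bf_cor
#' @export
glance.lmr_bf_cor <- function(x, ...) {
  mutate(tidy(x), n = nrow(x$data))
}

#' @rdname tidy.lmr_bf_cor
#' @export
tidy.lmr_bf_study <- function(x, ...) {
  x$pairs
}

#' @rdname tidy.lmr_bf_cor
#' @export
glance.lmr_bf_study <- function(x, ...) {
  glance(x$correlation)
}

#' Tidy and summarise vibration analyses
#'
#' `tidy()` returns the peak table of the analysis, `glance()` its one-row
#' summary.
#'
#' @param x An [analyze_vibration()] result.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.vibration_analysis <- function(x, ...) {
  as_tibble(x$peaks)
}

#' @rdname tidy.vibration_analysis
#' @export
glance.vibration_analysis <- function(x, ...) {
  glance(x$peaks)
}
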