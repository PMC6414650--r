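# Columnar text files with a "# key: value" metadata header block.

write_columnar <- function(df, path, meta = list()) {
  header <- vapply(names(meta), function(k) sprintf("# %s: %s", k, meta[[k]]),
                   character(1))
  writeLines(header, path)
  readr::write_csv(df, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

read_columnar <- function(path) {
  lines <- readLines(path, n = 100)
  hdr <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (h in hdr) {
    kv <- sub("^#\\s*", "", h)
    key <- sub(":.*$", "", kv)
    val <- trimws(sub("^[^:]*:\\s*", "", kv))
    num <- suppressWarnings(as.numeric(val))
    meta[[trimws(key)]] <- if (!is.na(num)) num else val
  }
  df <- readr::read_csv(path, comment = "#", show_col_types = FALSE)
  attr(df, "meta") <- meta
  df
}

#' Read and write pulse trains as columnar text
#'
#' Pulse trains are stored as `time_s, amplitude, energy_uj` with the
#' stimulus parameters in a `# key: value` header block.
#'
#' @param train A [make_pulse_train()] result.
#' @param path File path.
#' @return `write_pulse_train()` returns the path invisibly;
#'   `read_pulse_train()` returns a `pulse_train` tibble.
#' @export
write_pulse_train <- function(train, path) {
  stopifnot(inherits(train, "pulse_train"))
  p <- attr(train, "params")
  write_columnar(as_tibble(train)[, c("time_s", "amplitude", "energy_uj")],
                 path,
                 meta = list(lpr_khz = p$lpr, lmr_khz = p$lmr,
                             duration_ms = p$duration, ramp_ms = p$ramp,
                             peak_power_mw = p$peak_power,
                             unit_rate = p$unit_rate))
}

#' @rdname write_pulse_train
#' @export
read_pulse_train <- function(path) {
  df <- read_columnar(path)
  m <- attr(df, "meta")
  params <- stimulus_params(lpr = m$lpr_khz, lmr = m$lmr_khz,
                            duration = m$duration_ms, ramp = m$ramp_ms,
                            peak_power = m$peak_power_mw,
                            unit_rate = m$unit_rate)
  out <- as_tibble(df)
  attr(out, "params") <- params
  class(out) <- c("pulse_train", class(out))
  out
}

#' Read and write impulse responses as columnar text
#'
#' Impulse responses are stored as `time_s, velocity` (plus `displacement`
#' when present) with the sampling rate and reference stimulus energy in
#' the header.
#'
#' @param ir An `impulse_response` tibble.
#' @param path File path.
#' @return `write_impulse_response()` returns the path invisibly;
#'   `read_impulse_response()` returns an `impulse_response` tibble.
#' @export
write_impulse_response <- function(ir, path) {
  stopifnot(inherits(ir, "impulse_response"))
  write_columnar(as_tibble(ir), path,
                 meta = list(fs_hz = attr(ir, "fs"),
                             stimulus_energy_uj = attr(ir, "stimulus_energy")))
}

#' @rdname write_impulse_response
#' @export
read_impulse_response <- function(path) {
  df <- read_columnar(path)
  m <- attr(df, "meta")
  out <- as_tibble(df)
  attr(out, "fs") <- m$fs_hz
  attr(out, "stimulus_energy") <- m$stimulus_energy_uj
  class(out) <- c("impulse_response", class(out))
  out
}
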