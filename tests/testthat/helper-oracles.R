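# Independent oracles used across the suite.

# O(N^2) full linear convolution, index by index.
brute_convolve <- function(x, h) {
  nx <- length(x)
  nh <- length(h)
  y <- numeric(nx + nh - 1)
  for (n in seq_along(y)) {
    k <- max(1, n - nh + 1):min(nx, n)
    y[n] <- sum(x[k] * h[n - k + 1])
  }
  y
}

# Rice formula: expected rate of negative crossings of level -u*sd for
# Gaussian noise band-limited to [lo, hi] Hz (flat band).
rice_crossing_rate <- function(u, lo, hi) {
  nu0 <- sqrt((hi^3 - lo^3) / (3 * (hi - lo)))
  nu0 * exp(-u^2 / 2)
}

# published pulses-per-period table: (LPR kHz, LMR kHz, pulses)
table2 <- data.frame(
  lpr = c(32, 50, 32, 50, 32, 50, 32, 50, 32, 50, 32, 50),
  lmr = c(1, 1, 2, 2, 4, 4, 8, 8, 10, 10, 16, 16),
  pulses = c(32, 50, 16, 25, 8, 12.5, 4, 6.25, 3.2, 5, 2, 3.125)
)

# published power/energy table: (LPR kHz, peak power mW, energy uJ)
table3 <- data.frame(
  lpr = c(50, 32, 50, 32, 50, 32, 50, 32, 50, 32, 50, 32, 50),
  power = c(20, 32, 30, 48, 50, 83.2, 75, 128, 130, 201.6, 200, 320, 315),
  energy = c(0.4, 1, 0.6, 1.5, 1, 2.6, 1.5, 4, 2.6, 6.3, 4, 10, 6.3)
)

# default study frequency grid and helpers
default_grid <- function() frm_frequencies(1000, 22000)

grid_index <- function(f, grid = default_grid()) {
  vapply(f, function(x) which.min(abs(log(grid) - log(x))), integer(1))
}

# score all trial/channel pairs of a detected block against its ground truth
score_block <- function(block) {
  out <- list()
  k <- 0L
  for (tr in unique(block$truth$trial)) {
    for (ch in unique(block$truth$channel)) {
      d <- block$detections$time_s[block$detections$trial == tr &
                                     block$detections$channel == ch]
      g <- block$truth$time_s[block$truth$trial == tr &
                                block$truth$channel == ch]
      k <- k + 1L
      out[[k]] <- score_detection(d, g)
    }
  }
  dplyr::bind_rows(out)
}
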