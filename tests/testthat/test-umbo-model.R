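test_that("synthetic impulse response is deterministic and mode-faithful", {
  p <- oscillator_params(noise_sd = 1e-6)
  ir1 <- synth_impulse_response(p, seed = 5)
  ir2 <- synth_impulse_response(p, seed = 5)
  expect_identical(ir1$velocity, ir2$velocity)

  # noise-free single mode matches the analytic damped-oscillator velocity
  m <- oscillator_params(modes = tibble::tibble(freq_hz = 3000, zeta = 0.05,
                                                gain = 1e-4))
  ir <- synth_impulse_response(m, fs = 2e5, duration = 0.05)
  a <- 2 * pi * 3000 * 0.05
  wd <- 2 * pi * 3000 * sqrt(1 - 0.05^2)
  t <- ir$time_s
  expect_equal(ir$velocity,
               1e-4 * exp(-a * t) * (cos(wd * t) - a / wd * sin(wd * t)))

  # spectral maximum at the damped resonance (within a couple of bins)
  spec <- single_sided_spectrum(ir$velocity, 2e5)
  fpk <- spec$freq_hz[which.max(spec$amplitude)]
  expect_lt(abs(fpk - 3000 * sqrt(1 - 0.05^2)), 2.5 * attr(spec, "df"))

  # the record decays: tail mean below 1% of the peak
  tail_mean <- mean(abs(utils::tail(ir$velocity, 100)))
  expect_lt(tail_mean, 0.01 * max(abs(ir$velocity)))
})

test_that("velocity integrates to detrended displacement", {
  fs <- 1e5
  mk <- function(v) {
    ir <- tibble::tibble(time_s = (seq_along(v) - 1) / fs, velocity = v)
    attr(ir, "fs") <- fs
    class(ir) <- c("impulse_response", class(ir))
    ir
  }
  # constant velocity integrates to a line, removed entirely by the detrend
  d <- velocity_to_displacement(mk(rep(2, 1000)))
  expect_equal(d$displacement, rep(0, 1000), tolerance = 1e-9)
  expect_equal(nrow(d), 1000)
  # zero in, zero out
  expect_equal(velocity_to_displacement(mk(numeric(500)))$displacement,
               numeric(500))
  # sinusoid: amplitude 1/(2 pi f), phase -90 degrees
  f <- 2000  # 20 bins over the 10 ms record
  t <- (0:999) / fs
  d <- velocity_to_displacement(mk(sin(2 * pi * f * t)))
  expect_equal(max(abs(d$displacement)), 1 / (2 * pi * f), tolerance = 0.01)
  mid <- 200:800
  expect_lt(max(abs(d$displacement[mid] +
                      cos(2 * pi * f * t[mid]) / (2 * pi * f))),
            0.01 / (2 * pi * f))
})

test_that("model input sequence samples the raised sinusoid at the carrier", {
  inp <- build_input_sequence(stimulus_params(lpr = 8, lmr = 2,
                                              peak_power = 10))
  expect_equal(inp$weight[1:8], rep(c(1, 2, 1, 0), 2), tolerance = 1e-12)
  expect_equal(inp$weight[1], 1)
  inp2 <- build_input_sequence(stimulus_params(50, 1, peak_power = 10))
  expect_equal(nrow(inp2), 5000)
  expect_equal(inp2$weight[1:50], inp2$weight[51:100], tolerance = 1e-9)
})

test_that("convolution model obeys the LTI contract", {
  set.seed(31)
  fs <- 1e5
  h <- tibble::tibble(time_s = (0:199) / fs, velocity = rnorm(200))
  attr(h, "fs") <- fs
  class(h) <- c("impulse_response", class(h))
  h <- velocity_to_displacement(h)

  mk_input <- function(w, dt) {
    inp <- tibble::tibble(time_s = (seq_along(w) - 1) * dt, weight = w)
    attr(inp, "lpr") <- 1 / dt / 1000
    attr(inp, "lmr") <- 1
    attr(inp, "dt") <- dt
    class(inp) <- c("model_input", class(inp))
    inp
  }

  # delta input returns the impulse response exactly
  out <- convolve_model(mk_input(c(1), 1 / fs), h)
  expect_equal(out$y[seq_len(200)], h$displacement)

  # linearity: scaling the input scales the output
  w <- runif(20)
  y1 <- convolve_model(mk_input(w, 1e-4), h)$y
  y3 <- convolve_model(mk_input(3 * w, 1e-4), h)$y
  expect_equal(y3, 3 * y1, tolerance = 1e-12)

  # superposition
  w2 <- runif(20)
  ya <- convolve_model(mk_input(w + w2, 1e-4), h)$y
  yb <- convolve_model(mk_input(w, 1e-4), h)$y +
    convolve_model(mk_input(w2, 1e-4), h)$y
  expect_equal(ya, yb, tolerance = 1e-9)

  # brute-force O(N^2) oracle on dense instances up to 1000 samples
  for (n in c(100, 1000)) {
    x <- rnorm(n)
    hh <- rnorm(min(n, 300))
    expect_equal(stats::convolve(x, rev(hh), type = "open"),
                 brute_convolve(x, hh), tolerance = 1e-9)
  }
  # and through the model path itself (inputs on the h grid)
  w <- runif(100)
  y <- convolve_model(mk_input(w, 1 / fs), h)$y
  expect_equal(y, brute_convolve(w, h$displacement), tolerance = 1e-9)

  # incommensurate carrier grid warns
  expect_warning(convolve_model(mk_input(runif(30), 1.00407e-4), h),
                 "incommensurate")
})

test_that("time-shifted input yields time-shifted output", {
  set.seed(7)
  fs <- 1e5
  h <- tibble::tibble(time_s = (0:99) / fs, velocity = rnorm(100))
  attr(h, "fs") <- fs
  class(h) <- c("impulse_response", class(h))
  h <- velocity_to_displacement(h)
  w <- runif(10)
  mk <- function(w, t0 = 0) {
    inp <- tibble::tibble(time_s = t0 + (seq_along(w) - 1) * 1e-4, weight = w)
    attr(inp, "lpr") <- 10
    attr(inp, "lmr") <- 1
    attr(inp, "dt") <- 1e-4
    class(inp) <- c("model_input", class(inp))
    inp
  }
  y0 <- convolve_model(mk(w), h)$y
  k <- 30  # three carrier steps on the h grid
  y1 <- convolve_model(mk(w, t0 = k / fs), h)$y
  n <- length(y0)
  expect_equal(y1[(k + 1):(n)], y0[seq_len(n - k)], tolerance = 1e-12)
})

test_that("predicted spectra are fundamental-normalised and guard degeneracy", {
  ir <- velocity_to_displacement(synth_impulse_response(fs = 4e5))
  p <- stimulus_params(50, 4, peak_power = 100)
  out <- convolve_model(build_input_sequence(p), ir)
  spec <- predict_spectrum(out)
  f0 <- attr(spec, "f0_hz")
  expect_equal(spec$amplitude[spec$freq_hz == f0], 1)
  expect_lt(abs(f0 - 4000), attr(spec, "df") + 1e-9)

  out$y <- 0 * out$y
  expect_error(predict_spectrum(out), "[Dd]egenerate")
})
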