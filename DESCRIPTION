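Package: optopulse
Title: Amplitude-Modulated Laser Pulse Stimulation and Auditory Response Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Synthesis and analysis tools for optoacoustic stimulation of the
    middle ear with amplitude-modulated laser pulse trains. Provides pulse-train
    generation with power and energy bookkeeping, a convolution-based linear
    time-invariant model predicting umbo displacement from a measured or
    synthetic impulse response, an offline vibrometry pipeline (zero-phase
    band-pass filtering, run averaging, velocity-to-displacement integration,
    single-sided amplitude spectra, harmonic and sideband peak extraction with
    signal-to-noise quality control), a synthetic 16-channel extracellular
    recording generator with a tonotopic gradient and inhomogeneous-Poisson
    spiking, and the spike analysis chain: threshold detection, peri-stimulus
    time histograms, driven spike rates, frequency response maps, best-frequency
    estimation, modulation-rate/best-frequency correlation, and acoustic
    equivalent-level estimation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
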