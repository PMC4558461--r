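# EEG preprocessing, window-length selection, AR spectral estimation and
# onset-aligned averaging

test_that("band-pass and notch filtering meet their design responses", {
  fs <- 512
  t <- seq(1 / fs, 10, by = 1 / fs)
  core <- (fs):(9 * fs)             # avoid filter edge transients
  f50 <- eeg_preprocess(sin(2 * pi * 50 * t), fs)
  att <- 20 * log10(sd(f50[core]) / sd(sin(2 * pi * 50 * t)))
  expect_lt(att, -30)
  f10 <- eeg_preprocess(sin(2 * pi * 10 * t), fs)
  expect_lt(abs(sd(f10[core]) / sd(sin(2 * pi * 10 * t)) - 1), 0.05)
  # band edges of the single-pass Butterworth design sit at -3 dB
  bp <- signal::butter(5, c(0.5, 70) / (fs / 2), type = "pass")
  h <- signal::freqz(bp$b, bp$a, 2 * pi * c(0.5, 70) / fs)$h
  expect_equal(abs(h), rep(1 / sqrt(2), 2), tolerance = 1e-3)
  expect_error(eeg_preprocess(rnorm(100), fs = 100), "160")
})

test_that("multichannel input is re-referenced to the common average", {
  fs <- 256
  set.seed(41)
  x <- matrix(rnorm(fs * 4 * 3), ncol = 3)
  x[, 1] <- x[, 1] + 5 * sin(2 * pi * 3 * seq_len(nrow(x)) / fs)  # common-ish
  y <- eeg_preprocess(x, fs)
  yref <- eeg_preprocess(x - rowMeans(x), fs)
  expect_equal(y, yref, tolerance = 1e-6)
})

test_that("window-length selection distinguishes stationary from chirping data", {
  fs <- 256
  set.seed(9)
  r <- 0.9; f0 <- 10
  xs <- as.numeric(stats::filter(rnorm(60 * fs),
                                 c(2 * r * cos(2 * pi * f0 / fs), -r^2),
                                 method = "recursive"))
  ws <- select_window_length(xs, fs)
  expect_equal(as.numeric(ws), 4)        # stationary: the largest candidate
  expect_true(2.0 %in% eval(formals(select_window_length)$candidates))
  tt <- seq(0, 4, length.out = 4 * fs)
  ph <- 2 * pi * cumsum(20 + (5 - 20) * tt / 4) / fs
  ch <- rep(sin(ph), 15) + 0.2 * rnorm(60 * fs)
  expect_warning(wc <- select_window_length(ch, fs), "90")
  expect_lt(as.numeric(wc), as.numeric(ws))  # chirp: a shorter window
  expect_error(select_window_length(xs, fs, candidates = c(2, 1)), "ascending")
})

test_that("AR spectra are calibrated: flat noise, resonances, Parseval", {
  fs <- 256
  set.seed(5)
  # white noise is flat within +-20% over 1-40 Hz
  d <- ar_spectrum(rnorm(2 * fs), fs, order = 8)
  expect_true(all(abs(d / mean(d) - 1) < 0.2))
  # an AR(2) resonance at 10 Hz peaks within +-1 Hz
  r <- 0.95
  x2 <- as.numeric(stats::filter(rnorm(2 * fs),
                                 c(2 * r * cos(2 * pi * 10 / fs), -r^2),
                                 method = "recursive"))
  d2 <- ar_spectrum(x2, fs, order = 8)
  expect_lte(abs(frequency_grid()[which.max(d2)] - 10), 1)
  # the density integrates to the segment variance over 0..Nyquist
  set.seed(6)
  xn <- rnorm(2 * fs)
  grid <- seq(0.25, fs / 2, by = 0.25)
  dens <- ar_spectrum(xn, fs, order = 8, freq = grid)
  expect_lt(abs(sum(dens) * 0.25 / var(xn) - 1), 0.1)
  expect_error(ar_spectrum(rnorm(16), fs, order = 8), "too short")
})

test_that("windowing and averaging follow the onset-aligned rules", {
  fs <- 250
  set.seed(13)
  s20 <- rnorm(20 * fs)
  s60 <- rnorm(60 * fs)
  expect_equal(nrow(build_spectral_data(s20, fs)$S), 10)   # 20 s -> 10 windows
  expect_equal(nrow(build_spectral_data(s60, fs)$S), 30)   # 60 s -> 30
  # two identical seizures average to either one
  one <- build_spectral_data(s20, fs)
  two <- build_spectral_data(list(s20, s20), fs)
  expect_equal(two$S, one$S)
  expect_equal(two$n_seizures, 2)
  # unequal lengths: late windows averaged over the subset that has them
  mix <- build_spectral_data(list(s20, s60), fs)
  expect_equal(nrow(mix$S), 30)
  expect_equal(mix$n_avg, c(rep(2L, 10), rep(1L, 20)))
  # trailing partial windows are discarded
  expect_equal(nrow(build_spectral_data(rnorm(4.9 * fs), fs)$S), 2)
  # onsets shift the first window
  sh <- build_spectral_data(list(c(rnorm(2 * fs), s20)), fs, onsets = 2)
  expect_equal(sh$S, one$S, tolerance = 1e-10)
})

test_that("averaging across seizures shrinks spectral variance like 1/n", {
  fs <- 250
  set.seed(17)
  mk <- function() as.numeric(stats::filter(rnorm(8 * fs), 0.6,
                                            method = "recursive"))
  spectra <- t(replicate(24, build_spectral_data(mk(), fs,
                                                 preprocess = FALSE)$S[1, ]))
  v1 <- mean(apply(spectra, 2, var))
  groups <- matrix(seq_len(24), nrow = 4)
  means4 <- t(apply(groups, 2, function(i) colMeans(spectra[i, ])))
  v4 <- mean(apply(means4, 2, var))
  expect_lt(abs(v1 / v4 / 4 - 1), 0.25)
})

test_that("the feature pipeline is deterministic", {
  fs <- 250
  set.seed(19)
  sz <- list(rnorm(10 * fs), rnorm(12 * fs))
  a <- build_spectral_data(sz, fs)
  b <- build_spectral_data(sz, fs)
  expect_identical(a, b)
})
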