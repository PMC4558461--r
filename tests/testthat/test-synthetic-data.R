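# the seizure generator: noise synthesis, the two simulation routes and
# their cross-validation

test_that("spectral synthesis produces calibrated scale-free noise", {
  x0 <- one_over_f_noise(2^16, 256, exponent = 0, seed = 7)
  w0 <- welch_psd(x0, 256, seg_s = 8)
  sel <- w0$frequency >= 1 & w0$frequency <= 40
  s0 <- coef(lm(log(density) ~ log(frequency), data = w0[sel, ]))[2]
  expect_lt(abs(s0), 0.1)
  x1 <- one_over_f_noise(2^18, 256, exponent = 1, seed = 7)
  w1 <- welch_psd(x1, 256, seg_s = 8)
  sel <- w1$frequency >= 1 & w1$frequency <= 40
  s1 <- coef(lm(log(density) ~ log(frequency), data = w1[sel, ]))[2]
  expect_lt(abs(s1 + 1), 0.1)
  expect_equal(var(x1), 1, tolerance = 1e-12)
  expect_identical(one_over_f_noise(1024, 256, 1, seed = 3),
                   one_over_f_noise(1024, 256, 1, seed = 3))
  expect_error(one_over_f_noise(128, 256, 1), "256")
  expect_error(one_over_f_noise(1024, 256, -1), "non-negative")
})

test_that("scenario presets encode their generating models and durations", {
  sc <- seizure_scenario("patient1", seed = 1)
  expect_equal(sc$n_windows, 10)           # 20 s in 2 s windows
  expect_equal(sc$n_seizures, 55)
  expect_equal(sc$spec$label, "Inhibitory + excitatory + endogenous")
  # sequential motif: inhibitory peak before excitatory peak
  expect_lt(which.max(sc$lambda[, "g3"]), which.max(sc$lambda[, "g5"]))
  sc2 <- seizure_scenario("patient2", seed = 1)
  expect_equal(sc2$n_windows, 30)
  expect_equal(sc2$n_seizures, 2)
  scn <- seizure_scenario("stationary", seed = 1)
  expect_true(all(scn$lambda == 0))
  expect_equal(scn$spec$label, "Null")
})

test_that("the fast spectral route is exact at infinite SNR and seeded", {
  sc <- seizure_scenario("patient1", snr = Inf, seed = 2)
  ss <- simulate_spectra(sc)
  expect_identical(ss$data$S, ss$truth$S_true)
  sc10 <- seizure_scenario("patient1", snr = 10, seed = 2)
  expect_identical(simulate_spectra(sc10)$data$S, simulate_spectra(sc10)$data$S)
})

test_that("averaging seizures shrinks spectral residuals like 1/sqrt(n)", {
  rms <- vapply(c(4, 16, 64), function(n) {
    ss <- simulate_spectra(seizure_scenario("stationary", n_seizures = n,
                                            seed = 6))
    sqrt(mean((log(ss$data$S) - log(ss$truth$S_true))^2))
  }, numeric(1))
  expect_lt(abs(rms[1] / rms[2] / 2 - 1), 0.25)
  expect_lt(abs(rms[2] / rms[3] / 2 - 1), 0.25)
})

test_that("the chirp scenario's peak frequency never increases", {
  ss <- simulate_spectra(seizure_scenario("chirp", seed = 3, snr = Inf))
  pk <- peak_frequencies(ss$truth$S_true)
  expect_true(all(diff(pk) <= 0))
  expect_gt(pk[1], tail(pk, 1))
})

test_that("silence in, silence out: no input, no noise, no output", {
  sc <- seizure_scenario("stationary", n_seizures = 1, duration_s = 4, seed = 1)
  sc$base <- cmc_parameters(a1 = 0, b1 = 0)
  sim <- simulate_timeseries(sc)
  expect_equal(max(abs(sim$seizures[[1]])), 0)
})

test_that("stationary simulations reproduce the predicted spectrum", {
  sc <- seizure_scenario("stationary", n_seizures = 4, duration_s = 50,
                         seed = 3)
  sim <- simulate_timeseries(sc)
  wm <- Reduce(`+`, lapply(sim$seizures, function(y)
    welch_psd(y, sim$fs, seg_s = 2, freq = frequency_grid())$density)) / 4
  pred <- predicted_spectrum(cmc_parameters())$density
  expect_lt(sqrt(mean(((wm - pred) / pred)^2)), 0.15)
})

test_that("halving the integration step barely changes the output spectrum", {
  sc <- seizure_scenario("stationary", n_seizures = 1, duration_s = 20,
                         seed = 5)
  th <- seizuredcm:::scenario_theta(sc)
  set.seed(5)
  u1 <- seizuredcm:::synth_input(th, 2000, 1000, 100)
  u2 <- approx(seq_along(u1), u1, xout = seq(1, length(u1), by = 0.5))$y
  V1 <- seizuredcm:::cpp_simulate(th, u1, 1000, 2000, 100, FALSE)
  V2 <- seizuredcm:::cpp_simulate(th, u2, 2000, 4000, 200, FALSE)
  y1 <- V1[, 2] + 0.5 * V1[, 4]
  y2 <- V2[seq(1, nrow(V2), 2), 2] + 0.5 * V2[seq(1, nrow(V2), 2), 4]
  w1 <- welch_psd(y1, 1000, 2, freq = frequency_grid())$density
  w2 <- welch_psd(y2, 1000, 2, freq = frequency_grid())$density
  expect_lt(seizuredcm:::rel_rms(w1, w2), 0.02)
})

test_that("the time-domain and spectral routes cross-validate each other", {
  sc <- seizure_scenario("patient1", n_seizures = 16, seed = 4)
  sim <- simulate_timeseries(sc)
  from_time <- build_spectral_data(sim$seizures, sim$fs, window_s = 2)
  from_spec <- simulate_spectra(sc)$data
  expect_equal(nrow(from_time$S), nrow(from_spec$S))
  for (w in seq_len(nrow(from_time$S)))
    expect_lt(seizuredcm:::rel_rms(from_time$S[w, ], from_spec$S[w, ]), 0.20)
})

test_that("ground truth is serialised alongside exported datasets", {
  sc <- seizure_scenario("stationary", n_seizures = 2, duration_s = 4, seed = 8)
  sim <- simulate_timeseries(sc)
  dir <- withr::local_tempdir()
  write_seizure_dataset(sim, dir)
  expect_length(list.files(dir, pattern = "seizure_.*\\.txt"), 2)
  truth <- jsonlite::read_json(file.path(dir, "ground_truth.json"),
                               simplifyVector = TRUE)
  expect_true(truth$synthetic)
  expect_equal(truth$seed, 8)
  expect_equal(as.matrix(as.data.frame(truth$lambda)),
               sim$truth$lambda, ignore_attr = TRUE)
  # recovery-style consumption: read data back, compare against sidecar only
  rec <- read_eeg_delim(file.path(dir, "seizure_001.txt"))
  expect_equal(rec$fs, sim$fs)
  expect_equal(rec$data[, 1], sim$seizures[[1]], tolerance = 1e-6)
})
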