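# linearised transfer functions, input spectrum and predicted spectral
# density

freq <- frequency_grid()

test_that("frequency grid is positive, increasing, defaulting to 1-40 Hz", {
  expect_equal(freq, 1:40)
  expect_error(frequency_grid(0, 40), "positive")
})

test_that("with coupling removed the granular transfer is the closed-form kernel", {
  p <- cmc_parameters()
  p[5:14] <- 1e-12
  H <- seizuredcm:::transfer_matrix_r(p, freq)
  T1 <- p[["T1"]]
  w <- 2 * pi * freq
  closed <- T1 / ((1i * w)^2 + 2 * T1 * (1i * w) + T1^2)
  expect_equal(H[1, ], closed, tolerance = 1e-9)
  expect_true(all(Mod(H[2:4, ]) < 1e-9))
  # and only the granular population carries spectral power
  ps <- population_spectra(p, freq)
  on_pathway <- ps$density[ps$population == "spiny stellate"]
  off_pathway <- ps$density[ps$population != "spiny stellate"]
  expect_true(all(on_pathway > 0))
  expect_true(all(off_pathway < 1e-12 * max(on_pathway)))
})

test_that("c_dp = 0 reduces the observed transfer to the superficial one", {
  p <- cmc_parameters(c_dp = 0)
  tf <- transfer_function(p, freq)
  obs <- tf$gain[tf$population == "observed"]
  sp <- tf$gain[tf$population == "superficial pyramidal"]
  expect_equal(obs, 1000 * sp, tolerance = 1e-12)
})

test_that("the delay enters exactly and vanishes in the d -> 0 limit", {
  p <- cmc_parameters(delay = 1e-9)
  H <- seizuredcm:::transfer_matrix_r(p, freq)
  J <- cmc_jacobian(p)
  B <- rep(0, 8); B[5] <- p[["T1"]]
  H0 <- vapply(freq, function(f) {
    h <- solve(1i * 2 * pi * f * diag(8) - J$J0 - J$Jd, B)
    h[1:4]
  }, complex(4))
  expect_equal(H, matrix(H0, 4), tolerance = 1e-9)
})

test_that("compiled and pure-R transfer paths agree", {
  set.seed(31)
  for (rep in 1:3) {
    lam <- rnorm(16, sd = 0.2)
    p <- cmc_parameters()
    p[1:16] <- p[1:16] * exp(lam)
    expect_equal(seizuredcm:::transfer_matrix_r(p, freq),
                 seizuredcm:::cpp_transfer(as.numeric(p), freq)$H,
                 tolerance = 1e-10)
  }
})

test_that("input spectrum: flat, power-law and bump-projection behaviour", {
  flat <- endogenous_input_spectrum(cmc_parameters(a2 = 0, d_spec = rep(0, 8)))
  expect_equal(flat$density, rep(1, 40))
  pl <- endogenous_input_spectrum(cmc_parameters(a1 = 1, a2 = 1,
                                                 d_spec = rep(0, 8)))
  slope <- coef(lm(log(pl$density) ~ log(pl$frequency)))[2]
  expect_equal(unname(slope), -1, tolerance = 1e-12)
  expect_error(endogenous_input_spectrum(cmc_parameters(), freq = c(0, 1)),
               "positive")

  # least-squares innovations reproduce a log-spectral bump within the
  # resolution of the 8-component cosine set
  target_shape <- 1.5 * exp(-(freq - 18)^2 / (2 * 5^2))
  psi <- seizuredcm:::dct_basis_frequency(freq)
  cf <- qr.solve(psi, target_shape)
  p <- cmc_parameters(a2 = 0, d_spec = cf)
  got <- log(endogenous_input_spectrum(p)$density)
  basis_resid <- sqrt(mean((psi %*% cf - target_shape)^2))
  expect_equal(sqrt(mean((got - target_shape)^2)), basis_resid,
               tolerance = 1e-8)
  expect_lt(basis_resid / sqrt(mean(target_shape^2)), 0.15)
})

test_that("predicted spectrum is positive, linear in input power, and
          separates neuronal and noise terms", {
  p <- cmc_parameters()
  s1 <- predicted_spectrum(p)
  expect_true(all(s1$density > 0))
  p2 <- p; p2["a1"] <- 2 * p2["a1"]
  s2 <- predicted_spectrum(p2)
  expect_equal(s2$density - s2$noise, 2 * (s1$density - s1$noise),
               tolerance = 1e-9)
  p3 <- cmc_parameters(b1 = 0)
  s3 <- predicted_spectrum(p3)
  expect_equal(s3$density, s3$neuronal, tolerance = 1e-12)
})

test_that("predicted spectrum is continuous in the parameters", {
  p <- cmc_parameters()
  s0 <- predicted_spectrum(p)$density
  gaps <- vapply(c(1e-2, 1e-3, 1e-4), function(d) {
    p2 <- p; p2["g3"] <- p2["g3"] * exp(d)
    max(abs(predicted_spectrum(p2)$density - s0) / s0)
  }, numeric(1))
  expect_true(all(diff(gaps) < 0))
  expect_lt(gaps[3], 1e-3)
})

test_that("population spectra: mixture is coherent, superficial cells are faster", {
  p <- cmc_parameters()
  ps <- population_spectra(p, freq)
  obs <- predicted_spectrum(p, freq)
  total <- tapply(ps$density, ps$frequency, sum)
  expect_gt(max(abs(total[as.character(freq)] -
                      (obs$density - obs$noise))), 1e-6)  # mixture != sum
  sp <- ps$density[ps$population == "superficial pyramidal"]
  dp <- ps$density[ps$population == "deep pyramidal"]
  expect_gt(sum(sp[freq > 13]), sum(dp[freq > 13]))
})

test_that("transfer-function spectra match long linearised simulations", {
  # brute-force oracle: drive the linearised delay system with unit white
  # noise for 400 s and compare the Welch spectrum with kappa^2 |H|^2 / fs
  set.seed(77)
  fs <- 1000
  n <- 400 * fs
  draws <- 5
  for (k in seq_len(draws)) {
    p <- cmc_parameters()
    lam <- rnorm(16) * 0.5 * sqrt(c(rep(0.0625, 14), 0.03125, 0.03125))
    p[1:16] <- p[1:16] * exp(lam)
    if (max(Re(eigen(Reduce(`+`, cmc_jacobian(p)),
                     only.values = TRUE)$values)) >= 0) next
    u <- rnorm(n)
    V <- seizuredcm:::cpp_simulate(matrix(as.numeric(p), 1, 29), u, fs,
                                   n, 0, TRUE)
    y <- 1000 * (V[, 2] + p[["c_dp"]] * V[, 4])
    w <- welch_psd(y, fs, seg_s = 2, overlap = 0.5, freq = freq)
    H <- seizuredcm:::cpp_transfer(as.numeric(p), freq)$H
    pred <- Mod(1000 * (H[2, ] + p[["c_dp"]] * H[4, ]))^2 * 2 / fs
    expect_lt(sqrt(mean(((w$density - pred) / pred)^2)), 0.10)
  }
})
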