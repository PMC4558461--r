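# variational Laplace: conjugate-model correctness, free-energy behaviour,
# and inversion of the spectral model

test_that("the optimiser reproduces the conjugate linear-Gaussian posterior", {
  set.seed(51)
  n <- 40; L <- 6
  A <- matrix(rnorm(n * L), n, L)
  lam_true <- rnorm(L)
  prec <- 50
  y <- as.numeric(A %*% lam_true) + rnorm(n, sd = 1 / sqrt(prec))
  prior_var <- rep(0.5, L)
  fit <- vl_invert(y, function(m) list(pred = as.numeric(A %*% m), J = A),
                   prior_mean = rep(0, L), prior_var = prior_var,
                   hyper_mean = log(prec), hyper_var = 1e-10)
  S_exact <- solve(prec * crossprod(A) + diag(1 / prior_var, L))
  m_exact <- S_exact %*% (prec * crossprod(A, y))
  expect_equal(fit$mean, as.numeric(m_exact), tolerance = 1e-6)
  expect_equal(fit$cov, S_exact, tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("free energy falls when an informed latent's prior is inflated", {
  set.seed(52)
  n <- 30
  A <- cbind(rnorm(n), 0.1 * rnorm(n))   # second latent weakly informed
  y <- as.numeric(A %*% c(1, 0)) + 0.05 * rnorm(n)
  fit_F <- function(v2) {
    vl_invert(y, function(m) list(pred = as.numeric(A %*% m), J = A),
              prior_mean = c(0, 0), prior_var = c(1, v2),
              hyper_mean = log(400), hyper_var = 1e-10)$free_energy
  }
  Fs <- vapply(c(0.5, 2, 8, 32), fit_F, numeric(1))
  expect_true(all(diff(Fs) < 0))
})

test_that("accepted free energies never decrease and inversion is reproducible", {
  ss <- simulate_spectra(tiny_scenario(seed = 2, preset = "patient1"))
  post <- dcm_invert(ss$data, model_spec(TRUE, FALSE, FALSE))
  expect_true(all(diff(post$trace$F) >= 0))
  expect_gte(sum(post$trace$accepted), 2)
  post2 <- dcm_invert(ss$data, model_spec(TRUE, FALSE, FALSE))
  expect_identical(post$mean, post2$mean)
  expect_identical(post$free_energy, post2$free_energy)
})

test_that("posterior variances shrink below the prior for identifiable latents", {
  ss <- simulate_spectra(tiny_scenario(seed = 3, preset = "patient1"))
  post <- dcm_invert(ss$data, model_spec(TRUE, TRUE, FALSE))
  expect_true(all(diag(post$cov) <= post$map$prior_sd^2 + 1e-9))
})

test_that("predictions have the right shape and match the generator exactly", {
  spec <- model_spec(FALSE, FALSE, FALSE)
  W <- 6
  np <- nrow(dcm_priors(spec, W))
  pred <- dcm_predict(rep(0, np), spec, W)
  expect_length(pred, W * 40)
  m <- matrix(pred, W, 40, byrow = TRUE)
  expect_equal(m, matrix(m[1, ], W, 40, byrow = TRUE))  # null: identical windows

  # a latent vector expanded through the basis predicts exactly the
  # noiseless spectra that simulate_spectra() builds from the same lambda
  full <- model_spec(TRUE, TRUE, TRUE)
  map <- seizuredcm:::latent_map(full, W)
  basis <- dct_basis(W, min(8, W))
  set.seed(55)
  lat <- rnorm(nrow(map)) * 0.2 * map$prior_sd / max(map$prior_sd)
  lam <- seizuredcm:::dcm_lambda(lat, map, basis, W)
  sc <- seizure_scenario("stationary", duration_s = 2 * W, snr = Inf, seed = 1)
  sc$lambda <- lam
  ss <- simulate_spectra(sc)
  expect_equal(dcm_predict(lat, full, W), log(c(t(ss$data$S))),
               tolerance = 1e-9)
})

test_that("unstable parameter regions yield a finite penalty, not an error", {
  spec <- model_spec(FALSE, FALSE, FALSE)
  W <- 2
  map <- seizuredcm:::latent_map(spec, W)
  lat <- rep(0, nrow(map))
  lat[map$name == "gamma"] <- 3   # extreme gain: linearisation unstable
  pred <- dcm_predict(lat, spec, W)
  expect_true(all(is.finite(pred)))
  expect_gt(max(pred), 19)        # the large-residual penalty
})

test_that("free energy prefers the null model on featureless (null) data", {
  wins <- 0L
  for (sd in 1:3) {
    ss <- simulate_spectra(seizure_scenario("stationary", seed = sd,
                                            duration_s = 12))
    Ff <- dcm_invert(ss$data, model_spec(TRUE, TRUE, TRUE))$free_energy
    Fn <- dcm_invert(ss$data, model_spec(FALSE, FALSE, FALSE))$free_energy
    wins <- wins + (Fn > Ff)
  }
  expect_gte(wins, 2L)
})
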