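# the 8-model hypothesis space, free-energy comparison and posterior
# read-outs

test_that("the model space enumerates all 2^3 combinations exactly once", {
  space <- enumerate_models()
  expect_equal(nrow(space), 8)
  combos <- paste(space$inhibitory, space$excitatory, space$endogenous)
  expect_equal(length(unique(combos)), 8)
  expect_equal(space$label[1], "Inhibitory + excitatory + endogenous")
  expect_equal(space$label[8], "Null")
  expect_equal(sum(!space$inhibitory & !space$excitatory & !space$endogenous), 1)
  expect_equal(sum(space$inhibitory + space$excitatory + space$endogenous == 1), 3)
  expect_equal(space$label,
               c("Inhibitory + excitatory + endogenous",
                 "Inhibitory + excitatory", "Inhibitory + endogenous",
                 "Excitatory + endogenous", "Inhibitory", "Excitatory",
                 "Endogenous", "Null"))
})

test_that("free energies convert to calibrated posterior model probabilities", {
  cmp <- compare_models(c(Full = 3, Null = 0))
  expect_equal(cmp$relative_F, c(3, 0))
  odds <- cmp$probability[1] / cmp$probability[2]
  expect_equal(odds, exp(3), tolerance = 1e-12)
  expect_equal(round(odds), 20)            # "about 20:1"
  expect_equal(sum(cmp$probability), 1, tolerance = 1e-12)
  # invariant to adding a constant to every free energy
  cmp2 <- compare_models(c(Full = 1003, Null = 1000))
  expect_equal(cmp2$probability, cmp$probability, tolerance = 1e-12)
  expect_warning(cmp3 <- compare_models(c(A = 1, B = NaN, Null = 0)),
                 "non-finite")
  expect_equal(nrow(cmp3), 2)
})

test_that("balance time courses summarise groups and handle the null model", {
  ss <- simulate_spectra(tiny_scenario(seed = 7, preset = "patient1"))
  pn <- dcm_invert(ss$data, model_spec(FALSE, FALSE, FALSE))
  btn <- balance_timecourse(pn)
  expect_true(all(btn$log_scaling == 0))
  expect_true(isTRUE(attr(btn, "null_model")))

  pf <- dcm_invert(ss$data)
  bt <- balance_timecourse(pf)
  lam <- seizuredcm:::posterior_lambda(pf)
  expect_equal(bt$log_scaling[bt$quantity == "inhibitory"],
               unname(rowMeans(lam[, c("g3", "g4", "g9")])), tolerance = 1e-9)
  expect_equal(bt$log_scaling[bt$quantity == "balance"],
               bt$log_scaling[bt$quantity == "excitatory"] -
                 bt$log_scaling[bt$quantity == "inhibitory"], tolerance = 1e-9)
  expect_true(all(bt$upper >= bt$log_scaling & bt$lower <= bt$log_scaling))
})

test_that("identical inhibitory and excitatory scalings give zero balance", {
  # construct a posterior-like object directly through the latent map
  spec <- model_spec(TRUE, TRUE, FALSE)
  W <- 6
  map <- seizuredcm:::latent_map(spec, W)
  basis <- dct_basis(W, min(8, W))
  m <- rep(0, nrow(map))
  # one bump, applied with the same coefficients to all six connections
  bump_coef <- crossprod(basis, 0.3 * exp(-((1:W) - 3)^2 / 2))
  for (g in c("g3", "g4", "g9", "g5", "g6", "g8"))
    m[grepl(paste0("^", g, "\\.k"), map$name)] <- bump_coef
  post <- structure(list(mean = m, cov = diag(1e-6, nrow(map)), map = map,
                         model = spec, basis = basis, n_windows = W),
                    class = "cmc_posterior")
  bt <- balance_timecourse(post)
  expect_equal(bt$log_scaling[bt$quantity == "balance"], rep(0, W),
               tolerance = 1e-12)
  expect_gt(max(bt$log_scaling[bt$quantity == "inhibitory"]), 0.2)
})

test_that("reconstruction agrees with the fitted features and prior means", {
  ss <- simulate_spectra(tiny_scenario(seed = 8, preset = "patient1"))
  post <- dcm_invert(ss$data, model_spec(TRUE, TRUE, FALSE))
  rec <- dcm_reconstruct(post)
  # observed-mixture reconstruction equals the fitted features
  expect_equal(rec$observed$predicted,
               c(t(post$fitted)), tolerance = 1e-9)
  # reconstruction at zero latents equals the prior-mean prediction
  post0 <- post
  post0$mean[] <- 0
  rec0 <- dcm_reconstruct(post0)
  prior_pred <- predicted_spectrum(cmc_parameters())$density
  expect_equal(rec0$observed$predicted[1:40], prior_pred, tolerance = 1e-9)
  # shapes
  expect_equal(nrow(rec$populations), post$n_windows * 4 * 40)
  expect_equal(nrow(rec$input), post$n_windows * 40)
})

test_that("a decreasing-frequency drive is reconstructed as a falling peak", {
  ss <- simulate_spectra(seizure_scenario("chirp", seed = 9))
  post <- dcm_invert(ss$data)
  rec <- dcm_reconstruct(post)
  pk <- peak_frequencies(rec$observed[, c("window", "frequency", "predicted")],
                         value = "predicted")
  rho <- cor(seq_along(pk), pk, method = "spearman")
  expect_lte(rho, -0.7)
})
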