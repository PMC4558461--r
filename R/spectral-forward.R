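# Linearised spectral forward model: transfer functions of the delayed
# microcircuit, power-law endogenous input with cosine-shaped innovations,
# and the observed spectral density (pyramidal mixture + power-law
# measurement noise).

#' Frequency grid for spectral modelling
#'
#' @param fmin,fmax Band edges in Hz (defaults 1 and 40, the modelled band).
#' @param by Step in Hz (default 1, the coarsest resolution consistent with
#'   2 s windows).
#' @return Strictly increasing vector of frequencies, all > 0.
#' @export
frequency_grid <- function(fmin = 1, fmax = 40, by = 1) {
  f <- seq(fmin, fmax, by = by)
  if (any(f <= 0)) stop("frequencies must be positive (power laws diverge at 0)",
                        call. = FALSE)
  f
}

# complex depolarisation transfer per population, pure R route:
# H(w) = (i w I - J0 - Jd e^{-i w d})^{-1} B with B injecting input into the
# granular currents. Rows: the four populations. This duplicates the
# compiled path on purpose and the two are held together by tests.
transfer_matrix_r <- function(p, freq) {
  J <- cmc_jacobian(p)
  d_s <- p[["delay"]] / 1000
  B <- rep(0, 8); B[5] <- p[["T1"]]
  H <- vapply(freq, function(f) {
    w <- 2 * pi * f
    A <- 1i * w * diag(8) - J$J0 - J$Jd * exp(-1i * w * d_s)
    h <- tryCatch(solve(A, B),
                  error = function(e) stop(sprintf(
                    "resolvent not invertible at %g Hz", f), call. = FALSE))
    h[1:4]
  }, complex(4))
  matrix(H, nrow = 4)
}

#' Transfer functions of the linearised microcircuit
#'
#' Complex frequency-domain gain from the endogenous input to each
#' population's depolarisation, and to the observed mixture
#' (superficial + `c_dp` x deep pyramidal, times the fixed observation
#' gain). The linearisation is taken at the resting equilibrium (the
#' origin); conduction delays enter exactly through `exp(-i w d)` factors.
#'
#' @param p A [cmc_parameters()] vector.
#' @param freq Frequency grid from [frequency_grid()].
#' @return A tibble with columns `frequency`, `population` (the four
#'   populations plus `"observed"`), `gain` (complex) and `magnitude`.
#' @export
#' @examples
#' tf <- transfer_function(cmc_parameters(), frequency_grid())
#' head(tf)
transfer_function <- function(p, freq = frequency_grid()) {
  validate_cmc_parameters(p)
  stab <- linearisation_stable(p)
  if (!stab$stable)
    warning(sprintf("linearisation unstable (max Re(eig) = %.2f)", stab$max_re))
  H <- transfer_matrix_r(p, freq)
  Hobs <- .obs_gain * (H[2, ] + p[["c_dp"]] * H[4, ])
  gain <- c(H[1, ], H[2, ], H[3, ], H[4, ], Hobs)
  tibble::tibble(
    frequency = rep(freq, 5),
    population = rep(c(.population_names, "observed"), each = length(freq)),
    gain = gain,
    magnitude = Mod(gain)
  )
}

linearisation_stable <- function(p) {
  J <- cmc_jacobian(p)
  max_re <- max(Re(eigen(J$J0 + J$Jd, only.values = TRUE)$values))
  list(stable = max_re < 0, max_re = max_re)
}

#' Endogenous input spectral density
#'
#' Power-law ("scale-free") input spectrum with cosine-shaped spectral
#' innovations:
#' `g_u(f) = a1 * f^-a2 * exp(sum_k d_spec_k psi_k(f))`, where psi_k are the
#' first 8 discrete cosine functions over the frequency grid.
#'
#' @inheritParams transfer_function
#' @return A tibble with columns `frequency` and `density`.
#' @export
#' @examples
#' p <- cmc_parameters(a2 = 0, d_spec = rep(0, 8))
#' endogenous_input_spectrum(p)$density[1:3]  # flat at height a1
endogenous_input_spectrum <- function(p, freq = frequency_grid()) {
  if (any(freq <= 0)) stop("frequencies must be positive", call. = FALSE)
  if (p[["a1"]] <= 0) stop("a1 must be positive", call. = FALSE)
  tibble::tibble(frequency = freq,
                 density = input_spectrum_vec(p, freq))
}

input_spectrum_vec <- function(p, freq) {
  psi <- dct_basis_frequency(freq)
  shape <- as.numeric(psi %*% p[22:29])
  p[["a1"]] * freq^(-p[["a2"]]) * exp(shape)
}

#' Predicted spectral density of the observed signal
#'
#' The steady-state observed spectrum
#' `S_y(f) = |H_obs(f)|^2 g_u(f) + b1 f^-b2`: the input spectrum filtered
#' through the observed transfer function, plus power-law measurement noise.
#'
#' @inheritParams transfer_function
#' @return A tibble with columns `frequency`, `density`, `neuronal` (the
#'   noise-free neuronal term) and `noise`.
#' @export
#' @examples
#' predicted_spectrum(cmc_parameters())
predicted_spectrum <- function(p, freq = frequency_grid()) {
  validate_cmc_parameters(p)
  out <- cpp_csd(matrix(as.numeric(p), 1), freq, dct_basis_frequency(freq),
                 .obs_gain, .penalty_log)
  if (out$max_re[1] >= 0)
    warning(sprintf("linearisation unstable (max Re(eig) = %.2f); penalty ",
                    out$max_re[1]), "spectrum returned")
  noise <- p[["b1"]] * freq^(-p[["b2"]])
  dens <- as.numeric(out$S[1, ])
  tibble::tibble(frequency = freq, density = dens,
                 neuronal = dens - noise, noise = noise)
}

#' Per-population spectral densities
#'
#' Noise-free spectral density of each population's depolarisation,
#' `|H_pop(f)|^2 g_u(f)` (on the same observation-gain scale as the
#' observed mixture). The observed spectrum is a coherent mixture, not the
#' sum of these.
#'
#' @inheritParams transfer_function
#' @return A tibble with columns `population`, `frequency`, `density`.
#' @export
population_spectra <- function(p, freq = frequency_grid()) {
  validate_cmc_parameters(p)
  H <- cpp_transfer(as.numeric(p), freq)$H
  gu <- input_spectrum_vec(p, freq)
  dens <- .obs_gain^2 * Mod(t(H))^2 * gu
  tibble::tibble(
    population = rep(.population_names, each = length(freq)),
    frequency = rep(freq, 4),
    density = c(dens)
  )
}

# windowed spectra for a per-window parameter matrix (W x 29); matrix route
# used by the inversion machinery
predicted_spectrum_windows <- function(theta, freq) {
  cpp_csd(theta, freq, dct_basis_frequency(freq), .obs_gain, .penalty_log)
}

predicted_spectrum_windows_grad <- function(theta, freq, step = 1e-3) {
  cpp_csd_grad(theta, freq, dct_basis_frequency(freq), .obs_gain,
               .penalty_log, step)
}
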