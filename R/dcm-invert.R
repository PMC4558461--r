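# Inversion of the windowed spectral model: latents are log-scalings of the
# microcircuit parameters (constants directly; time-varying groups through
# the cosine basis), the data features are log spectral densities stacked
# over windows x frequencies, and the optimiser is variational Laplace.

# one row per latent: name, parameter, param_index (1..29), component
# (0 = applies to every window directly; k >= 1 = cosine component), prior_sd
latent_map <- function(spec, n_windows, prior_table = cmc_prior_table()) {
  stopifnot(inherits(spec, "model_spec"))
  K <- min(8L, n_windows)
  vary <- varying_parameters(spec)
  constant <- prior_table$parameter[prior_table$group == "constant"]
  timedep <- prior_table$parameter[prior_table$group != "constant"]
  rows <- list()
  for (pn in constant) {
    v <- prior_table$log_prior_variance[prior_table$parameter == pn]
    rows[[length(rows) + 1L]] <- tibble::tibble(
      name = pn, parameter = pn,
      param_index = match(pn, .param_names), component = 0L,
      prior_sd = sqrt(v))
  }
  for (pn in timedep) {
    v <- prior_table$log_prior_variance[prior_table$parameter == pn]
    ks <- if (pn %in% vary) seq_len(K) else 1L
    for (k in ks) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        name = if (length(ks) == 1L) pn else sprintf("%s.k%d", pn, k),
        parameter = pn, param_index = match(pn, .param_names),
        component = as.integer(k),
        prior_sd = sqrt(if (k == 1L) v else v / 2))
    }
  }
  dplyr::bind_rows(rows)
}

# per-window log-scaling matrix (n_windows x 29) from a latent vector
dcm_lambda <- function(m, map, basis, n_windows) {
  lambda <- matrix(0, n_windows, length(.param_names),
                   dimnames = list(NULL, .param_names))
  for (j in seq_along(m)) {
    k <- map$component[j]
    col <- if (k == 0L) rep(m[j], n_windows) else basis[, k] * m[j]
    lambda[, map$param_index[j]] <- lambda[, map$param_index[j]] + col
  }
  lambda
}

# predictions (log spectral density stacked window-major) and their
# Jacobian with respect to the latents; the finite differencing is done on
# the per-window log-scalings in compiled code and chained through the
# (exact, linear) basis map
dcm_predictor <- function(map, basis, n_windows, freq,
                          base = cmc_parameters(), with_jacobian = TRUE) {
  base_num <- as.numeric(base)
  F <- length(freq)
  function(m) {
    lambda <- dcm_lambda(m, map, basis, n_windows)
    theta <- sweep(exp(lambda), 2, base_num, "*")
    if (!with_jacobian) {
      out <- predicted_spectrum_windows(theta, freq)
      return(list(pred = log(c(t(out$S))), max_re = out$max_re))
    }
    out <- predicted_spectrum_windows_grad(theta, freq)
    J <- matrix(0, n_windows * F, length(m))
    for (j in seq_along(m)) {
      p <- map$param_index[j]
      k <- map$component[j]
      bval <- if (k == 0L) rep(1, n_windows) else basis[, k]
      Gp <- out$G[, p, , drop = TRUE]           # F x W
      if (n_windows == 1L) Gp <- matrix(Gp, ncol = 1)
      J[, j] <- as.vector(Gp * rep(bval, each = F))
    }
    list(pred = log(c(t(out$S))), J = J, max_re = out$max_re)
  }
}

#' Prior specification for model inversion
#'
#' Latent-space priors for a given model: every latent (log-scaling) has
#' zero prior mean; constant parameters carry the Table-style log prior
#' variances; time-varying parameters get one variance per cosine
#' component (the full variance on the constant component, half on
#' components 2..8, encoding slow fluctuations).
#'
#' @param spec A [model_spec()].
#' @param n_windows Number of seizure windows.
#' @param prior_table Parameter prior table, see [cmc_prior_table()].
#' @return A tibble with one row per latent: `name`, `parameter`,
#'   `component`, `prior_sd`.
#' @export
dcm_priors <- function(spec, n_windows, prior_table = cmc_prior_table()) {
  latent_map(spec, n_windows, prior_table)[
    , c("name", "parameter", "component", "prior_sd")]
}

#' Predicted feature vector for a latent vector
#'
#' Expands latents to per-window parameters, evaluates the predicted
#' spectrum in every window, and returns the log densities stacked over
#' windows (window-major).
#'
#' @param latents Numeric latent vector (dimensioned per [dcm_priors()]).
#' @param spec A [model_spec()].
#' @param n_windows Number of windows.
#' @param freq Frequency grid.
#' @param base Base (prior-mean) parameters.
#' @return Numeric vector of length `n_windows * length(freq)`.
#' @export
dcm_predict <- function(latents, spec, n_windows, freq = frequency_grid(),
                        base = cmc_parameters()) {
  map <- latent_map(spec, n_windows)
  if (length(latents) != nrow(map))
    stop("latents must have length ", nrow(map), " for this model", call. = FALSE)
  basis <- dct_basis(n_windows, min(8L, n_windows))
  fn <- dcm_predictor(map, basis, n_windows, freq, base, with_jacobian = FALSE)
  fn(latents)$pred
}

#' Free energy of a latent vector
#'
#' Evaluates the variational free energy (accuracy minus complexity) at a
#' given latent vector, with the observation log-precision set to its
#' conditional optimum under the hyperprior.
#'
#' @inheritParams dcm_predict
#' @param data A `spectral_data` object.
#' @param hyper_mean,hyper_var Hyperprior on the log-precision of the
#'   observation error.
#' @return The free energy (scalar).
#' @export
dcm_free_energy <- function(latents, data, spec,
                            base = cmc_parameters(),
                            hyper_mean = 0, hyper_var = 1 / 16) {
  stopifnot(inherits(data, "spectral_data"))
  W <- nrow(data$S)
  map <- latent_map(spec, W)
  basis <- dct_basis(W, min(8L, W))
  fn <- dcm_predictor(map, basis, W, data$freq, base)
  y <- log(c(t(data$S)))
  out <- fn(latents)
  e <- y - out$pred
  h <- vl_update_h(hyper_mean, e, 0, length(y), hyper_mean, hyper_var)
  fe <- vl_free_energy(e, out$J, latents, h, rep(0, nrow(map)),
                       map$prior_sd^2, hyper_mean, hyper_var)
  fe$F
}

#' Invert the windowed spectral model against data
#'
#' Fits the canonical-microcircuit spectral model to windowed spectral
#' densities by variational Laplace: log spectral densities are the data
#' features, the latents are log-scalings of the model parameters (with
#' time-varying groups expanded on the cosine basis per the model
#' specification), and a single log-precision hyperparameter scales the
#' observation error. Initialisation is at the prior means (zero latents);
#' the optimisation is deterministic.
#'
#' @param data A `spectral_data` object (see [build_spectral_data()] or
#'   [simulate_spectra()]).
#' @param spec A [model_spec()]; default the full model.
#' @param base Base (prior-mean) parameters.
#' @param prior_table Parameter prior table.
#' @param hyper_mean,hyper_var Hyperprior on the observation log-precision.
#' @param rescale Apply a single global scale to the measured densities so
#'   their grand mean log density matches the prior-mean prediction
#'   (recommended for spectra in arbitrary units; the scale is recorded).
#' @param max_iter,tol Optimiser settings, see [vl_invert()].
#' @return An object of class `"cmc_posterior"`.
#' @export
dcm_invert <- function(data, spec = model_spec(TRUE, TRUE, TRUE),
                       base = cmc_parameters(),
                       prior_table = cmc_prior_table(),
                       hyper_mean = 0, hyper_var = 1 / 16,
                       rescale = TRUE, max_iter = 128, tol = 0.01) {
  stopifnot(inherits(data, "spectral_data"), inherits(spec, "model_spec"))
  W <- nrow(data$S)
  freq <- data$freq
  map <- latent_map(spec, W, prior_table)
  basis <- dct_basis(W, min(8L, W))
  scale <- 1
  if (rescale) {
    prior_pred <- predicted_spectrum_windows(
      matrix(as.numeric(base), W, 29, byrow = TRUE), freq)$S
    scale <- exp(mean(log(prior_pred)) - mean(log(data$S)))
  }
  S_fit <- data$S * scale
  y <- log(c(t(S_fit)))
  fn <- dcm_predictor(map, basis, W, freq, base)
  fit <- vl_invert(y, fn, prior_mean = rep(0, nrow(map)),
                   prior_var = map$prior_sd^2,
                   hyper_mean = hyper_mean, hyper_var = hyper_var,
                   max_iter = max_iter, tol = tol)
  post <- list(mean = stats::setNames(fit$mean, map$name), cov = fit$cov,
               free_energy = fit$free_energy,
               variance_explained = fit$variance_explained,
               h = fit$h, trace = fit$trace, converged = fit$converged,
               warning = fit$warning, iterations = fit$iterations,
               map = map, model = spec, basis = basis, n_windows = W,
               freq = freq, base = as_cmc_parameters(base),
               data_S = S_fit, scale = scale,
               fitted = matrix(exp(fit$fitted), W, length(freq), byrow = TRUE))
  class(post) <- "cmc_posterior"
  post
}

# posterior-mean per-window log-scalings / parameters
posterior_lambda <- function(post) {
  dcm_lambda(post$mean, post$map, post$basis, post$n_windows)
}

posterior_theta <- function(post) {
  sweep(exp(posterior_lambda(post)), 2, as.numeric(post$base), "*")
}

#' @export
print.cmc_posterior <- function(x, ...) {
  cat(sprintf("<cmc_posterior> model: %s\n", x$model$label))
  cat(sprintf("  %d windows x %d frequencies, %d latents\n",
              x$n_windows, length(x$freq), length(x$mean)))
  cat(sprintf("  F = %.2f, variance explained = %.3f, %s after %d iterations\n",
              x$free_energy, x$variance_explained,
              if (x$converged) "converged" else "not converged", x$iterations))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a DCM posterior
#'
#' @param x A `cmc_posterior`.
#' @param ... Unused.
#' @return One row per latent: `term`, `parameter`, `component`, `estimate`,
#'   `std.error`, `prior.sd`.
#' @export
tidy.cmc_posterior <- function(x, ...) {
  tibble::tibble(term = x$map$name,
                 parameter = x$map$parameter,
                 component = x$map$component,
                 estimate = unname(x$mean),
                 std.error = sqrt(pmax(0, diag(x$cov))),
                 prior.sd = x$map$prior_sd)
}

#' Glance at a DCM posterior
#'
#' @param x A `cmc_posterior`.
#' @param ... Unused.
#' @return A one-row tibble: `label`, `free_energy`, `variance_explained`,
#'   `n_latents`, `n_windows`, `iterations`, `converged`.
#' @export
glance.cmc_posterior <- function(x, ...) {
  tibble::tibble(label = x$model$label,
                 free_energy = x$free_energy,
                 variance_explained = x$variance_explained,
                 log_precision = x$h,
                 n_latents = length(x$mean),
                 n_windows = x$n_windows,
                 iterations = x$iterations,
                 converged = x$converged)
}

#' Serialise a posterior to JSON (plus trajectory CSV)
#'
#' Writes posterior means and SDs, the free energy and fit summary to a
#' JSON file, and optionally the per-window parameter trajectories to CSV.
#'
#' @param post A `cmc_posterior`.
#' @param json_path Output JSON path.
#' @param csv_path Optional CSV path for per-window log-scalings.
#' @return `json_path`, invisibly.
#' @export
write_posterior <- function(post, json_path, csv_path = NULL) {
  td <- tidy(post)
  obj <- list(model = post$model$label,
              free_energy = post$free_energy,
              variance_explained = post$variance_explained,
              log_precision = post$h,
              converged = post$converged,
              scale = post$scale,
              latents = td)
  jsonlite::write_json(obj, json_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  if (!is.null(csv_path)) {
    lam <- posterior_lambda(post)
    out <- tibble::as_tibble(as.data.frame(lam))
    out$window <- seq_len(nrow(lam))
    utils::write.csv(
      tidyr::pivot_longer(out, -dplyr::all_of("window"),
                          names_to = "parameter", values_to = "log_scaling"),
      csv_path, row.names = FALSE)
  }
  invisible(json_path)
}
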