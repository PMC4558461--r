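# Discrete cosine expansion of slowly varying parameters over seizure
# windows. Each time-dependent parameter theta with prior mean mu follows
# theta(t) = mu * exp(lambda(t)), lambda(t) = sum_k beta_k psi_k(t), with
# psi_k the first components of an orthonormal type-II DCT over the window
# index (onset-aligned). Non-varying parameters carry only the constant
# component.

#' Orthonormal discrete cosine basis
#'
#' Type-II DCT columns over `n_windows` points; the first column is constant
#' (`1/sqrt(n)`), column k has k-1 sign changes. Columns are orthonormal.
#'
#' @param n_windows Number of time windows (>= 1).
#' @param n_components Number of basis functions (default 8); truncated to
#'   `n_windows` with a warning if larger.
#' @return `n_windows` x `n_components` matrix.
#' @export
#' @examples
#' B <- dct_basis(10)
#' max(abs(crossprod(B) - diag(8)))  # orthonormal
dct_basis <- function(n_windows, n_components = 8) {
  if (n_windows < 1) stop("n_windows must be >= 1", call. = FALSE)
  if (n_components > n_windows) {
    warning("truncating cosine basis to ", n_windows, " components")
    n_components <- n_windows
  }
  n <- seq_len(n_windows)
  B <- vapply(seq_len(n_components), function(k) {
    col <- sqrt(2 / n_windows) * cos(pi * (2 * n - 1) * (k - 1) / (2 * n_windows))
    if (k == 1) col / sqrt(2) else col
  }, numeric(n_windows))
  matrix(B, nrow = n_windows)
}

# cosine set over the frequency grid shaping the input spectrum (the
# "spectral innovations"); same construction, fixed at 8 components
dct_basis_frequency <- function(freq) {
  dct_basis(length(freq), min(8L, length(freq)))
}

#' Parameter trajectory over seizure windows
#'
#' Bundles cosine-basis coefficients for the time-varying parameters of a
#' model. `beta` has one row per varying parameter (rownames must name
#' parameters in the model's varying set) and up to 8 columns of cosine
#' coefficients.
#'
#' @param beta Coefficient matrix (varying parameters x components), with
#'   rownames identifying the parameters.
#' @param n_windows Number of seizure windows.
#' @param spec A [model_spec()].
#' @return An object of class `"parameter_trajectory"`.
#' @export
parameter_trajectory <- function(beta, n_windows, spec) {
  beta <- as.matrix(beta)
  vary <- varying_parameters(spec)
  rn <- rownames(beta)
  if (is.null(rn)) rn <- character(0)
  if (!setequal(rn, vary))
    stop("rownames(beta) must be exactly the varying parameters of the model: ",
         paste(vary, collapse = ", "), call. = FALSE)
  if (any(!is.finite(beta))) stop("coefficients must be finite", call. = FALSE)
  k <- min(8L, n_windows)
  if (ncol(beta) > k)
    stop("at most ", k, " cosine components are supported for ", n_windows,
         " windows", call. = FALSE)
  structure(list(beta = beta, n_windows = n_windows, spec = spec),
            class = "parameter_trajectory")
}

#' Expand a trajectory into per-window parameter sets
#'
#' Maps cosine coefficients to per-window log-scalings
#' `lambda(t) = sum_k beta_k psi_k(t)` and applies them multiplicatively to
#' the base parameters, `theta(t) = mu * exp(lambda(t))`. Parameters outside
#' the model's varying set keep their base value in every window.
#'
#' @param traj A [parameter_trajectory()].
#' @param base Base parameters ([cmc_parameters()]), the prior means by
#'   default.
#' @return A list with `theta` (n_windows x 29 matrix, one parameter set per
#'   window) and `lambda` (n_windows x 29 matrix of log-scalings).
#' @export
#' @examples
#' spec <- model_spec(inhibitory = TRUE, excitatory = FALSE, endogenous = FALSE)
#' beta <- matrix(0, 3, 8, dimnames = list(c("g3", "g4", "g9"), NULL))
#' ex <- expand_trajectory(parameter_trajectory(beta, 10, spec))
#' all(ex$theta[1, ] == cmc_parameters())  # zero coefficients: prior means
expand_trajectory <- function(traj, base = cmc_parameters()) {
  stopifnot(inherits(traj, "parameter_trajectory"))
  validate_cmc_parameters(base)
  W <- traj$n_windows
  B <- dct_basis(W, min(8L, W))
  lambda <- matrix(0, W, length(.param_names),
                   dimnames = list(NULL, .param_names))
  for (pn in rownames(traj$beta)) {
    coef <- traj$beta[pn, ]
    lambda[, pn] <- B[, seq_along(coef), drop = FALSE] %*% coef
  }
  theta <- sweep(exp(lambda), 2, as.numeric(base), "*")
  colnames(theta) <- .param_names
  list(theta = theta, lambda = lambda)
}
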