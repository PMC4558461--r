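# Canonical-microcircuit dynamics: sigmoid activation, state derivatives,
# equilibria and linearisation. The state has 8 components: the mean
# depolarisations v1..v4 of (spiny stellate, superficial pyramidal,
# inhibitory interneurons, deep pyramidal), then the synaptic currents
# i1..i4 (their first derivatives).

# wiring: one row per intrinsic connection (target, source, sign, g, delayed)
.wiring <- data.frame(
  target  = c(1, 1, 1, 2, 2, 3, 3, 3, 4, 4),
  source  = c(1, 2, 3, 1, 2, 1, 3, 4, 3, 4),
  sign    = c(-1, -1, -1, +1, -1, +1, -1, +1, -1, -1),
  g       = c(1, 2, 3, 8, 7, 5, 4, 6, 9, 10),
  delayed = c(0, 1, 1, 1, 0, 1, 0, 1, 1, 0)
)

#' Centred sigmoid firing-rate function
#'
#' Maps mean depolarisation to (centred) population firing rate,
#' `1 / (1 + exp(-gamma * v)) - 1/2`. The centred form is odd and bounded in
#' \[-1/2, 1/2\], so the all-zero state is an exact resting equilibrium at
#' zero input for every parameter set; its slope at the origin is `gamma/4`.
#'
#' @param v Depolarisation (any numeric vector).
#' @param gamma Sigmoid slope, > 0.
#' @return Firing rate(s) in \[-1/2, 1/2\].
#' @export
#' @examples
#' cmc_sigmoid(0, 0.67)        # 0: the origin is the resting point
#' cmc_sigmoid(c(-50, 50), 0.67)
cmc_sigmoid <- function(v, gamma) {
  if (any(!is.finite(v))) stop("depolarisation must be finite", call. = FALSE)
  if (!is.numeric(gamma) || gamma <= 0) stop("gamma must be > 0", call. = FALSE)
  1 / (1 + exp(-gamma * v)) - 0.5
}

# derivative of the centred sigmoid (equals gamma/4 at v = 0)
cmc_sigmoid_deriv <- function(v, gamma) {
  s <- 1 / (1 + exp(-gamma * v))
  gamma * s * (1 - s)
}

#' State derivative of the delayed canonical microcircuit
#'
#' Evaluates the eight coupled first-order ODEs. Each population k follows
#' the second-order synaptic kernel `vdot_k = i_k`,
#' `idot_k = T_k * drive_k - 2 T_k i_k - T_k^2 v_k`, where the presynaptic
#' drive sums signed firing-rate inputs: connections from the inhibitory
#' population (g3, g4, g9) and the recurrent gain-control connections
#' (g1, g2, g7, g10) enter negatively, the excitatory connections
#' (g5, g6, g8) positively, and the exogenous input `u` drives the granular
#' (spiny stellate) population only. Between-population terms use the
#' delayed state, self-connections the instantaneous one.
#'
#' @param x State vector (v1..v4, i1..i4).
#' @param x_delayed State vector delayed by the conduction delay.
#' @param u Exogenous input rate (scalar, finite).
#' @param p A [cmc_parameters()] vector.
#' @return The 8-vector of state derivatives.
#' @export
#' @examples
#' p <- cmc_parameters()
#' cmc_state_derivative(rep(0, 8), rep(0, 8), 0, p)  # origin is a fixed point
cmc_state_derivative <- function(x, x_delayed, u, p) {
  if (length(x) != 8 || length(x_delayed) != 8)
    stop("state vectors must have length 8 (4 populations x 2 states)",
         call. = FALSE)
  if (!is.finite(u)) stop("input u must be finite", call. = FALSE)
  validate_cmc_parameters(p)
  T <- p[1:4]; g <- p[5:14]; gamma <- p[["gamma"]]
  fr_inst <- cmc_sigmoid(x[1:4], gamma)
  fr_del <- cmc_sigmoid(x_delayed[1:4], gamma)
  drive <- numeric(4)
  for (r in seq_len(nrow(.wiring))) {
    w <- .wiring[r, ]
    fr <- if (w$delayed == 1) fr_del[w$source] else fr_inst[w$source]
    drive[w$target] <- drive[w$target] + w$sign * g[w$g] * fr
  }
  drive[1] <- drive[1] + u
  unname(c(x[5:8], T * drive - 2 * T * x[5:8] - T^2 * x[1:4]))
}

#' Steady state of the microcircuit under constant input
#'
#' Finds the equilibrium of the delay system under a constant input `u0`
#' (where delayed and instantaneous states coincide) by Newton iteration
#' initialised at the origin.
#'
#' @param p A [cmc_parameters()] vector.
#' @param u0 Constant exogenous input.
#' @param tol Residual norm required for convergence.
#' @param max_iter Iteration limit.
#' @return The 8-state equilibrium, with attribute `"residual"`.
#' @export
#' @examples
#' max(abs(cmc_equilibrium(cmc_parameters(), 0)))  # origin at zero input
cmc_equilibrium <- function(p, u0 = 0, tol = 1e-9, max_iter = 500) {
  validate_cmc_parameters(p)
  x <- rep(0, 8)
  for (it in seq_len(max_iter)) {
    f <- cmc_state_derivative(x, x, u0, p)
    if (sqrt(sum(f^2)) < tol) {
      attr(x, "residual") <- sqrt(sum(f^2))
      return(x)
    }
    J <- cmc_jacobian(p, x)
    x <- x - solve(J$J0 + J$Jd, f)
  }
  f <- cmc_state_derivative(x, x, u0, p)
  stop(sprintf(
    "equilibrium search did not converge in %d iterations (residual %.3e)",
    max_iter, sqrt(sum(f^2))), call. = FALSE)
}

#' Linearisation of the microcircuit about a state
#'
#' Returns the instantaneous and delayed Jacobians (d f / d x and
#' d f / d x_delayed) of [cmc_state_derivative()] evaluated at `x0`,
#' analytically or by central finite differences (step 1e-6).
#'
#' @param p A [cmc_parameters()] vector.
#' @param x0 Expansion state; defaults to the origin (the resting
#'   equilibrium at zero input).
#' @param method `"analytic"` (default) or `"fd"`.
#' @return A list with 8 x 8 matrices `J0` (instantaneous) and `Jd`
#'   (delayed).
#' @export
#' @examples
#' J <- cmc_jacobian(cmc_parameters())
#' max(Re(eigen(J$J0 + J$Jd)$values)) < 0  # resting stability
cmc_jacobian <- function(p, x0 = rep(0, 8), method = c("analytic", "fd")) {
  method <- match.arg(method)
  validate_cmc_parameters(p)
  if (method == "fd") {
    h <- 1e-6
    J0 <- matrix(0, 8, 8); Jd <- matrix(0, 8, 8)
    for (j in 1:8) {
      e <- rep(0, 8); e[j] <- h
      J0[, j] <- (cmc_state_derivative(x0 + e, x0, 0, p) -
                  cmc_state_derivative(x0 - e, x0, 0, p)) / (2 * h)
      Jd[, j] <- (cmc_state_derivative(x0, x0 + e, 0, p) -
                  cmc_state_derivative(x0, x0 - e, 0, p)) / (2 * h)
    }
    return(list(J0 = J0, Jd = Jd))
  }
  T <- p[1:4]; g <- p[5:14]; gamma <- p[["gamma"]]
  sd_inst <- cmc_sigmoid_deriv(x0[1:4], gamma)
  J0 <- matrix(0, 8, 8); Jd <- matrix(0, 8, 8)
  for (k in 1:4) {
    J0[k, 4 + k] <- 1
    J0[4 + k, k] <- J0[4 + k, k] - T[k]^2
    J0[4 + k, 4 + k] <- -2 * T[k]
  }
  for (r in seq_len(nrow(.wiring))) {
    w <- .wiring[r, ]
    val <- w$sign * T[w$target] * g[w$g] * sd_inst[w$source]
    if (w$delayed == 1) {
      Jd[4 + w$target, w$source] <- Jd[4 + w$target, w$source] + val
    } else {
      J0[4 + w$target, w$source] <- J0[4 + w$target, w$source] + val
    }
  }
  list(J0 = J0, Jd = Jd)
}
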