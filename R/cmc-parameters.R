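# Parameter container and prior table for the canonical microcircuit.

.param_names <- c("T1", "T2", "T3", "T4",
                  paste0("g", 1:10),
                  "gamma", "delay", "c_dp",
                  "a1", "a2", "b1", "b2",
                  paste0("d_spec", 1:8))

.population_names <- c("spiny stellate", "superficial pyramidal",
                       "inhibitory interneurons", "deep pyramidal")

# group membership used throughout the model space
.group_inhibitory <- c("g3", "g4", "g9")
.group_excitatory <- c("g5", "g6", "g8")
.group_endogenous <- c("a1", "a2", "b1", "b2", paste0("d_spec", 1:8))

#' Prior specification for the canonical microcircuit
#'
#' One row per model parameter: prior mean (natural units) and the prior
#' variance of its log-scaling latent. Rate constants and connection
#' strengths are in Hz, the conduction delay in ms; the sigmoid slope,
#' observation weight and spectral parameters are dimensionless. The
#' time-dependent parameters fall into three groups -- inhibitory-origin
#' connections (g3, g4, g9), excitatory connections (g5, g6, g8) and the
#' endogenous input/noise spectrum (a1, a2, b1, b2, d_spec1..8) -- which the
#' model space allows to drift over seizure windows; the remaining
#' parameters are constant.
#'
#' @return A tibble with columns `parameter`, `group` (one of `"constant"`,
#'   `"inhibitory"`, `"excitatory"`, `"endogenous"`), `prior_mean`, and
#'   `log_prior_variance`.
#' @export
#' @examples
#' cmc_prior_table()
cmc_prior_table <- function() {
  group <- rep("constant", length(.param_names))
  names(group) <- .param_names
  group[.group_inhibitory] <- "inhibitory"
  group[.group_excitatory] <- "excitatory"
  group[.group_endogenous] <- "endogenous"
  mean <- c(250, 170, 80, 70,
            800, 600, 1600, 800, 800, 400, 400, 800, 400, 200,
            0.67, 1, 0.5,
            1, 1, 1, 1,
            rep(1, 8))
  logvar <- c(rep(0.0625, 4),        # rate constants
              rep(0.0625, 10),       # connectivities
              0.03125, 0.03125,      # gamma, delay
              0.0625,                # observation weight
              rep(0.0078125, 12))    # input / noise spectral parameters
  tibble::tibble(parameter = .param_names,
                 group = unname(group),
                 prior_mean = mean,
                 log_prior_variance = logvar)
}

#' Canonical-microcircuit parameter set
#'
#' Builds a full parameter vector for the four-population canonical
#' microcircuit. Any field left `NULL` takes its prior-mean value, so
#' `cmc_parameters()` is the prior-mean model.
#'
#' @param T Four synaptic rate constants (Hz), ordered (spiny stellate,
#'   superficial pyramidal, inhibitory interneurons, deep pyramidal).
#' @param g Ten intrinsic connection strengths g1..g10 (Hz). g3, g4, g9
#'   originate from the inhibitory population; g5, g6, g8 are excitatory;
#'   g1, g2, g7, g10 are constant gain-control connections.
#' @param gamma Sigmoid slope (dimensionless, > 0).
#' @param delay Intrinsic conduction delay for between-population
#'   connections (ms).
#' @param c_dp Relative contribution of deep-pyramidal depolarisation to the
#'   observed signal (the superficial weight is fixed at 1).
#' @param a1,a2 Amplitude and power-law exponent of the endogenous input
#'   spectral density.
#' @param b1,b2 Amplitude and power-law exponent of the measurement-noise
#'   spectral density.
#' @param d_spec Eight spectral-innovation coefficients shaping the input
#'   spectrum over frequency.
#' @return A named numeric vector of class `"cmc_parameters"` (length 29).
#' @export
#' @examples
#' p <- cmc_parameters()
#' p[["gamma"]]
#' cmc_parameters(c_dp = 0.2)[["c_dp"]]
cmc_parameters <- function(T = NULL, g = NULL, gamma = NULL, delay = NULL,
                           c_dp = NULL, a1 = NULL, a2 = NULL, b1 = NULL,
                           b2 = NULL, d_spec = NULL) {
  pr <- cmc_prior_table()
  th <- stats::setNames(pr$prior_mean, pr$parameter)
  fill <- function(th, val, idx, what, len) {
    if (is.null(val)) return(th)
    if (length(val) != len) stop(what, " must have length ", len, call. = FALSE)
    th[idx] <- val
    th
  }
  th <- fill(th, T, 1:4, "T", 4)
  th <- fill(th, g, 5:14, "g", 10)
  th <- fill(th, gamma, "gamma", "gamma", 1)
  th <- fill(th, delay, "delay", "delay", 1)
  th <- fill(th, c_dp, "c_dp", "c_dp", 1)
  th <- fill(th, a1, "a1", "a1", 1)
  th <- fill(th, a2, "a2", "a2", 1)
  th <- fill(th, b1, "b1", "b1", 1)
  th <- fill(th, b2, "b2", "b2", 1)
  th <- fill(th, d_spec, 22:29, "d_spec", 8)
  validate_cmc_parameters(th)
  structure(th, class = "cmc_parameters")
}

validate_cmc_parameters <- function(th) {
  if (length(th) != 29 || !is.numeric(th))
    stop("parameter vector must be numeric of length 29", call. = FALSE)
  if (any(!is.finite(th)))
    stop("parameters must be finite", call. = FALSE)
  pos <- c(1:14, which(.param_names %in% c("gamma", "delay")))
  if (any(th[pos] <= 0))
    stop("rate constants, connectivities, gamma and delay must be ",
         "strictly positive", call. = FALSE)
  nn <- which(.param_names %in% c("a1", "b1", "a2", "b2"))
  if (any(th[nn] < 0))
    stop("spectral amplitudes and power-law exponents must be non-negative",
         call. = FALSE)
  invisible(th)
}

as_cmc_parameters <- function(th) {
  th <- stats::setNames(as.numeric(th), .param_names)
  structure(th, class = "cmc_parameters")
}

#' @export
print.cmc_parameters <- function(x, ...) {
  cat("<cmc_parameters>\n")
  cat("  T (Hz):    ", paste(signif(x[1:4], 4), collapse = " "), "\n")
  cat("  g (Hz):    ", paste(signif(x[5:14], 4), collapse = " "), "\n")
  cat(sprintf("  gamma %.3g  delay %.3g ms  c_dp %.3g\n",
              x[["gamma"]], x[["delay"]], x[["c_dp"]]))
  cat(sprintf("  input a1 %.3g a2 %.3g  noise b1 %.3g b2 %.3g\n",
              x[["a1"]], x[["a2"]], x[["b1"]], x[["b2"]]))
  cat("  d_spec:    ", paste(signif(x[22:29], 3), collapse = " "), "\n")
  invisible(x)
}

# apply log-scalings to a base parameter vector; lambda is a named vector or
# a length-29 vector aligned with .param_names
scale_parameters <- function(base, lambda) {
  th <- as.numeric(base) * exp(as.numeric(lambda))
  as_cmc_parameters(th)
}
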