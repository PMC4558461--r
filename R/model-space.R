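# The hypothesis space: which parameter groups may drift over seizure
# windows. Three binary factors (inhibitory connectivity, excitatory
# connectivity, endogenous input/noise spectrum) give 8 models; free-energy
# differences score them, and the winning posterior yields the scientific
# read-outs (connectivity time courses, excitation-inhibition balance,
# per-population and input spectra).

#' Specify which parameter groups vary over windows
#'
#' @param inhibitory Allow the inhibitory-origin connections (g3, g4, g9) to
#'   change over windows.
#' @param excitatory Allow the excitatory connections (g5, g6, g8) to change.
#' @param endogenous Allow the input and measurement-noise spectral
#'   parameters (a1, a2, b1, b2, d_spec1..8) to change.
#' @param label Optional label; a Table-style label is generated if omitted.
#' @return An object of class `"model_spec"`.
#' @export
#' @examples
#' model_spec(TRUE, TRUE, TRUE)   # the full model
#' model_spec(FALSE, FALSE, FALSE)  # the null model: nothing changes
model_spec <- function(inhibitory = FALSE, excitatory = FALSE,
                       endogenous = FALSE, label = NULL) {
  flags <- c(inhibitory = isTRUE(inhibitory), excitatory = isTRUE(excitatory),
             endogenous = isTRUE(endogenous))
  if (is.null(label)) {
    parts <- c("Inhibitory", "excitatory", "endogenous")[flags]
    if (length(parts) == 0) {
      label <- "Null"
    } else {
      parts[1] <- paste0(toupper(substring(parts[1], 1, 1)),
                         substring(parts[1], 2))
      label <- paste(parts, collapse = " + ")
    }
  }
  structure(list(inhibitory = flags[["inhibitory"]],
                 excitatory = flags[["excitatory"]],
                 endogenous = flags[["endogenous"]],
                 label = label),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("<model_spec> %s (inhibitory=%s, excitatory=%s, endogenous=%s)\n",
              x$label, x$inhibitory, x$excitatory, x$endogenous))
  invisible(x)
}

#' Parameters allowed to vary under a model
#'
#' @param spec A [model_spec()].
#' @return Character vector of parameter names.
#' @export
varying_parameters <- function(spec) {
  stopifnot(inherits(spec, "model_spec"))
  c(if (spec$inhibitory) .group_inhibitory,
    if (spec$excitatory) .group_excitatory,
    if (spec$endogenous) .group_endogenous)
}

#' Enumerate the eight candidate models
#'
#' All 2^3 combinations of time-varying parameter groups, in the
#' conventional order: the full model first, the null model (no changes over
#' windows) last.
#'
#' @return A tibble with columns `label`, `inhibitory`, `excitatory`,
#'   `endogenous` and a list-column `model` of [model_spec()] objects.
#' @export
#' @examples
#' enumerate_models()$label
enumerate_models <- function() {
  flags <- list(c(TRUE, TRUE, TRUE),
                c(TRUE, TRUE, FALSE),
                c(TRUE, FALSE, TRUE),
                c(FALSE, TRUE, TRUE),
                c(TRUE, FALSE, FALSE),
                c(FALSE, TRUE, FALSE),
                c(FALSE, FALSE, TRUE),
                c(FALSE, FALSE, FALSE))
  models <- purrr::map(flags, ~ model_spec(.x[1], .x[2], .x[3]))
  tibble::tibble(
    label = purrr::map_chr(models, "label"),
    inhibitory = purrr::map_lgl(models, "inhibitory"),
    excitatory = purrr::map_lgl(models, "excitatory"),
    endogenous = purrr::map_lgl(models, "endogenous"),
    model = models
  )
}

#' Bayesian model comparison from free energies
#'
#' Expresses free energies relative to the null model and converts them to
#' posterior model probabilities under uniform model priors
#' (`p_i = exp(F_i) / sum_j exp(F_j)`). A log-evidence difference of 3
#' corresponds to posterior odds of about 20:1.
#'
#' @param x A data frame with columns `label` and `free_energy` (e.g. from
#'   [run_analysis()]), or a list of [dcm_invert()] posteriors, or a named
#'   numeric vector of free energies.
#' @return A tibble with columns `label`, `free_energy`, `relative_F`
#'   (relative to the null model if present, otherwise to the smallest
#'   finite value), `probability`, and `variance_explained` when available,
#'   sorted as given.
#' @export
#' @examples
#' compare_models(c(Full = 10, Null = 0))
compare_models <- function(x) {
  if (inherits(x, "cmc_posterior")) x <- list(x)
  if (is.list(x) && !is.data.frame(x) &&
      all(purrr::map_lgl(x, inherits, "cmc_posterior"))) {
    x <- tibble::tibble(
      label = purrr::map_chr(x, ~ .x$model$label),
      free_energy = purrr::map_dbl(x, "free_energy"),
      variance_explained = purrr::map_dbl(x, "variance_explained")
    )
  } else if (is.numeric(x)) {
    x <- tibble::tibble(label = names(x) %||% paste0("model", seq_along(x)),
                        free_energy = as.numeric(x))
  } else {
    x <- tibble::as_tibble(x)
  }
  if (!all(c("label", "free_energy") %in% names(x)))
    stop("need columns `label` and `free_energy`", call. = FALSE)
  ok <- is.finite(x$free_energy)
  if (!all(ok)) {
    warning("excluding models with non-finite free energy: ",
            paste(x$label[!ok], collapse = ", "))
    x <- x[ok, ]
  }
  ref <- if ("Null" %in% x$label) {
    x$free_energy[match("Null", x$label)]
  } else {
    min(x$free_energy)
  }
  rel <- x$free_energy - ref
  prob <- exp(rel - max(rel))
  x$relative_F <- rel
  x$probability <- prob / sum(prob)
  class(x) <- c("dcm_comparison", class(x))
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Inhibitory/excitatory connectivity time courses and their balance
#'
#' Summarises the posterior per-window log-scalings by group: the inhibitory
#' trajectory is the mean log-scaling over g3, g4, g9; the excitatory
#' trajectory the mean over g5, g6, g8; balance is excitatory minus
#' inhibitory. Posterior uncertainty is propagated through the (linear)
#' cosine expansion, giving +-2 posterior-SD bands.
#'
#' @param post A posterior from [dcm_invert()].
#' @return A tibble with columns `window`, `quantity` (`"inhibitory"`,
#'   `"excitatory"`, `"balance"`), `log_scaling`, `lower`, `upper`. For a
#'   null-model posterior all trajectories are identically zero and the
#'   attribute `"null_model"` is set.
#' @export
balance_timecourse <- function(post) {
  stopifnot(inherits(post, "cmc_posterior"))
  W <- post$n_windows
  if (!post$model$inhibitory && !post$model$excitatory &&
      !post$model$endogenous) {
    out <- tidyr::expand_grid(
      quantity = c("inhibitory", "excitatory", "balance"),
      window = seq_len(W))
    out$log_scaling <- 0; out$lower <- 0; out$upper <- 0
    out <- out[, c("window", "quantity", "log_scaling", "lower", "upper")]
    attr(out, "null_model") <- TRUE
    return(out)
  }
  Ci <- group_functional(post, .group_inhibitory)
  Ce <- group_functional(post, .group_excitatory)
  rows <- purrr::map2_dfr(
    list(Ci, Ce, Ce - Ci), c("inhibitory", "excitatory", "balance"),
    function(C, nm) {
      est <- as.numeric(C %*% post$mean)
      sdv <- sqrt(pmax(0, diag(C %*% post$cov %*% t(C))))
      tibble::tibble(window = seq_len(W), quantity = nm, log_scaling = est,
                     lower = est - 2 * sdv, upper = est + 2 * sdv)
    })
  rows
}

# W x L matrix mapping latents to the per-window mean log-scaling of a
# parameter group
group_functional <- function(post, params) {
  W <- post$n_windows
  C <- matrix(0, W, length(post$mean))
  for (j in seq_len(nrow(post$map))) {
    m <- post$map[j, ]
    if (!(m$parameter %in% params)) next
    col <- if (m$component == 0) rep(1, W) else post$basis[, m$component]
    C[, j] <- C[, j] + col / length(params)
  }
  C
}

#' Reconstruct spectral responses under the posterior
#'
#' Evaluates the forward model at the posterior-mean parameters of every
#' window: the predicted observed spectrum (against the data), the
#' per-population time-frequency surfaces, and the endogenous input
#' spectrum surface.
#'
#' @param post A posterior from [dcm_invert()].
#' @return A list of class `"dcm_reconstruction"` with tibbles `observed`
#'   (`window`, `frequency`, `data`, `predicted`), `populations` (`window`,
#'   `population`, `frequency`, `density`) and `input` (`window`,
#'   `frequency`, `density`).
#' @export
dcm_reconstruct <- function(post) {
  stopifnot(inherits(post, "cmc_posterior"))
  W <- post$n_windows
  freq <- post$freq
  theta <- posterior_theta(post)
  Sw <- predicted_spectrum_windows(theta, freq)$S
  obs <- tibble::tibble(
    window = rep(seq_len(W), each = length(freq)),
    frequency = rep(freq, W),
    data = c(t(post$data_S)),
    predicted = c(t(Sw))
  )
  pops <- purrr::map_dfr(seq_len(W), function(w) {
    ps <- population_spectra(as_cmc_parameters(theta[w, ]), freq)
    ps$window <- w
    ps
  })
  inp <- purrr::map_dfr(seq_len(W), function(w) {
    gi <- endogenous_input_spectrum(as_cmc_parameters(theta[w, ]), freq)
    gi$window <- w
    gi
  })
  structure(list(observed = obs,
                 populations = pops[, c("window", "population", "frequency",
                                        "density")],
                 input = inp[, c("window", "frequency", "density")]),
            class = "dcm_reconstruction")
}

#' Peak frequency per window
#'
#' The frequency of maximal spectral density in each window, within a band.
#' The default band starts at 4 Hz so that the ubiquitous low-frequency
#' (delta/power-law) shoulder does not mask in-band seizure rhythms --
#' standard practice when tracking seizure chirps.
#'
#' @param S Window-by-frequency matrix of spectral density, or a long tibble
#'   with columns `window`, `frequency` and a density column.
#' @param freq Frequency grid matching the columns of `S` (matrix input).
#' @param band Length-2 numeric band in Hz.
#' @param value Density column name for tibble input.
#' @return Numeric vector of peak frequencies, one per window.
#' @export
peak_frequencies <- function(S, freq = frequency_grid(), band = c(4, 40),
                             value = "density") {
  if (is.data.frame(S)) {
    wide <- tidyr::pivot_wider(S[, c("window", "frequency", value)],
                               names_from = "frequency",
                               values_from = dplyr::all_of(value))
    freq <- as.numeric(names(wide)[-1])
    S <- as.matrix(wide[, -1])
  }
  sel <- freq >= band[1] & freq <= band[2]
  fb <- freq[sel]
  apply(S[, sel, drop = FALSE], 1, function(s) fb[which.max(s)])
}
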