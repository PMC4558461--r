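# ggplot2 displays for the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot windowed spectral data as a time-frequency image
#'
#' @param object A `spectral_data` object.
#' @param trans Transformation applied to density for display (default
#'   `log10`).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.spectral_data <- function(object, trans = log10, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s, y = .data$frequency,
                                   fill = trans(.data$density))) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "log10 density") +
    ggplot2::labs(x = "time from onset (s)", y = "frequency (Hz)",
                  title = sprintf("windowed spectral density (%d seizure(s))",
                                  object$n_seizures)) +
    ggplot2::theme_minimal()
}

#' Plot connectivity/balance time courses of a posterior
#'
#' @param object A `cmc_posterior`.
#' @param ... Unused.
#' @return A ggplot of the inhibitory, excitatory and balance log-scaling
#'   trajectories with +-2 posterior-SD bands.
#' @export
autoplot.cmc_posterior <- function(object, ...) {
  tc <- balance_timecourse(object)
  tc$quantity <- factor(tc$quantity,
                        levels = c("inhibitory", "excitatory", "balance"))
  ggplot2::ggplot(tc, ggplot2::aes(x = .data$window, y = .data$log_scaling)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
                         alpha = 0.2) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0, linetype = 3) +
    ggplot2::facet_wrap(~quantity, ncol = 1) +
    ggplot2::labs(x = "window", y = "log scaling",
                  title = object$model$label) +
    ggplot2::theme_minimal()
}

#' Plot a model comparison
#'
#' @param object A `dcm_comparison` from [compare_models()].
#' @param ... Unused.
#' @return A ggplot of free energies relative to the null model.
#' @export
autoplot.dcm_comparison <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$label <- factor(df$label, levels = rev(df$label))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$relative_F, y = .data$label)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "free energy relative to null", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a posterior reconstruction
#'
#' @param object A `dcm_reconstruction` from [dcm_reconstruct()].
#' @param ... Unused.
#' @return A ggplot comparing measured and predicted time-frequency
#'   surfaces.
#' @export
autoplot.dcm_reconstruction <- function(object, ...) {
  df <- tidyr::pivot_longer(object$observed, c("data", "predicted"),
                            names_to = "kind", values_to = "density")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$window, y = .data$frequency,
                                   fill = log10(.data$density))) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~kind) +
    ggplot2::scale_fill_viridis_c(name = "log10 density") +
    ggplot2::labs(x = "window", y = "frequency (Hz)") +
    ggplot2::theme_minimal()
}

#' Per-population time-frequency responses under a posterior
#'
#' @param post A `cmc_posterior`.
#' @return A ggplot with one panel per population.
#' @export
plot_population_spectra <- function(post) {
  rec <- dcm_reconstruct(post)
  ggplot2::ggplot(rec$populations,
                  ggplot2::aes(x = .data$window, y = .data$frequency,
                               fill = log10(.data$density))) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~population) +
    ggplot2::scale_fill_viridis_c(name = "log10 density") +
    ggplot2::labs(x = "window", y = "frequency (Hz)",
                  title = "reconstructed population spectra") +
    ggplot2::theme_minimal()
}
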