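#' Plot block-wise drift-corrected deltas over a run
#'
#' Shows each sample block's \eqn{\Delta\delta} against its mid-time,
#' with shot-noise error bars, faceted by isotopologue -- the standard
#' way to inspect intra-peak isotope trends (flat for a homogenized
#' chamber run, sloped for a capillary-captured peak).
#'
#' @param sample_blocks Tibble from [drift_correct()] (or the
#'   `"sample_blocks"` attribute of [process_run()]).
#' @return A ggplot object.
#' @export
plot_block_deltas <- function(sample_blocks) {
  ggplot2::ggplot(sample_blocks,
                  ggplot2::aes(x = .data$mid_min, y = .data$delta_permil)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$delta_permil - 1000 * .data$shot_noise_rse,
      ymax = .data$delta_permil + 1000 * .data$shot_noise_rse
    )) +
    ggplot2::facet_wrap(ggplot2::vars(.data$isotopologue),
                        scales = "free_y") +
    ggplot2::labs(x = "Block mid-time (min)",
                  y = expression(Delta * delta ~ "(‰)"))
}

#' Plot a linearity (amount-dependency) experiment
#'
#' Mean \eqn{\Delta\delta} versus infused concentration with +/- 1 SD
#' error bars, per element.
#'
#' @param linearity Tibble from [linearity_experiment()].
#' @return A ggplot object.
#' @export
plot_linearity <- function(linearity) {
  ggplot2::ggplot(linearity,
                  ggplot2::aes(x = .data$concentration_uM,
                               y = .data$mean_delta_permil)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$mean_delta_permil - .data$sd_delta_permil,
      ymax = .data$mean_delta_permil + .data$sd_delta_permil
    )) +
    ggplot2::facet_wrap(ggplot2::vars(.data$element), scales = "free_y") +
    ggplot2::labs(x = "Concentration (µM)",
                  y = expression(Delta * delta ~ "(‰)"))
}

#' Plot an Allan-deviation curve
#'
#' Log-log Allan deviation versus averaging time, with the
#' \eqn{\tau^{-1/2}} counting-statistics slope for reference; a minimum
#' marks the integration time beyond which drift outweighs counting
#' gains.
#'
#' @param allan Tibble from [allan_deviation()].
#' @return A ggplot object.
#' @export
plot_allan <- function(allan) {
  ref <- allan$adev[1] * sqrt(allan$tau_min[1] / allan$tau_min)
  ggplot2::ggplot(allan, ggplot2::aes(x = .data$tau_min, y = .data$adev)) +
    ggplot2::geom_line(ggplot2::aes(y = ref), linetype = "dotted",
                       colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = expression(tau ~ "(min)"),
                  y = expression(sigma[A](tau)))
}
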