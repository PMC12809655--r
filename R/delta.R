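#' Delta value of a ratio against a reference
#'
#' \deqn{\delta = 1000\,(R_{sample} - R_{reference})/R_{reference}}
#' in per mil.
#'
#' @param r_sample Sample isotope ratio(s).
#' @param r_reference Reference isotope ratio(s), > 0.
#' @return Delta value(s) in per mil.
#' @examples
#' delta_value(1.05, 1) # 50 permil
#' @export
delta_value <- function(r_sample, r_reference) {
  if (any(!is.finite(r_reference) | r_reference <= 0)) {
    abort("`r_reference` must be positive.")
  }
  1000 * (r_sample - r_reference) / r_reference
}

#' Difference between two delta values
#'
#' \eqn{\Delta\delta = \delta_{sample} - \delta_{reference}} in per mil.
#'
#' @param delta_sample,delta_reference Delta values in per mil.
#' @return \eqn{\Delta\delta} in per mil.
#' @export
delta_diff <- function(delta_sample, delta_reference) {
  delta_sample - delta_reference
}

#' Drift-correct sample blocks against bracketing reference blocks
#'
#' For one isotopologue, interpolates the reference isotopologue ratio
#' linearly in time between the two reference blocks bracketing each
#' sample block (at the sample block's midpoint) and reports each sample
#' block's deviation from that interpolated reference as a
#' \eqn{\Delta\delta} in per mil. Any drift that is linear in the ratio
#' between consecutive reference blocks cancels exactly.
#'
#' @param blocks Block tibble from [segment_blocks()] containing both
#'   channels.
#' @param isotopologue The rare-isotopologue label to correct (e.g.
#'   `"13C"`).
#' @param fragment Optional fragment label when `blocks` spans several.
#' @return A tibble with one row per sample block: `fragment_id,
#'   isotopologue, segment, mid_min, ratio, r_reference_interp,
#'   delta_permil, shot_noise_rse`.
#' @export
drift_correct <- function(blocks, isotopologue, fragment = NULL) {
  b <- blocks[blocks$isotopologue == isotopologue, , drop = FALSE]
  if (!is.null(fragment)) b <- b[b$fragment_id == fragment, , drop = FALSE]
  if (dplyr::n_distinct(b$fragment_id) > 1) {
    abort("`blocks` spans several fragments; supply `fragment`.")
  }
  refs <- dplyr::arrange(b[b$channel == "reference", , drop = FALSE],
                         .data$mid_min)
  smps <- dplyr::arrange(b[b$channel == "sample", , drop = FALSE],
                         .data$mid_min)
  if (nrow(refs) < 2) {
    abort("Drift correction needs at least two reference blocks.")
  }
  if (nrow(smps) == 0) abort("No sample blocks to correct.")
  unbracketed <- smps$mid_min < min(refs$mid_min) |
    smps$mid_min > max(refs$mid_min)
  if (any(unbracketed)) {
    abort(paste0(
      "Sample block(s) not bracketed by reference blocks at mid-time(s): ",
      paste(format(smps$mid_min[unbracketed]), collapse = ", ")
    ))
  }
  r_interp <- approx(refs$mid_min, refs$ratio, xout = smps$mid_min,
                     method = "linear", ties = "ordered")$y
  tibble(
    fragment_id = smps$fragment_id,
    isotopologue = smps$isotopologue,
    segment = smps$segment,
    mid_min = smps$mid_min,
    ratio = smps$ratio,
    r_reference_interp = r_interp,
    delta_permil = delta_value(smps$ratio, r_interp),
    shot_noise_rse = smps$shot_noise_rse
  )
}

#' Combined confidence interval from sample and reference block scatter
#'
#' Pools the empirical scatter of the sample-side and reference-side block
#' values: \eqn{SE = \sqrt{s_s^2/n_s + s_r^2/n_r}}, with effective degrees
#' of freedom by Welch--Satterthwaite, and returns the two-sided
#' `level`-confidence half-width \eqn{t_{df}\,SE}.
#'
#' @param sample_values Per-block sample values (n >= 2), e.g.
#'   drift-corrected \eqn{\Delta\delta} values in per mil.
#' @param reference_values Per-block reference values (n >= 2), e.g.
#'   reference-block deltas about their mean.
#' @param level Confidence level (default 0.95).
#' @return Half-width of the confidence interval (same units as input).
#' @examples
#' combined_ci(c(1, 2, 3, 4), rep(0, 5))
#' @export
combined_ci <- function(sample_values, reference_values, level = 0.95) {
  n_s <- length(sample_values)
  n_r <- length(reference_values)
  if (n_s < 2 || n_r < 2) {
    abort("Need at least two blocks on each side to estimate uncertainty.")
  }
  v_s <- stats::var(sample_values) / n_s
  v_r <- stats::var(reference_values) / n_r
  se <- sqrt(v_s + v_r)
  if (se == 0) return(0)
  df <- (v_s + v_r)^2 /
    ((if (v_s > 0) v_s^2 / (n_s - 1) else 0) +
       (if (v_r > 0) v_r^2 / (n_r - 1) else 0))
  qt(1 - (1 - level) / 2, df) * se
}

#' Non-overlapping Allan deviation of a block series
#'
#' For each averaging time \eqn{\tau}, partitions an equally spaced series
#' into consecutive non-overlapping \eqn{\tau}-averages
#' \eqn{\bar y_k} and computes
#' \eqn{\sigma_A(\tau) = \sqrt{\tfrac12\,\langle(\bar y_{k+1}-\bar y_k)^2\rangle}}.
#' Under pure white (shot) noise \eqn{\sigma_A \propto \tau^{-1/2}}; drift
#' makes it rise again, and the minimum locates the optimal integration
#' time.
#'
#' @param values Equally spaced series of measurements.
#' @param spacing_min Spacing between consecutive values, in minutes.
#' @param taus_min Averaging times to evaluate, in minutes (multiples of
#'   `spacing_min`); defaults to powers of two of the spacing. A
#'   \eqn{\tau} needing fewer than two averages is skipped with a warning.
#' @return A tibble `tau_min, adev, n_averages`.
#' @export
allan_deviation <- function(values, spacing_min = 1, taus_min = NULL) {
  n <- length(values)
  if (n < 2) abort("Need at least two values.")
  if (is.null(taus_min)) {
    k <- 2^(0:floor(log2(n / 2)))
    taus_min <- k * spacing_min
  }
  m_all <- round(taus_min / spacing_min)
  if (any(m_all < 1 | abs(m_all * spacing_min - taus_min) > 1e-8)) {
    abort("`taus_min` must be positive multiples of `spacing_min`.")
  }
  rows <- purrr::map_dfr(m_all, function(m) {
    k <- floor(n / m)
    if (k < 2) {
      warn(sprintf("tau = %g min needs >= 2 averages; skipped.",
                   m * spacing_min))
      return(NULL)
    }
    avg <- colMeans(matrix(values[seq_len(k * m)], nrow = m))
    tibble(
      tau_min = m * spacing_min,
      adev = sqrt(mean(diff(avg)^2) / 2),
      n_averages = k
    )
  })
  rows
}

#' Expected delta-33S under mass-dependent fractionation
#'
#' \deqn{\delta^{33}S = 1000\left[(1 + \delta^{34}S/1000)^{\lambda} - 1\right]}
#' with the conventional mass-dependent exponent \eqn{\lambda = 0.515}.
#'
#' @param delta34_permil \eqn{\delta^{34}S} in per mil (> -1000).
#' @param exponent Mass-dependence exponent (default 0.515).
#' @return Expected \eqn{\delta^{33}S} in per mil.
#' @examples
#' mass_dependent_delta33(10)
#' @export
mass_dependent_delta33 <- function(delta34_permil, exponent = 0.515) {
  if (any(delta34_permil <= -1000)) {
    abort("`delta34_permil` must exceed -1000.")
  }
  1000 * ((1 + delta34_permil / 1000)^exponent - 1)
}
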