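#' Number of ions observed per scan
#'
#' Converts a peak's signal-to-noise reading into the number of ions it
#' represents, using the Orbitrap ion-counting relation
#' \deqn{N_{IO} = \frac{S}{N}\,\frac{C_N}{z}\,\sqrt{R_N/R}\,\sqrt{\mu}}
#' where \eqn{S} is the ion intensity, \eqn{N} the peak noise, \eqn{C_N}
#' the empirical noise constant, \eqn{z} the charge, \eqn{R} the resolving
#' power relative to the reference \eqn{R_N}, and \eqn{\mu} the number of
#' microscans averaged into the spectrum.
#'
#' All arguments are vectorized.
#'
#' @param intensity Ion intensity S (arbitrary units, >= 0).
#' @param peak_noise Peak noise N (same units, > 0).
#' @param resolution Nominal resolving power R (> 0).
#' @param microscans Number of microscans averaged (>= 1).
#' @param charge Ion charge z (>= 1).
#' @param constants A [processing_constants()] list.
#' @return Numeric vector of ion counts (real-valued, >= 0).
#' @examples
#' ions_observed(1, 1, 240000, 1, 1) # = C_N = 3
#' @export
ions_observed <- function(intensity, peak_noise, resolution, microscans,
                          charge = 1, constants = processing_constants()) {
  if (any(!is.finite(peak_noise) | peak_noise <= 0)) {
    abort("`peak_noise` must be positive (cannot form a signal-to-noise ratio).")
  }
  if (any(!is.finite(resolution) | resolution <= 0) ||
      any(!is.finite(microscans) | microscans < 1) ||
      any(!is.finite(charge) | charge < 1)) {
    abort("`resolution` must be > 0, `microscans` >= 1 and `charge` >= 1.")
  }
  if (any(!is.finite(intensity) | intensity < 0)) {
    abort("`intensity` must be >= 0.")
  }
  (intensity / peak_noise) * (constants$cn / charge) *
    sqrt(constants$rn / resolution) * sqrt(microscans)
}

#' Signal-to-noise ratio for a given ion count
#'
#' Inverse of [ions_observed()]: the S/N that a spectrum must show for a
#' given number of ions under the stated resolution, microscan and charge
#' settings. Used by the simulator to encode sampled counts back into
#' scan-table intensities.
#'
#' @param n_io Ion count (>= 0); vectorized.
#' @inheritParams ions_observed
#' @return Numeric vector of signal-to-noise ratios.
#' @export
sn_from_ions <- function(n_io, resolution, microscans, charge = 1,
                         constants = processing_constants()) {
  if (any(!is.finite(resolution) | resolution <= 0) ||
      any(!is.finite(microscans) | microscans < 1)) {
    abort("`resolution` must be > 0 and `microscans` >= 1.")
  }
  if (any(!is.finite(n_io) | n_io < 0)) abort("`n_io` must be >= 0.")
  n_io * charge / (constants$cn * sqrt(constants$rn / resolution) *
                     sqrt(microscans))
}

#' Shot-noise limit of an isotopologue ratio
#'
#' Predicted relative standard error of a ratio of two independent
#' ion-count sums under Poisson counting statistics:
#' \eqn{\sqrt{1/N_{rare} + 1/N_{base}}}.
#'
#' @param summed_rare Total rare-isotopologue ion count (> 0).
#' @param summed_base Total basepeak ion count (> 0).
#' @return Relative standard error (dimensionless); vectorized.
#' @examples
#' shot_noise_limit(1e4, 1e6)
#' @export
shot_noise_limit <- function(summed_rare, summed_base) {
  if (any(!is.finite(summed_rare) | summed_rare <= 0) ||
      any(!is.finite(summed_base) | summed_base <= 0)) {
    abort("Ion-count sums must be positive to form a shot-noise estimate.")
  }
  sqrt(1 / summed_rare + 1 / summed_base)
}

# Internal: per-row ion counts added to a scan tibble.
add_ion_counts <- function(scans, constants = processing_constants()) {
  dplyr::mutate(scans, n_io = ions_observed(
    .data$intensity, .data$peak_noise, .data$resolution,
    .data$microscans, .data$charge, constants
  ))
}

#' Aggregate scans into block-level isotopologue ratios
#'
#' Sums the ions observed for each isotopologue over a half-open time
#' window `[start, end)` and forms the block isotopologue ratios
#' \deqn{R^i = \frac{\sum_j N_{IO}(\mathrm{isotopologue}_i)}{\sum_j N_{IO}(\mathrm{basepeak})}}
#' together with their predicted shot-noise relative standard errors.
#'
#' @param scans Scan-record tibble (one channel; mixing sample and
#'   reference rows in one block is an error).
#' @param window Numeric length-2: `c(start_min, end_min)`, half-open.
#' @param specs Isotopologue spec table identifying each fragment's
#'   basepeak.
#' @param constants A [processing_constants()] list.
#' @return A tibble with one row per (fragment, isotopologue):
#'   `fragment_id, start_min, end_min, channel, n_spectra, isotopologue,
#'   summed_ions, ratio, shot_noise_rse`. The basepeak row has `ratio` 1
#'   and `shot_noise_rse` `NA`.
#' @export
aggregate_block <- function(scans, window, specs,
                            constants = processing_constants()) {
  stopifnot(length(window) == 2, window[2] > window[1])
  inside <- scans$time_min >= window[1] & scans$time_min < window[2]
  block <- scans[inside, , drop = FALSE]
  if (nrow(block) == 0) {
    abort(sprintf("No spectra in window [%g, %g).", window[1], window[2]))
  }
  channels <- unique(block$channel)
  if (length(channels) > 1) {
    abort(sprintf(
      "Window [%g, %g) mixes channels (%s); blocks must not straddle a valve switch.",
      window[1], window[2], paste(channels, collapse = ", ")
    ))
  }
  block <- add_ion_counts(block, constants)
  sums <- dplyr::summarise(
    dplyr::group_by(block, .data$fragment_id, .data$isotopologue),
    summed_ions = sum(.data$n_io),
    n_spectra = dplyr::n_distinct(.data$scan_no),
    .groups = "drop"
  )
  base_map <- dplyr::select(
    dplyr::filter(specs, .data$is_basepeak),
    "fragment_id", base_isotopologue = "isotopologue"
  )
  sums <- dplyr::left_join(sums, base_map, by = "fragment_id")
  if (any(is.na(sums$base_isotopologue))) {
    abort("Spec table does not define a basepeak for every fragment present.")
  }
  base_sums <- dplyr::select(
    dplyr::filter(sums, .data$isotopologue == .data$base_isotopologue),
    "fragment_id", base_ions = "summed_ions"
  )
  sums <- dplyr::left_join(sums, base_sums, by = "fragment_id")
  if (any(is.na(sums$base_ions) | sums$base_ions <= 0)) {
    abort(sprintf(
      "Degenerate block [%g, %g): basepeak ion sum is zero or absent.",
      window[1], window[2]
    ))
  }
  out <- dplyr::mutate(
    sums,
    start_min = window[1],
    end_min = window[2],
    channel = channels,
    ratio = .data$summed_ions / .data$base_ions,
    shot_noise_rse = dplyr::if_else(
      .data$isotopologue == .data$base_isotopologue | .data$summed_ions <= 0,
      NA_real_,
      sqrt(1 / pmax(.data$summed_ions, .Machine$double.xmin) +
             1 / .data$base_ions)
    )
  )
  dplyr::select(
    out, "fragment_id", "start_min", "end_min", "channel", "n_spectra",
    "isotopologue", "summed_ions", "ratio", "shot_noise_rse"
  )
}
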