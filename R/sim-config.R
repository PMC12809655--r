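#' Default electrospray amount-bias parameters
#'
#' Per-element parameters of the concentration-dependent delta bias
#' applied by the simulated electrospray source: below the linear-range
#' onset `c_lin` the bias is `beta * ln(c / c_lin)` per mil (continuous at
#' `c_lin`, zero above it). Defaults reproduce the observed behaviour of
#' the SMX fragments: carbon is nonlinear across 1--10 uM with a bias
#' magnitude of ~65 per mil at 0.5 uM, sulfur has a linear range from
#' 4 uM up with at most 9 per mil of bias below it, and nitrogen sits in
#' between; the 33S bias is mass-dependently scaled from 34S.
#'
#' @return A named list (per element) of lists with `beta` (per mil per
#'   log-unit) and `c_lin` (uM).
#' @export
default_esi_bias_params <- function() {
  list(
    "13C" = list(beta = 65 / log(10 / 0.5), c_lin = 10),
    "15N" = list(beta = 8, c_lin = 10),
    "34S" = list(beta = 9 / log(4 / 0.5), c_lin = 4),
    "33S" = list(beta = 0.515 * 9 / log(4 / 0.5), c_lin = 4)
  )
}

#' Default spectrum period for a resolving power
#'
#' Acquisition time of one averaged spectrum: the detect transient scales
#' with resolving power (~0.512 s at the 240,000 reference), multiplied by
#' the number of microscans, plus fixed fill/processing overhead. The two
#' resolutions used for the SMX fragments map to 2.0 s (90,000) and
#' 0.75 s (30,000).
#'
#' @param resolution Nominal resolving power.
#' @param microscans Microscans averaged per spectrum.
#' @return Spectrum period in seconds.
#' @export
default_spectrum_period <- function(resolution, microscans = 10) {
  if (resolution == 90000 && microscans == 10) return(2.0)
  if (resolution == 30000 && microscans == 10) return(0.75)
  microscans * 0.512 * resolution / 240000 + 0.1
}

#' Configure a simulated LC-capture-ESI-Orbitrap experiment
#'
#' Assembles and validates the full parameterization of one simulated
#' run: the injected analyte and its true isotopic enrichment, the
#' chromatographic peak and per-isotopologue retention offsets, the
#' capture device (plug-flow capillary or dispersed-plug mixing chamber),
#' electrospray amount bias, instrument drift, and the ion-counting
#' settings of the mass analyzer (AGC target, maximum injection time,
#' microscans, resolving power, spectrum period).
#'
#' @param fragment Fragment to simulate: `"F99"`, `"F92"` or `"F64"`.
#' @param true_delta_permil Named numeric: true enrichment of the sample
#'   material relative to the reference material, per element (e.g.
#'   `c("13C" = 18.2)`); elements not named are at the reference
#'   composition.
#' @param injection_volume_uL,injection_conc_uM Injected volume and
#'   concentration (defaults 40 uL of 100 uM, i.e. 4 nmol).
#' @param hplc_flow_uL_min,low_flow_uL_min Column flow (500 uL/min) and
#'   low-flow elution into the source (4 uL/min).
#' @param peak_center_min,peak_sigma_s Retention time and Gaussian width
#'   of the analyte peak at the column outlet.
#' @param retention_offset_s Named numeric, per rare isotopologue: signed
#'   retention-time offset in seconds (positive = heavier species more
#'   retained, the "normal" isotope effect).
#' @param capture_mode `"chamber"`, `"capillary"` or `"none"` (direct
#'   infusion of the injected solution, as in a linearity experiment).
#' @param capillary_volume_uL,chamber_volume_uL,chamber_peclet Capture
#'   device geometry (540 uL capillary; 1140 uL chamber with washout
#'   Peclet number 40).
#' @param capture_window_s Valve-open capture window in seconds.
#' @param esi_bias_params See [default_esi_bias_params()].
#' @param esi_bias_enabled Logical; disable to simulate an ideal source.
#' @param drift_lin_permil_per_h,drift_walk_permil_per_sqrt_h Linear and
#'   random-walk components of the slow instrument drift of measured
#'   isotopologue ratios, in per mil per hour and per mil per sqrt-hour.
#' @param scale_distortion Multiplicative delta-scale distortion of the
#'   analyzer (1 = none); mimics a scale-expansion day.
#' @param reference_conc_uM Syringe reference concentration (4 uM).
#' @param agc_target Automatic-gain-control charge target per trap fill.
#' @param max_injection_ms Maximum ion injection time per fill.
#' @param ion_rate_per_uM_ms Source ion current reaching the trap, in
#'   ions per millisecond per uM of analyte.
#' @param spectrum_period_s Time between reported spectra; default derived
#'   from the resolving power via [default_spectrum_period()].
#' @param resolution Nominal resolving power; default 90,000 (30,000 for
#'   F64).
#' @param microscans Microscans per spectrum (default 10).
#' @param duration_min,switch_period_min,guard_min,block_min,first_channel
#'   Bracketing schedule and processing-block parameters (180-min run,
#'   20-min valve period, 2-min guard, 15-min blocks, reference first).
#' @param poisson Draw Poisson shot noise (disable for noise-free
#'   transparency checks).
#' @param seed Integer seed recorded in the truth log and used for every
#'   stochastic element of the run.
#' @return A validated list of class `"sim_config"`.
#' @examples
#' cfg <- sim_config(fragment = "F99", true_delta_permil = c("13C" = 18.2))
#' @export
sim_config <- function(fragment = "F99",
                       true_delta_permil = numeric(0),
                       injection_volume_uL = 40,
                       injection_conc_uM = 100,
                       hplc_flow_uL_min = 500,
                       low_flow_uL_min = 4,
                       peak_center_min = 5,
                       peak_sigma_s = 15,
                       retention_offset_s = numeric(0),
                       capture_mode = c("chamber", "capillary", "none"),
                       capillary_volume_uL = 540,
                       chamber_volume_uL = 1140,
                       chamber_peclet = 40,
                       capture_window_s = 80,
                       esi_bias_params = default_esi_bias_params(),
                       esi_bias_enabled = TRUE,
                       drift_lin_permil_per_h = 1,
                       drift_walk_permil_per_sqrt_h = 0.3,
                       scale_distortion = 1,
                       reference_conc_uM = 4,
                       agc_target = 1.5e5,
                       max_injection_ms = 1000,
                       ion_rate_per_uM_ms = 1000,
                       spectrum_period_s = NULL,
                       resolution = NULL,
                       microscans = 10,
                       duration_min = 180,
                       switch_period_min = 20,
                       guard_min = 2,
                       block_min = 15,
                       first_channel = "reference",
                       poisson = TRUE,
                       seed = 1L) {
  capture_mode <- match.arg(capture_mode)
  if (is.null(resolution)) {
    resolution <- if (fragment == "F64") 30000 else 90000
  }
  if (is.null(spectrum_period_s)) {
    spectrum_period_s <- default_spectrum_period(resolution, microscans)
  }
  cfg <- list(
    fragment = fragment,
    true_delta_permil = true_delta_permil,
    injection_volume_uL = injection_volume_uL,
    injection_conc_uM = injection_conc_uM,
    hplc_flow_uL_min = hplc_flow_uL_min,
    low_flow_uL_min = low_flow_uL_min,
    peak_center_min = peak_center_min,
    peak_sigma_s = peak_sigma_s,
    retention_offset_s = retention_offset_s,
    capture_mode = capture_mode,
    capillary_volume_uL = capillary_volume_uL,
    chamber_volume_uL = chamber_volume_uL,
    chamber_peclet = chamber_peclet,
    capture_window_s = capture_window_s,
    esi_bias_params = esi_bias_params,
    esi_bias_enabled = esi_bias_enabled,
    drift_lin_permil_per_h = drift_lin_permil_per_h,
    drift_walk_permil_per_sqrt_h = drift_walk_permil_per_sqrt_h,
    scale_distortion = scale_distortion,
    reference_conc_uM = reference_conc_uM,
    agc_target = agc_target,
    max_injection_ms = max_injection_ms,
    ion_rate_per_uM_ms = ion_rate_per_uM_ms,
    spectrum_period_s = spectrum_period_s,
    resolution = resolution,
    microscans = microscans,
    duration_min = duration_min,
    switch_period_min = switch_period_min,
    guard_min = guard_min,
    block_min = block_min,
    first_channel = first_channel,
    poisson = isTRUE(poisson),
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  pos <- c("injection_volume_uL", "injection_conc_uM", "hplc_flow_uL_min",
           "low_flow_uL_min", "peak_sigma_s", "capillary_volume_uL",
           "chamber_volume_uL", "chamber_peclet", "capture_window_s",
           "reference_conc_uM", "agc_target", "max_injection_ms",
           "ion_rate_per_uM_ms", "spectrum_period_s", "resolution",
           "duration_min", "switch_period_min", "block_min")
  for (key in pos) {
    v <- cfg[[key]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v <= 0) {
      abort(paste0("`", key, "` must be a single positive number."))
    }
  }
  if (cfg$microscans < 1) abort("`microscans` must be >= 1.")
  if (cfg$capture_mode == "capillary") {
    loaded <- cfg$capture_window_s / 60 * cfg$hplc_flow_uL_min
    if (loaded > cfg$capillary_volume_uL) {
      abort(sprintf(
        "Capture overflow: window loads %.0f uL but the capillary holds %.0f uL.",
        loaded, cfg$capillary_volume_uL
      ))
    }
  }
  if (length(cfg$true_delta_permil) > 0 &&
      is.null(names(cfg$true_delta_permil))) {
    abort("`true_delta_permil` must be a named numeric (per element).")
  }
  if (length(cfg$retention_offset_s) > 0 &&
      is.null(names(cfg$retention_offset_s))) {
    abort("`retention_offset_s` must be a named numeric (per isotopologue).")
  }
  invisible(cfg)
}

#' Named scenario presets for the simulator
#'
#' Ready-made [sim_config()]s mirroring the main experiment types:
#' \describe{
#'   \item{`"chamber"` / `"accuracy"`}{Chamber capture of a 40-uL, 100-uM
#'     injection, bracketed 180-min run (the accuracy workflow).}
#'   \item{`"capillary"`}{Capillary capture of the F64 fragment with a
#'     +0.075-s retention offset for the heavy sulfur isotopologue at
#'     peak sigma 15 s and a 60-s (+/- 2 sigma) capture window, source
#'     bias and drift disabled, isolating the chromatographic isotope
#'     effect.}
#'   \item{`"linearity"`}{Direct infusion (no column, no capture) of an
#'     80-uL injection at 4 uL/min, bracketed against the 4-uM syringe
#'     reference.}
#' }
#'
#' @param preset Preset name.
#' @param ... Overrides passed on to [sim_config()].
#' @return A [sim_config()] object.
#' @export
preset_config <- function(preset = c("chamber", "accuracy", "capillary",
                                     "linearity"), ...) {
  preset <- match.arg(preset)
  args <- switch(preset,
    chamber = ,
    accuracy = list(capture_mode = "chamber"),
    capillary = list(
      fragment = "F64",
      capture_mode = "capillary",
      capture_window_s = 60,
      retention_offset_s = c("34S" = 0.075),
      esi_bias_enabled = FALSE,
      drift_lin_permil_per_h = 0,
      drift_walk_permil_per_sqrt_h = 0
    ),
    linearity = list(
      capture_mode = "none",
      injection_volume_uL = 80,
      injection_conc_uM = 4,
      duration_min = 60
    )
  )
  over <- list(...)
  args[names(over)] <- over
  do.call(sim_config, args)
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("Simulated run: fragment %s, %s capture, %g min, seed %d\n",
              x$fragment, x$capture_mode, x$duration_min, x$seed))
  cat(sprintf("  injection: %g uL x %g uM (%.3g nmol); peak sigma %g s\n",
              x$injection_volume_uL, x$injection_conc_uM,
              x$injection_volume_uL * x$injection_conc_uM / 1000,
              x$peak_sigma_s))
  cat(sprintf("  instrument: R = %g, AGC %g, %d microscans, %g s/spectrum\n",
              x$resolution, x$agc_target, x$microscans,
              x$spectrum_period_s))
  if (length(x$true_delta_permil) > 0) {
    cat(sprintf("  true enrichment: %s\n",
                paste(sprintf("%s %+g permil", names(x$true_delta_permil),
                              x$true_delta_permil), collapse = ", ")))
  }
  invisible(x)
}

# Sample-material isotopologue/basepeak ratios: natural abundance shifted
# by the configured true enrichment of each element.
material_ratios <- function(specs, true_delta_permil = numeric(0)) {
  nat <- natural_ratio(specs)
  el <- isotopologue_element(nat$isotopologue)
  shift <- ifelse(el %in% names(true_delta_permil),
                  true_delta_permil[el], 0)
  shift[is.na(shift)] <- 0
  dplyr::mutate(nat, ratio = .data$ratio_natural * (1 + shift / 1000))
}
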