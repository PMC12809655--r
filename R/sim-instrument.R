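# Run code with a private, restorable RNG state.
with_local_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Concentration-dependent electrospray delta bias
#'
#' Amount bias of the simulated source, expressed directly as a delta
#' shift of the rare/basepeak isotopologue ratio: below the linear-range
#' onset \eqn{c_{lin}} the bias is \eqn{\beta \ln(c/c_{lin})} per mil
#' (negative at low concentration for \eqn{\beta > 0}), zero at and above
#' \eqn{c_{lin}}, and continuous at the boundary. Note that a bracketed
#' measurement reports the *difference* between sample and reference
#' bias, so a reference below the linear onset partially cancels the
#' sample's bias.
#'
#' @param concentration_uM Analyte concentration(s) at the source, > 0.
#' @param element Element label (`"13C"`, `"15N"`, `"34S"`, `"33S"`).
#' @param params Per-element parameter list, see
#'   [default_esi_bias_params()].
#' @return Bias in per mil (vectorized over `concentration_uM`).
#' @examples
#' esi_bias(0.5, "13C") # about -65 permil
#' @export
esi_bias <- function(concentration_uM, element,
                     params = default_esi_bias_params()) {
  if (any(!is.finite(concentration_uM) | concentration_uM <= 0)) {
    abort("`concentration_uM` must be positive.")
  }
  p <- params[[element]]
  if (is.null(p)) return(rep(0, length(concentration_uM)))
  ifelse(concentration_uM >= p$c_lin, 0,
         p$beta * log(concentration_uM / p$c_lin))
}

#' Slow instrument drift of measured isotopologue ratios
#'
#' Multiplicative ratio drift factor
#' \eqn{1 + (d_{lin} t + W(t))/1000} with a linear component (per mil per
#' hour) and a seeded Gaussian random walk (per mil per sqrt-hour),
#' evaluated by interpolation on a 1-min grid. The same trace applies to
#' sample and reference channels, which is what makes bracketing able to
#' remove it.
#'
#' @param t_min Times in minutes.
#' @param lin_permil_per_h Linear drift rate.
#' @param walk_permil_per_sqrt_h Random-walk scale.
#' @param seed Integer seed (the trace is reproducible given the seed).
#' @return Multiplicative factors, same length as `t_min`.
#' @export
instrument_drift <- function(t_min, lin_permil_per_h = 0,
                             walk_permil_per_sqrt_h = 0, seed = 1L) {
  t_h <- t_min / 60
  walk <- rep(0, length(t_min))
  if (walk_permil_per_sqrt_h > 0) {
    grid <- seq(0, max(t_min, 1) + 1, by = 1)
    steps <- with_local_seed(seed, {
      rnorm(length(grid) - 1, 0,
            walk_permil_per_sqrt_h * sqrt(1 / 60))
    })
    w_grid <- c(0, cumsum(steps))
    walk <- approx(grid, w_grid, xout = pmax(t_min, 0), rule = 2)$y
  }
  1 + (lin_permil_per_h * t_h + walk) / 1000
}

#' Sample scan records from an outlet concentration profile
#'
#' Simulates the Orbitrap acquisition over a bracketed run: at each
#' spectrum time the valve position (per the schedule) selects either the
#' capture-device outlet or the constant syringe reference; the expected
#' charge per trap fill is the automatic-gain-control target, or the
#' flux-proportional fill reached within the maximum injection time at
#' low concentration, summed over microscans; ions are split across
#' isotopologues by the instantaneous composition modified by the source
#' amount bias, the common drift trace, and any delta-scale distortion;
#' counts are drawn Poisson (unless `config$poisson` is off) and encoded
#' back to intensities with unit peak noise, so the ion-counting relation
#' recovers them exactly.
#'
#' @param outlet Outlet profile tibble (`time_min, isotopologue,
#'   conc_uM`) from a capture function.
#' @param config A [sim_config()].
#' @param schedule A [build_schedule()]; default built from `config`.
#' @return A scan-record tibble in the [read_scan_table()] dialect.
#' @export
sample_scans <- function(outlet, config, schedule = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (config$spectrum_period_s <= 0) {
    abort("`spectrum_period_s` must be positive.")
  }
  if (is.null(schedule)) {
    schedule <- build_schedule(config$duration_min,
                               config$switch_period_min,
                               config$first_channel, config$guard_min)
  }
  specs <- smx_isotopologues(config$fragment)
  base_iso <- specs$isotopologue[specs$is_basepeak]
  nat <- natural_ratio(specs)
  iso_rare <- nat$isotopologue
  elements <- isotopologue_element(iso_rare)

  period_min <- config$spectrum_period_s / 60
  times <- seq(period_min / 2, config$duration_min - period_min / 2,
               by = period_min)
  channel <- schedule_channel(schedule, times)
  keep <- !is.na(channel)
  times <- times[keep]
  channel <- channel[keep]
  n_t <- length(times)

  # concentration of each isotopologue at the source, per spectrum
  wide <- tidyr::pivot_wider(outlet, names_from = "isotopologue",
                             values_from = "conc_uM")
  conc_smp <- vapply(c(base_iso, iso_rare), function(i) {
    y <- approx(wide$time_min, wide[[i]], xout = times, rule = 1)$y
    y[is.na(y) | y < 0] <- 0
    y
  }, numeric(n_t))
  ref_r <- nat$ratio_natural
  ref_frac <- c(1, ref_r) / (1 + sum(ref_r))
  conc_ref <- matrix(rep(config$reference_conc_uM * ref_frac, each = n_t),
                     nrow = n_t)
  colnames(conc_ref) <- c(base_iso, iso_rare)
  is_smp <- channel == "sample"
  conc <- conc_ref
  conc[is_smp, ] <- conc_smp[is_smp, ]
  c_total <- rowSums(conc)

  live <- c_total * config$ion_rate_per_uM_ms * config$max_injection_ms >= 1
  times <- times[live]; channel <- channel[live]
  conc <- conc[live, , drop = FALSE]; c_total <- c_total[live]
  n_t <- length(times)
  if (n_t == 0) abort("Outlet profile yields no measurable spectra.")

  # instantaneous rare/basepeak ratios with bias, drift, distortion
  drift <- instrument_drift(times, config$drift_lin_permil_per_h,
                            config$drift_walk_permil_per_sqrt_h,
                            seed = config$seed)
  ratios <- vapply(seq_along(iso_rare), function(k) {
    r <- conc[, iso_rare[k]] / conc[, base_iso]
    if (config$esi_bias_enabled) {
      bias <- esi_bias(c_total, elements[k], config$esi_bias_params)
      r <- r * (1 + bias / 1000)
    }
    r <- r * drift
    if (config$scale_distortion != 1) {
      r_nat <- nat$ratio_natural[k]
      r <- r_nat * (1 + config$scale_distortion * (r / r_nat - 1))
    }
    r
  }, numeric(n_t))
  colnames(ratios) <- iso_rare

  comp <- cbind(1, ratios)
  colnames(comp) <- c(base_iso, iso_rare)
  frac <- comp / rowSums(comp)

  fill <- pmin(config$agc_target,
               config$ion_rate_per_uM_ms * c_total * config$max_injection_ms)
  lambda <- frac * (fill * config$microscans)

  counts <- if (config$poisson) {
    matrix(rpois(length(lambda), lambda), nrow = n_t)
  } else {
    lambda
  }
  colnames(counts) <- colnames(lambda)

  long <- tidyr::pivot_longer(
    dplyr::bind_cols(
      tibble(time_min = times, scan_no = seq_len(n_t), channel = channel),
      as_tibble(counts)
    ),
    cols = dplyr::all_of(c(base_iso, iso_rare)),
    names_to = "isotopologue", values_to = "n_io"
  )
  dplyr::select(
    dplyr::mutate(
      long,
      fragment_id = config$fragment,
      intensity = sn_from_ions(.data$n_io, config$resolution,
                               config$microscans, 1),
      peak_noise = 1,
      resolution = config$resolution,
      microscans = as.integer(config$microscans),
      charge = 1L
    ),
    "time_min", "scan_no", "fragment_id", "isotopologue", "intensity",
    "peak_noise", "resolution", "microscans", "charge", "channel"
  )
}
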