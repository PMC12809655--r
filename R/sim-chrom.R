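# Trapezoidal integral on a possibly non-uniform grid.
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2) return(0)
  sum((y[-1] + y[-n]) * diff(x)) / 2
}

#' Simulate the chromatographic peak at the column outlet
#'
#' Each isotopologue elutes as a Gaussian of common width, centered at the
#' analyte retention time plus its configured retention offset (positive =
#' heavier species more retained). Areas are the injected moles
#' partitioned by the sample material's isotopologue abundances. Because
#' the isotopologue peaks are shifted copies of one another, the log of
#' the instantaneous heavy/light flux ratio is linear in time with slope
#' \eqn{\Delta t_R/\sigma^2}: the front of the peak is isotopically light
#' and the tail heavy (for a normal isotope effect), which is the origin
#' of the intra-peak delta trend.
#'
#' @param config A [sim_config()].
#' @param dt_s Time grid spacing in seconds (default `peak_sigma_s / 100`).
#' @return A tibble `time_min, isotopologue, flux_nmol_min` over
#'   +/- 6 sigma around the peak (extended to cover the capture window),
#'   with attribute `moles_nmol` (named, per isotopologue).
#' @export
simulate_chromatogram <- function(config, dt_s = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (config$peak_sigma_s <= 0) abort("`peak_sigma_s` must be positive.")
  specs <- smx_isotopologues(config$fragment)
  mat <- material_ratios(specs, config$true_delta_permil)
  base_iso <- specs$isotopologue[specs$is_basepeak]
  iso <- c(base_iso, mat$isotopologue)
  r <- c(1, mat$ratio)
  total_nmol <- config$injection_volume_uL * config$injection_conc_uM / 1000
  moles <- total_nmol * r / sum(r)
  names(moles) <- iso

  offsets <- setNames(rep(0, length(iso)), iso)
  known <- intersect(names(config$retention_offset_s), iso)
  offsets[known] <- config$retention_offset_s[known]

  sigma_min <- config$peak_sigma_s / 60
  if (is.null(dt_s)) dt_s <- config$peak_sigma_s / 100
  half <- max(6 * sigma_min + max(abs(offsets)) / 60,
              config$capture_window_s / 120 + 2 * sigma_min)
  time_min <- seq(config$peak_center_min - half,
                  config$peak_center_min + half, by = dt_s / 60)

  out <- purrr::map_dfr(iso, function(i) {
    tibble(
      time_min = time_min,
      isotopologue = i,
      flux_nmol_min = moles[[i]] *
        dnorm(time_min, config$peak_center_min + offsets[[i]] / 60,
              sigma_min)
    )
  })
  attr(out, "moles_nmol") <- moles
  out
}

#' Capture the peak in a plug-flow capillary and elute at low flow
#'
#' The valve-open window of the column effluent is loaded into the
#' capillary at the column flow and subsequently pushed into the source at
#' the low flow. Plug flow preserves the spatial concentration profile,
#' so the outlet reproduces the captured slice of the peak, stretched in
#' time by the flow ratio and *reversed*: the end of the captured
#' chromatographic peak is infused first. Concentrations are unchanged
#' (same plug, slower carrier), and captured moles are conserved.
#'
#' @param chrom Column-outlet flux table from [simulate_chromatogram()].
#' @param config A [sim_config()] with `capture_mode = "capillary"`.
#' @return A tibble `time_min, isotopologue, conc_uM` over the full
#'   elution (duration = capillary volume / low flow), with attributes
#'   `captured_nmol` (named) and `slug_duration_min`.
#' @export
capture_capillary <- function(chrom, config) {
  stopifnot(inherits(config, "sim_config"))
  w_min <- config$capture_window_s / 60
  loaded_uL <- w_min * config$hplc_flow_uL_min
  if (loaded_uL > config$capillary_volume_uL) {
    abort(sprintf(
      "Capture overflow: window loads %.0f uL but the capillary holds %.0f uL.",
      loaded_uL, config$capillary_volume_uL
    ))
  }
  t0 <- config$peak_center_min - w_min / 2
  t1 <- config$peak_center_min + w_min / 2
  stretch <- config$hplc_flow_uL_min / config$low_flow_uL_min
  slug_min <- w_min * stretch
  elute_min <- config$capillary_volume_uL / config$low_flow_uL_min

  # resample the captured slice on a grid pinned exactly to the window
  # edges, so the loaded and eluted integrals agree to quadrature
  dt <- stats::median(diff(sort(unique(chrom$time_min))))
  t_grid <- seq(t0, t1, length.out = max(51, ceiling(w_min / dt) + 1))
  out <- purrr::map_dfr(split(chrom, chrom$isotopologue), function(d) {
    flux <- approx(d$time_min, d$flux_nmol_min, xout = t_grid,
                   rule = 2)$y
    # reversed, time-stretched image of the captured slice
    t_e <- (t1 - t_grid) * stretch
    ord <- order(t_e)
    tibble(
      time_min = t_e[ord],
      isotopologue = d$isotopologue[1],
      conc_uM = flux[ord] / config$hplc_flow_uL_min * 1000
    )
  })
  captured <- vapply(split(chrom, chrom$isotopologue), function(d) {
    flux <- approx(d$time_min, d$flux_nmol_min, xout = t_grid,
                   rule = 2)$y
    trapz(t_grid, flux)
  }, numeric(1))
  # quiescent carrier after the slug, until the capillary is fully flushed
  tail_times <- seq(slug_min + 1e-9, elute_min, length.out = 16)
  tail_rows <- tidyr::expand_grid(
    time_min = tail_times,
    isotopologue = unique(chrom$isotopologue)
  )
  tail_rows$conc_uM <- 0
  out <- dplyr::arrange(dplyr::bind_rows(out, tail_rows),
                        .data$isotopologue, .data$time_min)
  attr(out, "captured_nmol") <- captured
  attr(out, "slug_duration_min") <- slug_min
  out
}

#' Capture the peak in a stirred mixing chamber and elute at low flow
#'
#' All analyte captured during the valve-open window is homogenized in
#' the chamber (the stirrer erases both concentration and isotope
#' gradients), giving an initial concentration of captured moles over the
#' chamber volume with *identical* composition at every moment of the
#' subsequent elution. The washout of the homogenized slug by fresh
#' eluent is modeled as plug displacement with axial dispersion: the
#' outlet concentration follows
#' \deqn{C(t)/C_0 = \Phi\!\left(\frac{\tau - t}{\sigma_t}\right),\quad
#'   \tau = V/Q,\ \sigma_t = \tau\sqrt{2/Pe}}
#' so the signal holds a plateau and only decays once roughly one chamber
#' volume has been displaced.
#'
#' @inheritParams capture_capillary
#' @param horizon_min Output horizon (default covers the full washout
#'   front).
#' @return A tibble `time_min, isotopologue, conc_uM` with attributes
#'   `captured_nmol` and `c0_uM` (named, per isotopologue).
#' @export
capture_chamber <- function(chrom, config, horizon_min = NULL) {
  stopifnot(inherits(config, "sim_config"))
  w_min <- config$capture_window_s / 60
  t0 <- config$peak_center_min - w_min / 2
  t1 <- config$peak_center_min + w_min / 2
  dt <- stats::median(diff(sort(unique(chrom$time_min))))
  t_grid <- seq(t0, t1, length.out = max(51, ceiling(w_min / dt) + 1))
  captured <- vapply(split(chrom, chrom$isotopologue), function(d) {
    trapz(t_grid, approx(d$time_min, d$flux_nmol_min, xout = t_grid,
                         rule = 2)$y)
  }, numeric(1))
  c0 <- captured / config$chamber_volume_uL * 1000
  tau <- config$chamber_volume_uL / config$low_flow_uL_min
  sigma_t <- tau * sqrt(2 / config$chamber_peclet)
  if (is.null(horizon_min)) horizon_min <- tau + 6 * sigma_t
  time_min <- seq(0, horizon_min, by = 0.25)
  front <- pnorm((tau - time_min) / sigma_t)
  out <- purrr::map_dfr(names(c0), function(i) {
    tibble(time_min = time_min, isotopologue = i,
           conc_uM = c0[[i]] * front)
  })
  attr(out, "captured_nmol") <- captured
  attr(out, "c0_uM") <- c0
  out
}

#' Time at which the chamber outlet leaves its plateau
#'
#' Closed form of the washout-front model used by [capture_chamber()]:
#' the first time at which \eqn{C(t)/C_0} drops below `threshold`,
#' \eqn{t^\ast = \tau - \sigma_t\,\Phi^{-1}(\mathrm{threshold})} with
#' \eqn{\tau = V/Q} and \eqn{\sigma_t = \tau\sqrt{2/Pe}}.
#'
#' @param volume_uL Chamber volume (uL).
#' @param flow_uL_min Elution flow (uL/min).
#' @param peclet Washout Peclet number.
#' @param threshold Plateau fraction (default 0.95).
#' @return Time in minutes.
#' @examples
#' chamber_plateau_time(1140, 4, 40) / 60 # hours
#' @export
chamber_plateau_time <- function(volume_uL, flow_uL_min, peclet,
                                 threshold = 0.95) {
  stopifnot(volume_uL > 0, flow_uL_min > 0, peclet > 0,
            threshold > 0, threshold < 1)
  tau <- volume_uL / flow_uL_min
  sigma_t <- tau * sqrt(2 / peclet)
  tau - sigma_t * qnorm(threshold)
}

#' Usable infusion time of one injection
#'
#' How long one injected plug sustains the source at the low flow:
#' volume over flow (an 80-uL injection at 4 uL/min gives 20 min of
#' usable data).
#'
#' @param volume_uL Injected volume (uL).
#' @param flow_uL_min Infusion flow (uL/min).
#' @return Usable time in minutes.
#' @examples
#' usable_infusion_min(80, 4)
#' @export
usable_infusion_min <- function(volume_uL, flow_uL_min) {
  stopifnot(volume_uL > 0, flow_uL_min > 0)
  volume_uL / flow_uL_min
}

# Direct-infusion "capture": the injected solution is delivered at the low
# flow; each sample segment corresponds to a fresh injection, so the
# concentration is constant over the run. One injection sustains
# usable_infusion_min() minutes, recorded as an attribute.
capture_none <- function(config) {
  specs <- smx_isotopologues(config$fragment)
  mat <- material_ratios(specs, config$true_delta_permil)
  base_iso <- specs$isotopologue[specs$is_basepeak]
  iso <- c(base_iso, mat$isotopologue)
  r <- c(1, mat$ratio)
  conc <- config$injection_conc_uM * r / sum(r)
  names(conc) <- iso
  time_min <- seq(0, config$duration_min, by = 0.5)
  out <- purrr::map_dfr(iso, function(i) {
    tibble(time_min = time_min, isotopologue = i, conc_uM = conc[[i]])
  })
  attr(out, "captured_nmol") <-
    config$injection_volume_uL * conc / 1000
  attr(out, "usable_min") <-
    usable_infusion_min(config$injection_volume_uL, config$low_flow_uL_min)
  out
}
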