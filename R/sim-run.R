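#' Run one simulated experiment end to end
#'
#' Composes the full measurement chain under the configured seed:
#' chromatographic elution, peak capture (capillary, chamber, or direct
#' infusion), bracketed Orbitrap acquisition, and scan-table encoding.
#' Returns the scan records together with the truth log -- everything
#' needed to compute the expected pipeline output analytically (true
#' enrichments, captured moles, initial chamber concentration, the full
#' configuration and the seed).
#'
#' @param config A [sim_config()].
#' @param out_dir Optional directory; when given, writes `scans.tsv`
#'   (scan-table dialect), `isotopologues.tsv` (sidecar spec table) and
#'   `truth.yml`.
#' @return A list of class `"orbi_run"`: `scans` (tibble), `schedule`,
#'   `specs`, `truth` (list).
#' @export
run_experiment <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  specs <- smx_isotopologues(config$fragment)
  schedule <- build_schedule(config$duration_min, config$switch_period_min,
                             config$first_channel, config$guard_min)
  run <- with_local_seed(config$seed, {
    outlet <- switch(config$capture_mode,
      capillary = capture_capillary(simulate_chromatogram(config), config),
      chamber = capture_chamber(simulate_chromatogram(config), config),
      none = capture_none(config)
    )
    scans <- sample_scans(outlet, config, schedule)
    list(outlet = outlet, scans = scans)
  })
  truth <- list(
    seed = config$seed,
    injected_nmol = config$injection_volume_uL *
      config$injection_conc_uM / 1000,
    true_delta_permil = as.list(config$true_delta_permil),
    captured_nmol = as.list(attr(run$outlet, "captured_nmol")),
    c0_uM = as.list(attr(run$outlet, "c0_uM") %||% NULL),
    config = unclass(config)
  )
  out <- structure(
    list(scans = run$scans, schedule = schedule, specs = specs,
         truth = truth),
    class = "orbi_run"
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_scan_table(run$scans, file.path(out_dir, "scans.tsv"))
    readr::write_tsv(specs, file.path(out_dir, "isotopologues.tsv"),
                     progress = FALSE)
    truth_out <- truth
    truth_out$config$true_delta_permil <-
      as.list(truth_out$config$true_delta_permil)
    truth_out$config$retention_offset_s <-
      as.list(truth_out$config$retention_offset_s)
    yaml::write_yaml(truth_out, file.path(out_dir, "truth.yml"))
  }
  out
}

#' @export
print.orbi_run <- function(x, ...) {
  cat(sprintf("Simulated run: %d scan rows, %d schedule segments, seed %d\n",
              nrow(x$scans), nrow(x$schedule), x$truth$seed))
  invisible(x)
}

#' Summarize drift-corrected deltas from block results
#'
#' For every rare isotopologue of every fragment present, drift-corrects
#' the sample blocks against the bracketing reference blocks and reports
#' the mean \eqn{\Delta\delta}, its combined 95% confidence half-width
#' (from sample-block and reference-block scatter, Welch--Satterthwaite
#' degrees of freedom), and the block counts.
#'
#' @param blocks Block tibble from [segment_blocks()].
#' @param level Confidence level (default 0.95).
#' @return A tibble: `fragment_id, isotopologue, element, value_permil,
#'   ci95_permil, n_sample_blocks, n_reference_blocks, calibration`.
#' @export
summarize_deltas <- function(blocks, level = 0.95) {
  rare <- dplyr::distinct(
    dplyr::filter(blocks, !is.na(isotopologue_element(.data$isotopologue))),
    .data$fragment_id, .data$isotopologue
  )
  purrr::map_dfr(seq_len(nrow(rare)), function(i) {
    f <- rare$fragment_id[i]
    iso <- rare$isotopologue[i]
    dc <- drift_correct(blocks, iso, fragment = f)
    refs <- blocks[blocks$isotopologue == iso &
                     blocks$fragment_id == f &
                     blocks$channel == "reference", , drop = FALSE]
    # reference scatter about its own drift trend (the drift itself is
    # removed by bracketing, so only the residual scatter is uncertainty);
    # rescaled so var() reflects the regression degrees of freedom
    ref_deltas <- if (nrow(refs) >= 3) {
      e <- stats::resid(lm(ratio ~ mid_min, data = refs))
      1000 * e / mean(refs$ratio) *
        sqrt((nrow(refs) - 1) / (nrow(refs) - 2))
    } else {
      delta_value(refs$ratio, mean(refs$ratio))
    }
    ci <- if (nrow(dc) >= 2 && nrow(refs) >= 2) {
      combined_ci(dc$delta_permil, ref_deltas, level)
    } else {
      NA_real_
    }
    tibble(
      fragment_id = f,
      isotopologue = iso,
      element = isotopologue_element(iso),
      value_permil = mean(dc$delta_permil),
      ci95_permil = ci,
      n_sample_blocks = nrow(dc),
      n_reference_blocks = nrow(refs),
      calibration = "drift_corrected"
    )
  })
}

#' Process a bracketed run into drift-corrected delta values
#'
#' The standard processing pipeline: cut the run into fixed-length
#' blocks along the bracketing schedule, aggregate ion counts into block
#' isotopologue ratios, drift-correct sample blocks against the
#' bracketing reference blocks, and summarize per element with combined
#' confidence intervals.
#'
#' @param scans Scan-record tibble.
#' @param schedule A [build_schedule()] result.
#' @param specs Isotopologue spec table (default: SMX fragments present
#'   in `scans`).
#' @param block_min Processing-block length in minutes (default 15).
#' @param constants [processing_constants()].
#' @param level Confidence level.
#' @return The [summarize_deltas()] tibble, with the block tibble
#'   attached as attribute `"blocks"` and the per-sample-block
#'   drift-corrected values as attribute `"sample_blocks"`.
#' @export
process_run <- function(scans, schedule, specs = NULL, block_min = 15,
                        constants = processing_constants(), level = 0.95) {
  if (is.null(specs)) {
    specs <- smx_isotopologues(intersect(unique(scans$fragment_id),
                                         c("F99", "F92", "F64")))
  }
  blocks <- segment_blocks(scans, schedule, specs, block_min, constants)
  if (nrow(blocks) == 0) abort("No usable processing blocks in the run.")
  out <- summarize_deltas(blocks, level)
  sample_blocks <- purrr::map_dfr(
    seq_len(nrow(out)),
    function(i) drift_correct(blocks, out$isotopologue[i],
                              fragment = out$fragment_id[i])
  )
  attr(out, "blocks") <- blocks
  attr(out, "sample_blocks") <- sample_blocks
  out
}

#' Simulated linearity experiment
#'
#' Direct-infusion runs (no column, no capture) at a series of
#' concentrations, each bracketed against the syringe reference, in
#' `reps` replicates; reports mean and standard deviation of
#' \eqn{\Delta\delta} per concentration and element -- the simulated
#' analogue of an amount-dependency (linearity) test.
#'
#' @param concentrations_uM Concentrations to infuse (uM).
#' @param reps Replicates per concentration (>= 2).
#' @param config Base [sim_config()] (its `capture_mode` is forced to
#'   `"none"`); replicate r of concentration c runs with seed
#'   `seed + 1000*index + r`.
#' @return A tibble: `concentration_uM, fragment_id, isotopologue,
#'   element, n, mean_delta_permil, sd_delta_permil`.
#' @export
linearity_experiment <- function(concentrations_uM = c(0.5, 1, 2, 4, 6, 8, 10),
                                 reps = 5,
                                 config = preset_config("linearity")) {
  if (reps < 2) abort("`reps` must be at least 2.")
  grid <- tidyr::expand_grid(
    conc = concentrations_uM,
    rep = seq_len(reps)
  )
  per_run <- purrr::map_dfr(seq_len(nrow(grid)), function(i) {
    conc <- grid$conc[i]
    cfg <- config
    cfg$injection_conc_uM <- conc
    cfg$capture_mode <- "none"
    cfg$seed <- config$seed +
      1000L * match(conc, concentrations_uM) + grid$rep[i]
    run <- run_experiment(cfg)
    res <- process_run(run$scans, run$schedule, run$specs,
                       block_min = cfg$block_min)
    dplyr::mutate(res, concentration_uM = conc, rep = grid$rep[i])
  })
  dplyr::summarise(
    dplyr::group_by(per_run, .data$concentration_uM, .data$fragment_id,
                    .data$isotopologue, .data$element),
    n = dplyr::n(),
    mean_delta_permil = mean(.data$value_permil),
    sd_delta_permil = sd(.data$value_permil),
    .groups = "drop"
  )
}
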