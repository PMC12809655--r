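# Shared fixtures: all synthetic, built in code.

# A scan tibble with constant per-spectrum ion counts per isotopologue,
# encoded through the ion-counting relation so the pipeline decodes the
# counts exactly (peak_noise = 1).
make_count_scans <- function(counts, n_spectra = 10, fragment = "F99",
                             resolution = 90000, microscans = 10L,
                             channel = "sample", t0 = 0,
                             period_min = 0.5) {
  times <- t0 + (seq_len(n_spectra) - 0.5) * period_min
  rows <- tidyr::expand_grid(
    scan_no = seq_len(n_spectra),
    isotopologue = names(counts)
  )
  rows$time_min <- times[rows$scan_no]
  rows$fragment_id <- fragment
  rows$intensity <- sn_from_ions(unlist(counts[rows$isotopologue]),
                                 resolution, microscans, 1)
  rows$peak_noise <- 1
  rows$resolution <- resolution
  rows$microscans <- microscans
  rows$charge <- 1L
  rows$channel <- channel
  dplyr::select(rows, "time_min", "scan_no", "fragment_id", "isotopologue",
                "intensity", "peak_noise", "resolution", "microscans",
                "charge", "channel")
}

# A small, fast chamber configuration for end-to-end tests.
quick_chamber_cfg <- function(...) {
  preset_config("chamber", ...)
}

# Noise- and artifact-free ("transparent") configuration.
transparent_cfg <- function(...) {
  preset_config(
    "chamber",
    esi_bias_enabled = FALSE,
    drift_lin_permil_per_h = 0,
    drift_walk_permil_per_sqrt_h = 0,
    poisson = FALSE,
    ...
  )
}

# Drift-corrected, anchor-calibrated enrichment recovery for one seed:
# simulates a natural-abundance anchor run and an enriched run, both
# through the chamber pipeline, and calibrates one-point.
recover_enrichment <- function(seed, enrichment_permil,
                               isotopologue = "13C") {
  anchor_cfg <- preset_config("accuracy", seed = seed)
  smp_cfg <- preset_config(
    "accuracy",
    true_delta_permil = setNames(enrichment_permil,
                                 isotopologue_element(isotopologue)),
    seed = seed + 500000L
  )
  one <- function(cfg) {
    run <- run_experiment(cfg)
    res <- process_run(run$scans, run$schedule, run$specs)
    res[res$isotopologue == isotopologue, ]
  }
  anchor <- one(anchor_cfg)
  smp <- one(smp_cfg)
  cal <- delta_calibration(anchor$value_permil, 0)
  list(
    value = calibrate(cal, smp$value_permil),
    ci = sqrt(smp$ci95_permil^2 + anchor$ci95_permil^2)
  )
}
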