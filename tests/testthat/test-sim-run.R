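test_that("a transparent chamber run returns the true enrichment exactly", {
  cfg <- transparent_cfg(true_delta_permil = c("13C" = 18.2), seed = 1)
  run <- run_experiment(cfg)
  expect_equal(run$truth$injected_nmol, 4)
  res <- process_run(run$scans, run$schedule, run$specs)
  expect_identical(res$n_sample_blocks[1], 4L)
  expect_identical(res$n_reference_blocks[1], 5L)
  expect_equal(res$value_permil[res$isotopologue == "13C"], 18.2,
               tolerance = 1e-9)
  expect_equal(res$value_permil[res$isotopologue == "15N"], 0,
               tolerance = 1e-9)
})

test_that("linear instrument drift is removed exactly by bracketing", {
  cfg <- transparent_cfg(drift_lin_permil_per_h = 2, seed = 1)
  run <- run_experiment(cfg)
  res <- process_run(run$scans, run$schedule, run$specs)
  sb <- attr(res, "sample_blocks")
  expect_lt(max(abs(sb$delta_permil)), 1e-9)
  # without correction the drift is plainly visible
  blocks <- attr(res, "blocks")
  refs <- blocks[blocks$channel == "reference" &
                   blocks$isotopologue == "13C", ]
  raw_spread <- diff(range(delta_value(refs$ratio, refs$ratio[1])))
  expect_gt(raw_spread, 3)  # ~2 permil/h over 3 h
})

test_that("random drift is suppressed to within shot-noise scatter", {
  cfg <- quick_chamber_cfg(true_delta_permil = c("13C" = 18.2), seed = 9)
  run <- run_experiment(cfg)
  res <- process_run(run$scans, run$schedule, run$specs)
  v <- res$value_permil[res$isotopologue == "13C"]
  ci <- res$ci95_permil[res$isotopologue == "13C"]
  # bias offset from the sample/reference concentration difference
  c0 <- sum(unlist(run$truth$c0_uM))
  expected <- 18.2 + esi_bias(c0, "13C") - esi_bias(4, "13C")
  expect_lt(abs(v - expected), max(3 * ci, 1.5))
})

test_that("chamber homogenization flattens what the capillary tilts", {
  cap_cfg <- preset_config("capillary", seed = 12)
  cap_run <- run_experiment(cap_cfg)
  cap_res <- suppressWarnings(
    process_run(cap_run$scans, cap_run$schedule, cap_run$specs)
  )
  cap_sb <- attr(cap_res, "sample_blocks")
  cap_sb <- cap_sb[cap_sb$isotopologue == "34S", ]
  fit <- lm(delta_permil ~ mid_min, data = cap_sb)
  # analytic intra-peak slope, reversed and stretched by the capture
  stretch <- cap_cfg$hplc_flow_uL_min / cap_cfg$low_flow_uL_min
  slope_col_per_s <- 1000 * 0.075 / 15^2
  expected_slope <- -slope_col_per_s * 60 / stretch  # permil per elution-min
  expect_equal(unname(coef(fit)[2]), expected_slope, tolerance = 0.15)

  cham_cfg <- preset_config("chamber", fragment = "F64",
                            retention_offset_s = c("34S" = 0.075),
                            esi_bias_enabled = FALSE,
                            drift_lin_permil_per_h = 0,
                            drift_walk_permil_per_sqrt_h = 0, seed = 12)
  cham_run <- run_experiment(cham_cfg)
  cham_res <- process_run(cham_run$scans, cham_run$schedule, cham_run$specs)
  cham_sb <- attr(cham_res, "sample_blocks")
  cham_sb <- cham_sb[cham_sb$isotopologue == "34S", ]
  spread <- diff(range(cham_sb$delta_permil))
  # flat within a few shot-noise standard errors
  expect_lt(spread, 6 * 1000 * mean(cham_sb$shot_noise_rse))
  cap_spread <- diff(range(cap_sb$delta_permil))
  expect_gt(cap_spread, 5 * spread)
})

test_that("identical configuration and seed give identical scan tables", {
  cfg <- quick_chamber_cfg(seed = 77)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  run_experiment(cfg, out_dir = d1)
  run_experiment(cfg, out_dir = d2)
  expect_identical(readLines(file.path(d1, "scans.tsv")),
                   readLines(file.path(d2, "scans.tsv")))
  expect_true(file.exists(file.path(d1, "truth.yml")))
  truth <- yaml::read_yaml(file.path(d1, "truth.yml"))
  expect_identical(truth$seed, 77L)
  expect_equal(truth$config$chamber_volume_uL, 1140)
})

test_that("the linearity experiment reproduces the amount-dependency", {
  conc <- c(0.5, 2, 4, 10)
  lin <- linearity_experiment(conc, reps = 2,
                              config = preset_config(
                                "linearity",
                                drift_walk_permil_per_sqrt_h = 0,
                                seed = 50
                              ))
  expect_identical(nrow(lin), length(conc) * 2L)  # 13C and 15N rows
  c13 <- lin[lin$element == "13C", ]
  expect_identical(c13$n, rep(2L, 4))
  # monotone increase with concentration, negative below the reference
  expect_true(all(diff(c13$mean_delta_permil[order(c13$concentration_uM)]) > 0))
  expect_lt(c13$mean_delta_permil[c13$concentration_uM == 0.5], -20)
  # at the reference concentration the deviation vanishes (same bias)
  expect_equal(c13$mean_delta_permil[c13$concentration_uM == 4], 0,
               tolerance = 0.5)
  # with bias disabled all deviations are null
  lin0 <- linearity_experiment(c(0.5, 4), reps = 2,
                               config = preset_config(
                                 "linearity",
                                 esi_bias_enabled = FALSE,
                                 drift_walk_permil_per_sqrt_h = 0,
                                 seed = 60
                               ))
  expect_lt(max(abs(lin0$mean_delta_permil)), 3 * 0.5)
})

test_that("result summaries plot without error", {
  cfg <- transparent_cfg(true_delta_permil = c("13C" = 5), seed = 2,
                         poisson = TRUE)
  run <- run_experiment(cfg)
  res <- process_run(run$scans, run$schedule, run$specs)
  p1 <- plot_block_deltas(attr(res, "sample_blocks"))
  expect_s3_class(p1, "ggplot")
  ad <- allan_deviation(rnorm(256))
  expect_s3_class(plot_allan(ad), "ggplot")
  lin <- tibble::tibble(concentration_uM = c(1, 4), element = "13C",
                        mean_delta_permil = c(-10, 0),
                        sd_delta_permil = c(1, 1))
  expect_s3_class(plot_linearity(lin), "ggplot")
})
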