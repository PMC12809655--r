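test_that("ion counting reproduces worked values and scaling laws", {
  # S/N = 1 at the reference resolution, one microscan: C_N ions
  expect_equal(ions_observed(1, 1, 240000, 1, 1), 3)
  expect_equal(ions_observed(0, 5, 240000, 1, 1), 0)
  # independent arithmetic: 100 * 3 * sqrt(8) * sqrt(10)
  expect_equal(ions_observed(100, 1, 30000, 10, 1),
               100 * 3 * sqrt(240000 / 30000) * sqrt(10),
               tolerance = 1e-12)
  expect_error(ions_observed(1, 0, 240000, 1, 1), "peak_noise")

  # scaling: linear in S/N, sqrt in microscans, inverse sqrt in R, 1/z
  set.seed(42)
  sn <- runif(20, 0.1, 100)
  r <- sample(c(30000, 90000, 240000), 20, replace = TRUE)
  mu <- sample(1:12, 20, replace = TRUE)
  base <- ions_observed(sn, 1, r, mu, 1)
  expect_equal(ions_observed(3 * sn, 1, r, mu, 1), 3 * base)
  expect_equal(ions_observed(sn, 1, r, 4 * mu, 1), 2 * base)
  expect_equal(ions_observed(sn, 1, r / 4, mu, 1), 2 * base)
  expect_equal(ions_observed(sn, 1, r, mu, 2), base / 2)
})

test_that("signal-to-noise encoding inverts ion counting to 1e-12", {
  expect_equal(sn_from_ions(3, 240000, 1, 1), 1)
  expect_equal(sn_from_ions(0, 90000, 10, 1), 0)
  grid <- tidyr::expand_grid(
    n_io = 10^seq(-2, 7, by = 0.5),
    resolution = c(30000, 90000, 240000)
  )
  back <- ions_observed(
    sn_from_ions(grid$n_io, grid$resolution, 10, 1),
    1, grid$resolution, 10, 1
  )
  expect_lt(max(abs(back - grid$n_io) / grid$n_io), 1e-12)
  # strict monotonicity
  expect_true(all(diff(sn_from_ions(0:100, 90000, 10, 1)) > 0))
})

test_that("block aggregation forms ratios of summed ions", {
  scans <- make_count_scans(list(M0 = 1000, `13C` = 43), n_spectra = 10)
  block <- aggregate_block(scans, c(0, 5), smx_isotopologues("F99"))
  expect_equal(block$summed_ions[block$isotopologue == "M0"], 10000)
  expect_equal(block$ratio[block$isotopologue == "13C"], 0.043)
  expect_equal(block$ratio[block$isotopologue == "M0"], 1)
  expect_equal(block$n_spectra, c(10L, 10L))

  # identical series for rare and basepeak: ratio exactly 1
  same <- make_count_scans(list(M0 = 500, `13C` = 500), n_spectra = 4)
  b2 <- aggregate_block(same, c(0, 5), smx_isotopologues("F99"))
  expect_identical(b2$ratio[b2$isotopologue == "13C"], 1)

  # mixed channels and degenerate blocks are errors
  mixed <- dplyr::bind_rows(
    scans,
    make_count_scans(list(M0 = 10, `13C` = 1), channel = "reference")
  )
  expect_error(aggregate_block(mixed, c(0, 5), smx_isotopologues("F99")),
               "channels")
  zero <- make_count_scans(list(M0 = 0, `13C` = 10), n_spectra = 3)
  expect_error(aggregate_block(zero, c(0, 5), smx_isotopologues("F99")),
               "[Dd]egenerate")
})

test_that("aggregation is additive over adjacent windows and scale-invariant", {
  cfg <- transparent_cfg(duration_min = 20, poisson = TRUE, seed = 5)
  scans <- run_experiment(cfg)$scans
  specs <- smx_isotopologues("F99")
  whole <- aggregate_block(scans, c(0, 12), specs)
  left <- aggregate_block(scans, c(0, 7), specs)
  right <- aggregate_block(scans, c(7, 12), specs)
  merged <- dplyr::left_join(left, right, by = "isotopologue")
  expect_equal(whole$summed_ions[match(merged$isotopologue,
                                       whole$isotopologue)],
               merged$summed_ions.x + merged$summed_ions.y,
               tolerance = 1e-12)

  scaled <- dplyr::mutate(scans, intensity = intensity * 7.3,
                          peak_noise = peak_noise * 7.3)
  expect_equal(aggregate_block(scaled, c(0, 12), specs)$ratio, whole$ratio,
               tolerance = 1e-12)
})

test_that("measured natural-abundance ratio matches the binomial oracle", {
  # binomial isotopologue oracle: singly-substituted/basepeak = n p/(1-p)
  oracle_13c <- 4 * 0.0107 / (1 - 0.0107)
  cfg <- sim_config(capture_mode = "none", duration_min = 20,
                    switch_period_min = 20, first_channel = "sample",
                    injection_volume_uL = 80, injection_conc_uM = 4,
                    esi_bias_enabled = FALSE, drift_lin_permil_per_h = 0,
                    drift_walk_permil_per_sqrt_h = 0, seed = 21)
  run <- run_experiment(cfg)
  block <- aggregate_block(run$scans, c(2, 17), run$specs)
  r <- block[block$isotopologue == "13C", ]
  expect_equal(r$ratio, oracle_13c, tolerance = 3 * r$shot_noise_rse)
  expect_equal(oracle_13c, 0.043264, tolerance = 1e-4)
})

test_that("shot-noise limit obeys counting statistics", {
  expect_equal(shot_noise_limit(1e4, 1e6), sqrt(1e-4 + 1e-6))
  expect_equal(shot_noise_limit(50, 50), sqrt(2 / 50))
  expect_equal(shot_noise_limit(4e4, 4e6),
               shot_noise_limit(1e4, 1e6) / 2)
  expect_error(shot_noise_limit(0, 10), "positive")

  # Monte-Carlo: empirical RSE of a Poisson ratio vs the prediction
  set.seed(99)
  rare <- rpois(2000, 1e4)
  base <- rpois(2000, 1e6)
  emp <- sd(rare / base) / mean(rare / base)
  expect_equal(emp, shot_noise_limit(1e4, 1e6), tolerance = 0.1)
})

test_that("shot-noise z-scores over replicate Poisson blocks have unit sd", {
  set.seed(7)
  n <- 800
  r_true <- 0.043264
  base <- rpois(n, 2e6)
  rare <- rpois(n, 2e6 * r_true)
  ratio <- rare / base
  z <- (ratio - r_true) / (r_true * shot_noise_limit(rare, base))
  expect_lt(abs(sd(z) - 1), 0.15)
})
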