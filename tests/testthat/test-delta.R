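test_that("delta calculus matches its closed forms", {
  expect_equal(delta_value(1, 1), 0)
  expect_equal(delta_value(1.05, 1), 50)
  r0 <- 0.043264
  expect_equal(delta_value(r0 * 1.0182, r0), 18.2, tolerance = 1e-12)
  expect_error(delta_value(1, 0), "positive")

  expect_equal(delta_diff(5, 5), 0)
  expect_equal(delta_diff(18.2, 0), 18.2)
  expect_equal(delta_diff(-4.4, 2.6), -7)

  # chain composition: (1 + d_ac/1000) = (1 + d_ab/1000)(1 + d_bc/1000)
  set.seed(1)
  for (i in 1:20) {
    ra <- runif(1, 0.01, 0.1); rb <- runif(1, 0.01, 0.1)
    rc <- runif(1, 0.01, 0.1)
    d_ab <- delta_value(ra, rb); d_bc <- delta_value(rb, rc)
    d_ac <- delta_value(ra, rc)
    expect_equal(1 + d_ac / 1000,
                 (1 + d_ab / 1000) * (1 + d_bc / 1000),
                 tolerance = 1e-12)
  }
})

test_that("drift correction interpolates the bracketing references", {
  mk_block <- function(mid, ratio, channel, segment) {
    tibble::tibble(fragment_id = "F64", isotopologue = "34S",
                   segment = segment, mid_min = mid, start_min = mid - 7.5,
                   end_min = mid + 7.5, channel = channel, n_spectra = 10L,
                   summed_ions = 1e6, ratio = ratio,
                   shot_noise_rse = 1e-4)
  }
  blocks <- dplyr::bind_rows(
    mk_block(10, 1.0000, "reference", 1),
    mk_block(30, 1.0020, "sample", 2),
    mk_block(50, 1.0040, "reference", 3)
  )
  out <- drift_correct(blocks, "34S")
  expect_equal(out$delta_permil, 0, tolerance = 1e-12)

  # constant reference: equivalent to delta against the global mean
  blocks2 <- dplyr::bind_rows(
    mk_block(10, 2, "reference", 1),
    mk_block(30, 2.1, "sample", 2),
    mk_block(50, 2, "reference", 3)
  )
  expect_equal(drift_correct(blocks2, "34S")$delta_permil,
               delta_value(2.1, 2))

  # unbracketed sample block is an error naming its time
  blocks3 <- dplyr::bind_rows(
    mk_block(10, 1, "reference", 1),
    mk_block(50, 1, "reference", 3),
    mk_block(70, 1.001, "sample", 4)
  )
  expect_error(drift_correct(blocks3, "34S"), "not bracketed.*70")
  expect_error(drift_correct(blocks3[-1, ], "34S"), "two reference")
})

test_that("combined confidence interval follows the pooled-t recipe", {
  # reference side constant: df reduces to n_s - 1 = 3
  half <- combined_ci(c(1, 2, 3, 4), rep(0, 5))
  se <- sqrt(var(c(1, 2, 3, 4)) / 4)
  expect_equal(se, 0.6455, tolerance = 1e-4)
  expect_equal(half, qt(0.975, 3) * se, tolerance = 1e-12)
  expect_equal(half, 2.054, tolerance = 1e-3)

  expect_equal(combined_ci(rep(2, 4), rep(7, 5)), 0)
  expect_error(combined_ci(1, c(1, 2)), "at least two")

  # Welch-Satterthwaite df against the textbook formula
  s <- c(0.1, 0.5, -0.2, 0.4); r <- c(0.05, -0.1, 0.2, -0.3, 0.15)
  vs <- var(s) / 4; vr <- var(r) / 5
  df <- (vs + vr)^2 / (vs^2 / 3 + vr^2 / 4)
  expect_equal(combined_ci(s, r),
               qt(0.975, df) * sqrt(vs + vr), tolerance = 1e-12)
})

test_that("confidence intervals achieve nominal coverage under shot noise", {
  # 2000 replicate bracketed runs of Poisson blocks, truth Delta-delta = 0
  set.seed(123)
  n_rep <- 2000
  r_true <- 0.0447
  n_base <- 5e5
  covered <- logical(n_rep)
  for (i in seq_len(n_rep)) {
    ref_ratio <- rpois(5, n_base * r_true) / rpois(5, n_base)
    smp_ratio <- rpois(4, n_base * r_true) / rpois(4, n_base)
    ref_d <- delta_value(ref_ratio, mean(ref_ratio))
    smp_d <- delta_value(smp_ratio, mean(ref_ratio))
    est <- mean(smp_d)
    half <- combined_ci(smp_d, ref_d)
    covered[i] <- abs(est) <= half
  }
  expect_equal(mean(covered), 0.95, tolerance = 0.032)
})

test_that("Allan deviation identifies noise regimes", {
  ad0 <- allan_deviation(rep(3, 64))
  expect_true(all(ad0$adev == 0))

  # white noise: sigma_A(tau) = tau^(-1/2) within 15% at tau = 1, 4, 16
  set.seed(8)
  y <- rnorm(4096)
  ad <- allan_deviation(y, 1, c(1, 4, 16))
  expect_equal(ad$adev, ad$tau_min^(-0.5), tolerance = 0.15)

  # log-log slope under pure white noise is -1/2
  ad2 <- allan_deviation(y, 1, 2^(0:6))
  slope <- coef(lm(log(adev) ~ log(tau_min), data = ad2))[2]
  expect_gt(slope, -0.6)
  expect_lt(slope, -0.4)

  # white noise + linear drift: optimum integration time 10-15 min
  # (grid-search oracle: argmin of 1/tau + a^2 tau^2 / 2 at a^(-2/3))
  a <- 0.024
  drifted <- y + a * seq_along(y)
  ad3 <- allan_deviation(drifted, 1, c(2, 4, 6, 8, 10, 12, 14, 16, 20, 24, 32))
  tau_opt <- ad3$tau_min[which.min(ad3$adev)]
  expect_gte(tau_opt, 10)
  expect_lte(tau_opt, 15)
  expect_equal(a^(-2 / 3), 12, tolerance = 0.01)

  expect_warning(allan_deviation(rnorm(10), 1, c(1, 8)), "skipped")
})

test_that("mass-dependent fractionation maps delta34S to delta33S", {
  expect_equal(mass_dependent_delta33(0), 0)
  expect_equal(mass_dependent_delta33(10), 5.138, tolerance = 1e-3)
  expect_equal(mass_dependent_delta33(10, exponent = 1), 10)
  expect_error(mass_dependent_delta33(-1000), "-1000")
})

test_that("exact masses reproduce the extraction m/z values", {
  specs <- smx_isotopologues()
  f99 <- specs[specs$fragment_id == "F99" & specs$is_basepeak, ]
  expect_equal(exact_mass(f99), 99.0553, tolerance = 5e-4)
  f64 <- specs[specs$fragment_id == "F64" & specs$is_basepeak, ]
  expect_equal(exact_mass(f64), 63.9623, tolerance = 5e-4)
  expect_identical(exact_mass("12C", polarity = "neutral"), 12)
  # electron mass accounting by polarity
  expect_equal(exact_mass("32S1 16O2", "neutral") -
                 exact_mass("32S1 16O2", "positive"),
               0.000548579909, tolerance = 1e-9)
  expect_error(exact_mass("99Xx1", "neutral"), "Unknown nuclide")
  # every extraction mass in the spec table is consistent with its formula
  for (i in seq_len(nrow(specs))) {
    expect_silent(m <- exact_mass(specs[i, ]))
    expect_lt(abs(m - specs$mz[i]), 0.001)
  }
  # a wrong nominal mass is flagged, not silently accepted
  wrong <- specs[1, ]
  wrong$mz <- wrong$mz + 0.01
  expect_warning(exact_mass(wrong), "differs from nominal")
})
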