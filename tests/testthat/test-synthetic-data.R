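test_that("identical scenarios and seeds reproduce identical draws", {
  s1 <- simulate_incubation(incubation_scenario(preset = "goa", seed = 7))
  s2 <- simulate_incubation(incubation_scenario(preset = "goa", seed = 7))
  expect_identical(s1, s2)
  s3 <- simulate_incubation(incubation_scenario(preset = "goa", seed = 8))
  expect_false(identical(s1$conc_nM, s3$conc_nM))

  expect_identical(simulate_profiles(profile_scenario(seed = 9)),
                   simulate_profiles(profile_scenario(seed = 9)))
  expect_identical(simulate_specimens(preset = "goa", n = 30, seed = 2),
                   simulate_specimens(preset = "goa", n = 30, seed = 2))
  expect_identical(simulate_standard_series(seed = 4),
                   simulate_standard_series(seed = 4))
})

test_that("the generator does not disturb the caller's random stream", {
  set.seed(99)
  before <- .Random.seed
  invisible(simulate_incubation(incubation_scenario(preset = "na", seed = 1)))
  expect_identical(.Random.seed, before)
})

test_that("no negative concentrations are ever emitted", {
  for (seed in 1:5) {
    inc <- simulate_incubation(
      incubation_scenario(preset = "na", noise_sd_nM = 5, seed = seed)
    )
    expect_true(all(inc$conc_nM >= 0))
    pr <- simulate_profiles(profile_scenario(noise_sd_nM = 2, seed = seed))
    expect_true(all(pr$tau_nM >= 0))
  }
})

test_that("noise-free incubations close the loop with the estimator", {
  sc <- incubation_scenario(preset = "goa", noise_sd_nM = 0, seed = 1)
  expect_equal(unname(sc$volumetric_rate_nM_h), 42.5) # 425 x 50 / 500
  inc <- simulate_incubation(sc)
  d <- inc[!inc$is_control, ]
  f <- fit_release_rate(d$time_h, d$conc_nM)
  expect_equal(f$slope_nM_h, 42.5, tolerance = 1e-12)
  nr <- normalize_rates(f$slope_nM_h, sc$volume_L, sc$n_individuals,
                        sc$biomass_gC)
  expect_equal(nr$rate_pmol_ind_h, 425, tolerance = 1e-9)

  # an 8 h plateau on the 24 h sampling grid is truncated at 8 h
  sc8 <- incubation_scenario(preset = "goa", plateau_time_h = 8,
                             noise_sd_nM = 0, seed = 1)
  inc8 <- simulate_incubation(sc8)
  d8 <- inc8[!inc8$is_control, ]
  expect_equal(truncate_series(d8$time_h, d8$conc_nM), 8)

  # handling-stress spike raises early points without changing the plateau tail
  scs <- incubation_scenario(preset = "na", spike_nM = 5, spike_decay_h = 0.5,
                             noise_sd_nM = 0, seed = 1)
  incs <- simulate_incubation(scs)
  ds <- incs[!incs$is_control, ]
  expect_gt(ds$conc_nM[1], 5)
})

test_that("simulated profiles hit the target epipelagic mean", {
  pr <- simulate_profiles(profile_scenario(n_stations = 20, seed = 61))
  m <- layer_mean_concentration(pr, depth_range = c(0, 100))
  expect_lt(abs(m - 2.5) / 2.5, 0.10)

  # zero noise gives the exact exponential
  pr0 <- simulate_profiles(profile_scenario(noise_sd_nM = 0, n_stations = 1,
                                            seed = 1))
  expect_equal(pr0$tau_nM,
               0.15 + (4.9 - 0.15) * exp(-pr0$depth_m / 60),
               tolerance = 1e-12)
  expect_true(all(pr0$tau_nM[pr0$depth_m >= 300] < 0.2))
})

test_that("specimen presets bracket the two observed biomass regimes", {
  # degenerate size distribution: identical individuals, additive biomass
  fixed <- simulate_specimens(preset = "custom", n = 10, group = "copepod",
                              meanlog_length = log(1000), sdlog_length = 0,
                              diameter_ratio = 5, seed = 3)
  expect_equal(nrow(fixed), 10)
  expect_equal(length(unique(fixed$length_um)), 1)
  bm <- specimen_set_biomass(fixed)
  expect_equal(bm$total_carbon_g, 10 * bm$mean_individual_gC)

  # large Pacific assemblage: hundreds of ug C per individual
  goa <- specimen_set_biomass(simulate_specimens(preset = "goa", n = 200,
                                                 seed = 17))
  expect_gt(goa$mean_individual_gC, 3.4e-4 / 2)
  expect_lt(goa$mean_individual_gC, 3.4e-4 * 2)

  # small Atlantic copepods: a few ug C per individual
  na <- specimen_set_biomass(simulate_specimens(preset = "na", n = 200,
                                                seed = 17))
  expect_gt(na$mean_individual_gC, 1e-6)
  expect_lt(na$mean_individual_gC, 6e-6)
})

test_that("standard-series generator supports the validation suite", {
  clean <- simulate_standard_series(noise_frac = 0, seed = 1)
  expect_equal(fit_calibration(clean)$r_squared, 1, tolerance = 1e-12)

  st <- simulate_standard_series(seed = 5)
  # S/N grows linearly with concentration: limits sit on the design grid
  lims <- detect_limits(data.frame(conc_nM = st$conc_nM, signal = st$response,
                                   noise = st$noise))
  expect_equal(lims$lod_nM, 0.02)
  expect_equal(lims$loq_nM, 0.1)
  expect_gte(fit_calibration(st)$r_squared, 0.997)
})

test_that("scenario validation rejects impossible designs", {
  expect_error(incubation_scenario(preset = "goa",
                                   true_rate_pmol_ind_h = c(Tau = -1), seed = 1),
               "positive")
  expect_error(incubation_scenario(preset = "custom", seed = 1), "must set")
  expect_error(incubation_scenario(preset = "goa",
                                   times_h = c(0, 2, 2), seed = 1),
               "increase")
  expect_error(profile_scenario(surface_conc_nM = 0.1, deep_baseline_nM = 0.2,
                                seed = 1),
               "below the surface")
})
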