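test_that("the regression window ends where the first analyte plateaus", {
  t_goa <- c(0, 2, 4, 6, 8, 10, 12, 24)
  rising <- 1 + 2 * t_goa
  expect_equal(truncate_series(t_goa, rising), 24)

  # plateau after 8 h: the full 24 h experiment is truncated to 8
  flat8 <- c(1, 3, 5, 7, 9, 9, 9, 9)
  expect_equal(truncate_series(t_goa, flat8), 8)

  # a companion analyte decreasing after t = 3 cuts every series there
  t <- 0:5
  tau <- 1 + t
  companion <- c(1, 2, 3, 4, 3.5, 3)
  expect_equal(truncate_series(t, cbind(tau, companion)), 3)

  # tolerance: a rise smaller than tol does not count
  expect_equal(truncate_series(0:3, c(1, 2, 2.05, 3), tol_nM = 0.1), 1)
})

test_that("truncation never passes the first monotonicity violation", {
  set.seed(19)
  for (i in 1:30) {
    n <- sample(5:10, 1)
    t <- sort(sample(0:30, n))
    t <- t - t[1]
    if (any(diff(t) == 0)) next
    m <- matrix(abs(cumsum(rnorm(n * 3, 0.5, 1))), ncol = 3)
    m <- apply(m, 2, function(x) pmax(x, 0))
    t_c <- truncate_series(t, m)
    steps_ok <- sapply(seq_len(n - 1), function(j) all(m[j + 1, ] - m[j, ] > 0))
    first_bad <- which(!steps_ok)
    expected <- if (length(first_bad)) t[min(first_bad)] else t[n]
    expect_equal(t_c, expected)
    # column order of companions is irrelevant
    expect_equal(truncate_series(t, m[, 3:1]), t_c)
  }
})

test_that("release-rate regression matches the normal-equations oracle", {
  f <- fit_release_rate(0:4, 1 + 2 * (0:4))
  expect_equal(f$slope_nM_h, 2)
  expect_equal(f$r_squared, 1)
  expect_lt(f$p_value, 0.001)

  set.seed(23)
  for (i in 1:40) {
    n <- sample(4:12, 1)
    t <- sort(runif(n, 0, 24))
    y <- pmax(runif(1, 0, 5) + runif(1, 0.1, 5) * t + rnorm(n, 0, 2), 0)
    f <- fit_release_rate(t, y)
    o <- ols_oracle(t, y)
    expect_equal(f$slope_nM_h, o$slope, tolerance = 1e-9)
    expect_equal(f$r_squared, o$r_squared, tolerance = 1e-9)
    expect_equal(f$p_value, o$p_value, tolerance = 1e-9)
  }
})

test_that("constant series are flagged rather than fitted", {
  f <- fit_release_rate(0:4, rep(2, 5))
  expect_equal(f$slope_nM_h, 0)
  expect_true(is.na(f$r_squared))
  expect_equal(apply_qc(f, 0:4, rep(2, 5)), "low_fit")
  expect_error(fit_release_rate(0:1, c(1, 2)), "insufficient")
})

test_that("duplicate time points are averaged before regression", {
  f <- fit_release_rate(c(0, 0, 1, 2), c(1, 3, 4, 6))
  o <- ols_oracle(c(0, 1, 2), c(2, 4, 6))
  expect_equal(f$slope_nM_h, o$slope)
  expect_equal(f$n, 3)
})

test_that("QC keeps sound fits and rejects weak or stress-dominated ones", {
  # retained in the field data: r2 = 0.616 with p below 0.05
  t <- c(0, 1, 2, 3, 5, 8)
  set.seed(5)
  good <- list(r_squared = 0.616, p_value = 0.02)
  class(good) <- "rate_fit"
  rising <- 1 + 0.5 * t
  expect_equal(apply_qc(good, t, rising), "pass")

  weak_r2 <- structure(list(r_squared = 0.55, p_value = 0.01), class = "rate_fit")
  expect_equal(apply_qc(weak_r2, t, rising), "low_fit")
  weak_p <- structure(list(r_squared = 0.80, p_value = 0.08), class = "rate_fit")
  expect_equal(apply_qc(weak_p, t, rising), "low_fit")
  # AND combinator only rejects when both thresholds fail
  expect_equal(apply_qc(weak_p, t, rising, combine = "and"), "pass")
  expect_equal(
    apply_qc(structure(list(r_squared = 0.5, p_value = 0.5), class = "rate_fit"),
             t, rising, combine = "and"),
    "low_fit"
  )

  # handling-stress signature: everything released in the first interval
  jumpy <- c(0, 5, 5.1, 5, 4.9, 5)
  f <- fit_release_rate(t, jumpy)
  expect_equal(apply_qc(f, t, jumpy), "early_release_only")
})

test_that("rate normalisation reproduces the chamber arithmetic", {
  nr <- normalize_rates(31.68, 0.5, 50, 0.0176)
  expect_equal(nr$rate_pmol_ind_h, 316.8)
  expect_equal(nr$rate_umol_gC_h, 0.9)
  small <- normalize_rates(0.0317, 0.5, 50, 0.0176)
  expect_equal(small$rate_pmol_ind_h, 0.317)

  # doubling the chamber volume at fixed slope doubles both rates
  d1 <- normalize_rates(10, 0.5, 40, 1e-4)
  d2 <- normalize_rates(10, 1.0, 40, 1e-4)
  expect_equal(d2$rate_pmol_ind_h, 2 * d1$rate_pmol_ind_h)
  expect_equal(d2$rate_umol_gC_h, 2 * d1$rate_umol_gC_h)

  # unit identity: rate_ind / rate_gC = biomass per individual x 1e6
  expect_equal(d1$rate_pmol_ind_h / d1$rate_umol_gC_h, 1e-4 / 40 * 1e6)
  expect_error(normalize_rates(1, 0.5, 0, 1), "invalid chamber")
  expect_error(normalize_rates(1, 0.5, 10, 0), "invalid chamber")
})

test_that("control subtraction removes the control signal point-wise", {
  s <- data.frame(time_h = 0:4, conc_nM = 1 + 2 * (0:4))
  zero_ctrl <- data.frame(time_h = 0:4, conc_nM = rep(0, 5))
  expect_equal(control_correct(s, zero_ctrl)$conc_nM, s$conc_nM)
  expect_equal(control_correct(s, s)$conc_nM, rep(0, 5))

  # a control rising at 10% of the sample slope leaves 90% of the slope
  ctrl <- data.frame(time_h = 0:4, conc_nM = 0.2 * (0:4))
  corrected <- control_correct(s, ctrl)
  f <- fit_release_rate(corrected$time_h, corrected$conc_nM)
  expect_equal(f$slope_nM_h, 1.8)

  bad <- data.frame(time_h = 0:4, conc_nM = 1:5, analyte = "Gly")
  s$analyte <- "Tau"
  expect_error(control_correct(s, bad), "pairing")
})

test_that("taurine to DFAA ratio guards its domain", {
  expect_equal(tau_dfaa_ratio(1, c(2, 3, 5)), 0.1)
  expect_error(tau_dfaa_ratio(0, c(1, 2)), "undefined ratio")
  expect_error(tau_dfaa_ratio(1, numeric(0)), "undefined ratio")
})

test_that("group summaries reproduce the cruise means", {
  s <- summarize_rates(community_release_rates(), by = "cruise")
  goa <- s[s$cruise == "GoA", ]
  na <- s[s$cruise == "NA", ]
  expect_equal(goa$mean_pmol_ind_h, 425.1, tolerance = 1e-6)
  expect_equal(goa$sd_pmol_ind_h, 95.60528, tolerance = 1e-6)
  expect_equal(goa$mean_nmol_ind_d, 10.2024, tolerance = 1e-6)
  expect_equal(na$mean_pmol_ind_h, 24.43333, tolerance = 1e-6)
  expect_equal(na$sd_pmol_ind_h, 0.3055050, tolerance = 1e-6)
  expect_equal(na$mean_nmol_ind_d, 0.5864, tolerance = 1e-6)

  sp <- summarize_rates(species_release_rates(), by = "species")
  cen <- sp[sp$species == "Centropages sp.", ]
  expect_equal(cen$mean_umol_gC_h, 4 / 3, tolerance = 1e-6)
  expect_equal(cen$n, 3)
  expect_error(summarize_rates(community_release_rates(), by = "nonexistent"))
})

test_that("the chamber driver fits, QCs and normalises every analyte", {
  t <- c(0, 2, 4, 6, 8, 10, 12, 24)
  mk <- function(an, slope, plateau = 24) {
    data.frame(station = "X", replicate = "A", analyte = an, time_h = t,
               conc_nM = 1 + slope * pmin(t, plateau), is_control = FALSE)
  }
  inc <- rbind(
    mk("Tau", 2),
    mk("Gly", 1),
    transform(mk("Tau", 0.01), replicate = "ctl",
              is_control = TRUE)
  )
  chambers <- data.frame(station = "X", replicate = "A", volume_L = 0.5,
                         n_individuals = 50, total_biomass_gC = 0.017)
  out <- estimate_release_rates(inc, chambers)
  expect_equal(nrow(out), 2)
  expect_setequal(out$qc_status, "pass")
  tau <- out[out$analyte == "Tau", ]
  expect_equal(tau$slope_nM_h, 2, tolerance = 1e-12)
  expect_equal(tau$t_c_h, 24)
  expect_equal(tau$rate_pmol_ind_h, 2 * 0.5 / 50 * 1e3)
  expect_equal(tau$control_slope_nM_h, 0.01, tolerance = 1e-9)

  # a plateau in one analyte truncates the whole chamber
  inc2 <- rbind(mk("Tau", 2), mk("Gly", 1, plateau = 8))
  out2 <- estimate_release_rates(inc2, chambers)
  expect_equal(unique(out2$t_c_h), 8)

  # subtracting the control reduces the fitted slope accordingly
  out3 <- estimate_release_rates(inc, chambers, subtract_control = TRUE)
  expect_equal(out3$slope_nM_h[out3$analyte == "Tau"], 1.99, tolerance = 1e-9)
})
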