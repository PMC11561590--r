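test_that("osmometry chain handles the degenerate and linear cases", {
  rec0 <- osmometry_record(30, pi_cpa = 0.29, pi_pbs = 0.29, v_pbs = 0.01,
                           w1 = 0.2, w2 = 1.0, mw_cpa = 117.15,
                           rho_cpa = 1.19)
  out0 <- permeated_amount(rec0)
  expect_equal(out0$n_cpa, 0)
  expect_equal(out0$c_cpa, 0)

  rec1 <- osmometry_record(30, 0.39, 0.29, 0.01, 0.2, 1.0, 117.15, 1.19)
  rec2 <- osmometry_record(30, 0.39, 0.29, 0.02, 0.2, 1.0, 117.15, 1.19)
  expect_equal(permeated_amount(rec2)$n_cpa, 2 * permeated_amount(rec1)$n_cpa)

  # a physically impossible record is flagged
  bad <- osmometry_record(30, 10, 0.29, 0.1, 0.2, 0.3, 342.3, 1.5)
  expect_warning(outb <- permeated_amount(bad), "inconsistent")
  expect_false(outb$consistent)

  expect_error(osmometry_record(30, 0.2, 0.29, 0.01, 0.2, 1, 117, 1.19))
})

test_that("generate -> analyze round trip is algebraically exact", {
  sp <- permeation_spec(c_inf = 0.8, tau = 20, noise_sd = 0)
  gp <- gen_permeation(sp, seed = 3)
  ser <- permeation_series(gp$records)
  expect_equal(ser$c_cpa, gp$truth$concentrations, tolerance = 1e-10)

  # property: exact inversion for random positive parameter draws
  set.seed(11)
  for (i in 1:20) {
    spi <- permeation_spec(c_inf = runif(1, 0.05, 2), tau = runif(1, 5, 60),
                           noise_sd = 0, w2 = runif(1, 0.8, 2),
                           mw_cpa = runif(1, 60, 400),
                           rho_cpa = runif(1, 1.0, 1.6))
    gi <- gen_permeation(spi, seed = i)
    expect_equal(permeation_series(gi$records)$c_cpa,
                 gi$truth$concentrations, tolerance = 1e-10)
  }
})

test_that("equilibration time matches the first-order closed form", {
  tt <- seq(1, 180, by = 1)
  conc <- 0.8 * (1 - exp(-tt / 20))
  expect_equal(equilibration_time(tt, conc, 0.95), -20 * log(0.05),
               tolerance = 1)
  # constant series: first time point; fraction 1 on an increasing series:
  # last time point
  expect_equal(equilibration_time(tt, rep(0.5, length(tt))), 1)
  expect_equal(equilibration_time(tt, conc, 1.0), 180)
  expect_warning(equilibration_time(c(1, 2, 3, 4), c(1, 0.5, 1.4, 0.7)),
                 "tail")
})

test_that("DSC quantities recover generator ground truth", {
  sp <- dsc_spec(noise_sd = 0, nonfreezing = 0.30)
  gd <- gen_dsc(sp, seed = 1)
  q <- dsc_quantities(gd$thermogram)
  expect_equal(q$melting_enthalpy_j_g, gd$truth$melting_enthalpy_j_g,
               tolerance = 0.01)
  expect_equal(q$nonfreezing_water_fraction, 0.30, tolerance = 0.02)
  expect_lt(q$onset_freezing_point_c, q$peak_temperature_c)

  # flat trace: no detectable peak
  flat <- thermogram(seq(-30, 10, 0.1), rep(0, 401), 5, 0.85)
  expect_error(dsc_quantities(flat), "no detectable")
})

test_that("DSC enthalpy is invariant to the linear baseline", {
  sp <- dsc_spec(noise_sd = 0)
  g0 <- gen_dsc(sp, seed = 1)
  q0 <- dsc_quantities(g0$thermogram)
  for (ab in list(c(0.4, 0), c(0, 0.01), c(-0.2, -0.005))) {
    tg <- g0$thermogram
    tg$heat_flow <- tg$heat_flow + ab[1] + ab[2] * tg$temperature_c
    qi <- dsc_quantities(tg)
    expect_equal(qi$melting_enthalpy_j_g, q0$melting_enthalpy_j_g,
                 tolerance = 0.005)
  }
})

test_that("nonfreezing fraction is monotone nonincreasing in enthalpy", {
  nf <- vapply(c(0.0, 0.2, 0.4, 0.6), function(f) {
    g <- gen_dsc(dsc_spec(noise_sd = 0, nonfreezing = f), seed = 1)
    dsc_quantities(g$thermogram)$nonfreezing_water_fraction
  }, numeric(1))
  expect_true(all(diff(nf) > 0))   # higher withheld latent -> higher nf
})

test_that("nucleation detection hits generator truth on clean traces", {
  sp <- trace_spec(noise_sd = 0, initial_c = 15, nucleation_c = -7,
                   freezing_point_c = -2, cooling_rate = -1)
  gt <- gen_trace(sp, seed = 1)
  ev <- detect_nucleation(gt$trace$time, gt$trace$T_C, equilibrium_tf = -2)
  expect_true(ev$detected)
  expect_lte(abs(ev$time - gt$truth$nucleation_time_s), sp$sampling_s)
  expect_lt(abs(ev$supercooling_depth_k - gt$truth$supercooling_depth_k),
            0.05)
  expect_equal(ev$recalescence_amplitude_k,
               gt$truth$recalescence_amplitude_k, tolerance = 0.1)
  # plateau sits inside the generated plateau interval
  expect_gte(ev$plateau_start_s, gt$truth$plateau_start_s)
  expect_lte(ev$plateau_start_s, gt$truth$plateau_end_s)

  # monotone ramp: explicit no-event result
  ramp <- data.frame(time = 0:600, T_C = 15 - (0:600) / 60)
  ev0 <- detect_nucleation(ramp$time, ramp$T_C, equilibrium_tf = -2)
  expect_false(ev0$detected)
})

test_that("detection is invariant to time and temperature offsets", {
  sp <- trace_spec(noise_sd = 0.03)
  gt <- gen_trace(sp, seed = 9)
  ev <- detect_nucleation(gt$trace$time, gt$trace$T_C, equilibrium_tf = -2)
  ev_t <- detect_nucleation(gt$trace$time + 500, gt$trace$T_C,
                            equilibrium_tf = -2)
  expect_equal(ev_t$time - 500, ev$time)
  expect_equal(ev_t$supercooling_depth_k, ev$supercooling_depth_k)
  ev_T <- detect_nucleation(gt$trace$time, gt$trace$T_C + 3,
                            equilibrium_tf = -2 + 3)
  expect_equal(ev_T$time, ev$time)
  expect_equal(ev_T$supercooling_depth_k, ev$supercooling_depth_k,
               tolerance = 1e-9)
})

test_that("uniform sampling is required", {
  expect_error(detect_nucleation(c(0, 1, 2, 4, 5, 6, 7, 8, 9, 10, 11, 12),
                                 rnorm(12), -2),
               "uniform")
})
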