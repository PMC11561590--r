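test_that("scalar stress measures match their algebraic oracles", {
  # hydrostatic state has zero von Mises
  expect_equal(von_mises(c(5e6, 5e6, 5e6, 0)), 0)
  # uniaxial identity
  expect_equal(von_mises(c(-3e6, 0, 0, 0)), 3e6)
  expect_equal(max_principal(c(7e6, 0, 0, 0)), 7e6)

  # eigenvalue oracle on random symmetric tensors
  sig <- random_stress(50)
  for (r in seq_len(nrow(sig))) {
    S3 <- matrix(c(sig[r, 1], sig[r, 4], 0,
                   sig[r, 4], sig[r, 2], 0,
                   0, 0, sig[r, 3]), 3, 3)
    ev <- eigen(S3, symmetric = TRUE, only.values = TRUE)$values
    vm_oracle <- sqrt(0.5 * ((ev[1] - ev[2])^2 + (ev[2] - ev[3])^2 +
                               (ev[3] - ev[1])^2))
    expect_equal(von_mises(sig[r, , drop = FALSE]), vm_oracle,
                 tolerance = 1e-10)
    expect_equal(max_principal(sig[r, , drop = FALSE]), max(ev),
                 tolerance = 1e-10)
  }
})

test_that("zero thermal input leaves a stress-free state untouched", {
  g <- build_grid(8, 8, extent = c(0.008, 0.008), skin = NULL)
  msys <- mech_system(g, inert_material())
  mst <- mech_state(msys)
  mst2 <- update_stress(mst, msys, rep(0, g$n), rep(0, g$n), rep(1, g$n), 1)
  expect_equal(max(abs(mst2$sig)), 0)
  expect_equal(max(abs(mst2$u)), 0)
})

test_that("all-free supports are rejected as singular", {
  g <- build_grid(8, 8, skin = NULL)
  expect_error(mech_system(g, inert_material(),
                           mech_bc("free", "free", "free", "free")),
               "singular")
})

test_that("fully constrained uniform cooling gives the plane-strain closed form", {
  E <- 2e9; nu <- 0.3; al <- 5e-5; dT <- -10
  g <- build_grid(8, 8, extent = c(0.008, 0.008), skin = NULL)
  msys <- mech_system(g, inert_material(E = E, nu = nu, alpha = al),
                      mech_bc("roller", "roller", "roller", "roller"))
  mst <- update_stress(mech_state(msys), msys,
                       rep(dT, g$n), rep(0, g$n), rep(1, g$n), 1)
  cs <- cell_stress(mst)
  expected <- -E * al * dT / (1 - 2 * nu)
  expect_equal(unname(cs[, 1]), rep(expected, g$n), tolerance = 1e-10)
  expect_equal(unname(cs[, 2]), rep(expected, g$n), tolerance = 1e-10)
  expect_equal(unname(cs[, 3]), rep(expected, g$n), tolerance = 1e-10)
  expect_lt(max(abs(cs[, 4])), 1e-6 * abs(expected))
  # trace consistency with the isotropic compliance: the elastic volumetric
  # strain (zero here, full constraint) equals (1-2nu)/E tr(sigma) + 3 alpha dT
  expect_equal((1 - 2 * nu) / E * 3 * expected, -3 * al * dT,
               tolerance = 1e-12)
})

test_that("deviatoric stress relaxes as exp(-t/tau) with tau = 2 mu (1+nu)/E", {
  E <- 2e9; nu <- 0.3; mu <- 1e11
  tau <- 2 * mu * (1 + nu) / E
  g <- build_grid(8, 8, extent = c(0.008, 0.008), skin = NULL)
  msys <- mech_system(g, inert_material(E = E, nu = nu, mu = mu),
                      mech_bc("fixed", "fixed", "fixed", "fixed"))
  mst <- mech_state(msys)
  S0 <- 1e6
  for (gp in 1:4) { mst$sig[, 1, gp] <- S0; mst$sig[, 2, gp] <- -S0 }
  dt <- tau / 400
  for (i in seq_len(round(3 * tau / dt)))
    mst <- update_stress(mst, msys, rep(0, g$n), rep(0, g$n), rep(1, g$n), dt)
  cs <- cell_stress(mst)
  expect_equal(unname(cs[1, 1]) / S0, exp(-3), tolerance = 0.01)
  expect_equal(unname(cs[1, 2]) / S0, -exp(-3), tolerance = 0.01)
  # elastic limit: infinite viscosity preserves the stress exactly
  msys_el <- mech_system(g, inert_material(E = E, nu = nu, mu = Inf),
                         mech_bc("fixed", "fixed", "fixed", "fixed"))
  mst_el <- mech_state(msys_el)
  for (gp in 1:4) mst_el$sig[, 1, gp] <- S0
  mst_el <- update_stress(mst_el, msys_el, rep(0, g$n), rep(0, g$n),
                          rep(1, g$n), 1e6)
  expect_equal(unname(cell_stress(mst_el)[1, 1]), S0, tolerance = 1e-9)
})

test_that("equilibrium residual stays at solver precision on mixed phases", {
  g <- build_grid(12, 12, extent = c(0.012, 0.012),
                  skin = c(0.006, 0.002))
  mats <- default_materials()
  msys <- mech_system(g, mats)
  mst <- mech_state(msys)
  set.seed(7)
  th2 <- rep(1, g$n)
  for (i in 1:5) {
    dth <- -pmin(th2, runif(g$n, 0, 0.3) * exp(-((g$xc_all^2 + g$yc_all^2)) / 5e-5))
    th2 <- th2 + dth
    mst <- update_stress(mst, msys, rep(-2, g$n), dth, th2, 1)
    smax <- max(abs(mst$sig))
    expect_lt(equilibrium_residual(mst, msys),
              1e-6 * smax * g$dx * g$thickness)
  }
  # deviatoric part is traceless
  cs <- cell_stress(mst)
  pm <- (cs[, 1] + cs[, 2] + cs[, 3]) / 3
  dev_tr <- (cs[, 1] - pm) + (cs[, 2] - pm) + (cs[, 3] - pm)
  expect_lt(max(abs(dev_tr)), 1e-6 * max(abs(cs)))
})

test_that("viscoelastic step reduces to thermoelasticity as mu -> Inf", {
  g <- build_grid(10, 10, skin = c(0.01, 0.004))
  dT <- rep(-5, g$n)
  run_once <- function(mu) {
    m <- inert_material(mu = mu)
    msys <- mech_system(g, m)
    update_stress(mech_state(msys), msys, dT, rep(0, g$n), rep(1, g$n),
                  dt = 1e-3)
  }
  cs_big <- cell_stress(run_once(1e20))
  cs_inf <- cell_stress(run_once(Inf))
  expect_equal(cs_big, cs_inf, tolerance = 1e-8)
})

test_that("peak_stress recovers injected spikes with the stated tie rules", {
  g <- build_grid(8, 8, skin = NULL)
  zero <- matrix(0, g$n, 4)
  hist0 <- list(list(time = 0, sig = zero), list(time = 5, sig = zero))
  p0 <- peak_stress(hist0, g, region = "all")
  expect_equal(p0$value, 0)
  expect_equal(p0$time, 0)
  expect_equal(p0$cell, 1L)

  spike <- zero; spike[37, 1] <- 4e6
  hist1 <- list(list(time = 0, sig = zero), list(time = 5, sig = spike),
                list(time = 10, sig = zero))
  p1 <- peak_stress(hist1, g, region = "all")
  expect_equal(p1$value, 4e6)
  expect_equal(p1$time, 5)
  expect_equal(p1$cell, 37L)

  # equal maxima at two times: earlier wins
  hist2 <- list(list(time = 1, sig = spike), list(time = 2, sig = spike))
  expect_equal(peak_stress(hist2, g, region = "all")$time, 1)
  expect_error(peak_stress(hist2, g, region = "nowhere"), "unknown region")
})

test_that("stress profiles reproduce manufactured fields", {
  g <- build_grid(20, 20)
  sig <- matrix(0, g$n, 4)
  sig[, 1] <- 1e6 * g$xc_all                     # linear sigma_xx in x
  pr <- stress_profile(sig, g, axis = "x", measure = "xx")
  expect_equal(pr$value, 1e6 * g$x, tolerance = 1e-12)
  expect_equal(pr$position, g$x)
  # zero state: all-zero profile; symmetric loading: symmetric profile
  pr0 <- stress_profile(matrix(0, g$n, 4), g, axis = "y")
  expect_true(all(pr0$value == 0))
  sig2 <- matrix(0, g$n, 4)
  sig2[, 1] <- 1e6 * abs(g$xc_all)
  v <- stress_profile(sig2, g, axis = "x", measure = "xx")$value
  expect_equal(v, rev(v), tolerance = 1e-9)
})
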