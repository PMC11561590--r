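test_that("phase fraction is a C1 monotone step with the stated limits", {
  mat <- water_like()
  Tm <- mat$melt_temperature; d <- mat$transition_half_width

  expect_equal(phase_fraction(Tm - 10 * d, mat), 0)
  expect_equal(phase_fraction(Tm + 10 * d, mat), 1)
  expect_equal(phase_fraction(Tm, mat), 0.5)

  Ts <- seq(Tm - 5 * d, Tm + 5 * d, length.out = 2001)
  th2 <- phase_fraction(Ts, mat)
  expect_false(is.unsorted(th2))
  expect_true(all(th2 >= 0 & th2 <= 1))

  # quadrature oracle: theta2 equals the integral of its analytic derivative
  for (Tq in c(Tm - 0.3, Tm, Tm + 0.41)) {
    q <- integrate(function(x) phase_fraction_deriv(x, mat),
                   Tm - 5 * d, Tq, rel.tol = 1e-12)$value
    expect_equal(q, phase_fraction(Tq, mat), tolerance = 1e-8)
  }
})

test_that("mixture rules reproduce pure phases and bound all properties", {
  mat <- water_like()
  m0 <- mixture_properties(0, mat)
  expect_equal(m0$rho, mat$phase1$density)
  expect_equal(m0$k, mat$phase1$conductivity)
  expect_equal(m0$cp_sensible, mat$phase1$heat_capacity)
  expect_equal(m0$alpha_m, -0.5)
  m1 <- mixture_properties(1, mat)
  expect_equal(m1$rho, mat$phase2$density)
  expect_equal(m1$alpha_m, 0.5)

  # equal densities cancel alpha_m at the midpoint
  sym <- water_like(rho_ice = 1000, rho_liq = 1000)
  expect_equal(mixture_properties(0.5, sym)$alpha_m, 0)

  expect_error(mixture_properties(1.2, mat), "0, 1")
  expect_error(mixture_properties(0.4, mat, theta1 = 0.4), "equal 1")

  th <- seq(0, 1, by = 0.01)
  mm <- mixture_properties(th, mat)
  for (f in c("rho", "k", "cp_sensible")) {
    expect_true(all(mm[[f]] >= min(mm[[f]][1], mm[[f]][101]) - 1e-9))
    expect_true(all(mm[[f]] <= max(mm[[f]][1], mm[[f]][101]) + 1e-9))
  }
  expect_true(all(mm$theta1 + mm$theta2 == 1))
  expect_true(all(diff(mm$alpha_m) > 0))
  expect_true(all(mm$alpha_m >= -0.5 & mm$alpha_m <= 0.5))
})

test_that("apparent heat capacity carries exactly the latent heat", {
  mat <- water_like()
  Tm <- mat$melt_temperature; d <- mat$transition_half_width

  # no latent heat: equals the sensible mixture everywhere
  m0 <- water_like(latent = 0)
  Ts <- seq(Tm - 3, Tm + 3, by = 0.05)
  sens <- vapply(Ts, function(t)
    mixture_properties(phase_fraction(t, m0), m0)$cp_sensible, numeric(1))
  expect_equal(apparent_heat_capacity(Ts, m0), sens, tolerance = 1e-12)

  # far above the window: pure liquid value
  expect_equal(apparent_heat_capacity(Tm + 50, mat),
               mat$phase2$heat_capacity)

  # quadrature oracle: integral of rho * C_eff = sensible + rho_bar * L
  lo <- Tm - 10 * d; hi <- Tm + 10 * d
  rho_cp <- function(t) {
    th <- phase_fraction(t, mat)
    mixture_properties(th, mat)$rho * apparent_heat_capacity(t, mat)
  }
  total <- integrate(function(x) vapply(x, rho_cp, numeric(1)), lo, hi,
                     rel.tol = 1e-10, subdivisions = 500L)$value
  sens_i <- integrate(function(x) vapply(x, function(t) {
    m <- mixture_properties(phase_fraction(t, mat), mat)
    m$rho * m$cp_sensible
  }, numeric(1)), lo, hi, rel.tol = 1e-10, subdivisions = 500L)$value
  rho_bar <- mean(c(mat$phase1$density, mat$phase2$density))
  expect_equal(total - sens_i, rho_bar * mat$latent_heat,
               tolerance = 0.005)

  # closed-form enthalpy agrees with the quadrature oracle
  expect_equal(volumetric_enthalpy(hi, mat) - volumetric_enthalpy(lo, mat),
               total, tolerance = 1e-7)
})

test_that("phase-change eigenstrain follows the density contrast", {
  mat <- water_like(rho_ice = 1000, rho_liq = 1000)
  expect_equal(phase_change_eigenstrain(c(0, 0.3, 1), mat), c(0, 0, 0))
  mat2 <- water_like()
  expect_equal(phase_change_eigenstrain(0, mat2), 0)
  expect_equal(phase_change_eigenstrain(1, mat2), (917 / 1000)^(1 / 3) - 1)
})

test_that("material presets honour formulation chemistry", {
  for (nm in c("none", "betaine", "BT-1", "BT-2", "BT-3", "trehalose",
               "glycerol", "DMSO")) {
    m <- solution_material(nm)
    expect_s3_class(m, "phase_change_material")
    expect_true(m$melt_temperature < celsius_to_kelvin(0))
    expect_true(m$latent_heat > 0 && m$latent_heat <= .L_WATER)
  }
  # stronger colligative depression for smaller molar mass at equal wt%
  expect_lt(solution_material("DMSO")$melt_temperature,
            solution_material("trehalose")$melt_temperature)
  # BT lowers the frozen skin's expansion coefficient by 40%
  expect_equal(skin_material("BT-2")$phase1$expansion /
                 skin_material("none")$phase1$expansion, 0.6)
  expect_error(cpa_preset("unobtainium"), "unknown")
})

test_that("material config files override preset fields", {
  cfg <- system.file("extdata", "materials_example.cfg", package = "cryoskin")
  mats <- read_material_config(cfg)
  expect_equal(mats$solution$phase1$density, 960)
  expect_equal(mats$solution$melt_temperature, celsius_to_kelvin(-2))
  expect_equal(mats$solution$latent_heat, 207000)
  expect_equal(mats$skin$phase2$young_modulus, 5e5)
  # untouched fields keep their defaults
  expect_equal(mats$skin$phase1$density,
               default_materials()$skin$phase1$density)
})
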