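# shared fixtures: small inert materials and grids used across test files

# single-phase-like material with no latent heat (transition far from use)
inert_material <- function(E = 1e9, nu = 0.3, alpha = 5e-5, mu = Inf,
                           rho = 1000, cp = 2000, k = 2) {
  p <- phase_properties(rho, cp, k, E, nu, alpha, mu)
  phase_change_material(p, p, melt_temperature = 150,
                        transition_half_width = 0.5, latent_heat = 0)
}

# water-like two-phase material with configurable transition sharpness
water_like <- function(dtr = 0.5, latent = 334e3, rho_ice = 917,
                       rho_liq = 1000) {
  ice <- phase_properties(rho_ice, 2050, 2.25, 9e9, 0.33, 5.1e-5, 1e13)
  liq <- phase_properties(rho_liq, 4180, 0.56, 1e5, 0.45, 2e-4, 1e3)
  phase_change_material(ice, liq, 273.15, dtr, latent)
}

# random symmetric stress tensors as component rows (xx, yy, zz, xy)
random_stress <- function(n, seed = 42) {
  set.seed(seed)
  matrix(stats::rnorm(4 * n, sd = 1e6), n, 4)
}
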