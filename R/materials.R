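#' Per-phase thermophysical and mechanical constants
#'
#' A single phase (frozen or liquid) of a phase-change material. Units are
#' strict SI: `density` kg/m^3, `heat_capacity` J/(kg K), `conductivity`
#' W/(m K), `young_modulus` Pa, `poisson` dimensionless, `expansion` 1/K
#' (linear), `maxwell_viscosity` Pa s (`Inf` for a purely elastic phase).
#'
#' @param density,heat_capacity,conductivity,young_modulus positive scalars
#' @param poisson in `[0, 0.5)`
#' @param expansion finite scalar
#' @param maxwell_viscosity positive scalar or `Inf`
#' @return object of class `phase_properties`
#' @export
phase_properties <- function(density, heat_capacity, conductivity,
                             young_modulus, poisson, expansion,
                             maxwell_viscosity = Inf) {
  stopifnot(density > 0, heat_capacity > 0, conductivity > 0,
            young_modulus > 0, poisson >= 0, poisson < 0.5,
            is.finite(expansion), maxwell_viscosity > 0)
  structure(list(density = density, heat_capacity = heat_capacity,
                 conductivity = conductivity, young_modulus = young_modulus,
                 poisson = poisson, expansion = expansion,
                 maxwell_viscosity = maxwell_viscosity),
            class = "phase_properties")
}

#' Two-phase material with a smoothed solid/liquid transition
#'
#' Phase 1 is the low-temperature (frozen) phase, phase 2 the
#' high-temperature (liquid) phase; the liquid fraction
#' \eqn{\theta_2(T)} rises smoothly from 0 to 1 across
#' `melt_temperature` +/- `transition_half_width`.  `latent_heat` is the heat
#' of fusion absorbed on melting (J/kg).
#'
#' @param phase1,phase2 [phase_properties()] objects (frozen, liquid)
#' @param melt_temperature K
#' @param transition_half_width K, > 0 (default 0.5)
#' @param latent_heat J/kg, >= 0
#' @param name optional label used in reports
#' @return object of class `phase_change_material`
#' @export
phase_change_material <- function(phase1, phase2, melt_temperature,
                                  transition_half_width = 0.5,
                                  latent_heat, name = "material") {
  stopifnot(inherits(phase1, "phase_properties"),
            inherits(phase2, "phase_properties"),
            is.finite(melt_temperature),
            transition_half_width > 0, latent_heat >= 0)
  structure(list(phase1 = phase1, phase2 = phase2,
                 melt_temperature = melt_temperature,
                 transition_half_width = transition_half_width,
                 latent_heat = latent_heat, name = name),
            class = "phase_change_material")
}

#' @export
print.phase_change_material <- function(x, ...) {
  cat(sprintf("<phase_change_material '%s'> T_m = %.2f K (%.2f degC), dT_tr = %.2f K, L = %.3g J/kg\n",
              x$name, x$melt_temperature, kelvin_to_celsius(x$melt_temperature),
              x$transition_half_width, x$latent_heat))
  invisible(x)
}

#' Liquid-phase fraction of a phase-change material
#'
#' C1 smoothstep profile: \eqn{\theta_2 = x^2 (3 - 2x)} with
#' \eqn{x = (T - T_m + \Delta T_{tr}) / (2 \Delta T_{tr})} clamped to
#' `[0, 1]`.  Monotone nondecreasing, 0 below the transition window, 1 above
#' it, and exactly 1/2 at `T = T_m`.
#'
#' @param temperature K (vectorised)
#' @param mat a [phase_change_material()]
#' @return liquid fraction \eqn{\theta_2} in `[0, 1]`
#' @export
phase_fraction <- function(temperature, mat) {
  stopifnot(all(is.finite(temperature)))
  d <- mat$transition_half_width
  x <- (temperature - mat$melt_temperature + d) / (2 * d)
  x <- pmin(pmax(x, 0), 1)
  x * x * (3 - 2 * x)
}

#' @rdname phase_fraction
#' @details `phase_fraction_deriv()` is the analytic derivative
#'   \eqn{d\theta_2/dT}, used by the latent term of the apparent heat
#'   capacity.
#' @export
phase_fraction_deriv <- function(temperature, mat) {
  d <- mat$transition_half_width
  x <- (temperature - mat$melt_temperature + d) / (2 * d)
  inside <- x > 0 & x < 1
  out <- numeric(length(x))
  out[inside] <- 6 * x[inside] * (1 - x[inside]) / (2 * d)
  out
}

# bounded mass-fraction function alpha_m(theta2) in [-1/2, 1/2]
alpha_m_of_theta <- function(theta2, rho1, rho2) {
  theta1 <- 1 - theta2
  0.5 * (theta2 * rho2 - theta1 * rho1) / (theta1 * rho1 + theta2 * rho2)
}

# d alpha_m / d theta2 = rho1 rho2 / (theta1 rho1 + theta2 rho2)^2
alpha_m_dtheta <- function(theta2, rho1, rho2) {
  mix <- rho1 + (rho2 - rho1) * theta2
  rho1 * rho2 / mix^2
}

#' Effective mixture properties at given phase fractions
#'
#' Mixture closure of the smoothed two-phase model: density and conductivity
#' are phase-fraction weighted sums, the sensible heat capacity is the
#' mass-weighted mean \eqn{(\theta_1\rho_1 C_1 + \theta_2\rho_2 C_2)/\rho},
#' and `alpha_m` is the bounded mass-fraction function whose temperature
#' derivative carries the latent heat.  Mechanical constants (E, nu, alpha,
#' mu) interpolate linearly in \eqn{\theta_2}.
#'
#' @param theta1,theta2 phase fractions; must sum to 1 (vectorised).
#'   `theta1` defaults to `1 - theta2`.
#' @param mat a [phase_change_material()]
#' @return list of class `mixture_state` with fields `theta1`, `theta2`,
#'   `rho`, `k`, `cp_sensible`, `alpha_m`, `young_modulus`, `poisson`,
#'   `expansion`, `maxwell_viscosity`
#' @export
mixture_properties <- function(theta2, mat, theta1 = 1 - theta2) {
  if (any(theta2 < 0 | theta2 > 1 | theta1 < 0 | theta1 > 1))
    stop("phase fractions must lie in [0, 1]")
  if (any(abs(theta1 + theta2 - 1) > 1e-12))
    stop("theta1 + theta2 must equal 1")
  p1 <- mat$phase1; p2 <- mat$phase2
  rho <- theta1 * p1$density + theta2 * p2$density
  k   <- theta1 * p1$conductivity + theta2 * p2$conductivity
  cps <- (theta1 * p1$density * p1$heat_capacity +
          theta2 * p2$density * p2$heat_capacity) / rho
  lin <- function(f) theta1 * p1[[f]] + theta2 * p2[[f]]
  structure(list(
    theta1 = theta1, theta2 = theta2, rho = rho, k = k,
    cp_sensible = cps,
    alpha_m = alpha_m_of_theta(theta2, p1$density, p2$density),
    young_modulus = lin("young_modulus"),
    poisson = lin("poisson"),
    expansion = lin("expansion"),
    maxwell_viscosity = lin("maxwell_viscosity")
  ), class = "mixture_state")
}

#' Apparent heat capacity with latent-heat spike
#'
#' Sensible mixture heat capacity plus the latent term
#' \eqn{L_{1\to2}\,\partial\alpha_m/\partial T} evaluated analytically
#' through the smoothed \eqn{\theta_2(T)}.  The latent contribution has
#' compact support on the transition window, so integrating
#' \eqn{\rho\,C_P} across the window recovers sensible + latent heat.
#'
#' @inheritParams phase_fraction
#' @return effective heat capacity, J/(kg K) (vectorised)
#' @export
apparent_heat_capacity <- function(temperature, mat) {
  th2 <- phase_fraction(temperature, mat)
  mix <- mixture_properties(th2, mat)
  dam_dT <- alpha_m_dtheta(th2, mat$phase1$density, mat$phase2$density) *
    phase_fraction_deriv(temperature, mat)
  mix$cp_sensible + mat$latent_heat * dam_dT
}

#' Volumetric enthalpy of the smoothed two-phase mixture
#'
#' Closed-form integral \eqn{H_v(T)=\int \rho C_{P,\mathrm{eff}}\,dT}
#' (J/m^3) measured from `reference` (default: 20 half-widths below the melt
#' point).  Used by the conservative chord linearisation of the thermal
#' solver and by the energy ledger.
#'
#' @inheritParams phase_fraction
#' @param reference K, temperature at which the enthalpy is zero
#' @return volumetric enthalpy J/m^3 (vectorised)
#' @export
volumetric_enthalpy <- function(temperature, mat,
                                reference = mat$melt_temperature -
                                  20 * mat$transition_half_width) {
  p1 <- mat$phase1; p2 <- mat$phase2
  d <- mat$transition_half_width
  a <- mat$melt_temperature - d
  # integral of theta2 from `reference` (below window) up to T
  x <- pmin(pmax((temperature - a) / (2 * d), 0), 1)
  i2 <- 2 * d * (x^3 - x^4 / 2) + pmax(temperature - (a + 2 * d), 0)
  th2 <- phase_fraction(temperature, mat)
  # latent: integral of rho * L * d(alpha_m)/dT; rho*dalpha_m/dtheta
  # = rho1 rho2 / (rho1 + (rho2-rho1) theta2), integrable in closed form
  if (abs(p2$density - p1$density) < 1e-9) {
    lat <- mat$latent_heat * p1$density * th2
  } else {
    b <- p2$density - p1$density
    lat <- mat$latent_heat * p1$density * p2$density / b *
      log((p1$density + b * th2) / p1$density)
  }
  rc1 <- p1$density * p1$heat_capacity
  rc2 <- p2$density * p2$heat_capacity
  rc1 * (temperature - reference) + (rc2 - rc1) * i2 + lat
}

#' Phase-change volumetric eigenstrain (linear measure)
#'
#' Converts the density contrast between the frozen and liquid phases into a
#' linear mechanical strain, \eqn{\theta_2\,[(\rho_1/\rho_2)^{1/3} - 1]}.
#' Only increments of this quantity enter the stress update, so the
#' reference offset at the initial state is immaterial.  With
#' \eqn{\rho_1 < \rho_2} (ice lighter than water) the strain decreases on
#' melting: freezing expands, melting contracts.
#'
#' @param theta2 liquid fraction in `[0, 1]` (vectorised)
#' @param mat a [phase_change_material()]
#' @return linear eigenstrain, dimensionless
#' @export
phase_change_eigenstrain <- function(theta2, mat) {
  stopifnot(all(theta2 >= -1e-12 & theta2 <= 1 + 1e-12))
  theta2 * ((mat$phase1$density / mat$phase2$density)^(1 / 3) - 1)
}
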