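#' Neumann two-phase Stefan closed form
#'
#' Analytical similarity solution for 1D freezing of a half-space: wall held
#' at `t_wall` (below the melt point), liquid initially at `t_init` (at or
#' above it), equal phase densities.  The freezing front sits at
#' \eqn{X(t) = 2\lambda\sqrt{\alpha_s t}} with \eqn{\lambda} solving the
#' transcendental Stefan condition.  Used as the independent oracle for the
#' phase-change solver.
#'
#' @param t_wall,t_melt,t_init temperatures, K
#' @param k_s,k_l conductivities W/(m K) of solid and liquid
#' @param c_s,c_l heat capacities J/(kg K)
#' @param rho density kg/m^3 (common to both phases)
#' @param latent_heat J/kg
#' @return list with `lambda`, `front(t)` (front position in m), and
#'   `temperature(x, t)` (K)
#' @export
neumann_stefan <- function(t_wall, t_melt, t_init, k_s, k_l, c_s, c_l,
                           rho, latent_heat) {
  stopifnot(t_wall < t_melt, t_init >= t_melt)
  a_s <- k_s / (rho * c_s)
  a_l <- k_l / (rho * c_l)
  nu <- sqrt(a_s / a_l)
  erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1
  erfc <- function(x) 2 * stats::pnorm(-x * sqrt(2))
  f <- function(lam) {
    k_s * (t_melt - t_wall) * exp(-lam^2) / (erf(lam) * sqrt(pi * a_s)) -
      k_l * (t_init - t_melt) * exp(-lam^2 * nu^2) /
        (erfc(lam * nu) * sqrt(pi * a_l)) -
      rho * latent_heat * lam * sqrt(a_s)
  }
  lam <- stats::uniroot(f, c(1e-8, 5), tol = 1e-12)$root
  front <- function(t) 2 * lam * sqrt(a_s * t)
  temperature <- function(x, t) {
    X <- front(t)
    eta_s <- x / (2 * sqrt(a_s * t))
    eta_l <- x / (2 * sqrt(a_l * t))
    ifelse(x <= X,
           t_wall + (t_melt - t_wall) * erf(eta_s) / erf(lam),
           t_init - (t_init - t_melt) * erfc(eta_l) / erfc(lam * nu))
  }
  list(lambda = lam, front = front, temperature = temperature)
}
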