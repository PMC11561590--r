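#' Seeded per-stream RNG for the synthetic-data generators
#'
#' One global seed expands into independent per-stream seeds by a fixed
#' counter scheme, `(seed * 1000003 + 7919 * stream) mod (2^31 - 1)`, so
#' adding a new generator stream never perturbs existing ones.  Streams:
#' trace = 1, dsc = 2, permeation = 3 (offset by a caller-supplied replicate
#' counter).  Generators save and restore the caller's RNG state.
#'
#' @param seed integer global seed
#' @param stream integer stream id
#' @return integer seed for `set.seed()`
#' @export
stream_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 1000003 + 7919 * as.numeric(stream)) %%
               2147483647)
}

with_stream_seed <- function(seed, stream, expr) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  }
  set.seed(stream_seed(seed, stream))
  expr
}

#' Specification of a synthetic thermocouple trace
#'
#' The stated world of the generator: imposed cooling at `cooling_rate` from
#' `initial_c` until the supercooled liquid nucleates at `nucleation_c`
#' (below the equilibrium freezing point `freezing_point_c`), exponential
#' recalescence with time constant `rise_time_s` toward the freezing plateau
#' (capped at `amplitude_cap_k` above the nucleation temperature), a plateau
#' of `plateau_duration_s`, then resumed cooling at `post_plateau_rate`,
#' with additive Gaussian noise.
#'
#' @param cooling_rate K/min (negative)
#' @param initial_c degC
#' @param freezing_point_c equilibrium freezing point, degC
#' @param nucleation_c nucleation temperature, degC (below freezing point)
#' @param rise_time_s recalescence time constant, s
#' @param amplitude_cap_k max recalescence rise, K
#' @param plateau_duration_s s
#' @param post_plateau_rate K/min (negative)
#' @param noise_sd K (>= 0)
#' @param sampling_s sampling interval, s
#' @param duration_s total trace duration, s
#' @return list of class `trace_spec`
#' @export
trace_spec <- function(cooling_rate = -1, initial_c = 20,
                       freezing_point_c = -2, nucleation_c = -8,
                       rise_time_s = 5, amplitude_cap_k = Inf,
                       plateau_duration_s = 250, post_plateau_rate = -1,
                       noise_sd = 0.05, sampling_s = 1, duration_s = 3000) {
  stopifnot(cooling_rate < 0, nucleation_c < freezing_point_c,
            noise_sd >= 0, sampling_s > 0, rise_time_s > 0,
            plateau_duration_s > 0, post_plateau_rate < 0)
  structure(as.list(environment()), class = "trace_spec")
}

#' Generate a thermocouple trace with a nucleation event
#'
#' @param spec a [trace_spec()]
#' @param seed global seed
#' @param stream_offset replicate counter added to the trace stream id
#' @return list with `trace` (data.frame `time`, `T_C`) and `truth` (exact
#'   event parameters used)
#' @export
gen_trace <- function(spec, seed = 1, stream_offset = 0) {
  stopifnot(inherits(spec, "trace_spec"))
  r <- -spec$cooling_rate / 60                      # K/s, positive
  t_nuc <- (spec$initial_c - spec$nucleation_c) / r
  plateau_level <- min(spec$freezing_point_c,
                       spec$nucleation_c + spec$amplitude_cap_k)
  t_end_plateau <- t_nuc + spec$plateau_duration_s
  rp <- -spec$post_plateau_rate / 60
  tt <- seq(0, spec$duration_s, by = spec$sampling_s)
  model <- ifelse(tt <= t_nuc,
                  spec$initial_c - r * tt,
           ifelse(tt <= t_end_plateau,
                  plateau_level - (plateau_level - spec$nucleation_c) *
                    exp(-(tt - t_nuc) / spec$rise_time_s),
                  plateau_level - (plateau_level - spec$nucleation_c) *
                    exp(-spec$plateau_duration_s / spec$rise_time_s) -
                    rp * (tt - t_end_plateau)))
  noise <- with_stream_seed(seed, 1 + stream_offset,
                            stats::rnorm(length(tt), 0, spec$noise_sd))
  list(trace = data.frame(time = tt, T_C = model + noise),
       truth = list(nucleation_time_s = t_nuc,
                    nucleation_temperature_c = spec$nucleation_c,
                    supercooling_depth_k = spec$freezing_point_c - spec$nucleation_c,
                    recalescence_amplitude_k = plateau_level - spec$nucleation_c,
                    plateau_start_s = t_nuc,
                    plateau_end_s = t_end_plateau,
                    model = model))
}

#' Specification of a synthetic DSC thermogram
#'
#' Gaussian melting endotherm on a sloping linear baseline.  The peak area
#' encodes the melting enthalpy of the freezable water:
#' \eqn{\Delta H_m = (1 - f_{nf})\, w \, L}, i.e. the generator withholds the
#' nonfreezing fraction `nonfreezing` of the water's latent heat.
#'
#' @param freezing_point_c degC (peak onset region)
#' @param water_mass_fraction in `[0, 1]`
#' @param nonfreezing nonfreezing water fraction in `[0, 1]`
#' @param latent_heat J/g
#' @param peak_width_k Gaussian sigma, K
#' @param baseline_slope W/g per K
#' @param baseline_intercept W/g
#' @param noise_sd W/g
#' @param scan_rate K/min
#' @param t_min_c,t_max_c,step_k scan range and sampling
#' @return list of class `dsc_spec`
#' @export
dsc_spec <- function(freezing_point_c = -2, water_mass_fraction = 0.85,
                     nonfreezing = 0.27, latent_heat = .L_WATER / 1000,
                     peak_width_k = 1.5, baseline_slope = 2e-4,
                     baseline_intercept = 0.05, noise_sd = 5e-4,
                     scan_rate = 5, t_min_c = -30, t_max_c = 15,
                     step_k = 0.05) {
  stopifnot(water_mass_fraction >= 0, water_mass_fraction <= 1,
            nonfreezing >= 0, nonfreezing <= 1, peak_width_k > 0,
            noise_sd >= 0, scan_rate > 0, t_max_c > t_min_c)
  structure(as.list(environment()), class = "dsc_spec")
}

#' Generate a DSC thermogram with known ground truth
#'
#' @param spec a [dsc_spec()]
#' @param seed global seed
#' @param stream_offset replicate counter added to the dsc stream id
#' @return list with `thermogram` (a [thermogram()]) and `truth`
#' @export
gen_dsc <- function(spec, seed = 1, stream_offset = 0) {
  stopifnot(inherits(spec, "dsc_spec"))
  temp <- seq(spec$t_min_c, spec$t_max_c, by = spec$step_k)
  enthalpy <- (1 - spec$nonfreezing) * spec$water_mass_fraction *
    spec$latent_heat                                   # J/g
  beta <- spec$scan_rate / 60                          # K/s
  center <- spec$freezing_point_c + 2 * spec$peak_width_k
  peak <- enthalpy * beta * stats::dnorm(temp, center, spec$peak_width_k)
  base <- spec$baseline_intercept + spec$baseline_slope * temp
  noise <- with_stream_seed(seed, 2 + stream_offset,
                            stats::rnorm(length(temp), 0, spec$noise_sd))
  list(thermogram = thermogram(temp, base + peak + noise, spec$scan_rate,
                               spec$water_mass_fraction),
       truth = list(melting_enthalpy_j_g = enthalpy,
                    nonfreezing_water_fraction = spec$nonfreezing,
                    peak_center_c = center,
                    baseline = c(spec$baseline_intercept, spec$baseline_slope)))
}

#' Specification of a synthetic CPA-uptake osmometry series
#'
#' First-order uptake \eqn{C(t) = C_\infty (1 - e^{-t/\tau})}; each sampled
#' concentration is inverted exactly through the osmometry chain to the
#' osmolality a freezing-point osmometer would read, to which Gaussian noise
#' is added.
#'
#' @param c_inf equilibrium intratissue concentration, mol/L
#' @param tau uptake time constant, min
#' @param times sampling times, min, increasing
#' @param noise_sd osmolality noise, osmol/kg
#' @param v_pbs,w1,w2,mw_cpa,rho_cpa,rho_w,rho constants of the record, see
#'   [osmometry_record()]
#' @param pi_pbs blank PBS osmolality, osmol/kg
#' @return list of class `permeation_spec`
#' @export
permeation_spec <- function(c_inf = 0.8, tau = 20,
                            times = c(1, 2, 5, 10, 15, 20, 30, 45, 60, 90,
                                      120, 180),
                            noise_sd = 0.002, v_pbs = 0.01, w1 = 0.2,
                            w2 = 1.0, mw_cpa = 117.15, rho_cpa = 1.19,
                            rho_w = 1.0, rho = 1.0, pi_pbs = 0.29) {
  stopifnot(tau > 0, !is.unsorted(times, strictly = TRUE), c_inf >= 0,
            noise_sd >= 0, w2 > w1, w1 > 0)
  structure(as.list(environment()), class = "permeation_spec")
}

# exact inversion of the osmometry chain: moles giving concentration C
moles_for_concentration <- function(c_cpa, sp) {
  # n = C/1000 * [ (W2-W1)/rho + n*MW*(1/rho_cpa - 1/rho) ]
  a <- c_cpa / 1000 * (sp$w2 - sp$w1) / sp$rho
  b <- c_cpa / 1000 * sp$mw_cpa * (1 / sp$rho_cpa - 1 / sp$rho)
  a / (1 - b)
}

#' Generate an osmometry series from first-order CPA uptake
#'
#' @param spec a [permeation_spec()]
#' @param seed global seed
#' @param stream_offset replicate counter added to the permeation stream id
#' @return list with `records` (list of [osmometry_record()]s) and `truth`
#'   (`c_inf`, `tau`, and the exact noiseless concentrations)
#' @export
gen_permeation <- function(spec, seed = 1, stream_offset = 0) {
  stopifnot(inherits(spec, "permeation_spec"))
  conc <- spec$c_inf * (1 - exp(-spec$times / spec$tau))
  n <- vapply(conc, moles_for_concentration, numeric(1), sp = spec)
  pi_cpa <- spec$pi_pbs + n / (spec$v_pbs * spec$rho_w)
  noise <- with_stream_seed(seed, 3 + stream_offset,
                            stats::rnorm(length(pi_cpa), 0, spec$noise_sd))
  pi_obs <- pmax(pi_cpa + noise, spec$pi_pbs)
  records <- mapply(function(tm, p) {
    osmometry_record(immersion_time = tm, pi_cpa = p, pi_pbs = spec$pi_pbs,
                     v_pbs = spec$v_pbs, w1 = spec$w1, w2 = spec$w2,
                     mw_cpa = spec$mw_cpa, rho_cpa = spec$rho_cpa,
                     rho_w = spec$rho_w, rho = spec$rho)
  }, spec$times, pi_obs, SIMPLIFY = FALSE)
  list(records = records,
       truth = list(c_inf = spec$c_inf, tau = spec$tau,
                    concentrations = conc))
}
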