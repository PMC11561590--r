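#' Osmometry record for CPA permeation analysis
#'
#' One equilibration measurement: skin immersed in CPA for `immersion_time`
#' minutes, then transferred to PBS until osmotic equilibrium.  Unit
#' conventions are fixed here once: osmolality in osmol/kg, `v_pbs` in L,
#' weights in g, densities in g/mL, molar mass in g/mol.
#'
#' @param immersion_time min
#' @param pi_cpa measured osmolality after equilibration, osmol/kg
#' @param pi_pbs blank PBS osmolality, osmol/kg
#' @param v_pbs PBS volume, L
#' @param w1,w2 skin dry / moist weight, g
#' @param mw_cpa CPA molar mass, g/mol
#' @param rho_cpa CPA density at 4 degC, g/mL
#' @param rho_w water density at 4 degC, g/mL
#' @param rho density of the intratissue aqueous solution (the concentration
#'   denominator), g/mL
#' @return object of class `osmometry_record`
#' @export
osmometry_record <- function(immersion_time, pi_cpa, pi_pbs, v_pbs,
                             w1, w2, mw_cpa, rho_cpa,
                             rho_w = 1.0, rho = 1.0) {
  stopifnot(pi_cpa >= pi_pbs, pi_pbs >= 0, w2 >= w1, w1 > 0,
            v_pbs > 0, mw_cpa > 0, rho_cpa > 0, rho_w > 0, rho > 0)
  structure(as.list(environment()), class = "osmometry_record")
}

#' Permeated CPA amount and intratissue concentration
#'
#' Applies the four-step osmometry chain in order: moles
#' \eqn{n = (\pi_{CPA} - \pi_{PBS}) V_{PBS} \rho_W}, weight
#' \eqn{Wt = n \cdot MW}, volume \eqn{V = Wt/\rho_{cpa}}, and concentration
#' \eqn{C = n / (V + (W_2 - W_1 - Wt)/\rho)} with the volume denominator in
#' litres, so `c_cpa` is mol per litre of intratissue solution.  A negative
#' residual water mass \eqn{W_2 - W_1 - Wt} indicates inconsistent
#' measurements and is flagged with a warning (`consistent = FALSE`).
#'
#' @param rec an [osmometry_record()]
#' @return list with `n_cpa` (mol), `wt_cpa` (g), `v_cpa` (mL), `c_cpa`
#'   (mol/L), `consistent` (logical)
#' @export
permeated_amount <- function(rec) {
  stopifnot(inherits(rec, "osmometry_record"))
  n <- (rec$pi_cpa - rec$pi_pbs) * rec$v_pbs * rec$rho_w   # osmol/kg * L * kg/L
  wt <- n * rec$mw_cpa
  v <- wt / rec$rho_cpa                                     # mL
  water_ml <- (rec$w2 - rec$w1 - wt) / rec$rho              # mL
  consistent <- water_ml >= 0
  if (!consistent)
    warning("negative residual water mass (W2 - W1 - Wt): inconsistent record")
  denom_l <- (v + water_ml) / 1000
  c_cpa <- if (n == 0) 0 else n / denom_l
  list(n_cpa = n, wt_cpa = wt, v_cpa = v, c_cpa = c_cpa,
       consistent = consistent)
}

#' Analyze a series of osmometry records into an uptake curve
#'
#' @param records list of [osmometry_record()]s
#' @return data.frame with `time` (min) and `c_cpa` (mol/L)
#' @export
permeation_series <- function(records) {
  data.frame(
    time = vapply(records, function(r) r$immersion_time, numeric(1)),
    c_cpa = vapply(records, function(r) permeated_amount(r)$c_cpa, numeric(1)))
}

#' Time to reach a fraction of equilibrium permeation
#'
#' The plateau is estimated as the mean of the final three points; the
#' returned time is the first (linearly interpolated) crossing of
#' `fraction` times the plateau.  A tail that keeps moving by more than 5%
#' of the plateau triggers a warning but the estimate is still returned.
#'
#' @param time sampling times, min, strictly increasing
#' @param conc concentration series, mol/L
#' @param fraction target fraction of the plateau (default 0.95)
#' @return time in min (last time point if the target is never crossed)
#' @export
equilibration_time <- function(time, conc, fraction = 0.95) {
  stopifnot(length(time) == length(conc), length(time) >= 1,
            !is.unsorted(time, strictly = TRUE),
            fraction > 0, fraction <= 1)
  k <- min(3, length(conc))
  tail_c <- utils::tail(conc, k)
  plateau <- mean(tail_c)
  if (k == 3 && diff(range(tail_c)) > 0.05 * max(abs(plateau), .Machine$double.eps))
    warning("non-monotone or drifting tail; plateau estimate may be poor")
  if (fraction >= 1 && !is.unsorted(conc, strictly = TRUE))
    return(utils::tail(time, 1))
  target <- fraction * plateau
  hit <- conc >= target
  if (!any(hit)) return(utils::tail(time, 1))
  i <- which(hit)[1]
  if (i == 1) return(time[1])
  time[i - 1] + (target - conc[i - 1]) / (conc[i] - conc[i - 1]) *
    (time[i] - time[i - 1])
}

#' DSC thermogram container
#'
#' @param temperature_c temperature series, degC, strictly monotone
#' @param heat_flow heat-flow series, W/g, endotherm positive
#' @param scan_rate scan rate, K/min (> 0)
#' @param water_mass_fraction sample water mass fraction in `[0, 1]`
#' @return object of class `thermogram`
#' @export
thermogram <- function(temperature_c, heat_flow, scan_rate,
                       water_mass_fraction) {
  stopifnot(length(temperature_c) == length(heat_flow),
            length(temperature_c) >= 8,
            !is.unsorted(temperature_c, strictly = TRUE) ||
              !is.unsorted(rev(temperature_c), strictly = TRUE),
            scan_rate > 0,
            water_mass_fraction >= 0, water_mass_fraction <= 1)
  structure(list(temperature_c = temperature_c, heat_flow = heat_flow,
                 scan_rate = scan_rate,
                 water_mass_fraction = water_mass_fraction),
            class = "thermogram")
}

#' DSC melting-peak quantities
#'
#' Standard DSC conventions: a linear baseline is fitted over flanking
#' windows of width `baseline_window` K at both ends of the scan; the onset
#' is the intersection of that baseline with the steepest leading-edge
#' tangent of the endotherm; the melting enthalpy is the baseline-subtracted
#' peak integral over temperature divided by the scan rate; the nonfreezing
#' (bound) water fraction is the deficit of measured enthalpy relative to
#' the sample's total water, \eqn{(m_w - \Delta H_m / L_f)/m_w}, clipped to
#' `[0, 1]`.
#'
#' @param tg a [thermogram()]
#' @param baseline_window width of each baseline window, K
#' @param latent_heat latent heat of fusion used for the nonfreezing-water
#'   deficit, J/g (default pure water; lower it to correct for
#'   freezing-point depression)
#' @return list with `onset_freezing_point_c`, `melting_enthalpy_j_g`,
#'   `nonfreezing_water_fraction`, `peak_temperature_c`
#' @export
dsc_quantities <- function(tg, baseline_window = 5,
                           latent_heat = .L_WATER / 1000) {
  stopifnot(inherits(tg, "thermogram"))
  temp <- tg$temperature_c; hf <- tg$heat_flow
  if (temp[1] > utils::tail(temp, 1)) { temp <- rev(temp); hf <- rev(hf) }
  rng <- range(temp)
  base_sel <- temp <= rng[1] + baseline_window | temp >= rng[2] - baseline_window
  fit <- stats::lm.fit(cbind(1, temp[base_sel]), hf[base_sel])
  baseline <- fit$coefficients[1] + fit$coefficients[2] * temp
  resid <- hf - baseline
  noise <- stats::mad(resid[base_sel])
  ipk <- which.max(resid)
  peak <- resid[ipk]
  if (peak <= max(5 * noise, 1e-12))
    stop("no detectable endothermic peak in thermogram")

  # contiguous peak region above 0.5% of the apex
  above <- resid > 0.005 * peak
  lo <- ipk; while (lo > 1 && above[lo - 1]) lo <- lo - 1
  hi <- ipk; while (hi < length(resid) && above[hi + 1]) hi <- hi + 1
  seg <- lo:hi
  area <- sum(diff(temp[seg]) * (resid[seg][-1] + resid[seg][-length(seg)]) / 2)
  beta <- tg$scan_rate / 60                     # K/s
  enthalpy <- area / beta                       # (W/g * K) / (K/s) = J/g
  if (enthalpy < 0) stop("negative melting enthalpy")

  # steepest leading-edge tangent -> baseline intersection
  lead <- lo:ipk
  slope <- diff(resid[lead]) / diff(temp[lead])
  im <- which.max(slope)
  t_star <- (temp[lead][im] + temp[lead][im + 1]) / 2
  y_star <- (resid[lead][im] + resid[lead][im + 1]) / 2
  onset <- t_star - y_star / slope[im]

  w <- tg$water_mass_fraction
  nf <- if (w > 0) (w - enthalpy / latent_heat) / w else NA_real_
  nf <- min(max(nf, 0), 1)
  list(onset_freezing_point_c = onset,
       melting_enthalpy_j_g = enthalpy,
       nonfreezing_water_fraction = nf,
       peak_temperature_c = temp[ipk])
}

# Savitzky-Golay smoothing / differentiation with truncated edge windows.
# Returns the fitted value (deriv = 0) or first derivative per unit of
# `spacing` (deriv = 1).
sg_filter <- function(y, window = 11, order = 2, deriv = 0, spacing = 1) {
  n <- length(y)
  if (window %% 2 == 0) window <- window + 1
  window <- min(window, if (n %% 2 == 1) n else n - 1)
  h <- (window - 1) %/% 2
  ord <- min(order, window - 1)
  # central coefficients via least squares on offsets -h..h
  xs <- (-h):h
  V <- outer(xs, 0:ord, "^")
  Pinv <- solve(crossprod(V), t(V))
  coef_c <- Pinv[deriv + 1, ] * factorial(deriv)
  out <- as.numeric(stats::filter(y, rev(coef_c), sides = 2))
  # edges: refit on truncated windows
  for (i in c(seq_len(h), (n - h + 1):n)) {
    lo <- max(1, i - h); hi <- min(n, i + h)
    xe <- (lo:hi) - i
    Ve <- outer(xe, 0:min(ord, hi - lo), "^")
    ce <- solve(crossprod(Ve), t(Ve) %*% y[lo:hi])
    out[i] <- if (deriv == 0) ce[1] else if (nrow(ce) >= 2) ce[2] else 0
  }
  if (deriv == 1) out <- out / spacing
  out
}

#' Detect a supercooling/nucleation event on a cooling trace
#'
#' Phenomenology of a freezing thermocouple trace: steady imposed cooling, a
#' dip below the equilibrium freezing point (supercooling), an abrupt rise
#' when nucleation releases latent heat (recalescence), a near-isothermal
#' phase-transition plateau, then resumed cooling.  The detector smooths the
#' trace (local polynomial), finds the first derivative excursion exceeding
#' `k` times the robust noise scale (MAD of the smoothed derivative), and
#' anchors the nucleation point at the temperature minimum preceding it.
#' Temperatures at the event are read from the raw trace, so a noiseless
#' trace yields exact depths.
#'
#' @param time s, uniformly sampled
#' @param temperature_c degC
#' @param equilibrium_tf equilibrium freezing point, degC (for supercooling
#'   depth)
#' @param smoothing_window samples (odd)
#' @param k derivative threshold in MADs (default 5)
#' @return list of class `nucleation_event`: `detected`, `time`,
#'   `temperature_c`, `supercooling_depth_k`, `recalescence_amplitude_k`,
#'   `plateau_start_s`, `plateau_end_s`
#' @export
detect_nucleation <- function(time, temperature_c, equilibrium_tf,
                              smoothing_window = 11, k = 5) {
  stopifnot(length(time) == length(temperature_c), length(time) >= 12)
  dt <- diff(time)
  if (max(abs(dt - dt[1])) > 1e-6 * dt[1])
    stop("trace must be uniformly sampled")
  dt <- dt[1]
  no_event <- structure(list(detected = FALSE, time = NA_real_,
                             temperature_c = NA_real_,
                             supercooling_depth_k = NA_real_,
                             recalescence_amplitude_k = NA_real_,
                             plateau_start_s = NA_real_,
                             plateau_end_s = NA_real_),
                        class = "nucleation_event")

  tsm <- sg_filter(temperature_c, smoothing_window, 2, 0)
  d <- sg_filter(temperature_c, smoothing_window, 2, 1, spacing = dt)
  s <- stats::mad(d)
  thr <- max(stats::median(d) + k * s, 0.1 * abs(stats::median(d)), 1e-9)
  # exclude the half-window edges (their truncated fits are noisier) and
  # require the excursion to persist for 3 consecutive samples
  h <- (smoothing_window - 1) %/% 2
  n <- length(d)
  above <- d > thr
  above[c(seq_len(min(h, n)), seq(max(n - h + 1, 1), n))] <- FALSE
  persistent <- above & c(above[-1], FALSE) & c(above[-(1:2)], FALSE, FALSE)
  if (!any(persistent)) return(no_event)
  i_rise <- which(persistent)[1]
  # recalescence apex: first downward zero-crossing of the derivative after
  # the rise
  i_peak <- i_rise
  while (i_peak < length(d) && d[i_peak] > 0) i_peak <- i_peak + 1
  i_min <- which.min(temperature_c[1:max(i_peak, 2)])
  amp <- max(temperature_c[i_rise:i_peak]) - temperature_c[i_min]
  if (amp <= 0) return(no_event)

  # sub-sample nucleation time: intersect the pre-event ramp line (least
  # squares over the approach) with the steepest rising secant of the raw
  # trace.  Exact on noiseless traces; averages the noise otherwise.
  pre_lo <- max(1, i_min - 300)
  pre_hi <- max(pre_lo + 1, i_min - 2)
  cf <- stats::lm.fit(cbind(1, time[pre_lo:pre_hi]),
                      temperature_c[pre_lo:pre_hi])$coefficients
  seg <- i_min:min(i_peak, i_min + 50)
  t_nuc <- time[i_min]
  if (length(seg) >= 2) {
    js <- seg[which.max(diff(temperature_c[seg]))]
    s_rise <- (temperature_c[js + 1] - temperature_c[js]) / dt
    if (is.finite(s_rise) && s_rise > cf[2] + 1e-12) {
      # intersection of y = cf1 + cf2 t with y = T[js] + s_rise (t - t[js])
      t_star <- (cf[1] - (temperature_c[js] - s_rise * time[js])) /
        (s_rise - cf[2])
      if (t_star >= time[pre_lo] && t_star <= time[min(i_peak, length(time))])
        t_nuc <- t_star
    }
  }
  i_nuc <- i_min
  T_nuc <- cf[1] + cf[2] * t_nuc

  # plateau: |dT/dt| < 10% of the imposed (pre-nucleation) cooling rate
  pre <- d[1:max(i_nuc - 1, 1)]
  rate <- abs(stats::median(pre))
  calm <- abs(d) < 0.1 * max(rate, 1e-12)
  calm[seq_len(i_peak - 1)] <- FALSE
  if (any(calm)) {
    p0 <- which(calm)[1]
    p1 <- p0
    while (p1 < length(calm) && calm[p1 + 1]) p1 <- p1 + 1
    plateau <- c(time[p0], time[p1])
  } else plateau <- c(NA_real_, NA_real_)

  structure(list(detected = TRUE, time = t_nuc,
                 temperature_c = unname(T_nuc),
                 supercooling_depth_k = unname(equilibrium_tf - T_nuc),
                 recalescence_amplitude_k = amp,
                 plateau_start_s = plateau[1], plateau_end_s = plateau[2]),
            class = "nucleation_event")
}
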