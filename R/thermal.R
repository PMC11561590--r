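#' Thermal boundary conditions
#'
#' Three boundary-condition kinds drive the protocols: a Dirichlet ramp
#' (controlled-rate freezer), a Dirichlet hold, and a convective bath
#' (liquid-nitrogen plunge or 37 degC water-bath rewarming) with film
#' coefficient `h`.  `applies_to` selects outer edges
#' (`"left"`, `"right"`, `"bottom"`, `"top"`); edges no condition applies to
#' are adiabatic.
#'
#' @param start_temperature,target_temperature,temperature,bath_temperature K
#' @param ramp_rate K/s (sign must point from start to target)
#' @param h film coefficient W/(m^2 K)
#' @param applies_to character vector of edges
#' @param t0 absolute time (s) at which the ramp starts
#' @return object of class `thermal_bc`
#' @export
bc_dirichlet_ramp <- function(start_temperature, ramp_rate,
                              target_temperature = NULL,
                              applies_to = c("left", "right", "bottom", "top"),
                              t0 = 0) {
  stopifnot(ramp_rate != 0)
  if (!is.null(target_temperature) &&
      sign(target_temperature - start_temperature) != sign(ramp_rate))
    stop("ramp_rate sign inconsistent with start -> target direction")
  structure(list(kind = "dirichlet_ramp", start_temperature = start_temperature,
                 ramp_rate = ramp_rate, target_temperature = target_temperature,
                 applies_to = applies_to, t0 = t0), class = "thermal_bc")
}

#' @rdname bc_dirichlet_ramp
#' @export
bc_dirichlet_hold <- function(temperature,
                              applies_to = c("left", "right", "bottom", "top")) {
  structure(list(kind = "dirichlet_hold", temperature = temperature,
                 applies_to = applies_to), class = "thermal_bc")
}

#' @rdname bc_dirichlet_ramp
#' @export
bc_convective_bath <- function(bath_temperature, h = 200,
                               applies_to = c("left", "right", "bottom", "top")) {
  stopifnot(h > 0)
  structure(list(kind = "convective_bath", bath_temperature = bath_temperature,
                 h = h, applies_to = applies_to), class = "thermal_bc")
}

#' Imposed boundary temperature of a [thermal_bc] at absolute time `t`
#' @param bc a `thermal_bc`
#' @param t absolute time, s
#' @return boundary (or bath) temperature in K
#' @export
boundary_temperature <- function(bc, t) {
  switch(bc$kind,
    dirichlet_ramp = {
      T_b <- bc$start_temperature + bc$ramp_rate * pmax(t - bc$t0, 0)
      if (!is.null(bc$target_temperature)) {
        if (bc$ramp_rate < 0) T_b <- pmax(T_b, bc$target_temperature)
        else T_b <- pmin(T_b, bc$target_temperature)
      }
      T_b
    },
    dirichlet_hold = rep_len(bc$temperature, length(t)),
    convective_bath = rep_len(bc$bath_temperature, length(t)),
    stop("unknown bc kind"))
}

# ---------------------------------------------------------------------------
# Precomputed solver context: per-cell material vectors, face topology,
# boundary faces, sparse matrix pattern and cached Cholesky factorisation.

#' Assemble the thermal solver context for a grid and material pair
#'
#' @param grid a [build_grid()] object
#' @param materials either a single [phase_change_material()] (homogeneous
#'   domain) or `list(solution = , skin = )`
#' @return object of class `thermal_system`
#' @export
thermal_system <- function(grid, materials) {
  if (inherits(materials, "phase_change_material"))
    materials <- list(solution = materials, skin = materials)
  stopifnot(!is.null(materials$solution), !is.null(materials$skin))
  n <- grid$n; nx <- grid$nx; ny <- grid$ny
  mat_id <- ifelse(grid$skin_mask, 2L, 1L)
  pick <- function(f1, f2) ifelse(mat_id == 1L, f1, f2)
  ms <- materials$solution; mk <- materials$skin
  par <- list(
    Tm  = pick(ms$melt_temperature, mk$melt_temperature),
    dtr = pick(ms$transition_half_width, mk$transition_half_width),
    L   = pick(ms$latent_heat, mk$latent_heat),
    rho1 = pick(ms$phase1$density, mk$phase1$density),
    rho2 = pick(ms$phase2$density, mk$phase2$density),
    rc1  = pick(ms$phase1$density * ms$phase1$heat_capacity,
                mk$phase1$density * mk$phase1$heat_capacity),
    rc2  = pick(ms$phase2$density * ms$phase2$heat_capacity,
                mk$phase2$density * mk$phase2$heat_capacity),
    k1   = pick(ms$phase1$conductivity, mk$phase1$conductivity),
    k2   = pick(ms$phase2$conductivity, mk$phase2$conductivity))

  # interior faces (x-normal then y-normal); pf < qf by construction
  idx <- function(i, j) (j - 1L) * nx + i
  fx_p <- as.vector(outer(seq_len(nx - 1L), seq_len(ny), idx))
  fx_q <- fx_p + 1L
  fy_p <- as.vector(outer(seq_len(nx), seq_len(ny - 1L), idx))
  fy_q <- fy_p + nx
  pf <- c(fx_p, fy_p); qf <- c(fx_q, fy_q)
  dZ <- grid$thickness
  # area / half-distance for each face side (uniform grid: same both sides)
  cfac <- c(rep(grid$dy * dZ / (grid$dx / 2), length(fx_p)),
            rep(grid$dx * dZ / (grid$dy / 2), length(fy_p)))
  nfaces <- length(pf)
  Minc <- Matrix::sparseMatrix(i = c(pf, qf), j = rep(seq_len(nfaces), 2),
                               x = 1, dims = c(n, nfaces))

  edges <- list(
    left   = list(cells = idx(1L, seq_len(ny)),  area = grid$dy * dZ, hd = grid$dx / 2),
    right  = list(cells = idx(nx, seq_len(ny)),  area = grid$dy * dZ, hd = grid$dx / 2),
    bottom = list(cells = idx(seq_len(nx), 1L),  area = grid$dx * dZ, hd = grid$dy / 2),
    top    = list(cells = idx(seq_len(nx), ny),  area = grid$dx * dZ, hd = grid$dy / 2))

  A0 <- Matrix::sparseMatrix(i = c(seq_len(n), pf), j = c(seq_len(n), qf),
                             x = 1, dims = c(n, n), symmetric = TRUE)
  rows <- A0@i + 1L
  cols <- rep(seq_len(n), diff(A0@p))
  keys <- rows + (cols - 1) * n
  map_diag <- match(seq_len(n) + (seq_len(n) - 1) * n, keys)
  map_face <- match(pf + (qf - 1) * n, keys)
  stopifnot(!anyNA(map_diag), !anyNA(map_face))

  structure(list(grid = grid, materials = materials, mat_id = mat_id,
                 par = par, pf = pf, qf = qf, cfac = cfac, Minc = Minc,
                 edges = edges, A0 = A0, map_diag = map_diag,
                 map_face = map_face, cache = new.env(parent = emptyenv())),
            class = "thermal_system")
}

# vectorised per-cell closures ----------------------------------------------

theta2_of_T <- function(sys, temperature) {
  p <- sys$par
  x <- (temperature - p$Tm + p$dtr) / (2 * p$dtr)
  x <- pmin(pmax(x, 0), 1)
  x * x * (3 - 2 * x)
}

conductivity_of <- function(sys, theta2) {
  (1 - theta2) * sys$par$k1 + theta2 * sys$par$k2
}

# volumetric enthalpy per cell, J/m^3, reference 40 K below melt point
enthalpy_of_T <- function(sys, temperature) {
  p <- sys$par
  ref <- p$Tm - 40
  a <- p$Tm - p$dtr
  x <- pmin(pmax((temperature - a) / (2 * p$dtr), 0), 1)
  i2 <- 2 * p$dtr * (x^3 - x^4 / 2) + pmax(temperature - (a + 2 * p$dtr), 0)
  th2 <- x * x * (3 - 2 * x)
  b <- p$rho2 - p$rho1
  lat <- ifelse(abs(b) < 1e-9,
                p$L * p$rho1 * th2,
                p$L * p$rho1 * p$rho2 / ifelse(abs(b) < 1e-9, 1, b) *
                  log((p$rho1 + b * th2) / p$rho1))
  p$rc1 * (temperature - ref) + (p$rc2 - p$rc1) * i2 + lat
}

# pointwise volumetric apparent heat capacity rho*C_P,eff, J/(m^3 K)
rho_cp_eff_of_T <- function(sys, temperature) {
  p <- sys$par
  x <- (temperature - p$Tm + p$dtr) / (2 * p$dtr)
  inside <- x > 0 & x < 1
  xc <- pmin(pmax(x, 0), 1)
  th2 <- xc * xc * (3 - 2 * xc)
  dth <- numeric(length(x))
  dth[inside] <- 6 * xc[inside] * (1 - xc[inside]) / (2 * p$dtr[inside])
  mixrho <- p$rho1 + (p$rho2 - p$rho1) * th2
  sens <- (1 - th2) * p$rc1 + th2 * p$rc2
  # rho * L * d(alpha_m)/dT with rho*dalpha_m/dtheta = rho1 rho2 / mixrho
  sens + p$L * p$rho1 * p$rho2 / mixrho * dth
}

#' Initial thermal state
#'
#' @param sys a [thermal_system()]
#' @param temperature initial temperature, K (scalar or per-cell vector)
#' @param time initial time, s
#' @return object of class `thermal_state` with fields `time`, `temperature`,
#'   `theta2` (liquid fraction), `enthalpy_ledger` (cumulative boundary heat
#'   in, J)
#' @export
thermal_state <- function(sys, temperature, time = 0) {
  temperature <- rep_len(temperature, sys$grid$n)
  stopifnot(all(is.finite(temperature)))
  structure(list(time = time, temperature = temperature,
                 theta2 = theta2_of_T(sys, temperature),
                 enthalpy_ledger = 0),
            class = "thermal_state")
}

# resolve bc objects (single or list) to per-edge assignments; later wins
resolve_bcs <- function(bc) {
  if (inherits(bc, "thermal_bc")) bc <- list(bc)
  per_edge <- list(left = NULL, right = NULL, bottom = NULL, top = NULL)
  for (b in bc) for (e in b$applies_to) per_edge[[e]] <- b
  per_edge
}

#' Advance the temperature field by one implicit time step
#'
#' Backward-Euler finite-volume step of conduction with phase change.
#' The apparent heat capacity is linearised with the enthalpy chord
#' \eqn{(H_v(T_k) - H_v(T^n)) / (T_k - T^n)} and iterated (Picard) to
#' tolerance, which makes the step conservative: at convergence the discrete
#' enthalpy change equals the boundary flux exactly, so the energy ledger
#' closes to the Picard tolerance.
#'
#' @param state a [thermal_state()]
#' @param sys a [thermal_system()]
#' @param bc a [bc_dirichlet_ramp()]-family object, or a list of them
#' @param dt time step, s (> 0)
#' @param tol Picard tolerance on temperature, K
#' @param max_iter maximum Picard iterations
#' @param source volumetric heat source Q, W/m^3 (config hook, default 0)
#' @param q0 additional boundary heat flux, W/m^2, positive into the domain
#'   (config hook, default 0)
#' @return updated `thermal_state`
#' @export
step_temperature <- function(state, sys, bc, dt, tol = 1e-6, max_iter = 50,
                             source = 0, q0 = 0) {
  stopifnot(dt > 0)
  grid <- sys$grid; n <- grid$n
  per_edge <- resolve_bcs(bc)
  t_new <- state$time + dt
  T_old <- state$temperature
  H_old <- enthalpy_of_T(sys, T_old)
  vol_dt <- grid$vol / dt

  # warm start: extrapolate from the previous step's increment
  T_k <- if (!is.null(sys$cache$last_dT) &&
             length(sys$cache$last_dT) == length(T_old))
    T_old + sys$cache$last_dT else T_old
  # adaptive under-relaxation: the chord iteration can limit-cycle when a
  # cell straddles the latent front; damping on stagnation restores
  # contraction
  omega <- 1; prev_delta <- Inf
  for (iter in seq_len(max_iter)) {
    th2 <- theta2_of_T(sys, T_k)
    kc <- conductivity_of(sys, th2)
    g <- sys$cfac / 2 * (kc[sys$pf] * kc[sys$qf]) / (kc[sys$pf] + kc[sys$qf]) * 2
    # chord heat capacity (volumetric); pointwise fallback off the chord
    dTk <- T_k - T_old
    cbar <- ifelse(abs(dTk) > 1e-9,
                   (enthalpy_of_T(sys, T_k) - H_old) / dTk,
                   rho_cp_eff_of_T(sys, T_k))
    diagv <- vol_dt * cbar + as.vector(sys$Minc %*% g)
    rhs <- vol_dt * cbar * T_old + grid$vol * source

    for (e in names(per_edge)) {
      b <- per_edge[[e]]
      ed <- sys$edges[[e]]
      if (q0 != 0) rhs[ed$cells] <- rhs[ed$cells] + q0 * ed$area
      if (is.null(b)) next
      kcell <- kc[ed$cells]
      if (b$kind == "convective_bath") {
        gb <- ed$area / (1 / b$h + ed$hd / kcell)
      } else {
        gb <- ed$area * kcell / ed$hd
      }
      Tb <- boundary_temperature(b, t_new)
      diagv[ed$cells] <- diagv[ed$cells] + gb
      rhs[ed$cells] <- rhs[ed$cells] + gb * Tb
    }

    A <- sys$A0
    xs <- numeric(length(A@x))
    xs[sys$map_diag] <- diagv
    xs[sys$map_face] <- -g
    A@x <- xs
    if (is.null(sys$cache$chol)) {
      sys$cache$chol <- Matrix::Cholesky(A, LDL = FALSE, perm = TRUE,
                                         super = TRUE)
    } else {
      sys$cache$chol <- Matrix::update(sys$cache$chol, A)
    }
    T_next <- as.vector(Matrix::solve(sys$cache$chol, rhs))
    if (!all(is.finite(T_next)))
      stop(sprintf("non-finite temperature at t = %.3f s (iter %d); T range was [%.2f, %.2f] K",
                   t_new, iter, min(T_k), max(T_k)))
    delta <- max(abs(T_next - T_k))
    if (delta < tol) { T_k <- T_next; break }
    if (delta >= 0.7 * prev_delta) omega <- max(omega * 0.5, 0.2)
    else omega <- min(1, omega * 1.5)
    T_k <- omega * T_next + (1 - omega) * T_k
    prev_delta <- delta
  }
  sys$cache$last_dT <- T_k - T_old
  sys$cache$picard_total <- (sys$cache$picard_total %||% 0) + iter
  sys$cache$picard_max <- max(sys$cache$picard_max %||% 0L, iter)

  # boundary ledger with the converged field
  th2 <- theta2_of_T(sys, T_k)
  kc <- conductivity_of(sys, th2)
  Q_in <- 0
  for (e in names(per_edge)) {
    b <- per_edge[[e]]
    ed <- sys$edges[[e]]
    if (q0 != 0) Q_in <- Q_in + q0 * ed$area * length(ed$cells) * dt
    if (is.null(b)) next
    kcell <- kc[ed$cells]
    gb <- if (b$kind == "convective_bath") ed$area / (1 / b$h + ed$hd / kcell)
          else ed$area * kcell / ed$hd
    Q_in <- Q_in + sum(gb * (boundary_temperature(b, t_new) - T_k[ed$cells])) * dt
  }
  if (source != 0) Q_in <- Q_in + source * grid$vol * n * dt

  structure(list(time = t_new, temperature = T_k, theta2 = th2,
                 enthalpy_ledger = state$enthalpy_ledger + Q_in),
            class = "thermal_state")
}

#' First crossing time of a phase-fraction trace
#'
#' Linearly interpolates the first time a (near-)monotone phase-fraction
#' trace crosses `threshold`.  The crossing direction is inferred from the
#' trace unless given.
#'
#' @param time,fraction equal-length numeric vectors
#' @param threshold crossing level (default 0.999, the frozen-completion
#'   convention; use 0.001 on an ice-fraction trace for melt completion)
#' @param direction `"up"`, `"down"`, or `NULL` to infer from the trend
#' @return crossing time in s, or `NA_real_` if the threshold is never
#'   reached ("not reached" sentinel)
#' @export
phase_completion_time <- function(time, fraction, threshold = 0.999,
                                  direction = NULL) {
  stopifnot(length(time) == length(fraction), length(time) >= 1)
  if (is.null(direction))
    direction <- if (utils::tail(fraction, 1) >= fraction[1]) "up" else "down"
  hit <- if (direction == "up") fraction >= threshold else fraction <= threshold
  if (!any(hit)) return(NA_real_)
  i <- which(hit)[1]
  if (i == 1) return(time[1])
  f0 <- fraction[i - 1]; f1 <- fraction[i]
  if (f1 == f0) return(time[i])
  time[i - 1] + (threshold - f0) / (f1 - f0) * (time[i] - time[i - 1])
}
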