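#' Protocol stages and probes
#'
#' A protocol is an ordered list of boundary-condition stages, each with a
#' duration and an output (snapshot) interval, plus named probe points whose
#' temperature and phase traces are recorded.  Default probes follow the
#' concentric-circle construction: Point 1 on the skin/solution interface at
#' the skin's short-edge midpoint (5 mm, 0), Point 2 in the free solution at
#' the same radius from the domain centre, 90 degrees away (0, 5 mm).
#'
#' @param name stage label
#' @param bc a `thermal_bc` (or list of them)
#' @param duration stage duration, s (> 0)
#' @param output_interval snapshot cadence, s
#' @param dt time step for this stage, s
#' @return `protocol_stage()`: a stage; `protocol()`: object of class
#'   `cryo_protocol`
#' @export
protocol_stage <- function(name, bc, duration, output_interval = 10, dt = 1) {
  if (!(duration > 0)) stop("stage duration must be > 0 (zero-length stage rejected)")
  stopifnot(dt > 0, output_interval > 0)
  list(name = name, bc = bc, duration = duration,
       output_interval = output_interval, dt = dt)
}

#' @rdname protocol_stage
#' @param stages list of stages from [protocol_stage()]
#' @param probes named list of `c(x, y)` coordinates in metres
#' @param initial_temperature uniform initial field, K
#' @export
protocol <- function(stages, probes = default_probes(),
                     initial_temperature) {
  stopifnot(length(stages) >= 1)
  structure(list(stages = stages, probes = probes,
                 initial_temperature = initial_temperature),
            class = "cryo_protocol")
}

#' @rdname protocol_stage
#' @export
default_probes <- function() {
  # Point 1: skin-side cell at the midpoint of the upper long interface edge
  # ("the skin in contact" with the solution); Point 2: free solution on the
  # same vertical through the domain centre, 5 mm out.  See the methods
  # vignette for why the two constraints the probe description carries
  # (interface midpoint + concentric placement) cannot both hold.
  list("Point 1" = c(0, 0.00075), "Point 2" = c(0, 0.005))
}

#' Standard controlled-rate cooling protocol
#'
#' Stage 1: Dirichlet ramp on all outer edges at `ramp_rate` (default
#' -1 degC/min) from `T_init` down to -80 degC.  Stage 2: liquid-nitrogen
#' plunge modelled as a convective bath at -196 degC until `total_duration`
#' of simulated time (default 6000 s, so the late-hold snapshot time is
#' reachable).
#'
#' @param T_init initial/start temperature, K (default 4 degC, the CPA
#'   loading temperature)
#' @param ramp_rate K/s (negative)
#' @param ramp_target K (default -80 degC)
#' @param total_duration total simulated time, s
#' @param h_ln2 film coefficient of the LN2 bath, W/(m^2 K)
#' @param dt time step, s
#' @return a [protocol()]
#' @export
standard_cooling_protocol <- function(T_init = celsius_to_kelvin(4),
                                      ramp_rate = -1 / 60,
                                      ramp_target = celsius_to_kelvin(-80),
                                      total_duration = 6000,
                                      h_ln2 = 200, dt = 1,
                                      dt_deep = 5, split_at = 1500) {
  if (T_init <= ramp_target)
    stop("T_init must exceed the ramp target (degenerate zero-length ramp)")
  ramp_dur <- min((ramp_target - T_init) / ramp_rate, total_duration)
  ramp_bc <- bc_dirichlet_ramp(T_init, ramp_rate, ramp_target)
  # fine steps through the phase-change window, coarser afterwards (the
  # stepper is implicit/unconditionally stable; by split_at the transition
  # is complete on the default scenario)
  stages <- if (ramp_dur > split_at) list(
    protocol_stage("ramp_-1C_min", ramp_bc, duration = split_at,
                   output_interval = 10, dt = dt),
    protocol_stage("ramp_-1C_min_deep", ramp_bc,
                   duration = ramp_dur - split_at,
                   output_interval = 10, dt = dt_deep))
  else list(
    protocol_stage("ramp_-1C_min", ramp_bc, duration = ramp_dur,
                   output_interval = 10, dt = dt))
  if (total_duration > ramp_dur)
    stages <- c(stages, list(
      protocol_stage("ln2_hold",
                     bc_convective_bath(celsius_to_kelvin(-196), h = h_ln2),
                     duration = total_duration - ramp_dur,
                     output_interval = 10, dt = dt_deep)))
  protocol(stages, initial_temperature = T_init)
}

#' Standard water-bath rewarming protocol
#'
#' Single convective-bath stage at 37 degC from a uniform -196 degC initial
#' field, long enough for complete melting plus margin.
#'
#' @param duration stage duration, s
#' @param bath_temperature K
#' @param h film coefficient, W/(m^2 K)
#' @param T_init initial field, K
#' @param dt time step, s
#' @return a [protocol()]
#' @export
standard_rewarming_protocol <- function(duration = 600,
                                        bath_temperature = celsius_to_kelvin(37),
                                        h = 600,
                                        T_init = celsius_to_kelvin(-196),
                                        dt = 0.5, dt_late = 1,
                                        split_at = 120) {
  bc <- bc_convective_bath(bath_temperature, h = h)
  stages <- if (duration > split_at) list(
    protocol_stage("water_bath_37C", bc, duration = split_at,
                   output_interval = 1, dt = dt),
    protocol_stage("water_bath_37C_late", bc, duration = duration - split_at,
                   output_interval = 1, dt = dt_late))
  else list(
    protocol_stage("water_bath_37C", bc, duration = duration,
                   output_interval = 1, dt = dt))
  protocol(stages, initial_temperature = T_init)
}

#' Run a cooling/rewarming protocol (thermal only, or coupled)
#'
#' `run_cycle()` integrates the protocol with the implicit phase-change
#' thermal solver, one-way coupled per step to the quasi-static Maxwell
#' stress solver.  `run_thermal()` is the thermal-only variant.  Both are
#' fully deterministic given their configuration.
#'
#' Per-step running records keep memory bounded: probe traces at
#' `trace_interval`, global ice fraction, per-cell first ice-onset times
#' (liquid fraction dropping below 0.99), running peak stresses (von Mises
#' and maximum principal, per region), and the energy ledger.  Field
#' snapshots are written as VTK files to `snapshot_dir` at each stage's
#' `output_interval`, or retained in memory if `keep_history = TRUE`
#' (intended for small grids).
#'
#' @param protocol a [protocol()]
#' @param grid a [build_grid()] object
#' @param materials single material or `list(solution=, skin=)`
#' @param mechanical_bc a [mech_bc()]
#' @param trace_interval probe/global trace cadence, s
#' @param snapshot_dir directory for VTK snapshots (NULL: none)
#' @param keep_history retain thermal+stress snapshots in memory at each
#'   stage's `output_interval`
#' @param with_mech run the stress solver (TRUE for `run_cycle`)
#' @param picard_tol,picard_max Picard controls passed to
#'   [step_temperature()]
#' @return object of class `simulation_result`; see Details
#' @export
run_cycle <- function(protocol, grid, materials, mechanical_bc = mech_bc(),
                      trace_interval = 1, snapshot_dir = NULL,
                      keep_history = FALSE, with_mech = TRUE,
                      picard_tol = 1e-6, picard_max = 50) {
  stopifnot(inherits(protocol, "cryo_protocol"))
  sys <- thermal_system(grid, materials)
  st <- thermal_state(sys, protocol$initial_temperature)
  msys <- NULL; mst <- NULL
  if (with_mech) {
    msys <- mech_system(grid, materials, mechanical_bc)
    mst <- mech_state(msys)
  }

  probes <- protocol$probes
  probe_cells <- if (length(probes))
    vapply(probes, function(p) cell_at(grid, p[1], p[2]), integer(1))
  else integer(0)

  onset <- rep(NA_real_, grid$n)
  masks <- list(skin = region_mask(grid, "skin"),
                solution = region_mask(grid, "solution"),
                skin_boundary = region_mask(grid, "skin_boundary"),
                all = rep(TRUE, grid$n))
  peak <- list()
  for (ms in c("von_mises", "max_principal"))
    for (rg in names(masks))
      peak[[ms]][[rg]] <- list(value = -Inf, time = 0, cell = NA_integer_)

  H0 <- sum(grid$vol * enthalpy_of_T(sys, st$temperature))
  Q_abs <- 0
  max_theta2_drop <- 0; max_theta2_rise_after_melt <- 0
  trace_rows <- list(); global_rows <- list(); history <- list()
  next_trace <- 0
  record_trace <- function(st, mst) {
    th1 <- 1 - st$theta2
    g <- data.frame(time = st$time,
                    ice_fraction = mean(th1),
                    ice_skin = if (any(masks$skin)) mean(th1[masks$skin]) else NA_real_,
                    ice_solution = mean(th1[masks$solution]),
                    T_min_C = kelvin_to_celsius(min(st$temperature)),
                    T_max_C = kelvin_to_celsius(max(st$temperature)),
                    Q_boundary_J = st$enthalpy_ledger)
    global_rows[[length(global_rows) + 1]] <<- g
    if (length(probe_cells)) {
      cs <- if (!is.null(mst)) cell_stress(mst) else NULL
      p <- data.frame(time = st$time,
                      probe_id = names(probe_cells),
                      T_C = kelvin_to_celsius(st$temperature[probe_cells]),
                      theta2 = st$theta2[probe_cells])
      if (!is.null(cs)) {
        p$von_mises_Pa <- von_mises(cs)[probe_cells]
        p$max_principal_Pa <- max_principal(cs)[probe_cells]
      }
      trace_rows[[length(trace_rows) + 1]] <<- p
    }
  }
  record_trace(st, mst)

  melted <- st$theta2 > 0.999
  t_total <- 0
  for (stage in protocol$stages) {
    nstep <- max(1L, ceiling(stage$duration / stage$dt - 1e-9))
    dts <- rep(stage$dt, nstep)
    dts[nstep] <- stage$duration - (nstep - 1) * stage$dt
    next_snap <- st$time
    for (k in seq_len(nstep)) {
      dt <- dts[k]
      led0 <- st$enthalpy_ledger
      st_new <- step_temperature(st, sys, stage$bc, dt,
                                 tol = picard_tol, max_iter = picard_max)
      Q_abs <- Q_abs + abs(st_new$enthalpy_ledger - led0)
      dth2 <- st_new$theta2 - st$theta2
      max_theta2_drop <- max(max_theta2_drop, max(-pmin(dth2, 0)))
      newly <- is.na(onset) & st_new$theta2 < 0.99
      onset[newly] <- st_new$time
      refroze <- melted & (st_new$theta2 < 0.999)
      if (any(refroze))
        max_theta2_rise_after_melt <- max(max_theta2_rise_after_melt,
                                          max(0.999 - st_new$theta2[refroze]))
      melted <- melted | st_new$theta2 > 0.999

      if (with_mech) {
        mst <- update_stress(mst, msys,
                             dT_field = st_new$temperature - st$temperature,
                             dth2_field = dth2,
                             th2_field = st_new$theta2, dt = dt)
        cs <- cell_stress(mst)
        sc <- list(von_mises = von_mises(cs), max_principal = max_principal(cs))
        for (msn in names(sc)) for (rg in names(masks)) {
          v <- sc[[msn]]; v[!masks[[rg]]] <- -Inf
          if (max(v) > peak[[msn]][[rg]]$value) {
            peak[[msn]][[rg]] <- list(value = max(v), time = st_new$time,
                                      cell = which.max(v))
          }
        }
      }
      st <- st_new
      if (st$time >= next_trace - 1e-9) {
        record_trace(st, mst)
        next_trace <- next_trace + trace_interval
      }
      if (st$time >= next_snap + stage$output_interval - 1e-9) {
        next_snap <- st$time
        if (keep_history)
          history[[length(history) + 1]] <-
            list(time = st$time, temperature = st$temperature,
                 theta2 = st$theta2,
                 sig = if (with_mech) cell_stress(mst) else NULL)
        if (!is.null(snapshot_dir))
          write_vtk_snapshot(file.path(snapshot_dir,
                                       sprintf("snap_%08.1fs.vtk", st$time)),
                             grid, st, if (with_mech) mst else NULL)
      }
    }
    t_total <- t_total + stage$duration
  }

  H_end <- sum(grid$vol * enthalpy_of_T(sys, st$temperature))
  ledger <- list(H_initial = H0, H_final = H_end,
                 Q_boundary_net = st$enthalpy_ledger,
                 Q_exchanged_abs = Q_abs,
                 drift = (H_end - H0) - st$enthalpy_ledger)

  traces <- do.call(rbind, trace_rows)
  global <- do.call(rbind, global_rows)
  res <- structure(list(
    grid = grid, probes = probes, probe_cells = probe_cells,
    traces = traces, global = global, onset_time = onset,
    peaks = if (with_mech) peak else NULL,
    ledger = ledger, history = history,
    final_thermal = st, final_mech = mst,
    config = list(initial_temperature = protocol$initial_temperature,
                  stages = lapply(protocol$stages, function(s)
                    s[c("name", "duration", "dt", "output_interval")]),
                  nx = grid$nx, ny = grid$ny, with_mech = with_mech,
                  package_version = as.character(utils::packageVersion("cryoskin"))),
    max_theta2_drop = max_theta2_drop,
    max_refreeze = max_theta2_rise_after_melt),
    class = "simulation_result")
  res$milestones <- compute_milestones(res)
  res
}

#' @rdname run_cycle
#' @export
run_thermal <- function(protocol, grid, materials, trace_interval = 1,
                        snapshot_dir = NULL, keep_history = FALSE,
                        picard_tol = 1e-6, picard_max = 50) {
  run_cycle(protocol, grid, materials, with_mech = FALSE,
            trace_interval = trace_interval, snapshot_dir = snapshot_dir,
            keep_history = keep_history,
            picard_tol = picard_tol, picard_max = picard_max)
}

# milestone extraction from the running records
compute_milestones <- function(res) {
  grid <- res$grid
  g <- res$global
  onset <- res$onset_time
  nx <- grid$nx; ny <- grid$ny
  ring <- rep(FALSE, grid$n)
  ii <- rep(seq_len(nx), times = ny); jj <- rep(seq_len(ny), each = nx)
  ring[ii == 1 | ii == nx | jj == 1 | jj == ny] <- TRUE
  skin <- grid$skin_mask
  iface <- skin & (interface_distance(grid) == 0)
  center_cell <- cell_at(grid, 0, 0)
  first_onset <- function(mask) {
    v <- onset[mask]
    if (all(is.na(v))) NA_real_ else min(v, na.rm = TRUE)
  }
  onset_global <- first_onset(rep(TRUE, grid$n))
  first_cell <- if (!all(is.na(onset))) which.min(onset) else NA_integer_
  first_region <- if (is.na(first_cell)) NA_character_
    else if (ring[first_cell]) "boundary"
    else if (skin[first_cell]) "skin" else "solution_interior"

  melting <- utils::tail(g$ice_fraction, 1) < g$ice_fraction[1]
  list(
    ice_onset_s = onset_global,
    ice_onset_boundary_s = first_onset(ring),
    ice_onset_skin_interface_s = if (any(iface)) first_onset(iface) else NA_real_,
    ice_onset_skin_center_s = onset[center_cell],
    first_onset_region = first_region,
    freeze_completion_s = if (!melting)
      phase_completion_time(g$time, g$ice_fraction, 0.999, "up") else NA_real_,
    melt_completion_s = if (melting)
      phase_completion_time(g$time, g$ice_fraction, 0.001, "down") else NA_real_,
    peak_stress = res$peaks,
    energy_drift_fraction =
      abs(res$ledger$drift) / max(res$ledger$Q_exchanged_abs, .Machine$double.eps)
  )
}

#' @export
print.simulation_result <- function(x, ...) {
  m <- x$milestones
  cat("<simulation_result>\n")
  cat(sprintf("  t = [0, %.1f] s, grid %d x %d\n",
              max(x$global$time), x$grid$nx, x$grid$ny))
  cat(sprintf("  ice onset %.1f s (first region: %s)\n",
              m$ice_onset_s, m$first_onset_region))
  if (!is.na(m$freeze_completion_s))
    cat(sprintf("  freeze completion %.1f s\n", m$freeze_completion_s))
  if (!is.na(m$melt_completion_s))
    cat(sprintf("  melt completion %.1f s\n", m$melt_completion_s))
  if (!is.null(x$peaks))
    cat(sprintf("  peak skin-boundary stress: %.1f MPa (von Mises, t = %.1f s), %.1f MPa (max principal, t = %.1f s)\n",
                x$peaks$von_mises$skin_boundary$value / 1e6,
                x$peaks$von_mises$skin_boundary$time,
                x$peaks$max_principal$skin_boundary$value / 1e6,
                x$peaks$max_principal$skin_boundary$time))
  cat(sprintf("  energy ledger drift: %.3g%% of exchanged heat\n",
              100 * m$energy_drift_fraction))
  invisible(x)
}

#' Phase-transition completion lag between two probes
#'
#' Difference of per-probe phase-completion times (probe1 - probe2), positive
#' when probe1 completes later.  The transition direction (freeze vs. melt)
#' is inferred from the probe traces.
#'
#' @param result a [run_cycle()] result
#' @param probe1,probe2 probe names (defaults: "Point 1", "Point 2")
#' @return lag in seconds
#' @export
interface_lag <- function(result, probe1 = "Point 1", probe2 = "Point 2") {
  tr <- result$traces
  get <- function(p) {
    sub <- tr[tr$probe_id == p, ]
    if (nrow(sub) == 0) stop("missing probe: ", p)
    sub
  }
  completion <- function(sub) {
    melting <- utils::tail(sub$theta2, 1) > sub$theta2[1]
    if (melting) phase_completion_time(sub$time, sub$theta2, 0.999, "up")
    else phase_completion_time(sub$time, sub$theta2, 0.001, "down")
  }
  completion(get(probe1)) - completion(get(probe2))
}

#' Milestone report as deterministic JSON
#'
#' @param result a [run_cycle()] result
#' @param path optional output file
#' @return JSON string (invisibly if written to file)
#' @export
milestone_json <- function(result, path = NULL) {
  js <- jsonlite::toJSON(result$milestones, auto_unbox = TRUE, digits = 10,
                         na = "null", pretty = TRUE)
  if (!is.null(path)) { writeLines(js, path); return(invisible(js)) }
  js
}
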