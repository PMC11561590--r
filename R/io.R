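#' Write a field snapshot as a legacy ASCII VTK rectilinear file
#'
#' Cell data written: temperature (degC), liquid fraction `theta2`, and, when
#' a mechanical state is given, von Mises and maximum principal stress (Pa).
#'
#' @param path output file
#' @param grid a [build_grid()] object
#' @param tstate a [thermal_state()]
#' @param mstate optional [mech_state()]
#' @return `path`, invisibly
#' @export
write_vtk_snapshot <- function(path, grid, tstate, mstate = NULL) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  xe <- c(grid$x - grid$dx / 2, utils::tail(grid$x, 1) + grid$dx / 2)
  ye <- c(grid$y - grid$dy / 2, utils::tail(grid$y, 1) + grid$dy / 2)
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("# vtk DataFile Version 3.0")
  w("cryoskin snapshot t=%.4f s", tstate$time)
  w("ASCII")
  w("DATASET RECTILINEAR_GRID")
  w("DIMENSIONS %d %d 1", grid$nx + 1, grid$ny + 1)
  w("X_COORDINATES %d double", grid$nx + 1)
  writeLines(paste(format(xe, digits = 9), collapse = " "), con)
  w("Y_COORDINATES %d double", grid$ny + 1)
  writeLines(paste(format(ye, digits = 9), collapse = " "), con)
  w("Z_COORDINATES 1 double")
  writeLines("0", con)
  w("CELL_DATA %d", grid$n)
  dump_field <- function(name, v) {
    w("SCALARS %s double 1", name)
    w("LOOKUP_TABLE default")
    writeLines(paste(format(v, digits = 9), collapse = "\n"), con)
  }
  dump_field("temperature_C", kelvin_to_celsius(tstate$temperature))
  dump_field("theta2", tstate$theta2)
  if (!is.null(mstate)) {
    cs <- cell_stress(mstate)
    dump_field("von_mises_Pa", von_mises(cs))
    dump_field("max_principal_Pa", max_principal(cs))
  }
  invisible(path)
}

#' Write probe traces and the global trace of a run as CSV
#'
#' Probe trace schema: `time` (s), `probe_id`, `T_C`, `theta2`, and stress
#' columns when the run was coupled.
#'
#' @param result a [run_cycle()] result
#' @param path output CSV file
#' @return `path`, invisibly
#' @export
write_traces_csv <- function(result, path) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(result$traces, path, row.names = FALSE)
  invisible(path)
}

#' Read a thermocouple probe trace from CSV
#'
#' Expected columns: a time column (`time` or `time_s`, seconds) and a
#' temperature column (`T_C` or `temperature_C`, degC).
#'
#' @param path CSV file
#' @return data.frame with columns `time`, `T_C`
#' @export
read_probe_trace <- function(path) {
  d <- utils::read.csv(path)
  tcol <- intersect(c("time", "time_s"), names(d))[1]
  ycol <- intersect(c("T_C", "temperature_C"), names(d))[1]
  if (is.na(tcol) || is.na(ycol))
    stop("trace CSV needs time[_s] and T_C/temperature_C columns")
  data.frame(time = d[[tcol]], T_C = d[[ycol]])
}

#' Material configuration files
#'
#' Plain-text DCF blocks (blank-line separated `Key: value` records), one
#' block per material/phase plus one per-material block for the transition
#' parameters.  Unspecified fields keep their preset defaults.
#'
#' ```
#' Material: solution
#' Phase: 1
#' Density: 960
#' Conductivity: 2.0
#'
#' Material: solution
#' Melt_temperature_C: -2.0
#' Latent_heat: 207000
#' ```
#'
#' Recognised phase fields: `Density`, `Heat_capacity`, `Conductivity`,
#' `Young_modulus`, `Poisson`, `Expansion`, `Maxwell_viscosity`; transition
#' fields: `Melt_temperature_C`, `Transition_half_width`, `Latent_heat`.
#'
#' @param path config file
#' @param base starting materials to override (default [default_materials()])
#' @return `list(solution = , skin = )` of [phase_change_material()]s
#' @export
read_material_config <- function(path, base = default_materials()) {
  blocks <- read.dcf(path)
  phase_fields <- c(Density = "density", Heat_capacity = "heat_capacity",
                    Conductivity = "conductivity",
                    Young_modulus = "young_modulus", Poisson = "poisson",
                    Expansion = "expansion",
                    Maxwell_viscosity = "maxwell_viscosity")
  for (r in seq_len(nrow(blocks))) {
    row <- blocks[r, ]
    row <- row[!is.na(row)]
    matn <- tolower(row[["Material"]])
    if (!matn %in% names(base)) stop("unknown material block: ", matn)
    m <- base[[matn]]
    if ("Phase" %in% names(row)) {
      ph <- paste0("phase", row[["Phase"]])
      stopifnot(ph %in% c("phase1", "phase2"))
      p <- m[[ph]]
      for (key in intersect(names(phase_fields), names(row)))
        p[[phase_fields[[key]]]] <- as.numeric(row[[key]])
      m[[ph]] <- do.call(phase_properties, p[c("density", "heat_capacity",
        "conductivity", "young_modulus", "poisson", "expansion",
        "maxwell_viscosity")])
    } else {
      if ("Melt_temperature_C" %in% names(row))
        m$melt_temperature <- celsius_to_kelvin(as.numeric(row[["Melt_temperature_C"]]))
      if ("Transition_half_width" %in% names(row))
        m$transition_half_width <- as.numeric(row[["Transition_half_width"]])
      if ("Latent_heat" %in% names(row))
        m$latent_heat <- as.numeric(row[["Latent_heat"]])
      m <- phase_change_material(m$phase1, m$phase2, m$melt_temperature,
                                 m$transition_half_width, m$latent_heat,
                                 name = m$name)
    }
    base[[matn]] <- m
  }
  base
}
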