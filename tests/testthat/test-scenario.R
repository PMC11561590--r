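# scaled-down scenario used by the property tests: 10 mm domain, 5 x 1 mm
# skin, faster ramp so transitions complete in a few hundred steps
small_world <- function(n = 20, rate = -10 / 60, t_init = celsius_to_kelvin(4),
                        total = 420) {
  list(grid = build_grid(n, n, extent = c(0.01, 0.01),
                         skin = c(0.005, 0.001)),
       mats = default_materials("BT-2"),
       proto = protocol(list(
         protocol_stage("fast_ramp",
                        bc_dirichlet_ramp(t_init, rate),
                        duration = total, output_interval = 30, dt = 1)),
         initial_temperature = t_init))
}

test_that("protocol constructors encode the stated procedure", {
  p <- standard_cooling_protocol(T_init = celsius_to_kelvin(4))
  ramp_stages <- Filter(function(s) s$bc$kind == "dirichlet_ramp", p$stages)
  expect_equal(sum(vapply(ramp_stages, `[[`, numeric(1), "duration")),
               5040)                             # 84 K at 1 K/min
  expect_equal(boundary_temperature(p$stages[[1]]$bc, 60),
               celsius_to_kelvin(3))
  # boundary temperature continuous up to the stage change
  expect_equal(boundary_temperature(p$stages[[1]]$bc, 5040),
               celsius_to_kelvin(-80))
  ln2 <- p$stages[[length(p$stages)]]
  expect_equal(ln2$bc$bath_temperature, celsius_to_kelvin(-196))
  expect_error(standard_cooling_protocol(T_init = celsius_to_kelvin(-80)),
               "degenerate")
  expect_error(protocol_stage("x", bc_dirichlet_hold(270), duration = 0),
               "zero-length")

  r <- standard_rewarming_protocol()
  expect_equal(boundary_temperature(r$stages[[1]]$bc, c(0, 1e4)),
               rep(celsius_to_kelvin(37), 2))
  expect_equal(r$initial_temperature, celsius_to_kelvin(-196))
})

test_that("cooling run freezes boundary-first with the stated ordering", {
  w <- small_world()
  res <- run_thermal(w$proto, w$grid, w$mats)
  m <- res$milestones
  expect_equal(m$first_onset_region, "boundary")
  expect_lt(m$ice_onset_boundary_s, m$ice_onset_skin_interface_s)
  expect_lt(m$ice_onset_skin_interface_s, m$ice_onset_skin_center_s)
  expect_false(is.na(m$freeze_completion_s))
  expect_lte(m$freeze_completion_s, 420)
  expect_lt(m$energy_drift_fraction, 0.01)
})

test_that("rewarming run melts monotonically and records a positive lag", {
  w <- small_world()
  proto <- protocol(list(
    protocol_stage("bath", bc_convective_bath(celsius_to_kelvin(37), 600),
                   duration = 240, output_interval = 30, dt = 0.5)),
    initial_temperature = celsius_to_kelvin(-60))
  res <- run_cycle(proto, w$grid, w$mats)
  m <- res$milestones
  expect_false(is.na(m$melt_completion_s))
  expect_gt(m$melt_completion_s, 0)
  expect_lte(m$melt_completion_s, 240)
  # heating only: per-cell liquid fraction never decreases (no refreeze)
  expect_equal(res$max_theta2_drop, 0, tolerance = 1e-9)
  expect_equal(res$max_refreeze, 0, tolerance = 1e-9)
  # skin-side probe completes after the free-solution probe
  expect_gt(interface_lag(res), 0)
  # global ice fraction is monotone nonincreasing
  expect_true(all(diff(res$global$ice_fraction) <= 1e-12))
})

test_that("identical configurations give bit-identical milestone reports", {
  w <- small_world(n = 12, total = 150)
  r1 <- run_cycle(w$proto, w$grid, w$mats)
  r2 <- run_cycle(w$proto, w$grid, w$mats)
  expect_identical(as.character(milestone_json(r1)),
                   as.character(milestone_json(r2)))
  expect_identical(r1$final_thermal$temperature, r2$final_thermal$temperature)
})

test_that("interface lag is exact on constructed traces", {
  fake <- list(traces = data.frame(
    time = rep(0:100, 2),
    probe_id = rep(c("Point 1", "Point 2"), each = 101),
    theta2 = c(pmin(pmax((0:100 - 27) / 10, 0), 1),
               pmin(pmax((0:100 - 20) / 10, 0), 1))))
  expect_equal(interface_lag(fake), 7, tolerance = 1e-9)
  same <- fake; same$traces$theta2 <- rep(pmin(pmax((0:100 - 20) / 10, 0), 1), 2)
  expect_equal(interface_lag(same), 0)
  expect_error(interface_lag(fake, "Point 1", "Point 9"), "missing probe")
})

test_that("milestones are stable under grid refinement", {
  w1 <- small_world(n = 24)
  w2 <- small_world(n = 48)
  r1 <- run_thermal(w1$proto, w1$grid, w1$mats)
  r2 <- run_thermal(w2$proto, w2$grid, w2$mats)
  f1 <- r1$milestones$freeze_completion_s
  f2 <- r2$milestones$freeze_completion_s
  expect_lt(abs(f1 - f2) / f2, 0.05)
  o1 <- r1$milestones$ice_onset_s
  o2 <- r2$milestones$ice_onset_s
  expect_lt(abs(o1 - o2) / o2, 0.05)
})

test_that("snapshots and traces round-trip through the writers", {
  w <- small_world(n = 12, total = 60)
  res <- run_cycle(w$proto, w$grid, w$mats, keep_history = TRUE)
  expect_gt(length(res$history), 0)
  td <- file.path(tempdir(), "cryoskin-io-test")
  dir.create(td, showWarnings = FALSE, recursive = TRUE)
  on.exit(unlink(td, recursive = TRUE), add = TRUE)
  f <- write_traces_csv(res, file.path(td, "traces.csv"))
  back <- utils::read.csv(f)
  expect_equal(nrow(back), nrow(res$traces))
  p1 <- back[back$probe_id == "Point 1", ]
  rt <- read_probe_trace(f)  # reads time/T_C columns
  expect_true(all(c("time", "T_C") %in% names(rt)))

  v <- write_vtk_snapshot(file.path(td, "snap.vtk"), w$grid,
                          res$final_thermal, res$final_mech)
  lines <- readLines(v)
  expect_true(any(grepl("RECTILINEAR_GRID", lines)))
  expect_equal(sum(grepl("SCALARS", lines)), 4)
})
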