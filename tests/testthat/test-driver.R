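# Orchestration: configs, short coupled runs, sweeps, bisection scaffolding,
# oracle suite, fixtures, writers.

short_cfg <- function(...) {
  default_config(ablation_time = 40, record_every = 20,
                 domain = list(radius = 0.05, z_min = -0.045,
                               h_fine = 1e-3, h_coarse = 6e-3), ...)
}

test_that("configuration validation and YAML round-trip", {
  cfg <- default_config()
  expect_s3_class(cfg, "simulation_config")
  expect_equal(cfg$frequency, 2.45e9)
  expect_equal(cfg$ablation_time, 600)
  expect_error(default_config(input_power = -2), "non-negative")
  expect_error(default_config(backend = "magic"), "backend")
  expect_error(default_config(dt = 0), "positive")
  f <- tempfile(fileext = ".yaml")
  write_config(default_config(input_power = 9.5, backend = "lte"), f)
  cfg2 <- read_config(f)
  expect_equal(cfg2$input_power, 9.5)
  expect_equal(cfg2$backend, "lte")
  expect_equal(cfg2$tumor$semi_axes, cfg$tumor$semi_axes)
})

test_that("a zero-power run stays at body temperature with zero coverage", {
  rep <- run_simulation(short_cfg(input_power = 0))
  expect_equal(max(abs(rep$state$T_tissue - 37)), 0, tolerance = 1e-10)
  expect_equal(rep$metrics$tumor_coverage[nrow(rep$metrics)], 0)
  expect_equal(length(rep$em_solve_times), 0)
})

test_that("identical configurations reproduce bit-identical reports", {
  cfg <- short_cfg()
  a <- run_simulation(cfg)
  b <- run_simulation(cfg)
  expect_identical(a$metrics, b$metrics)
  expect_identical(a$state$T_tissue, b$state$T_tissue)
  expect_identical(a$state$Omega, b$state$Omega)
})

test_that("a short powered run heats the slot region and accumulates damage", {
  rep <- run_simulation(short_cfg(input_power = 20))
  expect_gt(max(rep$state$T_tissue), 50)
  expect_gt(max(rep$state$Omega), 0)
  expect_true(all(diff(rep$metrics$time) > 0))
  # time series monotonicity of damage-derived metrics
  expect_true(all(diff(rep$metrics$Omega_max) >= 0))
})

test_that("power sweep orders thermal dose with power and validates input", {
  cfg <- short_cfg()
  sw <- power_sweep(cfg, c(5, 25))
  expect_equal(nrow(sw$summary), 2)
  expect_lte(sw$summary$tumor_coverage[1], sw$summary$tumor_coverage[2])
  expect_lt(sw$summary$T_max[1], sw$summary$T_max[2])
  expect_error(power_sweep(cfg, numeric(0)), "at least one")
})

test_that("optimal-power search degenerates and brackets correctly", {
  cfg <- short_cfg()
  res0 <- optimal_power_search(cfg, 5, 30, coverage_target = 0)
  expect_equal(res0$P_opt, 5)
  # a 40 s run cannot fully cover the tumor at either tiny power: bad bracket
  expect_error(optimal_power_search(cfg, 0.01, 0.02, coverage_target = 1),
               "invalid bracket")
})

test_that("the oracle suite passes and degrades under a coarsened integrator", {
  v <- validate()
  expect_true(all(v$pass))
  expect_equal(nrow(v), 8)
  v100 <- validate(arrhenius_dt = 100)
  ramp <- which(v$oracle == "arrhenius_ramp_dt")
  expect_gt(v100$value[ramp], v$value[ramp])  # coarser dt degrades the check
  js <- jsonlite::toJSON(v, auto_unbox = TRUE)  # machine-readable summary
  expect_true(jsonlite::validate(js))
})

test_that("fixtures are seeded, complete and byte-reproducible", {
  d1 <- file.path(tempdir(), "fx_a"); d2 <- file.path(tempdir(), "fx_b")
  unlink(c(d1, d2), recursive = TRUE)
  p1 <- make_fixtures(d1, seed = 7)
  p2 <- make_fixtures(d2, seed = 7)
  expect_equal(length(list.files(d1, "\\.stl$")), 6)   # 3 ellipsoids + 3 lumpy
  expect_equal(length(list.files(d1, "\\.yaml$")), 6)
  same <- mapply(function(a, b)
    identical(readBin(a, "raw", file.size(a)), readBin(b, "raw", file.size(b))),
    sort(list.files(d1, full.names = TRUE)), sort(list.files(d2, full.names = TRUE)))
  expect_true(all(same))
  # different seed changes the lumpy surfaces
  d3 <- file.path(tempdir(), "fx_c")
  make_fixtures(d3, seed = 8)
  lump1 <- readLines(file.path(d1, "tumor_1_lumpy_synthetic.stl"))
  lump3 <- readLines(file.path(d3, "tumor_1_lumpy_synthetic.stl"))
  expect_false(identical(lump1, lump3))
  expect_error(make_fixtures("/proc/definitely/not/writable"), "cannot write")
  # a fixture config drives a surface-mesh run end to end
  cfg <- read_config(file.path(d1, "tumor_2_ellipsoid_config.yaml"))
  expect_equal(cfg$tumor$kind, "surface_mesh")
  geo <- mwablate:::build_geometry(cfg)
  expect_gt(sum(geo$mesh$region == "tumor"), 0)
})

test_that("VTK and CSV writers emit well-formed files", {
  msh <- strip_mesh(L = 0.01, H = 2e-3, nx = 2, nz = 6)
  f <- tempfile(fileext = ".vtk")
  write_vtk(msh, list(temperature = rep(37, nrow(msh$nodes))), f)
  lines <- readLines(f)
  expect_equal(lines[1], "# vtk DataFile Version 3.0")
  expect_true(any(grepl("^POINTS", lines)))
  expect_true(any(grepl("SCALARS temperature double", lines)))
  cfg <- short_cfg(input_power = 0)
  rep <- run_simulation(cfg)
  fcsv <- tempfile(fileext = ".csv")
  write_coverage_csv(rep, fcsv)
  df <- utils::read.csv(fcsv)
  expect_true(all(c("time", "tumor_coverage", "collateral_volume") %in% names(df)))
})
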