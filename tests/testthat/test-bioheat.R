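# Transient bioheat backends: equilibria, analytic oracles, conservation,
# maximum principle, and cross-backend limits.

test_that("uniform body-temperature state is exactly stationary", {
  msh <- strip_mesh(L = 0.02, H = 2e-3, nx = 2, nz = 12)
  for (backend in c("pennes", "lte")) {
    ctx <- thermal_context(msh, backend = backend)
    st <- thermal_state(msh, 37)
    st2 <- switch(backend,
                  pennes = step_pennes(st, 1, 0, 1, ctx),
                  lte = step_lte(st, 1, 0, 1, ctx))
    expect_equal(max(abs(st2$T_tissue - 37)), 0, tolerance = 1e-10)
  }
  ctx <- thermal_context(msh, backend = "ltne")
  st <- step_ltne(thermal_state(msh, 37, blood = TRUE), 1, 0, 1, ctx)
  expect_equal(max(abs(st$T_tissue - 37), abs(st$T_blood - 37)), 0,
               tolerance = 1e-10)
})

test_that("uniform source balances perfusion at the closed-form steady state", {
  msh <- strip_mesh(L = 0.02, H = 2e-3, nx = 2, nz = 12)
  ctx <- thermal_context(msh, backend = "pennes", bc = "insulated")
  perf <- perfusion_model()
  Q <- 5e4
  Tstar <- 37 + Q / (perf$rho_b * perf$omega_b * perf$c_b)
  st <- thermal_state(msh, 37)
  for (k in 1:500) st <- step_pennes(st, 5, Q, 1, ctx)
  expect_equal(max(abs(st$T_tissue - Tstar)) / (Tstar - 37), 0, tolerance = 5e-3)
})

test_that("slab conduction matches the Fourier-series solution within 0.5%", {
  Lz <- 0.02
  msh <- strip_mesh(L = Lz, H = 1e-3, nx = 1, nz = 100)
  props <- default_properties()
  props$perfusion$omega_b <- 0
  ctx <- thermal_context(msh, props, backend = "pennes",
                         dirichlet_tags = c("outer", "port"), bc_value = 37)
  st <- thermal_state(msh, 50)
  mat <- material_lookup("healthy_liver")
  kappa <- mat$thermal_conductivity / (mat$density * mat$specific_heat)
  dt <- 0.25; tend <- 150
  for (k in seq_len(tend / dt)) st <- step_pennes(st, dt, 0, 1, ctx)
  mid <- which(abs(msh$nodes[, 1]) < 1e-12)
  z <- msh$nodes[mid, 2]
  inner <- z > 0.2 * Lz & z < 0.8 * Lz
  ref <- mwablate:::slab_series(z[inner], tend, Lz, kappa, 50, 37)
  expect_lt(max(abs(st$T_tissue[mid][inner] - ref)) / (50 - 37), 5e-3)
})

test_that("enthalpy is conserved under insulated boundaries without sinks", {
  msh <- strip_mesh(L = 0.03, H = 2e-3, nx = 2, nz = 40)
  props <- default_properties()
  props$perfusion$omega_b <- 0
  ctx <- thermal_context(msh, props, backend = "pennes", bc = "insulated")
  z <- msh$nodes[, 2]
  st <- thermal_state(msh, 37 + 20 * exp(-((z - 0.015) / 5e-3)^2))
  enthalpy <- function(s) sum(mwablate:::rhoc_tissue(ctx, s$T_tissue) *
                                ctx$V * s$T_tissue)
  H0 <- enthalpy(st)
  for (k in 1:120) st <- step_pennes(st, 5, 0, 1, ctx)
  expect_lt(abs(enthalpy(st) / H0 - 1), 5e-3)
})

test_that("conduction respects the maximum principle", {
  msh <- strip_mesh(L = 0.03, H = 2e-3, nx = 2, nz = 40)
  props <- default_properties()
  props$perfusion$omega_b <- 0
  ctx <- thermal_context(msh, props, backend = "pennes",
                         dirichlet_tags = c("outer", "port"), bc_value = 37)
  set.seed(11)
  T0 <- runif(nrow(msh$nodes), 37, 80)
  st <- thermal_state(msh, T0)
  lo <- min(T0, 37); hi <- max(T0)
  for (k in 1:60) {
    st <- step_pennes(st, 2, 0, 1, ctx)
    expect_gte(min(st$T_tissue), lo - 1e-9)
    expect_lte(max(st$T_tissue), hi + 1e-9)
  }
})

test_that("LTNE collapses onto LTE as the interfacial coupling stiffens", {
  msh <- strip_mesh(L = 0.03, H = 2e-3, nx = 2, nz = 60)
  z <- msh$nodes[, 2]
  Q <- 2e6 * exp(-((z - 0.015) / 4e-3)^2)
  props_hi <- default_properties(); props_hi$perfusion$h_c_a <- 1e9
  ctx_ltne <- thermal_context(msh, props_hi, backend = "ltne")
  ctx_lte <- thermal_context(msh, default_properties(), backend = "lte")
  sa <- thermal_state(msh, 37, blood = TRUE)
  sb <- thermal_state(msh, 37)
  for (k in 1:60) {
    sa <- step_ltne(sa, 1, Q, 1, ctx_ltne)
    sb <- step_lte(sb, 1, Q, 1, ctx_lte)
  }
  expect_lt(max(abs(sa$T_tissue - sb$T_tissue)) / max(sb$T_tissue - 37), 0.01)
  expect_lt(max(abs(sa$T_tissue - sa$T_blood)), 1e-3)  # phases locked together
})

test_that("LTNE with zero porosity and no exchange leaves the blood phase inert", {
  msh <- strip_mesh(L = 0.02, H = 2e-3, nx = 2, nz = 20)
  props <- default_properties()
  props$perfusion$porosity_eps <- 0
  props$perfusion$h_c_a <- 0
  props$perfusion$omega_b <- 0
  ctx <- thermal_context(msh, props, backend = "ltne")
  z <- msh$nodes[, 2]
  st <- thermal_state(msh, 37, blood = TRUE)
  st$T_blood <- 37 + 5 * sin(z * 100)            # arbitrary uncoupled profile
  Q <- 1e6 * exp(-((z - 0.01) / 3e-3)^2)
  st2 <- st
  for (k in 1:20) st2 <- step_ltne(st2, 1, Q, 1, ctx)
  expect_gt(max(st2$T_tissue), 40)               # tissue heats
  expect_equal(st2$T_blood[ctx$free], st$T_blood[ctx$free], tolerance = 1e-9)
})

test_that("decoupled LTNE phases evolve independently", {
  msh <- strip_mesh(L = 0.02, H = 2e-3, nx = 2, nz = 20)
  props <- default_properties()
  props$perfusion$h_c_a <- 0
  props$perfusion$omega_b <- 0
  ctx <- thermal_context(msh, props, backend = "ltne")
  z <- msh$nodes[, 2]
  run <- function(Tb0) {
    st <- thermal_state(msh, 37, blood = TRUE)
    st$T_blood <- Tb0
    for (k in 1:15) st <- step_ltne(st, 1, 1e6 * exp(-((z - 0.01) / 3e-3)^2), 1, ctx)
    st
  }
  a <- run(rep(37, nrow(msh$nodes)))
  b <- run(37 + 10 * exp(-((z - 0.01) / 2e-3)^2))
  expect_equal(a$T_tissue, b$T_tissue, tolerance = 1e-10)  # blood never feeds back
  expect_false(isTRUE(all.equal(a$T_blood, b$T_blood)))
})

test_that("LTE with zero porosity and velocity reduces to pure conduction", {
  msh <- strip_mesh(L = 0.02, H = 2e-3, nx = 2, nz = 30)
  props <- default_properties()
  props$perfusion$porosity_eps <- 0
  props$perfusion$omega_b <- 0
  ctx_lte <- thermal_context(msh, props, backend = "lte")
  ctx_pen <- thermal_context(msh, props, backend = "pennes")
  z <- msh$nodes[, 2]
  Q <- 1e6 * exp(-((z - 0.01) / 3e-3)^2)
  sa <- thermal_state(msh, 37); sb <- thermal_state(msh, 37)
  for (k in 1:30) {
    sa <- step_lte(sa, 1, Q, 1, ctx_lte)
    sb <- step_pennes(sb, 1, Q, 1, ctx_pen)
  }
  expect_equal(sa$T_tissue, sb$T_tissue, tolerance = 1e-9)
})

test_that("advection of a uniform temperature leaves it unchanged", {
  msh <- strip_mesh(L = 0.02, H = 2e-3, nx = 2, nz = 30)
  props <- default_properties()
  props$perfusion$u <- c(0, 2e-3)
  props$perfusion$omega_b <- 0
  ctx <- suppressWarnings(thermal_context(msh, props, backend = "lte"))
  st <- thermal_state(msh, 42)
  ctx$bc_value <- 42
  st <- step_lte(st, 1, 0, 1, ctx)
  expect_equal(max(abs(st$T_tissue - 42)), 0, tolerance = 1e-9)
})

test_that("small-porosity LTE tracks a conduction-matched Pennes run", {
  msh <- strip_mesh(L = 0.03, H = 2e-3, nx = 2, nz = 60)
  z <- msh$nodes[, 2]
  Q <- 2e6 * exp(-((z - 0.015) / 4e-3)^2)
  props_lte <- default_properties()
  props_lte$perfusion$porosity_eps <- 0.05
  props_pen <- default_properties()
  props_pen$perfusion$omega_b <- 0    # LTE's perfusion lives in its advection term
  ctx_lte <- thermal_context(msh, props_lte, backend = "lte")
  ctx_pen <- thermal_context(msh, props_pen, backend = "pennes")
  sa <- thermal_state(msh, 37); sb <- thermal_state(msh, 37)
  for (k in 1:60) {
    sa <- step_lte(sa, 1, Q, 1, ctx_lte)
    sb <- step_pennes(sb, 1, Q, 1, ctx_pen)
  }
  expect_lt(max(abs(sa$T_tissue - sb$T_tissue)), 1)   # within 1 C max-norm
})
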