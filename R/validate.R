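# ---------------------------------------------------------------------------
# Closed-form verification oracles. Each entry compares a solver output
# against an independent analytic (or brute-force) reference and reports
# the discrepancy with its tolerance.
# ---------------------------------------------------------------------------

# analytic attenuation constant of a plane wave in a lossy medium
plane_wave_alpha <- function(eps_r, sigma, frequency) {
  omega <- 2 * pi * frequency
  k <- (omega / .c0) * sqrt(complex(real = eps_r,
                                    imaginary = -sigma / (omega * .eps0)))
  -Im(k)
}

# slab conduction reference: uniform initial T0, both faces held at Tb
slab_series <- function(z, t, L, kappa, T0, Tb, nmax = 399) {
  n <- seq(1, nmax, by = 2)
  out <- numeric(length(z))
  for (i in seq_along(z)) {
    out[i] <- Tb + (T0 - Tb) * sum(4 / (pi * n) * sin(n * pi * z[i] / L) *
                                     exp(-kappa * (n * pi / L)^2 * t))
  }
  out
}

#' Run the closed-form verification oracle suite
#'
#' Exercises every self-contained analytic check of the package: water-
#' content branch continuity, constant-temperature and ramp Arrhenius
#' integration, plane-wave attenuation of the electromagnetic solver,
#' uniform-equilibrium invariance, the uniform-source perfusion steady
#' state, transient slab conduction against its Fourier series, and the
#' stiff-coupling limit in which the two-temperature model collapses onto
#' the single-temperature porous model.
#'
#' @param arrhenius_dt time step used for the ramp-temperature Arrhenius
#'   check, s (enlarging it degrades that check, which is the point of the
#'   knob).
#' @return A data frame with one row per oracle: `oracle`, `value`
#'   (discrepancy measure), `tolerance`, `pass`. Serializes directly via
#'   [jsonlite::toJSON()].
#' @export
validate <- function(arrhenius_dt = 1) {
  rows <- list()
  add <- function(oracle, value, tolerance)
    rows[[length(rows) + 1]] <<- data.frame(oracle = oracle, value = value,
                                            tolerance = tolerance,
                                            pass = value < tolerance)

  # 1. water-content continuity at the branch joins
  jump <- max(abs(water_content(c(100, 104) - 1e-7) -
                  water_content(c(100, 104) + 1e-7)))
  add("water_content_continuity", jump, 1e-3)

  # 2. constant-temperature Arrhenius vs closed form
  p <- arrhenius_params()
  err <- max(vapply(c(37, 50, 60, 100), function(Tc) {
    Om <- 0
    for (k in 1:600) Om <- accumulate_damage(Om, Tc, 1, p)
    abs(Om / (p$A * 600 * exp(-p$dE / (p$R * (Tc + 273.15)))) - 1)
  }, numeric(1)))
  add("arrhenius_constant_T", err, 1e-3)

  # 3. ramp-temperature Arrhenius vs brute-force fine integration
  ramp <- function(t) 37 + 0.05 * t
  brute <- sum(p$A * exp(-p$dE / (p$R * (ramp(seq(0.005, 600, by = 0.01)) +
                                           273.15)))) * 0.01
  Om <- 0
  for (t in seq(arrhenius_dt, 600, by = arrhenius_dt))
    Om <- accumulate_damage(Om, ramp(t), arrhenius_dt, p)
  add("arrhenius_ramp_dt", abs(Om / brute - 1), 0.02)

  # 4. plane-wave attenuation in homogeneous lossy tissue
  d <- default_dielectric("healthy_liver")
  er <- relative_permittivity(37, d); sg <- electrical_conductivity(37, d)
  alpha_ref <- plane_wave_alpha(er, sg, 2.45e9)
  L <- 0.05
  msh <- strip_mesh(L = L, H = 2e-3, nx = 2, nz = 600)
  fld <- solve_em(msh, 37, default_properties(), frequency = 2.45e9, P_in = 1)
  mid <- which(abs(msh$nodes[, 1] - 1e-3) < 1e-9)
  z <- msh$nodes[mid, 2]
  sel <- z > 0.15 * L & z < 0.7 * L
  fit <- stats::lm(log(Mod(fld$H_phi[mid][sel])) ~ z[sel])
  alpha_num <- -stats::coef(fit)[2]
  add("em_plane_wave_attenuation", abs(alpha_num / alpha_ref - 1), 0.01)

  # 5a. uniform equilibrium is exactly stationary
  msh2 <- strip_mesh(L = 0.02, H = 2e-3, nx = 2, nz = 12)
  ctx <- thermal_context(msh2, backend = "pennes", bc = "insulated")
  st <- thermal_state(msh2, 37)
  st <- step_pennes(st, 1, 0, 1, ctx)
  add("pennes_uniform_equilibrium", max(abs(st$T_tissue - 37)), 1e-9)

  # 5b. uniform-source perfusion steady state
  perf <- perfusion_model()
  Q <- 5e4
  Tstar <- 37 + Q / (perf$rho_b * perf$omega_b * perf$c_b)
  st <- thermal_state(msh2, 37)
  for (k in 1:500) st <- step_pennes(st, 5, Q, 1, ctx)
  add("pennes_perfusion_steady_state",
      max(abs(st$T_tissue - Tstar)) / (Tstar - 37), 5e-3)

  # 6. transient slab conduction vs Fourier series
  Lz <- 0.02
  msh3 <- strip_mesh(L = Lz, H = 1e-3, nx = 1, nz = 100)
  props0 <- default_properties()
  props0$perfusion$omega_b <- 0
  ctx3 <- thermal_context(msh3, props0, backend = "pennes",
                          dirichlet_tags = c("outer", "port"), bc_value = 37)
  st <- thermal_state(msh3, 50)
  mat <- material_lookup("healthy_liver")
  kappa <- mat$thermal_conductivity / (mat$density * mat$specific_heat)
  dt <- 0.25; tend <- 150
  for (k in seq_len(tend / dt)) st <- step_pennes(st, dt, 0, 1, ctx3)
  mid3 <- which(abs(msh3$nodes[, 1]) < 1e-12)
  z3 <- msh3$nodes[mid3, 2]
  inner <- z3 > 0.2 * Lz & z3 < 0.8 * Lz
  ref <- slab_series(z3[inner], tend, Lz, kappa, 50, 37)
  add("pennes_slab_conduction",
      max(abs(st$T_tissue[mid3][inner] - ref)) / (50 - 37), 5e-3)

  # 7. LTNE -> LTE in the stiff interfacial-coupling limit
  msh4 <- strip_mesh(L = 0.03, H = 2e-3, nx = 2, nz = 60)
  z4 <- msh4$nodes[, 2]
  Qblob <- 2e6 * exp(-((z4 - 0.015) / 4e-3)^2)
  props_hi <- default_properties()
  props_hi$perfusion$h_c_a <- 1e9
  ctx_ltne <- thermal_context(msh4, props_hi, backend = "ltne")
  ctx_lte <- thermal_context(msh4, default_properties(), backend = "lte")
  st_a <- thermal_state(msh4, 37, blood = TRUE)
  st_b <- thermal_state(msh4, 37)
  for (k in 1:60) {
    st_a <- step_ltne(st_a, 1, Qblob, 1, ctx_ltne)
    st_b <- step_lte(st_b, 1, Qblob, 1, ctx_lte)
  }
  rise <- max(st_b$T_tissue - 37)
  add("ltne_to_lte_limit", max(abs(st_a$T_tissue - st_b$T_tissue)) / rise, 0.01)

  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
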