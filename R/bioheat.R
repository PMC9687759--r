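# ---------------------------------------------------------------------------
# Transient bioheat solve: Pennes (default), porous-media LTE (single
# temperature) and LTNE (two-temperature) backends. Implicit Euler with
# Picard iteration on temperature-dependent coefficients; lumped heat
# capacity (keeps uniform states exactly stationary and conserves enthalpy
# under insulated boundaries); Cholesky factor reuse across steps.
# ---------------------------------------------------------------------------

#' Perfusion and porous-media parameters
#'
#' Blood perfusion acts as a distributed heat sink toward the 37 C core
#' temperature, scaled by the damage-dependent shutdown coefficient beta.
#' The porous-media backends additionally carry the blood volume fraction
#' (porosity), the lumped interfacial transfer coefficient `h_c_a`, and a
#' constant blood velocity. Values not fixed by the tissue table are
#' literature defaults (external provenance) exposed for configuration.
#'
#' @param omega_b blood perfusion rate, 1/s.
#' @param rho_b,c_b blood density and specific heat.
#' @param T_b_core arterial core temperature, C.
#' @param porosity_eps blood volume fraction in `[0, 1)`.
#' @param h_c_a interfacial heat transfer coefficient times interface area
#'   density, W/(m^3 C) (LTNE).
#' @param u blood velocity vector (r/x, z), m/s (LTE/LTNE advection).
#' @param Q_m constant metabolic heat source, W/m^3 (default 0: negligible
#'   against microwave deposition during ablation).
#' @export
perfusion_model <- function(omega_b = 6.4e-3, rho_b = 1060, c_b = 3600,
                            T_b_core = 37, porosity_eps = 0.2, h_c_a = 2e4,
                            u = c(0, 0), Q_m = 0) {
  if (porosity_eps < 0 || porosity_eps >= 1) stop("porosity must be in [0, 1)")
  if (omega_b < 0 || h_c_a < 0) stop("omega_b and h_c_a must be non-negative")
  structure(list(omega_b = omega_b, rho_b = rho_b, c_b = c_b,
                 T_b_core = T_b_core, porosity_eps = porosity_eps,
                 h_c_a = h_c_a, u = as.numeric(u), Q_m = Q_m),
            class = "perfusion_model")
}

#' Thermal state of the tissue domain
#'
#' @param mesh an `mwa_mesh`.
#' @param T_init initial temperature, C (scalar or per node).
#' @param blood also carry a blood temperature field (LTNE backend).
#' @return An object of class `thermal_state` with per-node tissue (and
#'   optionally blood) temperatures, elapsed time, and the accumulated
#'   Arrhenius damage `Omega`.
#' @export
thermal_state <- function(mesh, T_init = 37, blood = FALSE) {
  n <- nrow(mesh$nodes)
  T0 <- if (length(T_init) == 1) rep(T_init, n) else T_init
  stopifnot(length(T0) == n, all(is.finite(T0)))
  structure(list(T_tissue = T0, T_blood = if (blood) T0 else NULL,
                 time = 0, Omega = rep(0, n)),
            class = "thermal_state")
}

#' @export
print.thermal_state <- function(x, ...) {
  cat(sprintf("<thermal_state> t = %g s, T in [%.1f, %.1f] C, max Omega = %.3g%s\n",
              x$time, min(x$T_tissue), max(x$T_tissue), max(x$Omega),
              if (!is.null(x$T_blood)) sprintf(", blood T in [%.1f, %.1f] C",
                                               min(x$T_blood), max(x$T_blood)) else ""))
  invisible(x)
}

#' Precomputed thermal discretization
#'
#' Builds the finite-element operators for a bioheat backend on the tissue
#' subdomain (tissue, tumor, slot fill and catheter; the antenna interior is
#' excluded, its interface acting through the catheter elements). Outer
#' boundary is Dirichlet at `bc_value` unless `bc = "insulated"`.
#'
#' @param mesh an `mwa_mesh`.
#' @param props property set from [default_properties()].
#' @param backend `"pennes"`, `"lte"` or `"ltne"`.
#' @param vaporization `"effective_heat"` (water-content latent term folded
#'   into the specific heat) or `"enthalpy"` (volumetric heat-capacity spike
#'   across 99-100 C).
#' @param bc `"dirichlet"` or `"insulated"` outer boundary.
#' @param bc_value boundary temperature, C.
#' @param lte_conductivity_form `"consistent"` uses the effective
#'   conductivity `(1-eps) k_t + eps k_b` obtained by summing the
#'   two-phase equations; `"as_printed"` multiplies it by a further
#'   `(1-eps)`.
#' @param dirichlet_tags boundary-edge tags held at `bc_value` (verification
#'   problems may add `"port"` to clamp both ends of a strip).
#' @return An object of class `thermal_context`.
#' @export
thermal_context <- function(mesh, props = default_properties(),
                            backend = c("pennes", "lte", "ltne"),
                            vaporization = c("effective_heat", "enthalpy"),
                            bc = c("dirichlet", "insulated"), bc_value = 37,
                            lte_conductivity_form = c("consistent", "as_printed"),
                            dirichlet_tags = "outer") {
  backend <- match.arg(backend)
  vaporization <- match.arg(vaporization)
  bc <- match.arg(bc)
  lte_conductivity_form <- match.arg(lte_conductivity_form)
  perf <- props$perfusion
  n <- nrow(mesh$nodes)

  solid <- c("healthy_liver", "tumor", "catheter", "slot_fill", "blood")
  el <- which(mesh$region %in% solid)
  if (length(el) == 0) stop("mesh has no thermal (tissue) elements")
  tissue <- mesh$region[el] %in% c("healthy_liver", "tumor", "blood")

  mat_of <- function(reg) switch(reg,
    healthy_liver = material_lookup("healthy_liver"),
    tumor = material_lookup("tumor"),
    blood = material_lookup("blood"),
    material_lookup("antenna_dielectric"))
  mats <- lapply(mesh$region[el], mat_of)
  k_el <- vapply(mats, `[[`, numeric(1), "thermal_conductivity")
  rho_el <- vapply(mats, `[[`, numeric(1), "density")
  c_el <- vapply(mats, `[[`, numeric(1), "specific_heat")
  eps_el <- ifelse(tissue, perf$porosity_eps, 0)

  # nodal quadrature weights and volume-weighted material projections
  w <- if (mesh$coord == "axisymmetric") mesh$rbar[el] else rep(1, length(el))
  contrib <- mesh$area[el] * w / 3
  tt <- mesh$tri[el, , drop = FALSE]
  f <- factor(as.vector(tt), levels = seq_len(n))
  proj <- function(x) as.vector(tapply(rep(contrib * x, 3), f, sum, default = 0))
  V <- proj(rep(1, length(el)))
  act <- which(V > 0)
  sf <- function(x) ifelse(V > 0, x / pmax(V, 1e-300), 0)
  rho_n <- sf(proj(rho_el))
  c_n <- sf(proj(c_el))
  rhoc_n <- sf(proj(rho_el * c_el))
  tis_frac <- sf(proj(as.numeric(tissue)))
  eps_n <- sf(proj(eps_el))

  # conduction operators per backend
  kb <- material_lookup("blood")$thermal_conductivity
  K <- switch(backend,
    pennes = fem_stiffness(mesh, el, k_el),
    lte = {
      keff <- (1 - eps_el) * k_el + eps_el * kb
      if (lte_conductivity_form == "as_printed") keff <- keff * (1 - eps_el)
      fem_stiffness(mesh, el, keff)
    },
    ltne = fem_stiffness(mesh, el, (1 - eps_el) * k_el))
  Kb <- if (backend == "ltne") fem_stiffness(mesh, el, eps_el * kb) else NULL

  # advection operator for the blood/mixture velocity
  A_adv <- NULL
  if (backend %in% c("lte", "ltne") && any(perf$u != 0)) {
    rc_b_liq <- perf$rho_b * perf$c_b
    coef <- eps_el * rc_b_liq
    A_adv <- fem_advection(mesh, el, coef, perf$u)
    h_el <- sqrt(2 * mesh$area[el])
    speed <- sqrt(sum(perf$u^2))
    Pe <- speed * h_el * coef / (2 * pmax((1 - eps_el) * k_el + eps_el * kb, 1e-12))
    if (any(Pe > 2))
      warning(sprintf("advection-dominated cells (max Peclet %.1f); streamline upwinding applied",
                      max(Pe)))
    A_adv <- A_adv + fem_streamline_diffusion(mesh, el, coef * speed * h_el / 2, perf$u)
  }

  dir_nodes <- integer(0)
  if (bc == "dirichlet") {
    oe <- mesh$edges[mesh$edge_tag %in% dirichlet_tags, , drop = FALSE]
    dir_nodes <- intersect(sort(unique(as.vector(oe))), act)
  }
  free <- setdiff(act, dir_nodes)

  structure(list(mesh = mesh, props = props, backend = backend,
                 vaporization = vaporization, bc = bc, bc_value = bc_value,
                 el = el, act = act, free = free, dir = dir_nodes,
                 V = V, rho_n = rho_n, c_n = c_n, rhoc_n = rhoc_n,
                 tis_frac = tis_frac, eps_n = eps_n,
                 K = K, Kb = Kb, A_adv = A_adv, perf = perf,
                 picard_tol = 1e-3, picard_max = 12,
                 cache = new.env(parent = emptyenv())),
            class = "thermal_context")
}

# nodal volumetric heat capacity of the tissue phase, J/(m^3 C)
rhoc_tissue <- function(ctx, T) {
  vc <- ctx$props$vap_consts
  if (ctx$vaporization == "effective_heat") {
    ctx$rhoc_n + ctx$tis_frac * ctx$rho_n * latent_heat_alpha() *
      (-water_content_deriv(T))
  } else {
    spike <- vc$h_fg * vc$C_w_tissue / vc$delta_T
    gas <- vc$rho_g * vc$c_g
    branch <- ifelse(T <= 100 - vc$delta_T, ctx$rhoc_n,
                     ifelse(T <= 100, spike, gas))
    (1 - ctx$tis_frac) * ctx$rhoc_n + ctx$tis_frac * branch
  }
}

# nodal volumetric heat capacity of the blood phase (enthalpy spike), Eq.-12 form
rhoc_blood <- function(ctx, T) {
  vc <- ctx$props$vap_consts
  liq <- ctx$perf$rho_b * ctx$perf$c_b
  spike <- vc$h_fg * vc$C_w_blood / vc$delta_T
  gas <- vc$rho_g * vc$c_g
  ifelse(T <= 100 - vc$delta_T, liq, ifelse(T <= 100, spike, gas))
}

# Solve (Diag(d) + K_extra) x = rhs on free nodes with Dirichlet lift;
# caches the Cholesky symbolic factorization (SPD systems only).
.solve_thermal <- function(ctx, Kmat, d, rhs, Tdir, sym = TRUE, key = "chol") {
  free <- ctx$free; dir <- ctx$dir
  A <- Kmat + Matrix::Diagonal(x = d)
  if (length(dir)) rhs <- rhs - as.vector(Kmat[, dir, drop = FALSE] %*% Tdir)
  Aff <- A[free, free, drop = FALSE]
  bf <- rhs[free]
  if (sym) {
    Asym <- Matrix::forceSymmetric(Aff)
    ch <- ctx$cache[[key]]
    ch <- if (is.null(ch)) Matrix::Cholesky(Asym, LDL = FALSE)
          else tryCatch(Matrix::update(ch, Asym), error = function(e)
            Matrix::Cholesky(Asym, LDL = FALSE))
    ctx$cache[[key]] <- ch
    as.vector(Matrix::solve(ch, bf))
  } else {
    as.vector(Matrix::solve(Aff, bf))
  }
}

#' One implicit step of the Pennes bioheat equation
#'
#' Advances `rho c' dT/dt = div(k grad T) + beta rho_b w_b c_b (T_core - T)
#' + Q_ext + Q_m` by one implicit Euler step with Picard iteration on the
#' temperature-dependent heat capacity (selected vaporization treatment).
#'
#' @param state a [thermal_state()].
#' @param dt time step, s (> 0).
#' @param Q_ext per-node volumetric heat source, W/m^3 (scalar or vector).
#' @param beta per-node perfusion shutdown coefficient in `[0, 1]`.
#' @param ctx a [thermal_context()] built with `backend = "pennes"`.
#' @return the updated `thermal_state`.
#' @export
step_pennes <- function(state, dt, Q_ext, beta, ctx) {
  stopifnot(dt > 0, inherits(ctx, "thermal_context"), ctx$backend == "pennes")
  n <- length(state$T_tissue)
  if (length(Q_ext) == 1) Q_ext <- rep(Q_ext, n)
  if (length(beta) == 1) beta <- rep(beta, n)
  if (any(beta < 0 | beta > 1)) stop("beta must lie in [0, 1]")
  perf <- ctx$perf
  Told <- state$T_tissue
  Tdir <- rep(ctx$bc_value, length(ctx$dir))
  p_diag <- beta * perf$rho_b * perf$omega_b * perf$c_b * ctx$tis_frac * ctx$V
  f0 <- Q_ext * ctx$V + p_diag * perf$T_b_core + perf$Q_m * ctx$tis_frac * ctx$V
  Tn <- Told
  for (it in seq_len(ctx$picard_max)) {
    m <- rhoc_tissue(ctx, Tn) * ctx$V
    d <- m / dt + p_diag
    rhs <- m / dt * Told + f0
    Tnew <- Told
    Tnew[ctx$free] <- .solve_thermal(ctx, ctx$K, d, rhs, Tdir)
    Tnew[ctx$dir] <- ctx$bc_value
    delta <- max(abs(Tnew - Tn))
    Tn <- Tnew
    if (delta < ctx$picard_tol) break
  }
  if (delta >= ctx$picard_tol && max(abs(delta)) > 1)
    warning(sprintf("Picard iteration did not converge (residual %.3g C)", delta))
  state$T_tissue <- Tn
  state$time <- state$time + dt
  state
}

#' One implicit step of the porous-media LTE bioheat equation
#'
#' Single-temperature model with effective heat capacity
#' `(1-eps)(rho c)_t + eps (rho c)_b`, effective conductivity from the
#' two-phase combination, and advection `eps (rho c)_b beta u . grad T`
#' (streamline-upwinded when active).
#'
#' @inheritParams step_pennes
#' @param ctx a [thermal_context()] built with `backend = "lte"`.
#' @export
step_lte <- function(state, dt, Q_ext, beta, ctx) {
  stopifnot(dt > 0, ctx$backend == "lte")
  n <- length(state$T_tissue)
  if (length(Q_ext) == 1) Q_ext <- rep(Q_ext, n)
  if (length(beta) == 1) beta <- rep(beta, n)
  perf <- ctx$perf
  Told <- state$T_tissue
  Tdir <- rep(ctx$bc_value, length(ctx$dir))
  f0 <- Q_ext * ctx$V
  beta_mean <- mean(beta)
  Kop <- ctx$K
  sym <- TRUE
  if (!is.null(ctx$A_adv)) { Kop <- Kop + beta_mean * ctx$A_adv; sym <- FALSE }
  Tn <- Told
  for (it in seq_len(ctx$picard_max)) {
    rc_eff <- (1 - ctx$eps_n) * rhoc_tissue(ctx, Tn) +
      ctx$eps_n * rhoc_blood(ctx, Tn)
    m <- rc_eff * ctx$V
    d <- m / dt
    rhs <- m / dt * Told + f0
    Tnew <- Told
    Tnew[ctx$free] <- .solve_thermal(ctx, Kop, d, rhs, Tdir, sym = sym)
    Tnew[ctx$dir] <- ctx$bc_value
    delta <- max(abs(Tnew - Tn))
    Tn <- Tnew
    if (delta < ctx$picard_tol) break
  }
  state$T_tissue <- Tn
  state$time <- state$time + dt
  state
}

#' One implicit step of the two-temperature LTNE bioheat system
#'
#' Coupled tissue/blood energy equations with interfacial exchange
#' `h_c_a (T_t - T_b)`, perfusion exchange, `(1-eps)/eps` weighting of
#' conduction and source terms, blood-phase advection, and the enthalpy
#' vaporization spike in the blood phase.
#'
#' @inheritParams step_pennes
#' @param ctx a [thermal_context()] built with `backend = "ltne"`.
#' @export
step_ltne <- function(state, dt, Q_ext, beta, ctx) {
  stopifnot(dt > 0, ctx$backend == "ltne")
  n <- length(state$T_tissue)
  if (is.null(state$T_blood)) state$T_blood <- state$T_tissue
  if (length(Q_ext) == 1) Q_ext <- rep(Q_ext, n)
  if (length(beta) == 1) beta <- rep(beta, n)
  perf <- ctx$perf
  Tt0 <- state$T_tissue; Tb0 <- state$T_blood
  free <- ctx$free; dir <- ctx$dir
  Tdir <- rep(ctx$bc_value, length(dir))
  h_diag <- perf$h_c_a * ctx$tis_frac * ctx$V
  p_diag <- beta * perf$rho_b * perf$omega_b * perf$c_b * ctx$tis_frac * ctx$V
  cpl <- h_diag + p_diag
  ft <- (1 - ctx$eps_n) * Q_ext * ctx$V
  fb <- ctx$eps_n * Q_ext * ctx$V
  Kb_op <- ctx$Kb
  if (!is.null(ctx$A_adv)) Kb_op <- Kb_op + mean(beta) * ctx$A_adv
  Tt <- Tt0; Tb <- Tb0
  for (it in seq_len(ctx$picard_max)) {
    mt <- (1 - ctx$eps_n) * rhoc_tissue(ctx, Tt) * ctx$V
    mb <- ctx$eps_n * rhoc_blood(ctx, Tb) * ctx$V
    At <- ctx$K + Matrix::Diagonal(x = mt / dt + cpl)
    Ab <- Kb_op + Matrix::Diagonal(x = mb / dt + cpl)
    # detect inert blood rows (eps = 0 and no exchange): pin to old value
    inert <- (Matrix::diag(Ab) == 0)
    if (any(inert[free])) {
      ii <- which(inert)
      Ab <- Ab + Matrix::sparseMatrix(i = ii, j = ii, x = rep(1, length(ii)),
                                      dims = dim(Ab))
    }
    rt <- mt / dt * Tt0 + ft
    rb <- mb / dt * Tb0 + fb + as.numeric(inert) * Tb0
    if (length(dir)) {
      rt <- rt - as.vector(ctx$K[, dir, drop = FALSE] %*% Tdir)
      rb <- rb - as.vector(Kb_op[, dir, drop = FALSE] %*% Tdir)
    }
    C <- Matrix::Diagonal(x = cpl)
    Aff <- rbind(cbind(At[free, free], -C[free, free]),
                 cbind(-C[free, free], Ab[free, free]))
    bf <- c(rt[free] + if (length(dir)) 0 else 0, rb[free])
    x <- as.vector(Matrix::solve(Aff, bf))
    nf <- length(free)
    Tt_new <- Tt0; Tb_new <- Tb0
    Tt_new[free] <- x[1:nf]; Tb_new[free] <- x[nf + 1:nf]
    Tt_new[dir] <- ctx$bc_value; Tb_new[dir] <- ctx$bc_value
    delta <- max(abs(Tt_new - Tt), abs(Tb_new - Tb))
    Tt <- Tt_new; Tb <- Tb_new
    if (delta < ctx$picard_tol) break
  }
  state$T_tissue <- Tt
  state$T_blood <- Tb
  state$time <- state$time + dt
  state
}
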