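# ---------------------------------------------------------------------------
# Orchestration: coupled EM-thermal-damage time loop, power/time sweeps,
# optimal-power bisection, fixtures.
# ---------------------------------------------------------------------------

build_geometry <- function(cfg) {
  antenna <- do.call(build_antenna, cfg$antenna)
  tumor <- if (identical(cfg$tumor$kind, "ellipsoid")) {
    make_ellipsoid_tumor(cfg$tumor$semi_axes, cfg$tumor$center)
  } else if (identical(cfg$tumor$kind, "surface_mesh")) {
    load_tumor_surface(cfg$tumor$surface_path, center_z = cfg$tumor$center[3])
  } else if (is.null(cfg$tumor) || identical(cfg$tumor$kind, "none")) {
    NULL
  } else stop("unknown tumor kind: ", cfg$tumor$kind)
  mesh <- generate_mesh(antenna, tumor, domain_radius = cfg$domain$radius,
                        z_min = cfg$domain$z_min, h_fine = cfg$domain$h_fine,
                        h_coarse = cfg$domain$h_coarse)
  list(antenna = antenna, tumor = tumor, mesh = mesh)
}

#' Run a coupled microwave-ablation simulation
#'
#' Alternates the frequency-domain electromagnetic solve with implicit
#' bioheat stepping and Arrhenius damage accumulation. The field is
#' re-solved whenever the temperature anywhere has drifted more than
#' `em_recouple_dT` degrees since the last solve, or after
#' `em_recouple_dt` seconds of simulated time, whichever comes first
#' (the dielectric sigmoids change slowly except near vaporization).
#' Perfusion shuts down per the damage-dependent beta model.
#'
#' @param cfg a `simulation_config` from [default_config()] /
#'   [read_config()].
#' @param mesh optionally, a prebuilt mesh (reused across sweep runs).
#' @param progress print per-record progress lines.
#' @return An object of class `ablation_report`: a `metrics` data frame
#'   (time series of tumor coverage, collateral volume, lethal-isotherm
#'   volume, peak temperature, |S11|), final `state`, nodal `Q_ext`, the
#'   mesh, the config echo, and EM re-solve diagnostics.
#' @export
run_simulation <- function(cfg, mesh = NULL, progress = FALSE) {
  cfg <- validate_config(unclass(cfg))
  if (is.null(mesh)) {
    geo <- build_geometry(cfg)
    mesh <- geo$mesh
  }
  props <- default_properties(cfg)
  ctx <- thermal_context(mesh, props, backend = cfg$backend,
                         vaporization = cfg$vaporization)
  state <- thermal_state(mesh, 37, blood = cfg$backend == "ltne")
  step_fun <- switch(cfg$backend, pennes = step_pennes, lte = step_lte,
                     ltne = step_ltne)
  n <- nrow(mesh$nodes)
  nsteps <- ceiling(cfg$ablation_time / cfg$dt)
  rec_steps <- max(1L, round(cfg$record_every / cfg$dt))

  em_times <- numeric(0)
  s11_trace <- complex(0)
  Q_ext <- rep(0, n)
  T_at_em <- state$T_tissue
  s11 <- NA_complex_

  resolve_em <- function(Tnow) {
    fld <- solve_em(mesh, Tnow, props, frequency = cfg$frequency,
                    P_in = cfg$input_power)
    sar <- compute_sar(fld, mesh)
    list(Q = sar$Q_ext, s11 = fld$port_reflection)
  }
  if (cfg$input_power > 0) {
    em <- resolve_em(state$T_tissue)
    Q_ext <- em$Q; s11 <- em$s11
    em_times <- 0; s11_trace <- s11
  }

  has_tumor <- any(mesh$region == "tumor")
  rec <- list()
  record <- function(state) {
    cv <- if (has_tumor) coverage(state$Omega, mesh, T = state$T_tissue)
          else list(tumor_coverage = NA_real_, collateral_volume = NA_real_,
                    lethal_isotherm_volume = superlevel_volume(mesh, state$T_tissue, 60))
    data.frame(time = state$time,
               tumor_coverage = cv$tumor_coverage,
               collateral_volume = cv$collateral_volume,
               lethal_isotherm_volume = cv$lethal_isotherm_volume,
               T_max = max(state$T_tissue),
               Omega_max = max(state$Omega),
               s11_mod = Mod(s11))
  }
  rec[[1]] <- record(state)
  t_last_em <- 0

  for (k in seq_len(nsteps)) {
    beta <- perfusion_beta(state$Omega, cfg$beta_model)
    state <- step_fun(state, cfg$dt, Q_ext, beta, ctx)
    state$Omega <- accumulate_damage(state$Omega, state$T_tissue, cfg$dt,
                                     props$arrhenius)
    if (cfg$input_power > 0 &&
        (max(abs(state$T_tissue - T_at_em)) > cfg$em_recouple_dT ||
         state$time - t_last_em >= cfg$em_recouple_dt) && k < nsteps) {
      em <- resolve_em(state$T_tissue)
      Q_ext <- em$Q; s11 <- em$s11
      T_at_em <- state$T_tissue
      t_last_em <- state$time
      em_times <- c(em_times, state$time)
      s11_trace <- c(s11_trace, s11)
    }
    if (k %% rec_steps == 0 || k == nsteps) {
      rec[[length(rec) + 1]] <- record(state)
      if (progress)
        cat(sprintf("t = %5.0f s  Tmax = %6.1f C  coverage = %s\n", state$time,
                    max(state$T_tissue),
                    if (has_tumor) sprintf("%.3f", rec[[length(rec)]]$tumor_coverage) else "-"))
    }
  }
  metrics <- do.call(rbind, rec)
  report <- structure(list(metrics = metrics, state = state, Q_ext = Q_ext,
                           mesh = mesh, config = cfg,
                           em_solve_times = em_times, s11_trace = s11_trace),
                      class = "ablation_report")
  if (!is.null(cfg$output$csv_path)) write_coverage_csv(report, cfg$output$csv_path)
  if (!is.null(cfg$output$vtk_dir)) {
    dir.create(cfg$output$vtk_dir, showWarnings = FALSE, recursive = TRUE)
    write_vtk(mesh, list(temperature = state$T_tissue, Omega = state$Omega,
                         necrotic_fraction = necrotic_fraction(state$Omega),
                         Q_ext = Q_ext),
              file.path(cfg$output$vtk_dir,
                        sprintf("fields_t%06.0f.vtk", state$time)))
  }
  report
}

#' @export
print.ablation_report <- function(x, ...) {
  fin <- x$metrics[nrow(x$metrics), ]
  cat(sprintf(paste0("<ablation_report> %s backend, P = %g W, t = %g s: ",
                     "coverage %.3f, collateral %.2f cm^3, Tmax %.1f C, ",
                     "%d EM solves\n"),
              x$config$backend, x$config$input_power, fin$time,
              fin$tumor_coverage, 1e6 * fin$collateral_volume, fin$T_max,
              length(x$em_solve_times)))
  invisible(x)
}

#' Sweep the input power
#'
#' Independent full simulations at each power on a shared mesh, with a
#' summary table of end-of-run coverage and collateral damage versus power.
#'
#' @param cfg a `simulation_config`.
#' @param powers numeric vector of input powers, W (at least one).
#' @return list with `reports` (one `ablation_report` per power) and
#'   `summary` (data frame).
#' @export
power_sweep <- function(cfg, powers) {
  if (length(powers) < 1) stop("powers must contain at least one value")
  cfg <- validate_config(unclass(cfg))
  geo <- build_geometry(cfg)
  reports <- lapply(powers, function(p) {
    ci <- cfg; ci$input_power <- p
    run_simulation(validate_config(unclass(ci)), mesh = geo$mesh)
  })
  summary <- do.call(rbind, lapply(seq_along(powers), function(i) {
    fin <- reports[[i]]$metrics[nrow(reports[[i]]$metrics), ]
    data.frame(power = powers[i], tumor_coverage = fin$tumor_coverage,
               collateral_volume = fin$collateral_volume,
               lethal_isotherm_volume = fin$lethal_isotherm_volume,
               T_max = fin$T_max)
  }))
  list(reports = reports, summary = summary)
}

#' Bisection search for the optimal input power
#'
#' The optimal power is the smallest input power whose end-of-run tumor
#' coverage reaches the target (complete ablation by default) -- treating
#' the entire tumor while minimizing collateral damage, which increases
#' monotonically with power. Bisection exploits the monotone
#' coverage-versus-power map.
#'
#' @param cfg a `simulation_config`.
#' @param p_lo,p_hi bracketing powers, W: coverage(p_lo) must be below the
#'   target and coverage(p_hi) at or above it.
#' @param coverage_target target tumor coverage in `[0, 1]`.
#' @param tol_W power tolerance, W.
#' @return list with `P_opt` (W), `trace` (data frame of evaluated powers
#'   and coverages) and `reports` at the bracket ends.
#' @export
optimal_power_search <- function(cfg, p_lo, p_hi, coverage_target = 1.0,
                                 tol_W = 0.5) {
  cfg <- validate_config(unclass(cfg))
  if (coverage_target <= 0)
    return(list(P_opt = p_lo, trace = data.frame(power = numeric(0),
                                                 coverage = numeric(0))))
  geo <- build_geometry(cfg)
  eval_cov <- function(p) {
    ci <- cfg; ci$input_power <- p
    rep <- run_simulation(validate_config(unclass(ci)), mesh = geo$mesh)
    rep$metrics$tumor_coverage[nrow(rep$metrics)]
  }
  trace <- data.frame(power = numeric(0), coverage = numeric(0))
  note <- function(p, cv) trace <<- rbind(trace, data.frame(power = p, coverage = cv))
  cl <- eval_cov(p_lo); note(p_lo, cl)
  ch <- eval_cov(p_hi); note(p_hi, ch)
  if (!(cl < coverage_target && ch >= coverage_target))
    stop(sprintf(paste0("invalid bracket: coverage(%g W) = %.3f, coverage(%g W) = %.3f ",
                        "do not straddle the target %.3f"),
                 p_lo, cl, p_hi, ch, coverage_target))
  while (p_hi - p_lo > tol_W) {
    pm <- (p_lo + p_hi) / 2
    cm <- eval_cov(pm); note(pm, cm)
    if (cm >= coverage_target) p_hi <- pm else p_lo <- pm
  }
  list(P_opt = p_hi, trace = trace)
}

#' Write synthetic tumor fixtures
#'
#' Writes triangulated ellipsoid tumor surfaces at the emulated
#' patient-tumor extents (1.64 x 1.71 x 3.81, 1.74 x 1.53 x 2.10 and
#' 1.78 x 1.97 x 2.27 cm), a seeded "lumpy" perturbed variant of each
#' (synthetic stand-ins for segmented patient geometry), and a matching
#' configuration file per surface.
#'
#' @param out_dir writable output directory (created if missing).
#' @param seed integer seed for the lumpy perturbations.
#' @return invisibly, the vector of written file paths.
#' @export
make_fixtures <- function(out_dir, seed = 1) {
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!ok || file.access(out_dir, 2) != 0)
    stop("cannot write fixtures to ", out_dir)
  extents_cm <- list(c(1.64, 1.71, 3.81), c(1.74, 1.53, 2.10), c(1.78, 1.97, 2.27))
  paths <- character(0)
  for (i in seq_along(extents_cm)) {
    ax <- extents_cm[[i]] * 1e-2 / 2
    base <- file.path(out_dir, sprintf("tumor_%d_ellipsoid.stl", i))
    lump <- file.path(out_dir, sprintf("tumor_%d_lumpy_synthetic.stl", i))
    write_surface_stl(ellipsoid_surface(ax, center = c(0, 0, 0.0096), subdiv = 3), base)
    write_surface_stl(ellipsoid_surface(ax, center = c(0, 0, 0.0096), subdiv = 3,
                                        lumpy_amplitude = 0.05, seed = seed + i), lump)
    for (p in c(base, lump)) {
      cfgp <- sub("\\.stl$", "_config.yaml", p)
      # surface path stored relative to the config file for portable fixtures
      cfg <- default_config(tumor = list(kind = "surface_mesh",
                                         semi_axes = NULL,
                                         surface_path = basename(p),
                                         center = c(0, 0, 0.0096)),
                            rng_seed = seed)
      write_config(cfg, cfgp)
      paths <- c(paths, p, cfgp)
    }
  }
  invisible(paths)
}
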