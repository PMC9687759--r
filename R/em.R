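# ---------------------------------------------------------------------------
# Frequency-domain electromagnetic solve: axisymmetric azimuthal-magnetic-
# field (TM) formulation of the Helmholtz problem for a coaxial applicator.
#
# Physics (e^{+j w t} phasors, peak amplitudes): the field equation
#   curl((1/et) curl H) - k0^2 mu_r H = 0,  et = eps_r - j sigma/(w eps0),
# reduces for H = H_phi(r, z) phi-hat to a scalar problem. The solver works
# in the scaled unknown w = r * H_phi, for which the weak form is
#   int (1/et) grad(w).grad(x) (1/r) dA - k0^2 mu_r int w x (1/r) dA
#     + j k0 sqrt(mu_r/et) int_abs  w x / r ds
#     + j k0 sqrt(mu_r/et_d) int_port w x / r ds
#   = 2 j k0 sqrt(mu_r/et_d) int_port (r H0) x / r ds,
# with H0 = C/r the incident TEM coax mode normalized so its time-averaged
# power equals P_in (so r H0 = C is exactly representable: the scaling
# removes the spurious modes a direct H_phi discretization suffers from).
# A first-order absorbing condition closes the outer boundary; perfect
# conductors are the natural (do-nothing) condition; w = 0 on the axis.
# Cartesian verification strips solve the plain H formulation (weight 1).
# ---------------------------------------------------------------------------

.eps0 <- 8.8541878128e-12
.mu0 <- 4e-7 * pi
.c0 <- 299792458
.eta0 <- sqrt(.mu0 / .eps0)

# complex permittivity per element from nodal temperature and region tags
element_permittivity <- function(mesh, T, props, omega) {
  Tm <- if (length(T) == 1) rep(T, nrow(mesh$tri)) else
    rowMeans(matrix(T[mesh$tri], ncol = 3))
  er <- rep(1, nrow(mesh$tri)); sg <- numeric(nrow(mesh$tri))
  for (reg in unique(mesh$region)) {
    d <- props$dielectrics[[reg]]
    if (is.null(d)) next
    sel <- mesh$region == reg
    er[sel] <- relative_permittivity(Tm[sel], d)
    sg[sel] <- electrical_conductivity(Tm[sel], d)
  }
  complex(real = er, imaginary = -sg / (omega * .eps0))
}

#' Solve the electromagnetic field of the slotted coaxial antenna
#'
#' Solves the axisymmetric scalar reduction of the frequency-domain field
#' equation in the azimuthal magnetic field, with a TEM coaxial port whose
#' inflowing time-averaged power equals `P_in`, a first-order absorbing
#' condition on the outer boundary, and perfect-conductor (natural)
#' conditions on metal. Dielectric properties are evaluated from the
#' current temperature field through the sigmoidal models, so the
#' deposition pattern follows the evolving tissue state. The solution
#' scales as `sqrt(P_in)`.
#'
#' @param mesh an `mwa_mesh`.
#' @param T nodal temperature field, degrees C (or a scalar).
#' @param props property set from [default_properties()].
#' @param frequency operating frequency, Hz.
#' @param P_in input power, W.
#' @return An object of class `em_field`: complex `H_phi` per node,
#'   per-element electric fields and volumetric heat source `Q_ext_el`
#'   (W/m^3), port reflection coefficient, and power-balance diagnostics.
#' @export
solve_em <- function(mesh, T = 37, props = default_properties(),
                     frequency = 2.45e9, P_in = 13) {
  if (P_in < 0) stop("input power must be non-negative")
  omega <- 2 * pi * frequency
  k0 <- omega / .c0
  n <- nrow(mesh$nodes)
  el <- which(mesh$region != "antenna_metal")
  axisym <- mesh$coord == "axisymmetric"

  et <- element_permittivity(mesh, T, props, omega)
  inv_et <- 1 / et[el]

  if (axisym) {
    Sr <- fem_stiffness_invr(mesh, el, Re(inv_et))
    Si <- fem_stiffness_invr(mesh, el, Im(inv_et))
    Mr <- fem_mass_invr(mesh, el, k0^2 * props$mu_r)
  } else {
    Sr <- fem_stiffness(mesh, el, Re(inv_et))
    Si <- fem_stiffness(mesh, el, Im(inv_et))
    Mr <- fem_mass(mesh, el, k0^2 * props$mu_r)
  }

  # boundary terms -----------------------------------------------------------
  port_idx <- which(mesh$edge_tag == "port")
  abs_idx <- which(mesh$edge_tag == "outer")
  if (length(port_idx) == 0) stop("mesh has no port edges")
  eadj <- edge_elements(mesh, abs_idx)
  keep <- eadj %in% el
  abs_idx <- abs_idx[keep]; eadj <- eadj[keep]

  g_port <- 1i * k0 * sqrt(props$mu_r / et[edge_elements(mesh, port_idx[1])])
  g_abs <- 1i * k0 * sqrt(props$mu_r / et[eadj])
  if (axisym) {
    Bp <- edge_mass_invr(mesh, port_idx, 1, n)
    Ba_r <- edge_mass_invr(mesh, abs_idx, Re(g_abs), n)
    Ba_i <- edge_mass_invr(mesh, abs_idx, Im(g_abs), n)
  } else {
    Bp <- edge_mass(mesh, port_idx, 1, n)
    Ba_r <- edge_mass(mesh, abs_idx, Re(g_abs), n)
    Ba_i <- edge_mass(mesh, abs_idx, Im(g_abs), n)
  }

  Ar <- Sr - Mr + Re(g_port) * Bp + Ba_r
  Ai <- Si + Im(g_port) * Bp + Ba_i

  # port excitation ----------------------------------------------------------
  e <- mesh$edges[port_idx, , drop = FALSE]
  p <- mesh$nodes
  if (axisym) {
    a <- mesh$antenna$inner_conductor_radius
    b <- mesh$antenna$dielectric_outer_radius
    er_d <- Re(et[edge_elements(mesh, port_idx[1])])
    Zd <- .eta0 * sqrt(props$mu_r / er_d)
    C <- sqrt(P_in / (pi * Zd * log(b / a)))      # H0 = C / r
    bvec <- 2 * g_port * C * edge_load_invr(mesh, port_idx, 1, n)
  } else {
    C <- sqrt(P_in)
    L <- sqrt((p[e[, 1], 1] - p[e[, 2], 1])^2 + (p[e[, 1], 2] - p[e[, 2], 2])^2)
    bvec <- complex(real = numeric(n))
    for (kk in 1:2) {
      idx <- e[, kk]
      bvec[idx] <- bvec[idx] + 2 * g_port * C * L / 2
    }
  }

  # Dirichlet: w = 0 on the symmetry axis; inactive nodes pinned to 0
  act <- sort(unique(as.vector(mesh$tri[el, ])))
  axis_nodes <- if (axisym) which(abs(mesh$nodes[, 1]) < 1e-12) else integer(0)
  dir_nodes <- sort(unique(c(axis_nodes, setdiff(seq_len(n), act))))
  dr <- apply_dirichlet(Ar, Re(bvec), dir_nodes, rep(0, length(dir_nodes)))
  di <- apply_dirichlet(Ai, Im(bvec), dir_nodes, rep(0, length(dir_nodes)))
  di$A[cbind(dir_nodes, dir_nodes)] <- 0

  w <- solve_complex(dr$A, di$A, complex(real = dr$b, imaginary = di$b))
  if (any(!is.finite(Re(w)))) stop("EM solve failed (singular system)")

  rnode <- mesh$nodes[, 1]
  H_phi <- if (axisym) ifelse(rnode > 1e-12, w / rnode, 0) else w

  # port reflection: project (H_phi - H0) on the TEM mode --------------------
  pn <- sort(unique(as.vector(e)))
  if (axisym) {
    rp <- p[pn, 1]
    ord <- order(rp); pn <- pn[ord]; rp <- rp[ord]
    g <- (w[pn] - C) / rp                          # (H - H0) = (w - C)/r
    num <- sum(diff(rp) * (utils::head(g, -1) + utils::tail(g, -1)) / 2)
    s11 <- num / (C * log(b / a))
  } else {
    s11 <- mean(w[pn] / C) - 1
  }

  # element electric fields and dissipation ----------------------------------
  tt <- mesh$tri[el, , drop = FALSE]
  wn <- matrix(w[tt], ncol = 3)
  dwdr <- rowSums(wn * mesh$gb[el, , drop = FALSE])
  dwdz <- rowSums(wn * mesh$gc[el, , drop = FALSE])
  jwe <- 1i * omega * .eps0 * et[el]
  if (axisym) {
    rb <- mesh$rbar[el]
    Er <- -(dwdz / rb) / jwe
    Ez <- (dwdr / rb) / jwe
  } else {
    Er <- -dwdz / jwe
    Ez <- dwdr / jwe
  }
  E2 <- Mod(Er)^2 + Mod(Ez)^2
  sig_el <- -Im(et[el]) * omega * .eps0
  Q_el <- sig_el * E2 / 2                # W/m^3, peak-phasor convention

  wgt <- if (axisym) 2 * pi * mesh$rbar[el] else 1
  P_abs <- sum(Q_el * mesh$area[el] * wgt)
  eabs <- mesh$edges[abs_idx, , drop = FALSE]
  Labs <- sqrt((p[eabs[, 1], 1] - p[eabs[, 2], 1])^2 +
               (p[eabs[, 1], 2] - p[eabs[, 2], 2])^2)
  u2_edge <- (Mod(H_phi[eabs[, 1]])^2 + Mod(H_phi[eabs[, 2]])^2) / 2
  r_edge <- if (axisym) (p[eabs[, 1], 1] + p[eabs[, 2], 1]) / 2 else
    1 / (2 * pi)
  eta_loc <- .eta0 * sqrt(props$mu_r / et[eadj])
  P_rad <- sum(2 * pi * r_edge * Labs * 0.5 * Re(eta_loc) * u2_edge)

  structure(list(H_phi = H_phi, w = w, frequency = frequency,
                 input_power = P_in,
                 port_reflection = s11, elements = el,
                 E_r = Er, E_z = Ez, E2 = E2,
                 sigma_el = sig_el, Q_ext_el = Q_el,
                 P_absorbed = P_abs, P_radiated = P_rad,
                 P_reflected = Mod(s11)^2 * P_in,
                 mesh_signature = c(nrow(mesh$nodes), nrow(mesh$tri))),
            class = "em_field")
}

#' @export
print.em_field <- function(x, ...) {
  cat(sprintf(paste0("<em_field> f = %.3g GHz, P_in = %g W, |S11| = %.3f, ",
                     "absorbed %.2f W, radiated (outer) %.3f W\n"),
              x$frequency / 1e9, x$input_power, Mod(x$port_reflection),
              x$P_absorbed, x$P_radiated))
  invisible(x)
}

#' Specific absorption rate and volumetric heat source
#'
#' Converts a solved field into the per-node specific absorption rate
#' SAR = sigma |E|^2 / (2 rho) (W/kg, peak-phasor convention) and the
#' volumetric source Q_ext = sigma |E|^2 / 2 = SAR * rho (W/m^3).
#' Element values are projected to nodes by volume-weighted averaging.
#'
#' @param field an `em_field` from [solve_em()].
#' @param mesh the mesh the field was solved on.
#' @param rho per-node density, kg/m^3; defaults to the material table by
#'   region (element densities projected to nodes).
#' @return An object of class `sar_field` with nodal `sar` and `Q_ext`.
#' @export
compute_sar <- function(field, mesh, rho = NULL) {
  if (!all(field$mesh_signature == c(nrow(mesh$nodes), nrow(mesh$tri))))
    stop("field was solved on a different mesh")
  el <- field$elements
  n <- nrow(mesh$nodes)
  w <- if (mesh$coord == "axisymmetric") mesh$rbar[el] else rep(1, length(el))
  contrib <- mesh$area[el] * w / 3
  tt <- mesh$tri[el, , drop = FALSE]
  f <- factor(as.vector(tt), levels = seq_len(n))
  vol_n <- as.vector(tapply(rep(contrib, 3), f, sum, default = 0))
  Q_n <- as.vector(tapply(rep(contrib * field$Q_ext_el, 3), f, sum, default = 0))
  Q_n <- ifelse(vol_n > 0, Q_n / pmax(vol_n, 1e-300), 0)
  if (is.null(rho)) {
    rho_el <- vapply(mesh$region[el], function(rg)
      switch(rg, healthy_liver = , tumor = , blood = material_lookup(rg)$density,
             material_lookup("antenna_dielectric")$density), numeric(1))
    r_n <- as.vector(tapply(rep(contrib * rho_el, 3), f, sum, default = 0))
    rho <- ifelse(vol_n > 0, r_n / pmax(vol_n, 1e-300), 1000)
  }
  structure(list(sar = Q_n / rho, Q_ext = Q_n, rho = rho,
                 mesh_signature = field$mesh_signature),
            class = "sar_field")
}

#' Port reflection coefficient of a solved field
#'
#' @param field an `em_field`.
#' @return complex S11; its modulus cannot exceed 1 in passive media.
#' @export
port_reflection <- function(field) field$port_reflection

#' Power balance diagnostics of a solved field
#'
#' @param field an `em_field`.
#' @return list with absorbed, radiated, reflected power and their sum
#'   relative to the input power.
#' @export
em_power_balance <- function(field) {
  tot <- field$P_absorbed + field$P_radiated + field$P_reflected
  list(P_in = field$input_power, absorbed = field$P_absorbed,
       radiated = field$P_radiated, reflected = field$P_reflected,
       balance = tot / field$input_power)
}
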