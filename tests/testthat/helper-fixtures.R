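# Shared fixtures built in code. Heavy objects are cached per session.

.shared <- new.env(parent = emptyenv())

# default-size antenna mesh + 37 C field solve, built once
default_antenna_mesh <- function() {
  if (is.null(.shared$mesh)) {
    ant <- build_antenna()
    tum <- make_ellipsoid_tumor(c(1.64, 1.71, 3.81) * 1e-2 / 2)
    .shared$mesh <- generate_mesh(ant, tum)
  }
  .shared$mesh
}

default_em_field <- function() {
  if (is.null(.shared$field))
    .shared$field <- solve_em(default_antenna_mesh(), 37, P_in = 13)
  .shared$field
}

# reduced problem size for end-to-end runs (stated in the methods vignette)
coarse_config <- function(...) {
  default_config(domain = list(radius = 0.05, z_min = -0.045,
                               h_fine = 8e-4, h_coarse = 5e-3), ...)
}

# straight coax section: uniform PTFE-like dielectric, port at z = L;
# bottom boundary either absorbing ("outer", a matched termination) or the
# natural PEC condition ("wall", a short circuit)
make_coax_mesh <- function(nr = 12, nz = 200, bottom = "outer") {
  a <- 1.5e-4; b <- 5e-4; L <- 0.03
  rc <- seq(a, b, length.out = nr)
  zc <- seq(0, L, length.out = nz)
  tt <- mwablate:::tensor_triangulate(rc, zc)
  msh <- list(nodes = tt$nodes, tri = tt$tri, coord = "axisymmetric")
  msh <- mwablate:::mesh_precompute(msh)
  msh$region <- rep("antenna_dielectric", nrow(msh$tri))
  edges <- mwablate:::boundary_edges_tensor(tt$nr, tt$nz)
  p <- msh$nodes
  z1 <- p[edges[, 1], 2]; z2 <- p[edges[, 2], 2]
  tag <- rep("wall", nrow(edges))
  tag[z1 < 1e-12 & z2 < 1e-12] <- bottom
  tag[abs(z1 - L) < 1e-12 & abs(z2 - L) < 1e-12] <- "port"
  msh$edges <- edges
  msh$edge_tag <- tag
  msh$antenna <- list(inner_conductor_radius = a, dielectric_outer_radius = b)
  class(msh) <- "mwa_mesh"
  msh
}

liver_plane_wave_alpha <- function(frequency = 2.45e9, T = 37) {
  d <- default_dielectric("healthy_liver")
  er <- relative_permittivity(T, d)
  sg <- electrical_conductivity(T, d)
  omega <- 2 * pi * frequency
  k <- (omega / 299792458) *
    sqrt(complex(real = er, imaginary = -sg / (omega * 8.8541878128e-12)))
  -Im(k)
}
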