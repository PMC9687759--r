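# ---------------------------------------------------------------------------
# Graded tensor-product triangulation of the axisymmetric (r, z) domain with
# material-region and boundary tagging. Coordinate lines are forced onto
# every material interface (coax radii, slot edges, tip cap) so elements
# never straddle a discontinuity.
# ---------------------------------------------------------------------------

# One graded coordinate axis: mandatory points are always included; between
# them the local spacing is the minimum over refinement windows of
# h_window + growth * distance-to-window, capped at h_coarse.
graded_axis <- function(mandatory, windows, h_coarse, growth = 0.35) {
  local_h <- function(x) {
    h <- rep(h_coarse, length(x))
    for (w in windows) {
      d <- pmax(0, pmax(w[1] - x, x - w[2]))
      h <- pmin(h, w[3] + growth * d)
    }
    h
  }
  mandatory <- sort(unique(mandatory))
  pts <- numeric(0)
  for (k in seq_len(length(mandatory) - 1)) {
    a <- mandatory[k]; b <- mandatory[k + 1]
    seg <- a
    x <- a
    while (x < b - 1e-12) {
      x <- x + local_h(x)
      seg <- c(seg, min(x, b))
    }
    # rescale the marched points so the last lands exactly on b
    if (length(seg) > 2) {
      seg <- a + (seg - a) * (b - a) / (seg[length(seg)] - a)
    } else seg <- c(a, b)
    pts <- c(pts, seg[-length(seg)])
  }
  c(pts, mandatory[length(mandatory)])
}

# Split a tensor grid of coordinates into triangles (two per quad, CCW).
tensor_triangulate <- function(rc, zc) {
  nr <- length(rc); nz <- length(zc)
  nodes <- cbind(r = rep(rc, times = nz), z = rep(zc, each = nr))
  i <- rep(seq_len(nr - 1), times = nz - 1)
  j <- rep(seq_len(nz - 1), each = nr - 1)
  n00 <- (j - 1) * nr + i
  n10 <- n00 + 1L
  n01 <- n00 + nr
  n11 <- n01 + 1L
  tri <- rbind(cbind(n00, n10, n11), cbind(n00, n11, n01))
  list(nodes = nodes, tri = tri, nr = nr, nz = nz)
}

# Precompute P1 element geometry: area, shape-function gradients, centroid.
mesh_precompute <- function(mesh) {
  p <- mesh$nodes; t <- mesh$tri
  x1 <- p[t[, 1], 1]; y1 <- p[t[, 1], 2]
  x2 <- p[t[, 2], 1]; y2 <- p[t[, 2], 2]
  x3 <- p[t[, 3], 1]; y3 <- p[t[, 3], 2]
  det <- (x2 - x1) * (y3 - y1) - (x3 - x1) * (y2 - y1)
  area <- det / 2
  if (any(area <= 0)) stop("meshing failure: inverted or degenerate elements")
  # grad N_i = (b_i, c_i) / det
  b <- cbind(y2 - y3, y3 - y1, y1 - y2) / det
  c_ <- cbind(x3 - x2, x1 - x3, x2 - x1) / det
  mesh$area <- area
  mesh$gb <- b
  mesh$gc <- c_
  mesh$rbar <- (x1 + x2 + x3) / 3
  mesh$zbar <- (y1 + y2 + y3) / 3
  mesh
}

boundary_edges_tensor <- function(nr, nz) {
  ij <- function(i, j) (j - 1L) * nr + i
  eb <- cbind(ij(seq_len(nr - 1), 1L), ij(seq_len(nr - 1) + 1L, 1L))          # bottom
  et <- cbind(ij(seq_len(nr - 1), nz), ij(seq_len(nr - 1) + 1L, nz))          # top
  el <- cbind(ij(1L, seq_len(nz - 1)), ij(1L, seq_len(nz - 1) + 1L))          # axis
  er <- cbind(ij(nr, seq_len(nz - 1)), ij(nr, seq_len(nz - 1) + 1L))          # outer r
  rbind(eb, et, el, er)
}

#' Build the axisymmetric simulation mesh
#'
#' Generates a graded triangulation of the (r, z) half-plane containing the
#' antenna cross-section and the tumor, with per-element material tags
#' (`healthy_liver`, `tumor`, `antenna_dielectric`, `slot_fill`,
#' `catheter`, `antenna_metal`) and boundary-edge tags (`port` on the coax
#' feed cross-section, `axis` at r = 0, `shaft` where the antenna exits the
#' domain, `outer` elsewhere). Element size is at most `h_fine` within the
#' slotted region and near the tumor boundary and at most `h_coarse`
#' elsewhere.
#'
#' @param antenna an [build_antenna()] geometry.
#' @param tumor a `tumor_shape` (ellipsoid or surface mesh), or `NULL` for
#'   homogeneous healthy tissue.
#' @param domain_radius radial extent of the tissue domain, m.
#' @param z_min lower axial extent (below the tip), m.
#' @param h_fine,h_coarse target element sizes, m.
#' @return An object of class `mwa_mesh`.
#' @export
generate_mesh <- function(antenna, tumor = NULL, domain_radius = 0.05,
                          z_min = -0.045, h_fine = 5e-4, h_coarse = 4e-3) {
  stopifnot(inherits(antenna, "antenna_geometry"))
  a <- antenna$inner_conductor_radius
  b <- antenna$dielectric_outer_radius
  b_o <- antenna$outer_conductor_radius
  rcat <- antenna$catheter_outer_radius
  ztop <- antenna$insertion_depth
  tcap <- antenna$tip_cap_thickness
  slots <- antenna$slot_z
  span_hi <- antenna$tip_offset + antenna$slotted_span

  sec <- if (!is.null(tumor)) tumor_axisym_section(tumor) else NULL
  if (!is.null(sec)) {
    if (sec$r >= domain_radius || sec$z0 + sec$c >= ztop || sec$z0 - sec$c <= z_min)
      stop("tumor does not fit inside the computational domain")
  }

  h_slot <- min(h_fine, antenna$slot_width / 2)
  r_mand <- c(0, a, a + (b - a) * (1:3) / 4, b, b_o, rcat, domain_radius)
  r_win <- list(c(0, rcat, min(h_fine, (b - a) / 2)),
                c(rcat, rcat + 3e-3, h_fine))
  cap_below <- 2e-3            # dielectric tip cap below the metal short
  z_mand <- c(z_min, -cap_below, 0, tcap, as.vector(slots), ztop)
  z_win <- list(c(-3e-3, antenna$tip_offset, h_fine),
                c(antenna$tip_offset, span_hi, h_slot),
                c(span_hi, span_hi + 3e-3, h_fine))
  if (!is.null(sec)) {
    r_mand <- c(r_mand, sec$r)
    z_mand <- c(z_mand, sec$z0 - sec$c, sec$z0 + sec$c)
    r_win <- c(r_win, list(c(sec$r - 1e-3, sec$r + 1e-3, h_fine)))
    z_win <- c(z_win, list(c(sec$z0 - sec$c - 1e-3, sec$z0 - sec$c + 1e-3, h_fine),
                           c(sec$z0 + sec$c - 1e-3, sec$z0 + sec$c + 1e-3, h_fine)))
  }
  rc <- graded_axis(r_mand[r_mand <= domain_radius + 1e-12], r_win, h_coarse)
  zc <- graded_axis(z_mand, z_win, h_coarse)

  tt <- tensor_triangulate(rc, zc)
  mesh <- list(nodes = tt$nodes, tri = tt$tri, coord = "axisymmetric")
  mesh <- mesh_precompute(mesh)

  rb <- mesh$rbar; zb <- mesh$zbar
  in_slot <- rep(FALSE, length(rb))
  for (k in seq_len(nrow(slots)))
    in_slot <- in_slot | (zb > slots[k, 1] & zb < slots[k, 2])
  region <- rep("healthy_liver", length(rb))
  if (!is.null(sec)) {
    inside_tum <- (rb / sec$r)^2 + ((zb - sec$z0) / sec$c)^2 <= 1
    region[inside_tum] <- "tumor"
  }
  in_ant_z <- zb > 0 & zb < ztop
  region[in_ant_z & rb > b_o & rb < rcat] <- "catheter"
  region[in_ant_z & rb > b & rb < b_o] <- ifelse(
    in_slot[in_ant_z & rb > b & rb < b_o], "slot_fill", "antenna_metal")
  region[in_ant_z & rb > a & rb < b & zb > tcap] <- "antenna_dielectric"
  region[in_ant_z & rb < a] <- "antenna_metal"
  region[zb > 0 & zb < tcap & rb < b_o] <- "antenna_metal"   # shorted tip cap
  region[zb > -cap_below & zb < 0 & rb < rcat] <- "catheter" # dielectric tip
  if (!is.null(sec) && !any(region == "tumor"))
    stop("tumor region is empty after meshing (tumor lies inside the antenna bore?)")

  edges <- boundary_edges_tensor(tt$nr, tt$nz)
  p <- mesh$nodes
  er <- cbind(p[edges[, 1], 1], p[edges[, 2], 1])
  ez <- cbind(p[edges[, 1], 2], p[edges[, 2], 2])
  tol <- 1e-12
  tag <- rep("outer", nrow(edges))
  tag[abs(er[, 1]) < tol & abs(er[, 2]) < tol] <- "axis"
  on_top <- abs(ez[, 1] - ztop) < tol & abs(ez[, 2] - ztop) < tol
  tag[on_top & er[, 1] >= a - tol & er[, 2] <= b + tol &
        er[, 2] >= a - tol & er[, 1] <= b + tol] <- "port"
  tag[on_top & pmax(er[, 1], er[, 2]) <= rcat + tol & tag != "port"] <- "shaft"

  mesh$region <- region
  mesh$edges <- edges
  mesh$edge_tag <- tag
  mesh$antenna <- antenna
  mesh$tumor <- tumor
  mesh$h_fine <- h_fine
  mesh$h_coarse <- h_coarse
  class(mesh) <- "mwa_mesh"
  mesh
}

#' @export
print.mwa_mesh <- function(x, ...) {
  cat(sprintf("<mwa_mesh> %s, %d nodes, %d triangles\n", x$coord,
              nrow(x$nodes), nrow(x$tri)))
  print(table(x$region))
  invisible(x)
}

#' Rectangular strip mesh for verification problems
#'
#' Uniform triangulated rectangle `[0, L] x [0, H]` in Cartesian (x, z)
#' coordinates, used by the closed-form verification oracles (plane-wave
#' attenuation, slab conduction). Boundary tags: `port` at z = 0, `outer`
#' at z = L, `wall` on the sides.
#'
#' @param L axial length, m; `H` transverse width, m.
#' @param nx transverse and `nz` axial element counts.
#' @param region material tag for all elements.
#' @param coord `"cartesian"` (default) or `"axisymmetric"`.
#' @export
strip_mesh <- function(L = 0.06, H = 2e-3, nx = 2, nz = 240,
                       region = "healthy_liver", coord = "cartesian") {
  rc <- seq(0, H, length.out = nx + 1)
  zc <- seq(0, L, length.out = nz + 1)
  tt <- tensor_triangulate(rc, zc)
  mesh <- list(nodes = tt$nodes, tri = tt$tri, coord = coord)
  mesh <- mesh_precompute(mesh)
  mesh$region <- rep(region, nrow(mesh$tri))
  edges <- boundary_edges_tensor(tt$nr, tt$nz)
  p <- mesh$nodes
  z1 <- p[edges[, 1], 2]; z2 <- p[edges[, 2], 2]
  tag <- rep("wall", nrow(edges))
  tag[z1 < 1e-12 & z2 < 1e-12] <- "port"
  tag[abs(z1 - L) < 1e-12 & abs(z2 - L) < 1e-12] <- "outer"
  mesh$edges <- edges
  mesh$edge_tag <- tag
  mesh$h_fine <- L / nz
  class(mesh) <- "mwa_mesh"
  mesh
}

# Triangle adjacent to each boundary edge (needed for edge-local material).
edge_elements <- function(mesh, edge_idx = seq_len(nrow(mesh$edges))) {
  t <- mesh$tri
  res <- integer(length(edge_idx))
  # node -> triangles incidence
  inc <- split(rep(seq_len(nrow(t)), 3), as.vector(t))
  for (k in seq_along(edge_idx)) {
    e <- mesh$edges[edge_idx[k], ]
    cand <- intersect(inc[[as.character(e[1])]], inc[[as.character(e[2])]])
    res[k] <- cand[1]
  }
  res
}

# Nodal quadrature weights: V_i = sum_e area_e * w_e / 3 with w_e = rbar
# (axisymmetric, per radian) or 1 (cartesian). Restricted to elements `el`.
nodal_weights <- function(mesh, el = seq_len(nrow(mesh$tri))) {
  w <- if (mesh$coord == "axisymmetric") mesh$rbar[el] else rep(1, length(el))
  contrib <- mesh$area[el] * w / 3
  n <- nrow(mesh$nodes)
  as.vector(tapply(rep(contrib, 3), factor(as.vector(mesh$tri[el, ]), levels = seq_len(n)),
                   sum, default = 0))
}

# Region volumes (axisymmetric: full revolved volume, i.e. 2*pi * int r dA).
#' Per-region volumes of a mesh
#' @param mesh an `mwa_mesh`.
#' @return named numeric vector of volumes, m^3 (axisymmetric meshes are
#'   revolved through 2*pi).
#' @export
region_volumes <- function(mesh) {
  w <- if (mesh$coord == "axisymmetric") 2 * pi * mesh$rbar else rep(1, nrow(mesh$tri))
  tapply(mesh$area * w, mesh$region, sum)
}
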