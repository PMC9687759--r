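# ---------------------------------------------------------------------------
# Parametric antenna and synthetic tumor geometry.
#
# Coordinate convention: z along the antenna axis, antenna tip at z = 0,
# antenna body in z > 0, SI meters throughout. The axisymmetric (r, z)
# half-plane has r >= 0.
# ---------------------------------------------------------------------------

#' Parametric multi-slot coaxial antenna
#'
#' Describes an interstitial coaxial applicator with `slot_count` periodic
#' slots cut in the outer conductor near the tip. Slots shape the deposition
#' pattern toward a near-spherical ablation zone. The default slot layout is
#' 10 slots of width 0.6 mm at 0.8 mm spacing; the coax radii default to a
#' roughly 50-ohm line with a PTFE-like dielectric (outer/inner radius ratio
#' about 3.3).
#'
#' @param slot_count number of slots (>= 1).
#' @param slot_width axial width of each slot, m.
#' @param slot_spacing axial gap between adjacent slots, m.
#' @param inner_conductor_radius,dielectric_outer_radius,catheter_outer_radius
#'   coax radii, m, strictly increasing.
#' @param outer_conductor_thickness radial thickness of the slotted outer
#'   conductor, m.
#' @param tip_offset distance from the (shorted) tip cap to the first slot, m.
#' @param insertion_depth length of antenna inside the simulated domain, m.
#' @return An object of class `antenna_geometry` with derived fields
#'   `slotted_span` (total axial extent of the slot array) and `slot_z`
#'   (matrix of lower/upper slot edges measured from the tip).
#' @export
#' @examples
#' a <- build_antenna(slot_count = 10)
#' a$slotted_span  # 10*0.6mm + 9*0.8mm = 13.2 mm
build_antenna <- function(slot_count = 10,
                          slot_width = 0.6e-3,
                          slot_spacing = 0.8e-3,
                          inner_conductor_radius = 1.5e-4,
                          dielectric_outer_radius = 5.0e-4,
                          catheter_outer_radius = 9.0e-4,
                          outer_conductor_thickness = 1.0e-4,
                          tip_offset = 3e-3,
                          insertion_depth = 0.06) {
  if (!is.numeric(slot_count) || length(slot_count) != 1L ||
      slot_count < 1 || slot_count != round(slot_count))
    stop("slot_count must be an integer >= 1")
  slot_count <- as.integer(slot_count)
  if (slot_width <= 0 || slot_spacing < 0)
    stop("slot_width must be positive and slot_spacing non-negative")
  r_oc <- dielectric_outer_radius + outer_conductor_thickness
  radii <- c(inner_conductor_radius, dielectric_outer_radius, r_oc,
             catheter_outer_radius)
  if (any(diff(radii) <= 0) || inner_conductor_radius <= 0)
    stop("antenna radii must be strictly increasing and positive")
  span <- slot_count * slot_width + (slot_count - 1) * slot_spacing
  if (tip_offset < 0 || tip_offset + span > insertion_depth)
    stop(sprintf(paste0("slot array infeasible: tip_offset + slotted span = %.4g m ",
                        "exceeds insertion depth %.4g m"),
                 tip_offset + span, insertion_depth))
  lower <- tip_offset + (seq_len(slot_count) - 1L) * (slot_width + slot_spacing)
  structure(list(slot_count = slot_count, slot_width = slot_width,
                 slot_spacing = slot_spacing,
                 inner_conductor_radius = inner_conductor_radius,
                 dielectric_outer_radius = dielectric_outer_radius,
                 outer_conductor_radius = r_oc,
                 catheter_outer_radius = catheter_outer_radius,
                 tip_offset = tip_offset, insertion_depth = insertion_depth,
                 slotted_span = span,
                 slot_z = cbind(lower = lower, upper = lower + slot_width),
                 tip_cap_thickness = 6e-4),
            class = "antenna_geometry")
}

#' @export
print.antenna_geometry <- function(x, ...) {
  cat(sprintf(paste0("<antenna_geometry> %d slots (w = %.2f mm, s = %.2f mm, ",
                     "span = %.1f mm), coax a/b = %.2f/%.2f mm, catheter %.2f mm, ",
                     "insertion %.1f mm\n"),
              x$slot_count, 1e3 * x$slot_width, 1e3 * x$slot_spacing,
              1e3 * x$slotted_span, 1e3 * x$inner_conductor_radius,
              1e3 * x$dielectric_outer_radius, 1e3 * x$catheter_outer_radius,
              1e3 * x$insertion_depth))
  invisible(x)
}

#' Synthetic ellipsoidal tumor
#'
#' Analytic triaxial ellipsoid standing in for patient-specific segmented
#' tumor geometry. Axisymmetric runs revolve the volume-equivalent ellipse
#' with semi-axes `(sqrt(a*b), c)` about the antenna axis, which preserves
#' the tumor volume exactly.
#'
#' @param semi_axes numeric length-3, ellipsoid semi-axes `(a, b, c)` in m;
#'   `c` is the axis aligned with the antenna.
#' @param center numeric length-3 `(x, y, z)` center, m. Axisymmetric runs
#'   require `x = y = 0`.
#' @return An object of class `tumor_shape` (kind `"ellipsoid"`), with
#'   analytic `volume` and the revolved radial semi-axis `r_equiv`.
#' @export
#' @examples
#' tum <- make_ellipsoid_tumor(c(0.82, 0.855, 1.905) * 1e-2)
#' tum$volume * 1e6   # cm^3
make_ellipsoid_tumor <- function(semi_axes, center = c(0, 0, 0.0096)) {
  if (length(semi_axes) != 3L || any(!is.finite(semi_axes)) || any(semi_axes <= 0))
    stop("ellipsoid semi-axes must be three positive numbers")
  if (length(center) != 3L || any(!is.finite(center)))
    stop("center must be a finite (x, y, z) triple")
  structure(list(kind = "ellipsoid",
                 semi_axes = as.numeric(semi_axes),
                 center = as.numeric(center),
                 r_equiv = sqrt(semi_axes[1] * semi_axes[2]),
                 volume = 4 / 3 * pi * prod(semi_axes)),
            class = "tumor_shape")
}

#' @export
print.tumor_shape <- function(x, ...) {
  if (x$kind == "ellipsoid") {
    cat(sprintf("<tumor_shape> ellipsoid, semi-axes %.2f x %.2f x %.2f mm, volume %.2f cm^3\n",
                1e3 * x$semi_axes[1], 1e3 * x$semi_axes[2], 1e3 * x$semi_axes[3],
                1e6 * x$volume))
  } else {
    cat(sprintf("<tumor_shape> surface mesh, %d vertices / %d faces, volume %.2f cm^3\n",
                nrow(x$vertices), nrow(x$faces), 1e6 * x$volume))
  }
  invisible(x)
}

# Volume-equivalent axisymmetric section of a tumor: radial and axial
# semi-axes plus axial center. Surface-mesh tumors are reduced by matching
# the axial bounding extent and preserving volume.
tumor_axisym_section <- function(tumor) {
  if (abs(tumor$center[1]) > 1e-12 || abs(tumor$center[2]) > 1e-12)
    stop("axisymmetric runs require the tumor centered on the antenna axis (x = y = 0)")
  if (tumor$kind == "ellipsoid") {
    list(r = tumor$r_equiv, c = tumor$semi_axes[3], z0 = tumor$center[3])
  } else {
    zext <- range(tumor$vertices[, 3])
    c_ax <- diff(zext) / 2
    # revolve an ellipse with matching volume: V = 4/3 pi r^2 c
    r_eq <- sqrt(tumor$volume / (4 / 3 * pi * c_ax))
    list(r = r_eq, c = c_ax, z0 = tumor$center[3] + mean(zext - tumor$center[3]))
  }
}
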