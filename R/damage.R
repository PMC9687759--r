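# ---------------------------------------------------------------------------
# Arrhenius thermal damage, necrotic fraction, perfusion shutdown,
# isocontour extraction with revolved enclosed volumes, and tumor-coverage
# metrics.
# ---------------------------------------------------------------------------

#' Arrhenius damage-kinetics parameters
#'
#' First-order damage kinetics `dOmega/dt = A exp(-dE / (R T_K))` with the
#' temperature in Kelvin. The default frequency factor and activation
#' energy are the standard liver parameter set from the thermal-damage
#' literature (external provenance; the model source cites them
#' symbolically).
#'
#' @param A frequency factor, 1/s.
#' @param dE activation energy, J/mol.
#' @param R universal gas constant, J/(mol K).
#' @export
arrhenius_params <- function(A = 7.39e39, dE = 2.577e5, R = 8.314) {
  if (A <= 0 || dE <= 0) stop("Arrhenius parameters A and dE must be positive")
  structure(list(A = A, dE = dE, R = R), class = "arrhenius_params")
}

#' Accumulate Arrhenius damage over one time step
#'
#' Rectangle-rule update `Omega' = Omega + dt * A * exp(-dE/(R T_K))` per
#' node, exact for the piecewise-constant-in-time temperature produced by
#' the implicit stepping.
#'
#' @param Omega per-node accumulated damage (dimensionless, >= 0).
#' @param T per-node temperature, degrees C.
#' @param dt time step, s (> 0).
#' @param params an [arrhenius_params()].
#' @return updated per-node Omega (strictly larger wherever T is finite).
#' @export
accumulate_damage <- function(Omega, T, dt, params = arrhenius_params()) {
  stopifnot(dt > 0, length(Omega) == length(T))
  Omega + dt * params$A * exp(-params$dE / (params$R * (T + 273.15)))
}

#' Necrotic tissue fraction from accumulated damage
#'
#' `theta = 1 - exp(-Omega)`: the fraction of cells destroyed under
#' first-order kinetics; `Omega = 1` corresponds to 63.2% cell death, the
#' conventional complete-ablation threshold.
#'
#' @param Omega per-node accumulated damage, must be >= 0.
#' @export
necrotic_fraction <- function(Omega) {
  if (any(Omega < 0)) stop("Omega must be non-negative")
  1 - exp(-Omega)
}

#' Perfusion shutdown coefficient
#'
#' Blood perfusion ceases in destroyed tissue. The default step model sets
#' `beta = 1` while `Omega < 1` and 0 after; the smooth alternative uses
#' `beta = exp(-Omega)` (the surviving-cell fraction).
#'
#' @param Omega per-node accumulated damage.
#' @param model `"step"` or `"smooth"`.
#' @return per-node beta in `[0, 1]`.
#' @export
perfusion_beta <- function(Omega, model = c("step", "smooth")) {
  model <- match.arg(model)
  if (model == "step") as.numeric(Omega < 1) else exp(-pmin(Omega, 700))
}

# ---------------------------------------------------------------------------
# Isocontours and enclosed volumes on the triangulated half-plane.
# The super-level set {field >= level} is cut element-by-element by linear
# interpolation; its volume is the revolved integral 2 pi int r dA
# (axisymmetric) or the plain area (cartesian).
# ---------------------------------------------------------------------------

# area and int r dA of the polygon where the linear interpolant >= level
# on one triangle with vertex coords (x, y) and values v
.cut_triangle <- function(x, y, v, level) {
  inside <- v >= level
  ni <- sum(inside)
  if (ni == 0) return(c(0, 0))
  poly_x <- numeric(0); poly_y <- numeric(0)
  for (i in 1:3) {
    j <- if (i == 3) 1L else i + 1L
    if (inside[i]) { poly_x <- c(poly_x, x[i]); poly_y <- c(poly_y, y[i]) }
    if (xor(inside[i], inside[j])) {
      t <- (level - v[i]) / (v[j] - v[i])
      poly_x <- c(poly_x, x[i] + t * (x[j] - x[i]))
      poly_y <- c(poly_y, y[i] + t * (y[j] - y[i]))
    }
  }
  n <- length(poly_x)
  jj <- c(2:n, 1)
  cr <- poly_x * poly_y[jj] - poly_x[jj] * poly_y
  area <- sum(cr) / 2
  rint <- sum((poly_x + poly_x[jj]) * cr) / 6   # int x dA by shoelace moments
  abs(c(area, rint)) * sign(1)
}

# total super-level volume of a nodal field over the given elements
superlevel_volume <- function(mesh, field, level, el = seq_len(nrow(mesh$tri))) {
  tt <- mesh$tri[el, , drop = FALSE]
  v <- matrix(field[tt], ncol = 3)
  vmin <- pmin(v[, 1], v[, 2], v[, 3])
  vmax <- pmax(v[, 1], v[, 2], v[, 3])
  axisym <- mesh$coord == "axisymmetric"
  full <- vmin >= level
  out <- rep(0, length(el))
  if (axisym) out[full] <- 2 * pi * mesh$rbar[el][full] * mesh$area[el][full]
  else out[full] <- mesh$area[el][full]
  part <- which(!full & vmax >= level)
  if (length(part)) {
    p <- mesh$nodes
    for (kk in part) {
      e <- el[kk]
      id <- mesh$tri[e, ]
      ar <- .cut_triangle(p[id, 1], p[id, 2], field[id], level)
      out[kk] <- if (axisym) 2 * pi * ar[2] else ar[1]
    }
  }
  sum(out)
}

#' Extract an isocontour and its enclosed volume
#'
#' Linear-interpolation contour of a nodal field on the triangulation, with
#' the volume of the super-level region `{field >= level}` computed by
#' revolving the enclosed (r, z) area (axisymmetric meshes) or as plain
#' area (cartesian). A level outside the field range yields an empty
#' contour with zero volume (not an error).
#'
#' @param mesh an `mwa_mesh`.
#' @param field per-node values (e.g. temperature or necrotic fraction).
#' @param level contour level.
#' @return list with `segments` (matrix of contour segment endpoints
#'   `x1, y1, x2, y2`), `polylines` (list of chained coordinate matrices)
#'   and `volume` (m^3, or m^2 for cartesian meshes).
#' @export
extract_isocontour <- function(mesh, field, level) {
  stopifnot(length(field) == nrow(mesh$nodes))
  tt <- mesh$tri
  v <- matrix(field[tt], ncol = 3)
  vmin <- pmin(v[, 1], v[, 2], v[, 3])
  vmax <- pmax(v[, 1], v[, 2], v[, 3])
  cross <- which(vmin < level & vmax >= level)
  segs <- matrix(numeric(0), 0, 4)
  p <- mesh$nodes
  if (length(cross)) {
    seg_list <- vector("list", length(cross))
    for (kk in seq_along(cross)) {
      id <- tt[cross[kk], ]
      x <- p[id, 1]; y <- p[id, 2]; val <- field[id]
      pts_x <- numeric(0); pts_y <- numeric(0)
      for (i in 1:3) {
        j <- if (i == 3) 1L else i + 1L
        below <- val[i] < level; belowj <- val[j] < level
        if (xor(below, belowj)) {
          t <- (level - val[i]) / (val[j] - val[i])
          pts_x <- c(pts_x, x[i] + t * (x[j] - x[i]))
          pts_y <- c(pts_y, y[i] + t * (y[j] - y[i]))
        }
      }
      if (length(pts_x) == 2)
        seg_list[[kk]] <- c(pts_x[1], pts_y[1], pts_x[2], pts_y[2])
    }
    seg_list <- seg_list[!vapply(seg_list, is.null, logical(1))]
    if (length(seg_list)) segs <- do.call(rbind, seg_list)
  }
  list(segments = segs, polylines = chain_segments(segs),
       volume = superlevel_volume(mesh, field, level))
}

# greedy chaining of contour segments into polylines
chain_segments <- function(segs, tol = 1e-9) {
  if (nrow(segs) == 0) return(list())
  key <- function(x, y) paste(round(x / tol), round(y / tol))
  ends <- rbind(cbind(segs[, 1], segs[, 2]), cbind(segs[, 3], segs[, 4]))
  used <- rep(FALSE, nrow(segs))
  out <- list()
  for (s0 in seq_len(nrow(segs))) {
    if (used[s0]) next
    used[s0] <- TRUE
    line <- rbind(segs[s0, 1:2], segs[s0, 3:4])
    for (pass in 1:2) {            # grow at the tail, then flip and repeat
      repeat {
        tail_key <- key(line[nrow(line), 1], line[nrow(line), 2])
        k1 <- which(!used & key(segs[, 1], segs[, 2]) == tail_key)
        k2 <- which(!used & key(segs[, 3], segs[, 4]) == tail_key)
        if (length(k1)) {
          used[k1[1]] <- TRUE
          line <- rbind(line, segs[k1[1], 3:4])
        } else if (length(k2)) {
          used[k2[1]] <- TRUE
          line <- rbind(line, segs[k2[1], 1:2])
        } else break
      }
      line <- line[rev(seq_len(nrow(line))), , drop = FALSE]
    }
    out[[length(out) + 1]] <- unname(line)
  }
  out
}

#' Tumor coverage and collateral-damage metrics
#'
#' Volume integrals of the complete-ablation indicator `Omega >= 1` by
#' region: the fraction of the tumor volume ablated, the volume of ablated
#' healthy tissue, and (when a temperature field is supplied) the volume
#' inside the 60 C lethal isotherm.
#'
#' @param Omega per-node accumulated damage.
#' @param mesh an `mwa_mesh` with a tagged tumor region.
#' @param T optional per-node temperature for the lethal-isotherm volume.
#' @param omega_threshold damage level counted as complete ablation.
#' @param lethal_T lethal isotherm temperature, C.
#' @return An object of class `coverage_metrics`: `tumor_coverage` in
#'   `[0, 1]`, `collateral_volume` and `lethal_isotherm_volume` in m^3.
#' @export
coverage <- function(Omega, mesh, T = NULL, omega_threshold = 1, lethal_T = 60) {
  el_t <- which(mesh$region == "tumor")
  if (length(el_t) == 0) stop("mesh has no tagged tumor region")
  el_h <- which(mesh$region == "healthy_liver")
  w <- if (mesh$coord == "axisymmetric") 2 * pi * mesh$rbar else rep(1, nrow(mesh$tri))
  vol_tumor <- sum(mesh$area[el_t] * w[el_t])
  abl_tumor <- superlevel_volume(mesh, Omega, omega_threshold, el_t)
  abl_healthy <- superlevel_volume(mesh, Omega, omega_threshold, el_h)
  iso <- if (!is.null(T)) superlevel_volume(mesh, T, lethal_T) else NA_real_
  structure(list(tumor_coverage = min(abl_tumor / vol_tumor, 1),
                 collateral_volume = abl_healthy,
                 lethal_isotherm_volume = iso,
                 tumor_volume = vol_tumor),
            class = "coverage_metrics")
}

#' @export
print.coverage_metrics <- function(x, ...) {
  cat(sprintf("<coverage_metrics> tumor coverage %.1f%%, collateral %.2f cm^3%s\n",
              100 * x$tumor_coverage, 1e6 * x$collateral_volume,
              if (is.finite(x$lethal_isotherm_volume))
                sprintf(", 60 C isotherm volume %.2f cm^3",
                        1e6 * x$lethal_isotherm_volume) else ""))
  invisible(x)
}
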