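# ---------------------------------------------------------------------------
# Triangulated tumor surface import/export and validation.
# Supported: STL (ASCII + binary) read/write, OFF and ASCII PLY read.
# ---------------------------------------------------------------------------

#' Load a tumor geometry from a triangulated surface file
#'
#' Reads an STL (ASCII or binary), OFF, or ASCII PLY surface, validates that
#' it is a closed orientable manifold, and returns it as a `tumor_shape`
#' with its enclosed volume (divergence theorem) and bounding box.
#'
#' @param path path to a surface-mesh file; format chosen by extension
#'   (`.stl`, `.off`, `.ply`).
#' @param center_z axial position to place the surface's centroid at, m
#'   (the surface is translated so its volume centroid sits on the axis at
#'   this height). `NULL` keeps the file coordinates.
#' @return A `tumor_shape` of kind `"surface_mesh"` with fields `vertices`
#'   (n x 3), `faces` (m x 3), `volume`, `bbox`.
#' @export
load_tumor_surface <- function(path, center_z = NULL) {
  if (!file.exists(path)) stop("cannot read surface file: ", path)
  if (file.size(path) == 0) stop("surface file is empty: ", path)
  ext <- tolower(tools::file_ext(path))
  surf <- switch(ext,
                 stl = read_stl(path),
                 off = read_off(path),
                 ply = read_ply(path),
                 stop("unsupported surface format '.", ext,
                      "' (supported: stl, off, ply)"))
  validate_surface(surf$vertices, surf$faces, path)
  vol <- surface_volume(surf$vertices, surf$faces)
  if (vol < 0) {  # flip orientation so the volume is positive
    surf$faces <- surf$faces[, c(1, 3, 2), drop = FALSE]
    vol <- -vol
  }
  v <- surf$vertices
  if (!is.null(center_z)) {
    cen <- surface_centroid(v, surf$faces)
    v <- sweep(v, 2, cen - c(0, 0, center_z))
  }
  structure(list(kind = "surface_mesh", vertices = v, faces = surf$faces,
                 volume = vol, bbox = apply(v, 2, range),
                 center = c(0, 0, if (is.null(center_z))
                   surface_centroid(v, surf$faces)[3] else center_z)),
            class = "tumor_shape")
}

validate_surface <- function(vertices, faces, path = "<surface>") {
  if (nrow(faces) < 4) stop("surface has too few faces to be closed: ", path)
  if (max(faces) > nrow(vertices) || min(faces) < 1)
    stop("face indices out of range in ", path)
  # undirected edge multiplicity: closed manifold <=> every edge in exactly
  # two faces; orientability <=> each directed edge appears exactly once
  e <- rbind(faces[, 1:2], faces[, 2:3], faces[, c(3, 1)])
  key_dir <- paste(e[, 1], e[, 2])
  if (anyDuplicated(key_dir))
    stop("surface is non-manifold or inconsistently oriented: ", path)
  key_und <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  cnt <- table(key_und)
  if (any(cnt != 2))
    stop("surface is not closed (", sum(cnt != 2), " boundary/non-manifold edges): ", path)
  invisible(TRUE)
}

# Signed enclosed volume via the divergence theorem (sum of signed tetrahedra)
surface_volume <- function(vertices, faces) {
  v1 <- vertices[faces[, 1], , drop = FALSE]
  v2 <- vertices[faces[, 2], , drop = FALSE]
  v3 <- vertices[faces[, 3], , drop = FALSE]
  sum(v1[, 1] * (v2[, 2] * v3[, 3] - v3[, 2] * v2[, 3]) -
      v2[, 1] * (v1[, 2] * v3[, 3] - v3[, 2] * v1[, 3]) +
      v3[, 1] * (v1[, 2] * v2[, 3] - v2[, 2] * v1[, 3])) / 6
}

surface_centroid <- function(vertices, faces) {
  v1 <- vertices[faces[, 1], , drop = FALSE]
  v2 <- vertices[faces[, 2], , drop = FALSE]
  v3 <- vertices[faces[, 3], , drop = FALSE]
  det6 <- v1[, 1] * (v2[, 2] * v3[, 3] - v3[, 2] * v2[, 3]) -
          v2[, 1] * (v1[, 2] * v3[, 3] - v3[, 2] * v1[, 3]) +
          v3[, 1] * (v1[, 2] * v2[, 3] - v2[, 2] * v1[, 3])
  vol <- sum(det6) / 6
  cen <- colSums((v1 + v2 + v3) / 4 * det6 / 6) / vol
  cen
}

# --- readers ---------------------------------------------------------------

read_stl <- function(path) {
  # binary STL: 80-byte header + uint32 count; ASCII starts with "solid"
  con <- file(path, "rb")
  head <- readBin(con, "raw", 80)
  close(con)
  txt_head <- rawToChar(head[head != as.raw(0)])
  is_ascii <- grepl("^\\s*solid", txt_head)
  if (is_ascii) {
    # also verify: binary files may start with 'solid'; check facet keyword
    lines <- readLines(path, warn = FALSE)
    if (!any(grepl("facet", lines[seq_len(min(10, length(lines)))])))
      is_ascii <- FALSE
  }
  if (is_ascii) read_stl_ascii(path) else read_stl_binary(path)
}

read_stl_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex", lines, value = TRUE)
  if (length(vl) == 0 || length(vl) %% 3 != 0)
    stop("malformed ASCII STL (vertex count not a multiple of 3): ", path)
  nums <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"), function(x)
    as.numeric(x[2:4])))
  weld_vertices(nums)
}

read_stl_binary <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", 80)
  n <- readBin(con, "integer", 1, size = 4, endian = "little")
  if (!is.finite(n) || n <= 0 || n > 5e7) stop("malformed binary STL: ", path)
  rec <- readBin(con, "raw", n * 50)
  if (length(rec) < n * 50) stop("truncated binary STL: ", path)
  m <- matrix(rec, nrow = 50)
  tri_raw <- m[1:48, , drop = FALSE]  # 12 floats; last 2 bytes attribute
  vals <- readBin(as.raw(tri_raw), "numeric", n * 12, size = 4, endian = "little")
  vals <- matrix(vals, ncol = 12, byrow = TRUE)
  verts <- rbind(vals[, 4:6, drop = FALSE], vals[, 7:9, drop = FALSE],
                 vals[, 10:12, drop = FALSE])
  # interleave back to per-face order v1,v2,v3
  idx <- as.vector(t(matrix(seq_len(3 * n), ncol = 3)))
  weld_vertices(verts[idx, , drop = FALSE])
}

# merge duplicated vertices from triangle-soup formats into an indexed mesh
weld_vertices <- function(coords, digits = 9) {
  key <- apply(round(coords, digits), 1, paste, collapse = " ")
  uid <- match(key, unique(key))
  verts <- coords[!duplicated(key), , drop = FALSE]
  faces <- matrix(uid, ncol = 3, byrow = TRUE)
  if (any(faces[, 1] == faces[, 2] | faces[, 2] == faces[, 3] |
          faces[, 1] == faces[, 3]))
    stop("degenerate (zero-area) triangles in surface")
  list(vertices = verts, faces = faces)
}

read_off <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) < 2 || trimws(lines[1]) != "OFF")
    stop("malformed OFF file: ", path)
  counts <- as.integer(strsplit(trimws(lines[2]), "\\s+")[[1]])
  nv <- counts[1]; nf <- counts[2]
  if (length(lines) < 2 + nv + nf) stop("truncated OFF file: ", path)
  verts <- do.call(rbind, lapply(strsplit(trimws(lines[3:(2 + nv)]), "\\s+"),
                                 function(x) as.numeric(x[1:3])))
  faces <- do.call(rbind, lapply(strsplit(trimws(lines[(3 + nv):(2 + nv + nf)]), "\\s+"),
                                 function(x) {
                                   x <- as.integer(x)
                                   if (x[1] != 3) stop("OFF reader supports triangles only")
                                   x[2:4] + 1L
                                 }))
  list(vertices = verts, faces = faces)
}

read_ply <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3 || trimws(lines[1]) != "ply")
    stop("malformed PLY file: ", path)
  hend <- grep("^\\s*end_header", lines)[1]
  if (is.na(hend)) stop("PLY header not terminated: ", path)
  header <- lines[1:hend]
  if (!any(grepl("format\\s+ascii", header)))
    stop("only ASCII PLY is supported: ", path)
  nv <- as.integer(sub(".*element\\s+vertex\\s+(\\d+).*", "\\1",
                       grep("element\\s+vertex", header, value = TRUE)[1]))
  nf <- as.integer(sub(".*element\\s+face\\s+(\\d+).*", "\\1",
                       grep("element\\s+face", header, value = TRUE)[1]))
  body <- lines[-(1:hend)]
  verts <- do.call(rbind, lapply(strsplit(trimws(body[1:nv]), "\\s+"),
                                 function(x) as.numeric(x[1:3])))
  faces <- do.call(rbind, lapply(strsplit(trimws(body[(nv + 1):(nv + nf)]), "\\s+"),
                                 function(x) {
                                   x <- as.integer(x)
                                   if (x[1] != 3) stop("PLY reader supports triangles only")
                                   x[2:4] + 1L
                                 }))
  list(vertices = verts, faces = faces)
}

# --- writers ---------------------------------------------------------------

#' Write a triangulated surface as STL
#'
#' @param tumor a `tumor_shape` of kind `"surface_mesh"` (or a list with
#'   `vertices` and `faces`).
#' @param path output file path.
#' @param binary write binary STL instead of ASCII.
#' @export
write_surface_stl <- function(tumor, path, binary = FALSE) {
  v <- tumor$vertices; f <- tumor$faces
  if (is.null(v) || is.null(f)) stop("tumor has no surface mesh to write")
  p1 <- v[f[, 1], , drop = FALSE]; p2 <- v[f[, 2], , drop = FALSE]
  p3 <- v[f[, 3], , drop = FALSE]
  nrm <- cbind((p2[, 2] - p1[, 2]) * (p3[, 3] - p1[, 3]) - (p2[, 3] - p1[, 3]) * (p3[, 2] - p1[, 2]),
               (p2[, 3] - p1[, 3]) * (p3[, 1] - p1[, 1]) - (p2[, 1] - p1[, 1]) * (p3[, 3] - p1[, 3]),
               (p2[, 1] - p1[, 1]) * (p3[, 2] - p1[, 2]) - (p2[, 2] - p1[, 2]) * (p3[, 1] - p1[, 1]))
  nrm <- nrm / pmax(sqrt(rowSums(nrm^2)), 1e-300)
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(as.raw(rep(0L, 80)), con)
    writeBin(as.integer(nrow(f)), con, size = 4, endian = "little")
    for (i in seq_len(nrow(f))) {
      writeBin(as.numeric(c(nrm[i, ], p1[i, ], p2[i, ], p3[i, ])), con,
               size = 4, endian = "little")
      writeBin(as.raw(c(0L, 0L)), con)
    }
  } else {
    fmt <- function(x) sprintf("%.9g", x)
    out <- character(7 * nrow(f) + 2)
    out[1] <- "solid tumor"
    k <- 2L
    for (i in seq_len(nrow(f))) {
      out[k:(k + 6)] <- c(
        sprintf("  facet normal %s %s %s", fmt(nrm[i, 1]), fmt(nrm[i, 2]), fmt(nrm[i, 3])),
        "    outer loop",
        sprintf("      vertex %s %s %s", fmt(p1[i, 1]), fmt(p1[i, 2]), fmt(p1[i, 3])),
        sprintf("      vertex %s %s %s", fmt(p2[i, 1]), fmt(p2[i, 2]), fmt(p2[i, 3])),
        sprintf("      vertex %s %s %s", fmt(p3[i, 1]), fmt(p3[i, 2]), fmt(p3[i, 3])),
        "    endloop",
        "  endfacet")
      k <- k + 7L
    }
    out[k] <- "endsolid tumor"
    writeLines(out, path)
  }
  invisible(path)
}

# --- generated surfaces -----------------------------------------------------

#' Subdivided icosahedron on the unit sphere
#'
#' @param subdiv number of 4-to-1 subdivision passes (0 = icosahedron).
#' @return list with `vertices` (on the unit sphere) and `faces`.
#' @export
icosphere <- function(subdiv = 3) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
             c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
             c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdiv)) {
    edge_key <- function(a, b) paste(pmin(a, b), pmax(a, b))
    ek <- c(edge_key(f[, 1], f[, 2]), edge_key(f[, 2], f[, 3]), edge_key(f[, 3], f[, 1]))
    uk <- unique(ek)
    mid_of <- match(ek, uk) + nrow(v)
    pairs <- do.call(rbind, strsplit(uk, " "))
    mids <- (v[as.integer(pairs[, 1]), , drop = FALSE] +
             v[as.integer(pairs[, 2]), , drop = FALSE]) / 2
    mids <- mids / sqrt(rowSums(mids^2))
    v <- rbind(v, mids)
    nf <- nrow(f)
    m12 <- mid_of[1:nf]; m23 <- mid_of[nf + 1:nf]; m31 <- mid_of[2 * nf + 1:nf]
    f <- rbind(cbind(f[, 1], m12, m31), cbind(f[, 2], m23, m12),
               cbind(f[, 3], m31, m23), cbind(m12, m23, m31))
  }
  list(vertices = v, faces = f)
}

#' Triangulated ellipsoid surface
#'
#' Icosphere scaled by the semi-axes; optionally perturbed by seeded
#' low-order spherical-harmonic radial noise to emulate the lumpy outline
#' of a real segmented tumor.
#'
#' @param semi_axes length-3 semi-axes, m.
#' @param center length-3 center, m.
#' @param subdiv icosphere subdivision level.
#' @param lumpy_amplitude relative radial perturbation amplitude (0 = exact
#'   ellipsoid).
#' @param seed RNG seed for the perturbation coefficients.
#' @return a `tumor_shape` of kind `"surface_mesh"`.
#' @export
ellipsoid_surface <- function(semi_axes, center = c(0, 0, 0.0096), subdiv = 3,
                              lumpy_amplitude = 0, seed = 1) {
  ico <- icosphere(subdiv)
  u <- ico$vertices
  if (lumpy_amplitude > 0) {
    # low-order real spherical harmonics (l <= 2) with seeded coefficients
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
    co <- stats::rnorm(8)
    x <- u[, 1]; y <- u[, 2]; z <- u[, 3]
    basis <- cbind(x, y, z, x * y, y * z, x * z, x^2 - y^2, 3 * z^2 - 1)
    pert <- as.vector(basis %*% co)
    pert <- pert / max(abs(pert))
    u <- u * (1 + lumpy_amplitude * pert)
  }
  v <- sweep(u * rep(semi_axes, each = nrow(u)), 2, -center)
  vol <- surface_volume(v, ico$faces)
  structure(list(kind = "surface_mesh", vertices = v, faces = ico$faces,
                 volume = abs(vol), bbox = apply(v, 2, range),
                 center = as.numeric(center)),
            class = "tumor_shape")
}
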