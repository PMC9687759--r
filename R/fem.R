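# ---------------------------------------------------------------------------
# P1 finite-element assembly on triangle meshes, axisymmetric (per-radian,
# weight r) or Cartesian (weight 1). All assemblers take a per-element
# coefficient vector and a set of active elements; sparse matrices from the
# Matrix package.
# ---------------------------------------------------------------------------

# interior 3-point quadrature, degree 2, barycentric weights 1/3 each
.bq <- matrix(c(2/3, 1/6, 1/6, 1/6, 2/3, 1/6, 1/6, 1/6, 2/3), 3, 3, byrow = TRUE)

.assemble <- function(mesh, el, entries_fun, n = nrow(mesh$nodes)) {
  # entries_fun(i, j) returns per-element entry for local pair (i, j)
  t <- mesh$tri[el, , drop = FALSE]
  I <- J <- X <- vector("list", 9)
  k <- 1
  for (i in 1:3) for (j in 1:3) {
    I[[k]] <- t[, i]; J[[k]] <- t[, j]; X[[k]] <- entries_fun(i, j)
    k <- k + 1
  }
  Matrix::sparseMatrix(i = unlist(I), j = unlist(J), x = unlist(X),
                       dims = c(n, n))
}

# int coef * grad(u).grad(v) * w dA   (w = r or 1)
fem_stiffness <- function(mesh, el, coef) {
  w <- if (mesh$coord == "axisymmetric") mesh$rbar[el] else 1
  s <- coef * mesh$area[el] * w
  gb <- mesh$gb[el, , drop = FALSE]; gc <- mesh$gc[el, , drop = FALSE]
  .assemble(mesh, el, function(i, j) s * (gb[, i] * gb[, j] + gc[, i] * gc[, j]))
}

# int coef * u v * w dA with 3-pt quadrature (w = r varies over element)
fem_mass <- function(mesh, el, coef) {
  A <- mesh$area[el]
  t <- mesh$tri[el, , drop = FALSE]
  rq <- if (mesh$coord == "axisymmetric") {
    rn <- matrix(mesh$nodes[t, 1], ncol = 3)
    rn %*% t(.bq)                        # element x quadrature-point radii
  } else matrix(1, length(el), 3)
  .assemble(mesh, el, function(i, j) {
    coef * A / 3 * rowSums(sweep(rq, 2, .bq[, i] * .bq[, j], `*`))
  })
}

# Weighted operators for the axisymmetric azimuthal-field solve in the
# scaled unknown w = r * H_phi:
#   stiffness: int coef grad(w).grad(x) (1/r) dA
#   mass:      int coef w x (1/r) dA
# (3-point interior quadrature for the 1/r weight; w = 0 on the axis keeps
# all integrands finite)
fem_stiffness_invr <- function(mesh, el, coef) {
  A <- mesh$area[el]
  t <- mesh$tri[el, , drop = FALSE]
  rn <- matrix(mesh$nodes[t, 1], ncol = 3)
  invr_bar <- rowMeans(1 / (rn %*% t(.bq)))
  s <- coef * A * invr_bar
  gb <- mesh$gb[el, , drop = FALSE]; gc <- mesh$gc[el, , drop = FALSE]
  .assemble(mesh, el, function(i, j) s * (gb[, i] * gb[, j] + gc[, i] * gc[, j]))
}

fem_mass_invr <- function(mesh, el, coef) {
  A <- mesh$area[el]
  t <- mesh$tri[el, , drop = FALSE]
  rn <- matrix(mesh$nodes[t, 1], ncol = 3)
  rq <- rn %*% t(.bq)
  .assemble(mesh, el, function(i, j) {
    coef * A / 3 * rowSums(sweep(1 / rq, 2, .bq[, i] * .bq[, j], `*`))
  })
}

# int coef w x / r ds over boundary edges (2-point Gauss)
edge_mass_invr <- function(mesh, edge_idx, coef, n = nrow(mesh$nodes)) {
  e <- mesh$edges[edge_idx, , drop = FALSE]
  p <- mesh$nodes
  L <- sqrt((p[e[, 1], 1] - p[e[, 2], 1])^2 + (p[e[, 1], 2] - p[e[, 2], 2])^2)
  tg <- c(0.5 - 0.5 / sqrt(3), 0.5 + 0.5 / sqrt(3))
  rp <- p[e[, 1], 1]; rq <- p[e[, 2], 1]
  ent <- function(i, j) {
    out <- 0
    for (t in tg) {
      Ni <- if (i == 1) 1 - t else t
      Nj <- if (j == 1) 1 - t else t
      rr <- rp + t * (rq - rp)
      out <- out + 0.5 * Ni * Nj / rr
    }
    coef * L * out
  }
  Matrix::sparseMatrix(i = c(e[, 1], e[, 2], e[, 1], e[, 2]),
                       j = c(e[, 1], e[, 2], e[, 2], e[, 1]),
                       x = c(ent(1, 1), ent(2, 2), ent(1, 2), ent(2, 1)),
                       dims = c(n, n))
}

# int coef N_i / r ds over boundary edges (2-point Gauss), returned as a
# dense load vector
edge_load_invr <- function(mesh, edge_idx, coef, n = nrow(mesh$nodes)) {
  e <- mesh$edges[edge_idx, , drop = FALSE]
  p <- mesh$nodes
  L <- sqrt((p[e[, 1], 1] - p[e[, 2], 1])^2 + (p[e[, 1], 2] - p[e[, 2], 2])^2)
  tg <- c(0.5 - 0.5 / sqrt(3), 0.5 + 0.5 / sqrt(3))
  rp <- p[e[, 1], 1]; rq <- p[e[, 2], 1]
  b <- rep(0 * coef[1], n)
  for (t in tg) {
    rr <- rp + t * (rq - rp)
    v1 <- coef * L * 0.5 * (1 - t) / rr
    v2 <- coef * L * 0.5 * t / rr
    for (k in seq_len(nrow(e))) {
      b[e[k, 1]] <- b[e[k, 1]] + v1[k]
      b[e[k, 2]] <- b[e[k, 2]] + v2[k]
    }
  }
  b
}

# int coef u (vel . grad v)? No: advection int coef (vel . grad u) v w dA
fem_advection <- function(mesh, el, coef, vel) {
  # vel: length-2 (r/x, z) constant velocity
  w <- if (mesh$coord == "axisymmetric") mesh$rbar[el] else 1
  A <- mesh$area[el]
  gb <- mesh$gb[el, , drop = FALSE]; gc <- mesh$gc[el, , drop = FALSE]
  ug <- function(j) vel[1] * gb[, j] + vel[2] * gc[, j]
  .assemble(mesh, el, function(i, j) coef * A * w / 3 * ug(j))
}

# streamline (upwind) artificial diffusion: coef (vel.grad u)(vel.grad v)/|vel|^2
fem_streamline_diffusion <- function(mesh, el, coef, vel) {
  v2 <- sum(vel^2)
  if (v2 == 0) return(Matrix::sparseMatrix(i = integer(0), j = integer(0),
                                           x = numeric(0),
                                           dims = rep(nrow(mesh$nodes), 2)))
  w <- if (mesh$coord == "axisymmetric") mesh$rbar[el] else 1
  A <- mesh$area[el]
  gb <- mesh$gb[el, , drop = FALSE]; gc <- mesh$gc[el, , drop = FALSE]
  ug <- function(j) (vel[1] * gb[, j] + vel[2] * gc[, j]) / sqrt(v2)
  .assemble(mesh, el, function(i, j) coef * A * w * ug(i) * ug(j))
}

# int coef u v w ds over the given boundary edges (linear edge elements)
edge_mass <- function(mesh, edge_idx, coef, n = nrow(mesh$nodes)) {
  e <- mesh$edges[edge_idx, , drop = FALSE]
  p <- mesh$nodes
  L <- sqrt((p[e[, 1], 1] - p[e[, 2], 1])^2 + (p[e[, 1], 2] - p[e[, 2], 2])^2)
  if (mesh$coord == "axisymmetric") {
    rp <- p[e[, 1], 1]; rq <- p[e[, 2], 1]
    m11 <- L * (rp / 4 + rq / 12); m22 <- L * (rp / 12 + rq / 4)
    m12 <- L * (rp + rq) / 12
  } else {
    m11 <- m22 <- L / 3; m12 <- L / 6
  }
  Matrix::sparseMatrix(i = c(e[, 1], e[, 2], e[, 1], e[, 2]),
                       j = c(e[, 1], e[, 2], e[, 2], e[, 1]),
                       x = c(coef * m11, coef * m22, coef * m12, coef * m12),
                       dims = c(n, n))
}

# Solve the complex sparse system (Ar + i Ai) x = br + i bi via the
# equivalent 2N-real block system (Matrix has no complex sparse solver).
solve_complex <- function(Ar, Ai, b) {
  n <- nrow(Ar)
  M <- rbind(cbind(Ar, -Ai), cbind(Ai, Ar))
  rhs <- c(Re(b), Im(b))
  x <- Matrix::solve(M, rhs)
  complex(real = x[1:n], imaginary = x[n + 1:n])
}

# Impose Dirichlet values: symmetric elimination.
apply_dirichlet <- function(A, b, idx, vals) {
  if (length(idx) == 0) return(list(A = A, b = b))
  b <- b - as.vector(A[, idx, drop = FALSE] %*% vals)
  A[idx, ] <- 0; A[, idx] <- 0
  A[cbind(idx, idx)] <- 1
  b[idx] <- vals
  list(A = A, b = b)
}
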