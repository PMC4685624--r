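# Internal geometry and array helpers shared across modules.

# Default voxel-to-world affine: diagonal spacing, origin at voxel (0,0,0).
defaultAffine <- function(spacing) {
  a <- diag(c(spacing, 1))
  a
}

# Physical coordinates (mm) of voxel centers, 0-based indexing convention.
# Returns an n x 3 matrix for the supplied 1-based linear voxel indices.
voxelCoords <- function(affine, dims, linearIdx) {
  i0 <- (linearIdx - 1L) %% dims[1L]
  r <- (linearIdx - 1L) %/% dims[1L]
  j0 <- r %% dims[2L]
  k0 <- r %/% dims[2L]
  ijk1 <- cbind(i0, j0, k0, 1)
  xyz <- ijk1 %*% t(affine[1:3, , drop = FALSE])
  dimnames(xyz) <- NULL
  xyz
}

# World mm -> continuous 0-based voxel coordinates.
worldToVoxel <- function(affine, xyz) {
  inv <- solve(affine)
  p1 <- cbind(xyz, 1) %*% t(inv[1:3, , drop = FALSE])
  dimnames(p1) <- NULL
  p1
}

# Full lattice of voxel-center coordinates as three 3D arrays (mm).
latticeCoords <- function(affine, dims) {
  i <- (seq_len(dims[1L]) - 1L)
  j <- (seq_len(dims[2L]) - 1L)
  k <- (seq_len(dims[3L]) - 1L)
  X <- affine[1, 1] * array(i, dims) +
    affine[1, 2] * array(rep(j, each = dims[1L]), dims) +
    affine[1, 3] * array(rep(k, each = dims[1L] * dims[2L]), dims) +
    affine[1, 4]
  Y <- affine[2, 1] * array(i, dims) +
    affine[2, 2] * array(rep(j, each = dims[1L]), dims) +
    affine[2, 3] * array(rep(k, each = dims[1L] * dims[2L]), dims) +
    affine[2, 4]
  Z <- affine[3, 1] * array(i, dims) +
    affine[3, 2] * array(rep(j, each = dims[1L]), dims) +
    affine[3, 3] * array(rep(k, each = dims[1L] * dims[2L]), dims) +
    affine[3, 4]
  list(x = X, y = Y, z = Z)
}

# Shift a 3D logical array by (dx, dy, dz), filling with FALSE.
shiftMask <- function(m, dx, dy, dz) {
  d <- dim(m)
  out <- array(FALSE, d)
  sx <- max(1L, 1L + dx):min(d[1L], d[1L] + dx)
  sy <- max(1L, 1L + dy):min(d[2L], d[2L] + dy)
  sz <- max(1L, 1L + dz):min(d[3L], d[3L] + dz)
  out[sx, sy, sz] <- m[sx - dx, sy - dy, sz - dz]
  out
}

# 3D binary dilation. connectivity 6 (faces) or 26 (full 3x3x3 box).
binaryDilate <- function(m, connectivity = 26L) {
  out <- m
  offs <- neighborOffsets(connectivity)
  for (r in seq_len(nrow(offs)))
    out <- out | shiftMask(m, offs[r, 1L], offs[r, 2L], offs[r, 3L])
  out
}

binaryErode <- function(m, connectivity = 26L) {
  # voxels outside the array border are treated as background
  !binaryDilate(!m, connectivity)
}

neighborOffsets <- function(connectivity) {
  if (connectivity == 6L) {
    rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
          c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  } else {
    g <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
    g[rowSums(abs(g)) > 0, , drop = FALSE]
  }
}

# Morphological closing with a radius-1 structuring element.
binaryClose <- function(m, connectivity = 26L) {
  binaryErode(binaryDilate(m, connectivity), connectivity)
}

# Flood fill: grow `seed` inside `domain` by 6-connected dilation to a fixed
# point. Used for hole filling and seeded component extraction.
floodFill3D <- function(seed, domain) {
  cur <- seed & domain
  repeat {
    nxt <- (cur | binaryDilate(cur, 6L)) & domain
    if (identical(nxt, cur)) return(cur)
    cur <- nxt
  }
}

# Fill internal cavities: background voxels not reachable from the array
# border become foreground.
fillHoles3D <- function(m) {
  d <- dim(m)
  border <- array(FALSE, d)
  border[c(1L, d[1L]), , ] <- TRUE
  border[, c(1L, d[2L]), ] <- TRUE
  border[, , c(1L, d[3L])] <- TRUE
  outside <- floodFill3D(border & !m, !m)
  m | (!m & !outside)
}

# Signed change of maximal absolute value relative to the first element.
# Shared rule for delta-KE and delta-vortex-volume over an ordered phase path.
signedMaxDelta <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2L) return(NA_real_)
  d <- x[-1L] - x[1L]
  d[which.max(abs(d))]
}

# Cyclic central difference dV/dt on a periodic time axis of period rr.
cyclicDerivative <- function(values, time, rr) {
  n <- length(values)
  nxt <- c(2:n, 1L)
  prv <- c(n, 1:(n - 1L))
  dt <- (time[nxt] - time[prv]) %% rr
  dt[dt == 0] <- rr
  (values[nxt] - values[prv]) / dt
}

# Largest eigenvalue of symmetric 3x3 matrices, vectorised over voxels.
# Components are equal-length numeric vectors. Analytic trigonometric method.
eigMaxSym3 <- function(a11, a12, a13, a22, a23, a33) {
  q <- (a11 + a22 + a33) / 3
  p1 <- a12^2 + a13^2 + a23^2
  p2 <- (a11 - q)^2 + (a22 - q)^2 + (a33 - q)^2 + 2 * p1
  lam <- q  # isotropic fallback when p2 ~ 0
  nz <- p2 > .Machine$double.eps * pmax(1, q^2)
  if (any(nz)) {
    p <- sqrt(p2[nz] / 6)
    b11 <- (a11[nz] - q[nz]) / p; b22 <- (a22[nz] - q[nz]) / p
    b33 <- (a33[nz] - q[nz]) / p
    b12 <- a12[nz] / p; b13 <- a13[nz] / p; b23 <- a23[nz] / p
    detB <- b11 * (b22 * b33 - b23^2) - b12 * (b12 * b33 - b23 * b13) +
      b13 * (b12 * b23 - b22 * b13)
    r <- pmin(1, pmax(-1, detB / 2))
    phi <- acos(r) / 3
    lam[nz] <- q[nz] + 2 * p * cos(phi)
  }
  lam
}

`%||%` <- function(a, b) if (is.null(a)) b else a
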