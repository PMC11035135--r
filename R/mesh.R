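# iso-surface meshing for surface-area estimation
#
# Surface area of a labeled voxel region is estimated by triangulating the
# 0.5 iso-surface of its (Gaussian-smoothed) binary indicator with marching
# tetrahedra: each grid cube is split into six tetrahedra, and within a
# tetrahedron the iso-surface is one or two triangles with vertices placed by
# linear interpolation along crossing edges. Counting exposed voxel faces
# instead would overestimate the area of any smooth surface by a direction-
# dependent factor (up to ~1.5) and bias sphericity low; the smoothed-mesh
# estimator is accurate to well under 1% for a ball of radius 20 voxels.

gauss_kernel_1d <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k / sum(k)
}

# separable Gaussian smoothing of a 3-D array, zero-padded borders
smooth_field <- function(a, sigma) {
  if (sigma <= 0) return(a)
  k <- gauss_kernel_1d(sigma)
  r <- (length(k) - 1L) / 2L
  conv_axis <- function(a, axis) {
    d <- dim(a)
    perm <- c(axis, setdiff(1:3, axis))
    m <- aperm(a, perm)
    dm <- dim(m)
    m2 <- matrix(m, nrow = dm[1])
    n <- dm[1]
    out <- matrix(0, n, ncol(m2))
    for (j in seq_along(k)) {
      off <- j - r - 1L
      src <- seq_len(n) + off
      ok <- src >= 1L & src <= n
      out[ok, ] <- out[ok, ] + k[j] * m2[src[ok], , drop = FALSE]
    }
    dim(out) <- dm
    aperm(out, order(perm))
  }
  for (ax in 1:3) a <- conv_axis(a, ax)
  a
}

# triangulated area of the `level` iso-surface of scalar field `f` sampled at
# voxel centers; `voxel` scales grid steps to physical units (anisotropy ok)
mesh_isosurface_area <- function(f, level = 0.5, voxel = c(1, 1, 1)) {
  d <- dim(f)
  stop_if(length(d) != 3L, "field must be 3-D")
  nx <- d[1] - 1L; ny <- d[2] - 1L; nz <- d[3] - 1L
  corner <- rbind(c(0L,0L,0L), c(1L,0L,0L), c(1L,1L,0L), c(0L,1L,0L),
                  c(0L,0L,1L), c(1L,0L,1L), c(1L,1L,1L), c(0L,1L,1L))
  V <- vapply(1:8, function(i) {
    off <- corner[i, ]
    as.vector(f[(1:nx) + off[1], (1:ny) + off[2], (1:nz) + off[3]])
  }, numeric(nx * ny * nz))
  keep <- which(matrixStats_rowMins(V) < level & matrixStats_rowMaxs(V) > level)
  if (!length(keep)) return(0)
  base <- cbind(rep.int(seq_len(nx), ny * nz),
                rep.int(rep(seq_len(ny), each = nx), nz),
                rep(seq_len(nz), each = nx * ny))[keep, , drop = FALSE]
  V <- V[keep, , drop = FALSE]
  cpos <- lapply(1:8, function(i) sweep(base, 2L, corner[i, ], "+"))
  tri_area <- function(p1, p2, p3) {
    u <- sweep(p2 - p1, 2L, voxel, "*")
    w <- sweep(p3 - p1, 2L, voxel, "*")
    cx <- u[, 2] * w[, 3] - u[, 3] * w[, 2]
    cy <- u[, 3] * w[, 1] - u[, 1] * w[, 3]
    cz <- u[, 1] * w[, 2] - u[, 2] * w[, 1]
    0.5 * sqrt(cx^2 + cy^2 + cz^2)
  }
  interp <- function(pa, pb, va, vb) pa + (pb - pa) * ((level - va) / (vb - va))
  # six tetrahedra around the main diagonal 1-7 of the cube
  tets <- rbind(c(1L,6L,2L,7L), c(1L,2L,3L,7L), c(1L,3L,4L,7L),
                c(1L,4L,8L,7L), c(1L,8L,5L,7L), c(1L,5L,6L,7L))
  total <- 0
  for (ti in 1:6) {
    tv <- tets[ti, ]
    vv <- V[, tv, drop = FALSE]
    above <- vv > level
    code <- above[, 1] + 2L * above[, 2] + 4L * above[, 3] + 8L * above[, 4]
    for (cs in 1:14) {
      rows <- which(code == cs)
      if (!length(rows)) next
      ab <- c(bitwAnd(cs, 1L) > 0L, bitwAnd(cs, 2L) > 0L,
              bitwAnd(cs, 4L) > 0L, bitwAnd(cs, 8L) > 0L)
      hi <- which(ab); lo <- which(!ab)
      pos <- lapply(1:4, function(k) cpos[[tv[k]]][rows, , drop = FALSE])
      val <- lapply(1:4, function(k) vv[rows, k])
      if (length(hi) == 1L || length(lo) == 1L) {
        a <- if (length(hi) == 1L) hi else lo
        oth <- setdiff(1:4, a)
        p1 <- interp(pos[[a]], pos[[oth[1]]], val[[a]], val[[oth[1]]])
        p2 <- interp(pos[[a]], pos[[oth[2]]], val[[a]], val[[oth[2]]])
        p3 <- interp(pos[[a]], pos[[oth[3]]], val[[a]], val[[oth[3]]])
        total <- total + sum(tri_area(p1, p2, p3))
      } else {
        a <- hi[1]; b2 <- hi[2]; cc <- lo[1]; dd <- lo[2]
        pac <- interp(pos[[a]], pos[[cc]], val[[a]], val[[cc]])
        pad <- interp(pos[[a]], pos[[dd]], val[[a]], val[[dd]])
        pbc <- interp(pos[[b2]], pos[[cc]], val[[b2]], val[[cc]])
        pbd <- interp(pos[[b2]], pos[[dd]], val[[b2]], val[[dd]])
        total <- total + sum(tri_area(pac, pad, pbd)) +
          sum(tri_area(pac, pbd, pbc))
      }
    }
  }
  total
}

# row-wise min/max without a matrixStats dependency
matrixStats_rowMins <- function(m) do.call(pmin, as.data.frame(m))
matrixStats_rowMaxs <- function(m) do.call(pmax, as.data.frame(m))

# surface area (physical units) of one label in a labeled 3-D array; the
# indicator is padded by one voxel so surfaces at the array edge are closed,
# smoothed (sigma in voxel units), then meshed at the 0.5 level
label_surface_area <- function(labels, label, voxel, smooth_sigma = 1.0) {
  ind <- array(0, dim(labels) + 2L)
  ind[2:(dim(labels)[1] + 1L), 2:(dim(labels)[2] + 1L),
      2:(dim(labels)[3] + 1L)] <- (labels == label) * 1
  mesh_isosurface_area(smooth_field(ind, smooth_sigma), 0.5, voxel)
}
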