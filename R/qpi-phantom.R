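# synthetic refractive-index tomograms of ellipsoidal cells

#' Construct a refractive-index tomogram
#'
#' A `tomogram` is a 3-D grid of refractive index n(x, y, z) with voxel
#' dimensions in um and the refractive index of the surrounding medium. The
#' default voxel dimensions match the holotomography resolution the package
#' models (0.202 um lateral, 0.363 um axial); anisotropy is honored in every
#' downstream computation.
#'
#' @param n 3-D numeric array of refractive index.
#' @param voxel_um voxel dimensions (x, y, z) in um.
#' @param n_surr refractive index of the surrounding medium.
#' @return an object of class `tomogram`.
#' @export
tomogram <- function(n, voxel_um = c(0.202, 0.202, 0.363), n_surr = 1.337) {
  stop_if(!is.array(n) || length(dim(n)) != 3L, "n must be a 3-D array")
  stop_if(any(!is.finite(n)), "refractive-index grid must be finite")
  stop_if(length(voxel_um) != 3L || any(voxel_um <= 0),
          "voxel_um must be three positive sizes")
  structure(list(n = n, voxel_um = as.numeric(voxel_um), n_surr = n_surr),
            class = "tomogram")
}

# analytic ellipsoid volume
ellipsoid_volume <- function(semiaxes) 4 / 3 * pi * prod(semiaxes)

# Knud Thomsen approximation to the ellipsoid surface area (p = 1.6075,
# max relative error ~1.06%); serves as the ground-truth oracle for
# tolerance-based tests of the mesh estimator
ellipsoid_area_thomsen <- function(semiaxes, p = 1.6075) {
  a <- semiaxes[1]; b <- semiaxes[2]; c <- semiaxes[3]
  4 * pi * ((a^p * b^p + a^p * c^p + b^p * c^p) / 3)^(1 / p)
}

#' Specify a synthetic tomogram scene of ellipsoidal cells
#'
#' Cells are homogeneous ellipsoids of elevated refractive index embedded in
#' medium; optional additive Gaussian index noise emulates reconstruction
#' noise. Each cell must have `n_cell > n_surr` (a cell with no index
#' contrast carries no dry mass and cannot be imaged), and cells must not
#' overlap.
#'
#' @param grid grid size in voxels (x, y, z).
#' @param voxel_um voxel dimensions in um.
#' @param cells list of cells; each a list with `center` (um), `semiaxes`
#'   (um, length 3) and `n_cell`.
#' @param n_surr surrounding-medium refractive index.
#' @param noise_sd additive index-noise standard deviation.
#' @param seed integer seed.
#' @return an object of class `tomogram_scene_spec`.
#' @seealso [make_tomogram()]
#' @export
tomogram_scene_spec <- function(grid = c(96L, 96L, 64L),
                                voxel_um = c(0.202, 0.202, 0.363),
                                cells = list(), n_surr = 1.337,
                                noise_sd = 0, seed = 1L) {
  stop_if(length(grid) != 3L || any(grid < 4), "grid must be three sizes >= 4")
  stop_if(length(cells) == 0L, "at least one cell is required")
  for (cl in cells) {
    stop_if(is.null(cl$center) || is.null(cl$semiaxes) || is.null(cl$n_cell),
            "cell needs center, semiaxes, n_cell")
    stop_if(length(cl$semiaxes) != 3L || any(cl$semiaxes <= 0),
            "semi-axes must be three positive lengths")
    stop_if(cl$n_cell <= n_surr,
            "cells must have n_cell > n_surr (positive index contrast)")
  }
  stop_if(noise_sd < 0, "noise_sd must be >= 0")
  structure(list(grid = as.integer(grid), voxel_um = as.numeric(voxel_um),
                 cells = cells, n_surr = n_surr, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "tomogram_scene_spec")
}

#' Generate a synthetic tomogram with per-cell ground truth
#'
#' Digitizes each ellipsoid onto the voxel grid (a voxel belongs to a cell if
#' its center lies inside the ellipsoid), assigns `n_cell` inside and
#' `n_surr` outside, and adds seeded Gaussian index noise if requested.
#' Ground truth per cell: analytic ellipsoid volume (4/3) pi a b c, surface
#' area by the Thomsen approximation, and dry mass
#' (n_cell - n_surr) * V / alpha with alpha = 0.18 um^3/pg.
#'
#' @param spec a [tomogram_scene_spec()].
#' @param alpha specific refractive increment in um^3/pg.
#' @return list with `tomogram` (a [tomogram()]), `labels` (integer array of
#'   cell ids, 0 = medium) and `truth` (data frame: label, volume_um3,
#'   surface_um2, mass_pg, n_cell).
#' @examples
#' sp <- tomogram_scene_spec(grid = c(40, 40, 30),
#'   cells = list(list(center = c(4, 4, 5.4), semiaxes = c(2.5, 2.5, 2.5),
#'                     n_cell = 1.37)))
#' tt <- make_tomogram(sp)
#' tt$truth
#' @export
make_tomogram <- function(spec, alpha = 0.18) {
  stop_if(!inherits(spec, "tomogram_scene_spec"),
          "spec must be a tomogram_scene_spec")
  g <- spec$grid; v <- spec$voxel_um
  x <- (seq_len(g[1]) - 0.5) * v[1]
  y <- (seq_len(g[2]) - 0.5) * v[2]
  z <- (seq_len(g[3]) - 0.5) * v[3]
  n <- array(spec$n_surr, g)
  labels <- array(0L, g)
  for (i in seq_along(spec$cells)) {
    cl <- spec$cells[[i]]
    dx2 <- ((x - cl$center[1]) / cl$semiaxes[1])^2
    dy2 <- ((y - cl$center[2]) / cl$semiaxes[2])^2
    dz2 <- ((z - cl$center[3]) / cl$semiaxes[3])^2
    inside <- outer(outer(dx2, dy2, "+"), dz2, "+") <= 1
    stop_if(any(labels[inside] != 0L), "cells must not overlap")
    n[inside] <- cl$n_cell
    labels[inside] <- i
  }
  if (spec$noise_sd > 0) {
    n <- n + with_seed(spec$seed,
                       array(stats::rnorm(length(n), sd = spec$noise_sd), g))
  }
  truth <- do.call(rbind, lapply(seq_along(spec$cells), function(i) {
    cl <- spec$cells[[i]]
    V <- ellipsoid_volume(cl$semiaxes)
    data.frame(label = i, volume_um3 = V,
               surface_um2 = ellipsoid_area_thomsen(cl$semiaxes),
               mass_pg = (cl$n_cell - spec$n_surr) * V / alpha,
               n_cell = cl$n_cell)
  }))
  list(tomogram = tomogram(n, v, spec$n_surr), labels = labels, truth = truth)
}
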