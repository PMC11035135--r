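# quantitative-phase-imaging morphometry: segmentation, optical path length,
# dry mass, volume / surface / sphericity

# connected-component labeling of a logical array, BFS with a vectorized
# frontier; 26-connectivity in 3-D, 8-connectivity in 2-D
label_components <- function(mask) {
  d <- dim(mask)
  nd <- length(d)
  stop_if(nd < 2L || nd > 3L, "mask must be 2-D or 3-D")
  if (nd == 2L) { mask <- array(mask, c(d, 1L)); d <- dim(mask) }
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  labels <- array(0L, d)
  nxt <- 0L
  todo <- which(mask)
  seen <- array(FALSE, d)
  strides <- c(1L, d[1], d[1] * d[2])
  for (seed_idx in todo) {
    if (seen[seed_idx]) next
    nxt <- nxt + 1L
    frontier <- seed_idx
    seen[seed_idx] <- TRUE
    labels[seed_idx] <- nxt
    while (length(frontier)) {
      fi <- arrayInd(frontier, d)
      nb <- do.call(rbind, lapply(seq_len(nrow(offs)), function(k)
        sweep(fi, 2L, offs[k, ], "+")))
      ok <- nb[, 1] >= 1L & nb[, 1] <= d[1] &
        nb[, 2] >= 1L & nb[, 2] <= d[2] &
        nb[, 3] >= 1L & nb[, 3] <= d[3]
      nb <- nb[ok, , drop = FALSE]
      lin <- unique((nb[, 3] - 1L) * strides[3] +
                      (nb[, 2] - 1L) * strides[2] + nb[, 1])
      lin <- lin[mask[lin] & !seen[lin]]
      seen[lin] <- TRUE
      labels[lin] <- nxt
      frontier <- lin
    }
  }
  if (nd == 2L) dim(labels) <- d[1:2]
  labels
}

#' Segment cells in a tomogram by index-contrast thresholding
#'
#' Voxels with n - n_surr >= threshold are grouped into 26-connected
#' components; components touching the lateral (x or y) image boundary are
#' flagged excluded — mirroring the rule that cells close to the image
#' boundaries are dropped from morphometry — and components smaller than
#' `min_voxels` are discarded as debris. This simple thresholding segmenter
#' is intended for synthetic scenes and well-separated cells; real data may
#' instead supply an externally produced label mask to the morphometry
#' functions directly.
#'
#' @param tom a [tomogram()].
#' @param threshold index-contrast threshold (> 0).
#' @param min_voxels minimum component size in voxels.
#' @return a `cell_mask`: list with `labels` (integer array), `excluded`
#'   (logical, per label, TRUE if boundary-touching), `voxel_um`.
#'   An empty segmentation yields zero labels with a warning, not an error.
#' @export
segment_cells <- function(tom, threshold, min_voxels = 20L) {
  stop_if(!inherits(tom, "tomogram"), "tom must be a tomogram")
  stop_if(threshold <= 0, "threshold must be positive")
  fg <- (tom$n - tom$n_surr) >= threshold
  if (!any(fg)) {
    warning("threshold yields an empty segmentation")
    return(structure(list(labels = array(0L, dim(tom$n)),
                          excluded = logical(0), voxel_um = tom$voxel_um),
                     class = "cell_mask"))
  }
  labels <- label_components(fg)
  keep <- which(tabulate(labels[labels > 0L]) >= min_voxels)
  relab <- integer(max(labels))
  relab[keep] <- seq_along(keep)
  labels[labels > 0L] <- relab[labels[labels > 0L]]
  nlab <- length(keep)
  d <- dim(labels)
  excluded <- logical(nlab)
  if (nlab > 0L) {
    border <- unique(c(labels[c(1, d[1]), , ], labels[, c(1, d[2]), ]))
    excluded[border[border > 0L]] <- TRUE
  }
  structure(list(labels = labels, excluded = excluded,
                 voxel_um = tom$voxel_um),
            class = "cell_mask")
}

#' Construct a cell mask from an externally produced label array
#'
#' @param labels integer array (0 = background, positive integers = cells).
#' @param voxel_um voxel dimensions in um.
#' @param excluded logical vector, one entry per label, marking cells to skip
#'   (e.g. boundary-touching or ambiguous cells).
#' @return a `cell_mask`.
#' @export
cell_mask <- function(labels, voxel_um, excluded = NULL) {
  stop_if(any(labels < 0) || any(labels != round(labels)),
          "labels must be non-negative integers")
  nlab <- max(0L, max(labels))
  if (is.null(excluded)) excluded <- logical(nlab)
  stop_if(length(excluded) != nlab, "need one excluded flag per label")
  structure(list(labels = labels, excluded = excluded,
                 voxel_um = as.numeric(voxel_um)),
            class = "cell_mask")
}

#' Project a cell's refractive-index contrast to optical path length
#'
#' Integrates the index contrast along the optical (z) axis over the voxels
#' of one labeled cell: OPL(x, y) = sum_z (n(x, y, z) - n_surr) * dz, in um.
#' Only voxels belonging to the label contribute, so neighboring cells or
#' background noise in the same column do not leak into the integral.
#'
#' @param tom a [tomogram()].
#' @param mask a `cell_mask` congruent with the tomogram.
#' @param label the cell label to project.
#' @return an `opl_image`: list with `opl` (2-D matrix, um) and
#'   `pixel_area_um2`.
#' @export
project_opl <- function(tom, mask, label) {
  stop_if(!inherits(tom, "tomogram"), "tom must be a tomogram")
  stop_if(!identical(dim(tom$n), dim(mask$labels)),
          "mask shape must match the tomogram")
  stop_if(!(label %in% mask$labels), sprintf("label %s not present", label))
  contrib <- (tom$n - tom$n_surr) * (mask$labels == label)
  opl <- rowSums(contrib, dims = 2L) * tom$voxel_um[3]
  structure(list(opl = opl,
                 pixel_area_um2 = tom$voxel_um[1] * tom$voxel_um[2]),
            class = "opl_image")
}

#' Dry mass from an optical path length image
#'
#' m = (integral of OPL over the cell footprint) / alpha, with the OPL
#' integral discretized as sum(OPL) * pixel area. alpha = 0.18 um^3/pg is the
#' standard specific refractive increment for eukaryotic cells.
#'
#' @param opl an `opl_image` from [project_opl()].
#' @param alpha specific refractive increment, um^3/pg (> 0).
#' @return dry mass in pg.
#' @examples
#' # uniform slab: contrast 0.03 over 5 um thickness and 100 um^2 footprint
#' # -> OPL 0.15 um everywhere -> m = 0.03 * 5 * 100 / 0.18 = 83.33 pg
#' @export
dry_mass <- function(opl, alpha = 0.18) {
  stop_if(!inherits(opl, "opl_image"), "opl must be an opl_image")
  stop_if(!is.numeric(alpha) || alpha <= 0, "alpha must be positive")
  sum(opl$opl) * opl$pixel_area_um2 / alpha
}

#' Sphericity from volume and surface area
#'
#' Psi = pi^(1/3) (6 V)^(2/3) / S. Equals 1 for a sphere and decreases for
#' elongated or irregular shapes; a cube gives pi^(1/3) 6^(2/3) / 6 ~ 0.806.
#'
#' @param volume volume (um^3).
#' @param surface surface area (um^2).
#' @return dimensionless sphericity.
#' @export
sphericity <- function(volume, surface) {
  stop_if(any(volume < 0) || any(surface <= 0),
          "volume must be >= 0 and surface > 0")
  pi^(1 / 3) * (6 * volume)^(2 / 3) / surface
}

#' Morphometrics of one segmented cell
#'
#' Volume is voxel count times voxel volume; surface area is measured on a
#' triangulated iso-surface of the (smoothed) label indicator rather than by
#' counting exposed voxel faces, which would systematically overestimate
#' smooth surfaces and bias sphericity low; sphericity follows from
#' [sphericity()]. Cells flagged excluded (boundary-touching) raise an error
#' unless `allow_excluded = TRUE`.
#'
#' @param mask a `cell_mask`.
#' @param label cell label.
#' @param smooth_sigma Gaussian pre-smoothing of the indicator, in voxels.
#' @param allow_excluded set TRUE to measure an excluded cell anyway.
#' @return a one-row data frame: label, n_voxels, volume_um3, surface_um2,
#'   sphericity, excluded.
#' @export
morphometrics <- function(mask, label, smooth_sigma = 1.0,
                          allow_excluded = FALSE) {
  stop_if(!inherits(mask, "cell_mask"), "mask must be a cell_mask")
  stop_if(!(label %in% mask$labels), sprintf("label %s not present", label))
  excl <- isTRUE(mask$excluded[label])
  stop_if(excl && !allow_excluded,
          sprintf(paste0("cell %s touches the image boundary and is excluded",
                         " from morphometry; pass allow_excluded = TRUE to",
                         " override"), label))
  nvox <- sum(mask$labels == label)
  v <- mask$voxel_um
  V <- nvox * prod(v)
  S <- label_surface_area(mask$labels, label, v, smooth_sigma)
  data.frame(label = label, n_voxels = nvox, volume_um3 = V, surface_um2 = S,
             sphericity = sphericity(V, S), excluded = excl)
}

#' Morphometry and dry mass for every non-excluded cell in a scene
#'
#' @param tom a [tomogram()].
#' @param mask a `cell_mask` for the tomogram.
#' @param alpha specific refractive increment, um^3/pg.
#' @param smooth_sigma indicator smoothing for the surface mesh, voxels.
#' @return data frame with one row per included cell: label, n_voxels,
#'   volume_um3, surface_um2, sphericity, mass_pg.
#' @export
morphometry_table <- function(tom, mask, alpha = 0.18, smooth_sigma = 1.0) {
  labs <- sort(unique(mask$labels[mask$labels > 0L]))
  labs <- labs[!mask$excluded[labs]]
  stop_if(length(labs) == 0L, "no included cells in the mask")
  do.call(rbind, lapply(labs, function(l) {
    rec <- morphometrics(mask, l, smooth_sigma)
    rec$mass_pg <- dry_mass(project_opl(tom, mask, l), alpha)
    rec[c("label", "n_voxels", "volume_um3", "surface_um2", "sphericity",
          "mass_pg")]
  }))
}

#' Fold change of a morphometric between two groups
#'
#' mean(case) / mean(control) per metric, with the standard error propagated
#' from the two group s.e.m.s: se(f) = f * sqrt((se_a/m_a)^2 + (se_b/m_b)^2).
#' Used to report reporter-vs-control ratios of dry mass, volume and
#' sphericity, where 1 means no difference.
#'
#' @param case,control numeric vectors of per-replicate (e.g. per-image mean)
#'   values.
#' @return list with `fold`, `se`, `n_case`, `n_control`.
#' @export
morphometry_fold <- function(case, control) {
  stop_if(length(case) == 0L || length(control) == 0L, "empty group")
  stop_if(mean(control) <= 0, "control mean must be positive")
  f <- mean(case) / mean(control)
  se <- if (length(case) > 1 && length(control) > 1)
    f * sqrt((sem(case) / mean(case))^2 + (sem(control) / mean(control))^2)
  else NA_real_
  list(fold = f, se = se, n_case = length(case), n_control = length(control))
}
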