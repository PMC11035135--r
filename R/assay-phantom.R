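# seeded fixtures with ground truth for the per-assay formulas

# digitized disk mask helper (pixel centers)
plant_disks <- function(dim, disks) {
  m <- matrix(FALSE, dim[1], dim[2])
  rows <- matrix(rep(seq_len(dim[1]), dim[2]), dim[1])
  cols <- matrix(rep(seq_len(dim[2]), each = dim[1]), dim[1])
  for (d in disks) {
    m <- m | ((rows - d$center[1])^2 + (cols - d$center[2])^2 <= d$radius^2)
  }
  m
}

#' Generate a ground-truth-annotated assay fixture
#'
#' One generator covering the five assay-quantification inputs:
#' * `"quadrants"` — flow-cytometry quadrant counts with known stimulation
#'   percentage. `params$counts`: named counts for `CD3+CD25+`, `CD3+CD25-`,
#'   `CD3-CD25+`, `CD3-CD25-`.
#' * `"invasion_mask"` — binary escaped-cell mask with planted disks.
#'   `params`: `dim`, `disks` (list of `center`/`radius`),
#'   `total_area_mm2` (default 113.5).
#' * `"bead_image"` — cell mask plus bead-fluorescence channel with planted
#'   per-cell integrated intensities. `params`: `dim`, `cells` (disks),
#'   `intensities` (one per cell), `background` level, optional `noise_sd`.
#' * `"dilution_series"` — Ct vs dilution with prescribed slope.
#'   `params`: `slope` (cycles/decade), `intercept`, `dilutions`,
#'   optional `noise_sd`.
#' * `"standard_curve"` — absorbance-concentration standards from a
#'   prescribed quadratic. `params`: `coef` (c(b0, b1, b2)),
#'   `concentrations`, optional `noise_sd`.
#'
#' @param kind fixture kind, one of the five above.
#' @param params named list of parameters (see above).
#' @param seed integer seed for any noise.
#' @return list with `data` (the fixture) and `truth` (the planted ground
#'   truth the corresponding estimator should recover).
#' @export
make_assay_fixture <- function(kind, params = list(), seed = 1L) {
  switch(
    kind,
    quadrants = {
      counts <- params$counts
      need <- c("CD3+CD25+", "CD3+CD25-", "CD3-CD25+", "CD3-CD25-")
      stop_if(is.null(counts) || !all(need %in% names(counts)),
              "params$counts must name all four quadrants")
      cd3 <- counts[["CD3+CD25+"]] + counts[["CD3+CD25-"]]
      list(data = counts,
           truth = list(stimulation_pct = 100 * counts[["CD3+CD25+"]] / cd3))
    },
    invasion_mask = {
      stop_if(is.null(params$dim) || is.null(params$disks),
              "params needs dim and disks")
      m <- plant_disks(params$dim, params$disks)
      area <- if (is.null(params$total_area_mm2)) 113.5 else
        params$total_area_mm2
      list(data = list(mask = m, total_area_mm2 = area),
           truth = list(escaped_pixels = sum(m),
                        area_mm2 = sum(m) / length(m) * area))
    },
    bead_image = {
      stop_if(is.null(params$dim) || is.null(params$cells) ||
                is.null(params$intensities), "params needs dim, cells, intensities")
      stop_if(length(params$cells) != length(params$intensities),
              "one intensity per cell")
      labels <- matrix(0L, params$dim[1], params$dim[2])
      bead <- matrix(if (is.null(params$background)) 0 else params$background,
                     params$dim[1], params$dim[2])
      for (i in seq_along(params$cells)) {
        d <- plant_disks(params$dim, params$cells[i])
        stop_if(any(labels[d] != 0L), "cells must not overlap")
        labels[d] <- i
        bead[d] <- bead[d] + params$intensities[i] / sum(d)
      }
      if (!is.null(params$noise_sd) && params$noise_sd > 0) {
        bead <- bead + with_seed(seed,
          matrix(stats::rnorm(length(bead), sd = params$noise_sd),
                 nrow(bead)))
      }
      list(data = list(bead = bead, cells = labels),
           truth = list(index = mean(params$intensities),
                        per_cell = params$intensities))
    },
    dilution_series = {
      stop_if(is.null(params$slope), "params needs slope")
      dil <- if (is.null(params$dilutions)) 10^-(0:4) else params$dilutions
      b0 <- if (is.null(params$intercept)) 20 else params$intercept
      ct <- b0 + params$slope * log10(dil)
      if (!is.null(params$noise_sd) && params$noise_sd > 0) {
        ct <- ct + with_seed(seed, stats::rnorm(length(ct),
                                                sd = params$noise_sd))
      }
      list(data = data.frame(dilution = dil, ct = ct),
           truth = list(slope = params$slope,
                        efficiency_pct = (10^(-1 / params$slope) - 1) * 100))
    },
    standard_curve = {
      stop_if(is.null(params$coef) || length(params$coef) != 3L,
              "params$coef must be the three quadratic coefficients")
      conc <- if (is.null(params$concentrations))
        c(0.1, 0.2, 0.4, 0.8, 1.6, 3.2, 6.4, 12.8) else params$concentrations
      sig <- params$coef[1] + params$coef[2] * conc + params$coef[3] * conc^2
      if (!is.null(params$noise_sd) && params$noise_sd > 0) {
        sig <- sig + with_seed(seed, stats::rnorm(length(sig),
                                                  sd = params$noise_sd))
      }
      list(data = data.frame(concentration = conc, signal = sig),
           truth = list(coef = params$coef, concentrations = conc))
    },
    stop(sprintf("unknown fixture kind '%s'", kind), call. = FALSE)
  )
}
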