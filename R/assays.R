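# per-assay quantification formulas: T-cell stimulation, phagocytic index,
# invasion area, viability-normalized fold changes, ELISA standard curve

#' T-cell stimulation percentage from flow-cytometry quadrant counts
#'
#' Stimulation% = 100 * CD3+CD25+ / (CD3+CD25+ + CD3+CD25-): the fraction of
#' CD3+ T cells that also express the activation marker CD25. The CD3-
#' quadrants are ignored by construction.
#'
#' @param counts named non-negative counts with entries `CD3+CD25+`,
#'   `CD3+CD25-` (the `CD3-` quadrants may be present and are ignored).
#' @return stimulation percentage in `[0, 100]`.
#' @examples
#' stimulation_pct(c(`CD3+CD25+` = 30, `CD3+CD25-` = 70,
#'                   `CD3-CD25+` = 5, `CD3-CD25-` = 95))  # 30
#' @export
stimulation_pct <- function(counts) {
  need <- c("CD3+CD25+", "CD3+CD25-")
  stop_if(!all(need %in% names(counts)),
          "counts must name CD3+CD25+ and CD3+CD25-")
  pp <- counts[["CD3+CD25+"]]; pm <- counts[["CD3+CD25-"]]
  stop_if(pp < 0 || pm < 0, "counts must be non-negative")
  stop_if(pp + pm == 0, "no CD3+ events: stimulation undefined")
  100 * pp / (pp + pm)
}

#' Phagocytic index from a bead-fluorescence image and a cell mask
#'
#' Background-subtracted total bead-channel fluorescence inside cell regions
#' divided by the number of cells: the average integrated bead fluorescence
#' per macrophage. Background defaults to the median of non-cell pixels.
#'
#' @param bead 2-D numeric matrix, bead-fluorescence channel.
#' @param cells either an integer label matrix (0 = background) or a logical
#'   mask (cells then counted as 8-connected components).
#' @param background `"median"` (median of non-cell pixels, default),
#'   `"none"`, or a number.
#' @return index in fluorescence a.u. per cell.
#' @export
phagocytic_index <- function(bead, cells, background = "median") {
  stop_if(!identical(dim(bead), dim(cells)), "bead and cells shapes differ")
  if (is.logical(cells)) cells <- label_components(cells)
  stop_if(!any(cells > 0), "cell mask is empty")
  n_cells <- length(unique(cells[cells > 0]))
  bg <- if (identical(background, "median")) {
    if (any(cells == 0)) stats::median(bead[cells == 0]) else 0
  } else if (identical(background, "none")) 0 else {
    stop_if(!is.numeric(background), "background must be 'median', 'none' or a number")
    background
  }
  sum(bead[cells > 0] - bg) / n_cells
}

#' Escaped-cell area from a Matrigel-invasion mask
#'
#' Converts the fraction of image pixels classified as escaped cells to
#' physical area: (escaped pixels / total pixels) * total imaged area. The
#' default imaged area of 113.5 mm^2 corresponds to the 10 x 10 tiled
#' confocal field used for invasion imaging.
#'
#' @param mask 2-D logical (or 0/1) matrix of escaped-cell pixels.
#' @param total_area_mm2 total imaged area in mm^2.
#' @return escaped area in mm^2.
#' @examples
#' invasion_area(matrix(c(TRUE, FALSE, FALSE, FALSE), 2))  # 28.375
#' @export
invasion_area <- function(mask, total_area_mm2 = 113.5) {
  stop_if(length(dim(mask)) != 2L, "mask must be 2-D")
  stop_if(total_area_mm2 <= 0, "total imaged area must be positive")
  sum(mask != 0) / length(mask) * total_area_mm2
}

#' Group fold change from plate-reader wells, with optional per-well
#' normalization
#'
#' Computes mean(case) / mean(control) of a per-well readout. When a
#' `normalizer` column is given (the viable-cell readout: total ATP content
#' or MTT reduction), each well's signal is first divided by its normalizer —
#' the convention for reporting caspase-3/7 activation per viable cell, so
#' that a change in cell number alone cancels. The standard error is
#' propagated from the two group s.e.m.s.
#'
#' @param wells data frame with columns `group`, `signal`, and optionally the
#'   normalizer column.
#' @param case,control group labels.
#' @param signal name of the signal column (default `"signal"`).
#' @param normalizer optional name of the per-well viability column.
#' @return list with `fold`, `se`, `n_case`, `n_control`.
#' @examples
#' w <- data.frame(group = rep(c("Aqp1", "GFP"), each = 3),
#'                 signal = c(2, 2.1, 1.9, 1, 1.05, 0.95),
#'                 atp = c(2, 2.1, 1.9, 1, 1.05, 0.95))
#' plate_fold(w, "Aqp1", "GFP", normalizer = "atp")$fold  # 1: ratio cancels
#' @export
plate_fold <- function(wells, case, control, signal = "signal",
                       normalizer = NULL) {
  stop_if(!is.data.frame(wells) || !all(c("group", signal) %in% names(wells)),
          "wells must have columns group and the signal column")
  val <- wells[[signal]]
  if (!is.null(normalizer)) {
    stop_if(!normalizer %in% names(wells),
            sprintf("normalizer column '%s' missing", normalizer))
    stop_if(any(wells[[normalizer]] <= 0), "normalizer must be positive")
    val <- val / wells[[normalizer]]
  }
  a <- val[wells$group == case]
  b <- val[wells$group == control]
  stop_if(length(a) == 0L || length(b) == 0L, "case or control group empty")
  stop_if(mean(b) <= 0, "control group mean must be positive")
  f <- mean(a) / mean(b)
  se <- if (length(a) > 1 && length(b) > 1)
    f * sqrt((sem(a) / mean(a))^2 + (sem(b) / mean(b))^2) else NA_real_
  list(fold = f, se = se, n_case = length(a), n_control = length(b))
}

#' Fit a quadratic ELISA standard curve
#'
#' Least-squares fit of signal = b0 + b1 c + b2 c^2 over the standard
#' concentrations. The fitted curve must be strictly monotone over the
#' calibrated concentration range (a usable immunoassay calibration is);
#' non-monotonicity is an error. The calibrated signal range is recorded so
#' inversion can refuse extrapolation.
#'
#' @param concentration standard concentrations (ng/mL), >= 3 distinct.
#' @param signal measured signals (a.u.).
#' @return a `standard_curve`: list with `coef` (b0, b1, b2), `conc_range`,
#'   `signal_range`, `r_squared`.
#' @export
fit_standard_curve <- function(concentration, signal) {
  stop_if(length(concentration) != length(signal), "lengths differ")
  stop_if(length(unique(concentration)) < 3L,
          "need >= 3 distinct standard concentrations")
  fit <- stats::lm(signal ~ concentration + I(concentration^2))
  cf <- unname(stats::coef(fit))
  rng <- range(concentration)
  # derivative b1 + 2 b2 c must not change sign inside the range
  dlo <- cf[2] + 2 * cf[3] * rng[1]
  dhi <- cf[2] + 2 * cf[3] * rng[2]
  stop_if(dlo * dhi <= 0,
          "fitted quadratic is not monotone over the calibrated range")
  pred <- cf[1] + cf[2] * rng + cf[3] * rng^2
  sst <- sum((signal - mean(signal))^2)
  structure(list(coef = cf, conc_range = rng,
                 signal_range = sort(pred),
                 r_squared = if (sst == 0) 1 else
                   1 - sum(stats::residuals(fit)^2) / sst),
            class = "standard_curve")
}

#' Invert a quadratic standard curve to concentrations
#'
#' Solves b2 c^2 + b1 c + (b0 - s) = 0 for each measured signal and keeps the
#' root inside the calibrated concentration range. Signals outside the
#' calibrated signal range are an error (no extrapolation beyond the assay's
#' dynamic range); two in-range roots would contradict monotonicity and are
#' also an error.
#'
#' @param curve a `standard_curve` from [fit_standard_curve()].
#' @param signal measured signals (a.u.).
#' @return concentrations in ng/mL.
#' @export
invert_standard_curve <- function(curve, signal) {
  stop_if(!inherits(curve, "standard_curve"), "curve must be a standard_curve")
  tol <- 1e-8 * max(1, abs(diff(curve$signal_range)))
  out_of_range <- signal < curve$signal_range[1] - tol |
    signal > curve$signal_range[2] + tol
  stop_if(any(out_of_range),
          sprintf("signal(s) %s outside the calibrated range [%.4g, %.4g]",
                  paste(signif(signal[out_of_range], 4), collapse = ", "),
                  curve$signal_range[1], curve$signal_range[2]))
  cf <- curve$coef
  rng <- curve$conc_range
  ctol <- 1e-9 * max(1, rng[2])
  vapply(signal, function(s) {
    if (abs(cf[3]) < 1e-14) {  # effectively linear
      return((s - cf[1]) / cf[2])
    }
    disc <- cf[2]^2 - 4 * cf[3] * (cf[1] - s)
    stop_if(disc < 0, "no real root for measured signal")
    roots <- (-cf[2] + c(-1, 1) * sqrt(disc)) / (2 * cf[3])
    inr <- roots[roots >= rng[1] - ctol & roots <= rng[2] + ctol]
    stop_if(length(inr) == 0L, "no root inside the calibrated range")
    stop_if(length(inr) > 1L && diff(range(inr)) > ctol,
            "ambiguous inversion: two roots inside the calibrated range")
    inr[1]
  }, numeric(1))
}

#' Insulin secretion from ELISA signals, normalized to total protein
#'
#' Inverts the standard curve for each supernatant signal and divides by the
#' sample's total cellular protein, giving secretion per unit protein —
#' the normalization that makes glucose-stimulated secretion comparable
#' across wells with different cell content.
#'
#' @param curve a `standard_curve`.
#' @param signal measured supernatant signals (a.u.).
#' @param total_protein_ug total cellular protein per sample (ug), positive.
#' @return data frame with `concentration_ng_ml` and
#'   `secretion_ng_per_ug_protein`.
#' @export
insulin_secretion <- function(curve, signal, total_protein_ug) {
  stop_if(any(total_protein_ug <= 0), "total protein must be positive")
  conc <- invert_standard_curve(curve, signal)
  data.frame(concentration_ng_ml = conc,
             secretion_ng_per_ug_protein = conc / total_protein_ug)
}
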