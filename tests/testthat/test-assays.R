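# assay formulas: stimulation %, phagocytic index, invasion area,
# viability-normalized folds, quadratic standard curve

test_that("stimulation percentage: worked example and edge cases", {
  q <- c(`CD3+CD25+` = 30, `CD3+CD25-` = 70, `CD3-CD25+` = 5,
         `CD3-CD25-` = 95)
  expect_equal(stimulation_pct(q), 30)
  q0 <- q; q0[["CD3+CD25+"]] <- 0
  expect_equal(stimulation_pct(q0), 0)
  qz <- q; qz[["CD3+CD25+"]] <- 0; qz[["CD3+CD25-"]] <- 0
  expect_error(stimulation_pct(qz), "CD3")
  # invariant to scaling all counts; CD3- quadrants ignored
  expect_equal(stimulation_pct(q * 7L), 30)
  qq <- q; qq[["CD3-CD25+"]] <- 1e6
  expect_equal(stimulation_pct(qq), 30)
})

test_that("stimulation matches brute-force ratio on random counts", {
  for (s in 1:100) {
    set.seed(s)
    cts <- c(`CD3+CD25+` = rpois(1, 200) + 1, `CD3+CD25-` = rpois(1, 500),
             `CD3-CD25+` = rpois(1, 50), `CD3-CD25-` = rpois(1, 800))
    brute <- 100 * cts[["CD3+CD25+"]] /
      (cts[["CD3+CD25+"]] + cts[["CD3+CD25-"]])
    expect_identical(stimulation_pct(cts), brute)
    expect_gte(stimulation_pct(cts), 0)
    expect_lte(stimulation_pct(cts), 100)
  }
})

test_that("invasion area: fraction times the imaged area", {
  m <- matrix(FALSE, 100, 100)
  m[1:10, 1:100] <- TRUE  # 10% of pixels
  expect_equal(invasion_area(m), 11.35)
  expect_equal(invasion_area(matrix(FALSE, 10, 10)), 0)
  # additive over disjoint regions, bounded by the imaged area
  m2 <- matrix(FALSE, 100, 100); m2[60:80, 5:30] <- TRUE
  expect_equal(invasion_area(m | m2), invasion_area(m) + invasion_area(m2))
  expect_lte(invasion_area(matrix(TRUE, 5, 5)), 113.5)
  # planted-disk fixture equals brute-force pixel count conversion
  fx <- make_assay_fixture("invasion_mask", list(
    dim = c(64L, 64L), disks = list(list(center = c(30, 30), radius = 10))))
  expect_equal(invasion_area(fx$data$mask), fx$truth$area_mm2)
  expect_equal(sum(fx$data$mask), fx$truth$escaped_pixels)
})

test_that("phagocytic index recovers planted per-cell intensities", {
  fx <- make_assay_fixture("bead_image", list(
    dim = c(64L, 64L),
    cells = list(list(center = c(16, 16), radius = 6),
                 list(center = c(44, 20), radius = 5),
                 list(center = c(30, 48), radius = 7)),
    intensities = c(900, 1200, 600), background = 10))
  idx <- phagocytic_index(fx$data$bead, fx$data$cells)
  expect_equal(idx, fx$truth$index, tolerance = 1e-10)
  # zero bead channel gives 0
  expect_equal(phagocytic_index(matrix(0, 64, 64), fx$data$cells,
                                background = "none"), 0)
  # uniform signal s over cells, zero background, N cells
  cells <- fx$data$cells
  bead <- matrix(0, 64, 64); bead[cells > 0] <- 2.5
  expect_equal(phagocytic_index(bead, cells, background = "none"),
               2.5 * sum(cells > 0) / 3)
  expect_error(phagocytic_index(bead, matrix(0L, 64, 64)), "empty")
})

test_that("plate folds: identity, ratio cancellation, scale invariance", {
  w <- data.frame(group = rep(c("A", "G"), each = 4),
                  signal = c(4, 4.2, 3.9, 4.1, 4, 4.2, 3.9, 4.1),
                  viability = c(2, 2.1, 1.95, 2.05, 2, 2.1, 1.95, 2.05))
  expect_equal(plate_fold(w, "A", "G")$fold, 1)
  # caspase and viability doubled together in the case group cancel
  w2 <- w
  w2$signal[w2$group == "A"] <- 2 * w2$signal[w2$group == "A"]
  w2$viability[w2$group == "A"] <- 2 * w2$viability[w2$group == "A"]
  expect_equal(plate_fold(w2, "A", "G", normalizer = "viability")$fold, 1,
               tolerance = 1e-12)
  expect_gt(plate_fold(w2, "A", "G")$fold, 1.9)  # unnormalized sees the 2x
  # invariant under global rescaling of reader units
  w3 <- w2; w3$signal <- w3$signal * 1e3
  expect_equal(plate_fold(w3, "A", "G")$fold,
               plate_fold(w2, "A", "G")$fold, tolerance = 1e-12)
  expect_error(plate_fold(w, "A", "X"), "empty")
})

test_that("plate folds equal brute-force spreadsheet computation", {
  for (s in 1:100) {
    set.seed(s)
    n <- 5L
    w <- data.frame(group = rep(c("A", "G"), each = n),
                    signal = runif(2 * n, 0.5, 2),
                    viability = runif(2 * n, 0.5, 2))
    got <- plate_fold(w, "A", "G", normalizer = "viability")$fold
    r <- w$signal / w$viability
    brute <- mean(r[1:n]) / mean(r[(n + 1):(2 * n)])
    expect_equal(got, brute, tolerance = 1e-12)
  }
})

test_that("standard-curve inversion is exact on noiseless quadratics", {
  fx <- make_assay_fixture("standard_curve",
                           list(coef = c(0.05, 0.3, -0.01)))
  curve <- fit_standard_curve(fx$data$concentration, fx$data$signal)
  back <- invert_standard_curve(curve, fx$data$signal)
  expect_equal(back, fx$data$concentration, tolerance = 1e-8)
  # forward-then-invert identity at arbitrary in-range concentrations
  conc <- seq(0.15, 12, length.out = 25)
  sig <- curve$coef[1] + curve$coef[2] * conc + curve$coef[3] * conc^2
  expect_equal(invert_standard_curve(curve, sig), conc, tolerance = 1e-8)
})

test_that("signals outside the calibrated range are refused", {
  fx <- make_assay_fixture("standard_curve", list(coef = c(0.05, 0.3, -0.01)))
  curve <- fit_standard_curve(fx$data$concentration, fx$data$signal)
  low <- min(fx$data$signal)
  expect_error(invert_standard_curve(curve, low - 0.5), "calibrated range")
  # non-monotone quadratic over the range is rejected at fit time
  conc <- c(0.1, 0.2, 0.4, 0.8, 1.6, 3.2, 6.4, 12.8)
  sig <- 1 + 0.5 * conc - 0.06 * conc^2  # vertex at c ~ 4.2, inside range
  expect_error(fit_standard_curve(conc, sig), "monotone")
})

test_that("quadratic inversion matches brute-force grid search", {
  for (s in 1:100) {
    set.seed(s)
    cf <- c(runif(1, 0, 0.2), runif(1, 0.35, 0.5), runif(1, -0.012, -0.001))
    conc <- c(0.1, 0.2, 0.4, 0.8, 1.6, 3.2, 6.4, 12.8)
    sig <- cf[1] + cf[2] * conc + cf[3] * conc^2
    curve <- fit_standard_curve(conc, sig)
    target <- runif(1, min(sig), max(sig))
    got <- invert_standard_curve(curve, target)
    grid <- seq(0.1, 12.8, by = 1e-5)
    brute <- grid[which.min(abs(cf[1] + cf[2] * grid + cf[3] * grid^2 -
                                  target))]
    expect_equal(got, brute, tolerance = 1e-4)
  }
})

test_that("insulin secretion normalizes to total protein", {
  fx <- make_assay_fixture("standard_curve", list(coef = c(0.05, 0.3, -0.01)))
  curve <- fit_standard_curve(fx$data$concentration, fx$data$signal)
  sig <- fx$data$signal[3:5]
  out <- insulin_secretion(curve, sig, total_protein_ug = 20)
  expect_equal(out$secretion_ng_per_ug_protein,
               out$concentration_ng_ml / 20)
  expect_error(insulin_secretion(curve, sig, 0), "positive")
})

test_that("unknown fixture kinds are rejected", {
  expect_error(make_assay_fixture("nope"), "unknown")
})
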