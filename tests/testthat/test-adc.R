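# ADC estimation: b-value algebra, ROI decay, scalar and voxel-wise fits,
# rendering, reporter contrast

test_that("effective b-value follows the pulsed-gradient formula", {
  expect_equal(effective_bvalue(G = 0), 0)
  # quadratic in G
  b1 <- effective_bvalue(G = 0.02)
  expect_equal(effective_bvalue(G = 0.04), 4 * b1, tolerance = 1e-12)
  # hand-tracked unit check: gamma = 2.675e8 rad/s/T, delta = 5 ms,
  # Delta = 300 ms, G = 43.3 mT/m:
  # b_SI = (2.675e8)^2 * 0.0433^2 * (5e-3)^2 * (0.3 - 5e-3/3) s/m^2
  #      = 1.0007e9 s/m^2 -> ~1.0 ms/um^2
  expect_equal(effective_bvalue(2.675e8, 0.0433, 5, 300), 1.0007,
               tolerance = 1e-3)
  expect_error(effective_bvalue(G = 0.02, delta_ms = -1), "positive")
  expect_error(effective_bvalue(G = 0.02, delta_ms = 300, Delta_ms = 5),
               "Delta")
})

test_that("diffusivity unit conversion round-trips exactly", {
  x <- c(0.1, 1, 2.5)
  expect_identical(mm2s_to_um2ms(um2ms_to_mm2s(x)), x)
  expect_equal(um2ms_to_mm2s(1), 1e-3)
})

test_that("roi_mean_signal equals the brute-force per-b mean", {
  spec <- one_disk_spec(noise = "rician", seed = 3L)
  ph <- make_pellet_phantom(spec)
  mask <- ph$truth$label == 1
  dec <- roi_mean_signal(ph$series, mask)
  for (k in seq_along(dec$bvalues)) {
    plane <- ph$series$data[, , k]
    expect_equal(dec$signal[k], sum(plane[mask]) / sum(mask))
  }
  # uniform image: decay is flat at the uniform value
  u <- diffusion_series(array(10, c(8, 8, 3)), c(1, 2, 3))
  expect_equal(roi_mean_signal(u, matrix(TRUE, 8, 8))$signal, rep(10, 3))
  # single-voxel mask returns that voxel's values
  m1 <- matrix(FALSE, 64, 64); m1[30, 31] <- TRUE
  expect_equal(roi_mean_signal(ph$series, m1)$signal,
               ph$series$data[30, 31, ])
  expect_error(roi_mean_signal(ph$series, matrix(FALSE, 64, 64)), "empty")
  expect_error(roi_mean_signal(ph$series, matrix(TRUE, 3, 3)), "shape")
})

test_that("fit_adc recovers noiseless exponentials to machine precision", {
  for (D in c(0.3, 0.8, 1.2, 2.6)) {
    for (bset in list(c(1, 3), c(1, 1.67, 2.33, 3), c(1.2, 1.9, 2.8))) {
      est <- fit_adc(list(bvalues = bset, signal = 1000 * exp(-bset * D)))
      expect_lt(abs(est$D - D) / D, 1e-10)
      expect_equal(est$r_squared, 1, tolerance = 1e-12)
      expect_equal(est$log_intercept, log(1000), tolerance = 1e-9)
    }
  }
  # constant signal -> D = 0
  expect_equal(fit_adc(list(bvalues = c(1, 2, 3), signal = rep(5, 3)))$D, 0)
})

test_that("fit_adc errors name the offending b-value", {
  expect_error(fit_adc(list(bvalues = c(1, 2, 3), signal = c(10, 0, 5))),
               "b = 2")
  expect_error(fit_adc(list(bvalues = 1, signal = 10)), "at least two")
})

test_that("ols and nls modes agree on clean data", {
  b <- c(1.0, 1.67, 2.33, 3.0)
  dec <- list(bvalues = b, signal = 800 * exp(-b * 1.4))
  expect_equal(fit_adc(dec, "nls")$D, fit_adc(dec, "ols")$D,
               tolerance = 1e-8)
})

test_that("rician ROI fit recovers D within 5% under study noise", {
  spec <- one_disk_spec(D = 1.2, noise = "rician", snr = 50, averages = 5L,
                        seed = 21L)
  ph <- make_pellet_phantom(spec)
  sigma <- estimate_noise_sigma(ph$series, ph$truth$label == 0)
  expect_lt(abs(sigma - ph$truth$sigma) / ph$truth$sigma, 0.1)
  dec <- roi_mean_signal(ph$series, ph$truth$label == 1)
  est <- fit_adc(dec, method = "rician", sigma = sigma)
  expect_lt(abs(est$D - 1.2) / 1.2, 0.05)
})

test_that("estimated D is increasing in true D (noiseless)", {
  Ds <- c(0.5, 1.0, 1.5, 2.0, 2.5)
  est <- vapply(Ds, function(D) {
    b <- c(1.0, 1.67, 2.33, 3.0)
    fit_adc(list(bvalues = b, signal = 1000 * exp(-b * D)))$D
  }, numeric(1))
  expect_true(all(diff(est) > 0))
})

test_that("fit_adc_map equals fit_adc applied voxel by voxel", {
  spec <- one_disk_spec(noise = "rician", seed = 5L)
  ph <- make_pellet_phantom(spec)
  mask <- ph$truth$label == 1
  map <- fit_adc_map(ph$series, mask)
  idx <- which(mask & map$valid, arr.ind = TRUE)
  for (r in sample(nrow(idx), 10)) {
    vox <- idx[r, ]
    dec <- list(bvalues = ph$series$bvalues,
                signal = ph$series$data[vox[1], vox[2], ])
    expect_equal(map$D[vox[1], vox[2]], fit_adc(dec)$D, tolerance = 1e-12)
  }
})

test_that("noiseless two-compartment map is exactly piecewise constant", {
  spec <- two_disk_spec(D0 = 1.0, D1 = 2.0, noise = "none")
  ph <- make_pellet_phantom(spec)
  mask <- ph$truth$label > 0
  map <- fit_adc_map(ph$series, mask)
  expect_true(all(map$valid[mask]))
  expect_equal(map$D[ph$truth$label == 1],
               rep(1.0, sum(ph$truth$label == 1)), tolerance = 1e-10)
  expect_equal(map$D[ph$truth$label == 2],
               rep(2.0, sum(ph$truth$label == 2)), tolerance = 1e-10)
})

test_that("a zero intensity invalidates only the affected voxel", {
  spec <- one_disk_spec(noise = "none")
  ph <- make_pellet_phantom(spec)
  ph$series$data[32, 32, 2] <- 0
  mask <- ph$truth$label == 1
  map <- fit_adc_map(ph$series, mask)
  expect_false(map$valid[32, 32])
  expect_true(is.na(map$D[32, 32]))
  others <- mask & !(row(mask) == 32 & col(mask) == 32)
  expect_true(all(map$valid[others]))
})

test_that("rendering clamps to [0, 255] and maps limits to the endpoints", {
  D <- matrix(1.0, 10, 10)
  mk <- function(val) {
    structure(list(D = matrix(val, 10, 10),
                   valid = matrix(TRUE, 10, 10),
                   bvalues = c(1, 2), voxel_mm = c(0.4, 0.4)),
              class = "diffusion_map")
  }
  expect_true(all(render_diffusion_map(mk(0.2), 0.2, 2.5)$pixels == 0L))
  expect_true(all(render_diffusion_map(mk(2.5), 0.2, 2.5)$pixels == 255L))
  expect_true(all(render_diffusion_map(mk(99), 0.2, 2.5)$pixels == 255L))
  expect_error(render_diffusion_map(mk(1), 2.5, 0.2), "lower")
  expect_error(render_diffusion_map(mk(1), 0.2, 2.5, kernel = 4), "odd")
})

test_that("rendering is invariant to joint affine rescaling", {
  set.seed(1)
  D <- matrix(runif(100, 0.5, 2), 10, 10)
  mk <- function(D) structure(list(D = D, valid = matrix(TRUE, 10, 10),
                                   bvalues = c(1, 2), voxel_mm = c(0.4, 0.4)),
                              class = "diffusion_map")
  r1 <- render_diffusion_map(mk(D), 0.2, 2.5, kernel = 1)
  r2 <- render_diffusion_map(mk(3 * D + 1), 3 * 0.2 + 1, 3 * 2.5 + 1,
                             kernel = 1)
  expect_identical(r1$pixels, r2$pixels)
})

test_that("kernel 1 is a pure rescale and kernel 3 removes a lone outlier", {
  D <- matrix(1.0, 9, 9)
  D[5, 5] <- 10
  map <- structure(list(D = D, valid = matrix(TRUE, 9, 9),
                        bvalues = c(1, 2), voxel_mm = c(0.4, 0.4)),
                   class = "diffusion_map")
  r1 <- render_diffusion_map(map, 0, 10, kernel = 1)
  expect_equal(r1$pixels[5, 5], 255L)
  r3 <- render_diffusion_map(map, 0, 10, kernel = 3)
  # brute-force median over the 3x3 window centred on the outlier
  expect_equal(r3$pixels[5, 5],
               as.integer(round(255 * median(D[4:6, 4:6]) / 10)))
  # median filter excludes invalid voxels from neighborhoods
  map$D[4, 4] <- NA; map$valid[4, 4] <- FALSE
  r3b <- render_diffusion_map(map, 0, 10, kernel = 3)
  win <- D[4:6, 4:6]; win[1, 1] <- NA
  expect_equal(r3b$pixels[5, 5],
               as.integer(round(255 * median(win, na.rm = TRUE) / 10)))
})

test_that("percent diffusivity increase matches the worked examples", {
  expect_equal(percent_delta_diffusivity(1.794, 1.0), 79.4, tolerance = 1e-12)
  expect_equal(percent_delta_diffusivity(2.625, 1.0), 162.5, tolerance = 1e-12)
  expect_equal(percent_delta_diffusivity(1.3, 1.3), 0)
  expect_error(percent_delta_diffusivity(1, 0), "positive")
})

test_that("replicate aggregation uses sample-sd s.e.m.", {
  D <- c(1.8, 1.75, 1.9, 1.82); D0 <- c(1.0, 0.98, 1.05, 1.01)
  s <- delta_diffusivity_summary(D, D0)
  pct <- 100 * (D - D0) / D0
  expect_equal(s$mean_pct, mean(pct))
  expect_equal(s$sem_pct, sd(pct) / sqrt(4))
  expect_equal(s$n, 4L)
})
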