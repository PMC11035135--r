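# tomogram generation, segmentation, OPL projection, dry mass, morphometry

test_that("tomogram truth: analytic sphere mass example", {
  # sphere r = 5 um, contrast 0.03, alpha 0.18: m = 0.03 * (4/3) pi 125 / 0.18
  sp <- tomogram_scene_spec(
    grid = c(60L, 60L, 60L), voxel_um = c(0.25, 0.25, 0.25),
    cells = list(list(center = c(7.5, 7.5, 7.5), semiaxes = c(5, 5, 5),
                      n_cell = 1.367)),
    n_surr = 1.337)
  tt <- make_tomogram(sp)
  expect_equal(tt$truth$mass_pg, 0.03 * 4 / 3 * pi * 125 / 0.18,
               tolerance = 1e-10)
  expect_equal(tt$truth$volume_um3, 4 / 3 * pi * 125, tolerance = 1e-12)
  # Thomsen formula reduces to 4 pi r^2 for a sphere
  expect_equal(tt$truth$surface_um2, 4 * pi * 25, tolerance = 1e-12)
})

test_that("zero index contrast is rejected", {
  expect_error(tomogram_scene_spec(
    cells = list(list(center = c(5, 5, 5), semiaxes = c(2, 2, 2),
                      n_cell = 1.337)), n_surr = 1.337), "contrast")
})

test_that("overlapping cells are rejected at generation", {
  sp <- tomogram_scene_spec(
    grid = c(60L, 60L, 40L), voxel_um = c(0.25, 0.25, 0.25),
    cells = list(
      list(center = c(6, 6, 5), semiaxes = c(3, 3, 3), n_cell = 1.37),
      list(center = c(8, 6, 5), semiaxes = c(3, 3, 3), n_cell = 1.37)))
  expect_error(make_tomogram(sp), "overlap")
})

test_that("digitized sphere voxel-count volume is within 1% of analytic", {
  sp <- single_sphere_scene(r_um = 4, grid = c(64L, 64L, 40L))
  tt <- make_tomogram(sp)
  vol <- sum(tt$labels == 1) * prod(sp$voxel_um)
  expect_lt(abs(vol - tt$truth$volume_um3) / tt$truth$volume_um3, 0.01)
})

test_that("segmentation labels equal brute-force component structure", {
  sp <- tomogram_scene_spec(
    grid = c(50L, 50L, 30L), voxel_um = c(0.25, 0.25, 0.25),
    cells = list(
      list(center = c(4, 4, 3.75), semiaxes = c(2, 2, 2), n_cell = 1.37),
      list(center = c(9, 8, 3.75), semiaxes = c(2, 2, 2), n_cell = 1.37)))
  tt <- make_tomogram(sp)
  mask <- segment_cells(tt$tomogram, threshold = 0.0165)
  expect_equal(length(mask$excluded), 2L)
  expect_false(any(mask$excluded))
  # labels partition exactly the thresholded voxel set
  expect_identical(mask$labels > 0, (tt$tomogram$n - 1.337) >= 0.0165)
  # same-label voxels belong to the same planted cell
  for (l in 1:2) {
    tl <- tt$labels[mask$labels == l]
    expect_equal(length(unique(tl)), 1L)
  }
})

test_that("cells touching the lateral boundary are flagged excluded", {
  sp <- tomogram_scene_spec(
    grid = c(40L, 40L, 30L), voxel_um = c(0.25, 0.25, 0.25),
    cells = list(list(center = c(0.5, 5, 3.75), semiaxes = c(2, 2, 2),
                      n_cell = 1.37)))
  tt <- make_tomogram(sp)
  mask <- segment_cells(tt$tomogram, threshold = 0.0165)
  expect_true(mask$excluded[1])
  expect_error(morphometrics(mask, 1), "excluded")
  expect_s3_class(morphometrics(mask, 1, allow_excluded = TRUE), "data.frame")
})

test_that("empty segmentation warns and returns zero labels", {
  sp <- single_sphere_scene()
  tt <- make_tomogram(sp)
  expect_warning(m <- segment_cells(tt$tomogram, threshold = 0.5), "empty")
  expect_equal(max(m$labels), 0L)
})

test_that("OPL projection matches the analytic slab and brute-force sums", {
  # uniform slab: contrast 0.03 over 5 um thickness -> OPL 0.15 um
  n <- array(1.337, c(10, 10, 20))
  n[3:8, 3:8, 6:15] <- 1.367   # 10 slices x 0.5 um = 5 um thick
  tom <- tomogram(n, voxel_um = c(1, 1, 0.5), n_surr = 1.337)
  labs <- array(0L, dim(n)); labs[3:8, 3:8, 6:15] <- 1L
  mask <- cell_mask(labs, tom$voxel_um)
  opl <- project_opl(tom, mask, 1)
  expect_equal(opl$opl[5, 5], 0.03 * 5, tolerance = 1e-12)
  expect_equal(opl$opl[1, 1], 0)  # empty column
  # brute force on a random sparse voxel set
  set.seed(42)
  n2 <- array(1.337, c(8, 8, 8))
  pick <- sample(length(n2), 40)
  n2[pick] <- 1.337 + runif(40, 0.01, 0.05)
  labs2 <- array(0L, dim(n2)); labs2[pick] <- 1L
  tom2 <- tomogram(n2, voxel_um = c(0.3, 0.3, 0.4), n_surr = 1.337)
  opl2 <- project_opl(tom2, cell_mask(labs2, tom2$voxel_um), 1)
  brute <- apply((n2 - 1.337) * (labs2 == 1L), c(1, 2), sum) * 0.4
  expect_equal(opl2$opl, brute, tolerance = 1e-12)
  expect_error(project_opl(tom2, cell_mask(labs2, tom2$voxel_um), 9),
               "not present")
})

test_that("dry mass is linear in contrast and thickness", {
  mk <- function(contrast, nz) {
    n <- array(1.337, c(6, 6, nz + 2))
    n[2:5, 2:5, 2:(nz + 1)] <- 1.337 + contrast
    labs <- array(0L, dim(n)); labs[2:5, 2:5, 2:(nz + 1)] <- 1L
    tom <- tomogram(n, voxel_um = c(1, 1, 1), n_surr = 1.337)
    dry_mass(project_opl(tom, cell_mask(labs, tom$voxel_um), 1))
  }
  m0 <- mk(0.01, 4)
  expect_equal(mk(0.03, 4), 3 * m0, tolerance = 1e-10)
  expect_equal(mk(0.01, 8), 2 * m0, tolerance = 1e-10)
  # slab example: contrast 0.03, 5 um thick, 100 um^2 footprint
  n <- array(1.337, c(12, 12, 7))
  n[2:11, 2:11, 2:6] <- 1.367
  labs <- array(0L, dim(n)); labs[2:11, 2:11, 2:6] <- 1L
  tom <- tomogram(n, voxel_um = c(1, 1, 1), n_surr = 1.337)
  expect_equal(dry_mass(project_opl(tom, cell_mask(labs, tom$voxel_um), 1)),
               0.03 * 5 * 100 / 0.18, tolerance = 1e-10)
  expect_error(dry_mass(project_opl(tom, cell_mask(labs, tom$voxel_um), 1),
                        alpha = 0), "positive")
})

test_that("sphericity formula: sphere gives 1, cube gives 0.806", {
  expect_equal(sphericity(4 * pi / 3, 4 * pi), 1, tolerance = 1e-12)
  expect_equal(sphericity(1, 6), pi^(1 / 3) * 6^(2 / 3) / 6,
               tolerance = 1e-12)
  expect_equal(sphericity(8, 24), pi^(1 / 3) * 6^(2 / 3) / 6,
               tolerance = 1e-12)  # scale invariance of the cube value
})

test_that("digitized ball sphericity is within 3% of 1", {
  arr <- ball_array(51, 20)
  labs <- array(as.integer(arr), dim(arr))
  mask <- cell_mask(labs, c(1, 1, 1))
  rec <- morphometrics(mask, 1)
  expect_lt(abs(rec$sphericity - 1), 0.03)
  expect_lt(abs(rec$volume_um3 - 4 / 3 * pi * 20^3) / (4 / 3 * pi * 20^3),
            0.01)
})

test_that("mesh surface area converges to the analytic sphere", {
  err <- vapply(c(10, 20), function(r) {
    arr <- ball_array(2 * r + 11, r)
    a <- aqpquant:::label_surface_area(array(as.integer(arr), dim(arr)), 1L,
                                       c(1, 1, 1))
    abs(a - 4 * pi * r^2) / (4 * pi * r^2)
  }, numeric(1))
  expect_lt(err[2], 0.01)
  expect_lt(err[2], err[1] / 1.5)  # error shrinks as resolution doubles
})

test_that("sphere maximizes sphericity among ellipsoids of equal volume", {
  # fixed volume, growing aspect ratio -> strictly decreasing sphericity
  psis <- vapply(c(1, 1.5, 2.5, 4), function(ar) {
    a <- 15 * ar^(2 / 3); b <- 15 / ar^(1 / 3)  # abc = 15^3
    sphericity(ellipsoid_volume(c(a, b, b)),
               ellipsoid_area_thomsen(c(a, b, b)))
  }, numeric(1))
  expect_true(all(diff(psis) < 0))
  expect_equal(psis[1], 1, tolerance = 1e-3)  # Thomsen exact for a sphere
})

test_that("digitized ellipsoid dry mass is within 2% of analytic truth", {
  sp <- tomogram_scene_spec(
    grid = c(80L, 80L, 44L), voxel_um = c(0.202, 0.202, 0.363),
    cells = list(list(center = c(8.08, 8.08, 7.99),
                      semiaxes = c(5, 4, 3.5), n_cell = 1.37)),
    n_surr = 1.337)
  tt <- make_tomogram(sp)
  mask <- segment_cells(tt$tomogram, threshold = 0.0165)
  m <- dry_mass(project_opl(tt$tomogram, mask, 1))
  expect_lt(abs(m - tt$truth$mass_pg) / tt$truth$mass_pg, 0.02)
})

test_that("mass is conserved under translation of the cell (<= 2%)", {
  masses <- vapply(list(c(7.9, 8.1, 7.3), c(8.03, 7.95, 7.12),
                        c(8.17, 8.02, 7.45)), function(ctr) {
    sp <- tomogram_scene_spec(
      grid = c(80L, 80L, 40L), voxel_um = c(0.202, 0.202, 0.363),
      cells = list(list(center = ctr, semiaxes = c(4, 3.5, 3),
                        n_cell = 1.37)), n_surr = 1.337)
    tt <- make_tomogram(sp)
    mask <- segment_cells(tt$tomogram, threshold = 0.0165)
    dry_mass(project_opl(tt$tomogram, mask, 1))
  }, numeric(1))
  expect_lt(diff(range(masses)) / mean(masses), 0.02)
})

test_that("morphometry fold change propagates group s.e.m.s", {
  a <- c(100, 105, 98); b <- c(50, 52, 49)
  f <- morphometry_fold(a, b)
  expect_equal(f$fold, mean(a) / mean(b))
  sem <- function(x) sd(x) / sqrt(length(x))
  expect_equal(f$se, f$fold * sqrt((sem(a) / mean(a))^2 +
                                     (sem(b) / mean(b))^2))
})
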