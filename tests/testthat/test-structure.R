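test_that("structure_function validates its invariants", {
  expect_error(structure_function(matrix(0, 4, 4), 1), "3D")
  expect_error(structure_function(array(0, c(1, 4, 4)), 1), ">= 2")
  expect_error(structure_function(array(2, c(4, 4, 4)), 1), "\\[0, 1\\]")
  expect_error(structure_function(array(0, c(4, 4, 4)), -1), "positive")
  sf <- structure_function(array(0.5, c(4, 5, 6)), 2, origin = c(1, 2, 3))
  expect_equal(dim(sf), c(4L, 5L, 6L))
  bb <- bounding_box(sf)
  expect_equal(bb$lo, c(0, 1, 2))
  expect_equal(bb$hi, c(1, 2, 3) + c(3.5, 4.5, 5.5) * 2)
})

test_that("sample_field reproduces stored values at voxel centers and linear
          midpoints", {
  set.seed(11)
  v <- array(runif(6 * 6 * 6), c(6, 6, 6))
  sf <- structure_function(v, 10)
  idx <- rbind(c(1, 1, 1), c(3, 4, 2), c(6, 6, 6))
  pts <- (idx - 1) * 10
  expect_equal(sample_field(sf, pts), v[idx], tolerance = 1e-14)
  # midpoint between a 0-voxel and a 1-voxel along x
  v2 <- array(0, c(4, 4, 4)); v2[3, 2, 2] <- 1
  sf2 <- structure_function(v2, 5)
  expect_equal(sample_field(sf2, c(1.5 * 5, 5, 5)), 0.5)
})

test_that("sample_field agrees with an independent 8-corner oracle", {
  set.seed(42)
  v <- array(runif(8 * 7 * 6), c(8, 7, 6))
  sf <- structure_function(v, 3.7, origin = c(-5, 2, 0.5))
  bb <- bounding_box(sf)
  for (i in 1:50) {
    p <- runif(3, bb$lo, bb$hi)
    expect_equal(sample_field(sf, p), trilinear_oracle(sf, p),
                 tolerance = 1e-12)
  }
})

test_that("sampling outside the bounding box errors, clamping applies inside
          the half-voxel margin", {
  v <- array(0, c(4, 4, 4)); v[1, , ] <- 1
  sf <- structure_function(v, 10)
  expect_error(sample_field(sf, c(-6, 10, 10)), "outside")
  # within the margin, beyond voxel centers: clamps to edge value
  expect_equal(sample_field(sf, c(-4.9, 10, 10)), 1)
  expect_equal(sample_field(sf, c(34.9, 10, 10)), 0)
})

test_that("is_solid uses the s >= 0.5 convention including the boundary", {
  v <- array(0, c(4, 4, 4)); v[3:4, , ] <- 1
  sf <- structure_function(v, 1)
  expect_true(is_solid(sf, c(2, 1, 1)))     # solid voxel center
  expect_false(is_solid(sf, c(1, 1, 1)))    # pore voxel center
  expect_true(is_solid(sf, c(1.5, 1, 1)))   # interpolates to exactly 0.5
})

test_that("porosity covers whole volumes and sub-regions", {
  expect_equal(porosity(structure_function(array(0, c(3, 3, 3)), 1)), 1)
  expect_equal(porosity(structure_function(array(1, c(3, 3, 3)), 1)), 0)
  v <- array(0, c(4, 4, 4)); v[1:2, , ] <- 1
  sf <- structure_function(v, 1)
  expect_equal(porosity(sf), 0.5)
  expect_equal(porosity(sf, region = list(lo = c(3, 1, 1), hi = c(4, 4, 4))),
               1)
  expect_error(porosity(sf, region = list(lo = c(3, 1, 1), hi = c(2, 4, 4))),
               "sub-box")
})

test_that("binarize separates a bimodal volume and is idempotent on binary
          input", {
  v <- array(0.1, c(8, 8, 8)); v[3:6, 3:6, 3:6] <- 0.9
  sf <- structure_function(v, 1)
  b <- binarize(sf, pre_median_radius = 0, threshold_mode = "global_otsu")
  expect_setequal(unique(as.vector(b$values)), c(0, 1))
  expect_equal(b$values[4, 4, 4], 1)
  expect_equal(b$values[1, 1, 1], 0)
  # per-slice mode on the same volume
  b2 <- binarize(sf, pre_median_radius = 0,
                 threshold_mode = "per_slice_otsu")
  expect_equal(b2$values[4, 4, 4], 1)
  # idempotence with fixed threshold and no filtering
  again <- binarize(b, pre_median_radius = 0, post_median_radius = 0,
                    threshold_mode = "fixed")
  expect_identical(again$values, b$values)
  expect_error(binarize(structure_function(array(0.4, c(4, 4, 4)), 1),
                        pre_median_radius = 0,
                        threshold_mode = "global_otsu"), "Otsu")
})

test_that("median filtering removes salt-and-pepper noise from a binary
          phantom", {
  clean <- make_phantom(phantom_sphere(radius = 48, grid_dim = 128,
                                       voxel_size = 10))
  set.seed(99)
  noisy <- clean$values
  flip <- sample(length(noisy), round(0.01 * length(noisy)))
  noisy[flip] <- 1 - noisy[flip]
  nf <- structure_function(noisy, 10)
  restored <- binarize(nf, pre_median_radius = 2, threshold_mode = "fixed")
  frac_wrong <- mean(restored$values != clean$values)
  expect_lt(frac_wrong, 0.001)
})

test_that("downscale_half averages 2x2x2 blocks exactly and doubles the
          voxel", {
  v <- array(0, c(4, 4, 4))
  v[1:2, 1:2, 1] <- 1                  # block with four 1s, four 0s -> 0.5
  v[3:4, 3:4, 3:4] <- 1                # all-ones block -> 1
  sf <- structure_function(v, 3.05)
  out <- downscale_half(sf)
  expect_equal(dim(out$values), c(2L, 2L, 2L))
  expect_equal(out$values[1, 1, 1], 0.5)
  expect_equal(out$values[2, 2, 2], 1)
  expect_equal(out$values[2, 1, 1], 0)
  expect_equal(out$voxel_size, 6.1)
  # mean conservation on a random even-sized volume
  set.seed(3)
  v2 <- array(runif(8^3), c(8, 8, 8))
  sf2 <- structure_function(v2, 2)
  expect_equal(mean(downscale_half(sf2)$values), mean(v2), tolerance = 1e-14)
  # odd dimension triggers edge-replication padding
  v3 <- array(0.3, c(3, 4, 4))
  expect_message(out3 <- downscale_half(structure_function(v3, 1)),
                 "padding")
  expect_equal(dim(out3$values), c(2L, 2L, 2L))
  expect_equal(as.vector(out3$values), rep(0.3, 8), tolerance = 1e-14)
})

test_that("volumes round-trip through TIFF stacks and raw + sidecar", {
  sf <- make_phantom(phantom_bead_packing(
    diameter_range = c(80, 120), target_solid_fraction = 0.2,
    grid_dim = 16, voxel_size = 10, seed = 5))
  tif <- withr::local_tempfile(fileext = ".tif")
  write_volume(sf, tif)
  back <- load_volume(tif, voxel_size = 10)
  expect_identical(back$values, sf$values)
  raw <- withr::local_tempfile(fileext = ".vol")
  write_volume(sf, raw)
  back2 <- load_volume(raw)
  expect_identical(back2$values, sf$values)
  expect_equal(back2$voxel_size, 10)
  # all-pore stack reads as porosity-1 volume
  zeros <- withr::local_tempfile(fileext = ".tif")
  write_volume(structure_function(array(0, c(4, 4, 4)), 1), zeros)
  expect_equal(porosity(load_volume(zeros, voxel_size = 1)), 1)
  expect_error(load_volume("no/such/file.tif", 1), "not found")
})

test_that("anisotropic sidecar metadata requires an explicit override", {
  sf <- structure_function(array(0.25, c(4, 4, 4)), 5)
  raw <- withr::local_tempfile(fileext = ".vol")
  write_volume(sf, raw)
  meta <- jsonlite::read_json(paste0(raw, ".json"), simplifyVector = TRUE)
  meta$voxel_size_um <- c(5, 5, 8)
  jsonlite::write_json(meta, paste0(raw, ".json"), auto_unbox = TRUE)
  expect_error(load_volume(raw), "anisotropic")
  expect_equal(load_volume(raw, voxel_size = 5)$voxel_size, 5)
})

test_that("sphere phantom porosity matches the analytic volume ratio", {
  r <- 20; n <- 64
  sf <- make_phantom(phantom_sphere(radius = r, grid_dim = n,
                                    voxel_size = 10))
  analytic <- 4 / 3 * pi * r^3 / n^3
  # tolerance: one voxel-surface shell
  shell <- 4 * pi * r^2 / n^3
  expect_lt(abs(porosity(sf) - analytic), shell)
})

test_that("cylinder phantom solid/pore classification matches point-line
          distance", {
  spec <- phantom_cylinder(radius = 6, length = 40, tilt_deg = 30,
                           grid_dim = 48, voxel_size = 10)
  sf <- make_phantom(spec)
  ctr <- (48 - 1) / 2
  axis <- c(0, sin(pi / 6), cos(pi / 6))
  set.seed(7)
  for (i in 1:200) {
    idx <- sample(2:47, 3, replace = TRUE)       # voxel index, 1-based
    p <- idx - 1 - ctr                           # voxel units about center
    axial <- sum(p * axis)
    rad <- sqrt(sum(p^2) - axial^2)
    expected_solid <- rad > 6 || abs(axial) > 20
    expect_equal(sf$values[idx[1], idx[2], idx[3]],
                 as.double(expected_solid))
  }
})

test_that("bead packings are reproducible, non-overlapping and reach their
          target", {
  spec <- phantom_bead_packing(diameter_range = c(100, 140),
                               target_solid_fraction = 0.25,
                               grid_dim = 32, voxel_size = 10, seed = 21)
  a <- make_phantom(spec)
  b <- make_phantom(spec)
  expect_identical(a$values, b$values)
  beads <- attr(a, "beads")
  n <- nrow(beads$centers)
  expect_gt(n, 1)
  for (i in seq_len(n - 1)) for (j in seq.int(i + 1, n)) {
    d <- sqrt(sum((beads$centers[i, ] - beads$centers[j, ])^2))
    expect_gte(d, beads$radii[i] + beads$radii[j] - 1e-9)
  }
  expect_gte(1 - porosity(a), 0.25 * 0.95)  # voxelization within 5 percent
  expect_error(make_phantom(phantom_bead_packing(
    diameter_range = c(100, 140), target_solid_fraction = 0.6,
    grid_dim = 24, voxel_size = 10, seed = 1, max_failures = 200)),
    "saturated")
})

test_that("crosshatch scaffolds lose porosity monotonically with infill", {
  por <- vapply(c(0, 0.25, 0.5), function(f) {
    porosity(make_phantom(phantom_crosshatch(
      infill_fraction = f, lateral_dim = 48, voxel_size = 25, seed = 9)))
  }, numeric(1))
  expect_true(all(diff(por) < 0))
  # infill converts the requested fraction of the initial pore volume
  expect_equal(por[2] / por[1], 0.75, tolerance = 0.01)
  # offset and aligned arrangements have (near) identical solid volume
  po <- porosity(make_phantom(phantom_crosshatch(
    arrangement = "offset", lateral_dim = 48, voxel_size = 25)))
  pa <- porosity(make_phantom(phantom_crosshatch(
    arrangement = "aligned", lateral_dim = 48, voxel_size = 25)))
  expect_equal(po, pa, tolerance = 0.02)
})
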