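test_that("zero activity produces an all-zero stack", {
  sm <- tiny_matrix()
  src <- tibble::tibble(x_mm = 0, y_mm = 0, z_mm = 80, activity_mbq = 0)
  stack <- simulate_acquisition(src, sm, acquisition_config(
    n_repeats = 2, penetration_fraction = 0, seed = 1))
  expect_true(all(vapply(stack$images, sum, numeric(1)) == 0))
})

test_that("per-pixel sample means match the Poisson rate", {
  sm <- tiny_matrix()
  src <- fixture_phantom("tiny")[5, ]
  cfg <- acquisition_config(n_repeats = 1000, penetration_fraction = 0,
                            counts_per_mbq_s = 1, seed = 99)
  stack <- simulate_acquisition(src, sm, cfg)
  lam <- image_to_vector(stack$lambda)
  fp <- which(lam > 0)
  means <- rowMeans(vapply(stack$images,
                           function(im) image_to_vector(im)[fp],
                           numeric(length(fp))))
  # sample mean within 5 sd/sqrt(n) of the rate, per footprint pixel
  expect_true(all(abs(means - lam[fp]) <= 5 * sqrt(lam[fp] / 1000)))
  # pixels with zero rate stay zero
  off <- image_to_vector(stack$images[[1]])[lam == 0]
  expect_true(all(off == 0))
})

test_that("the default protocol is 10 repeats of 8 s and is seed-reproducible", {
  cfg <- acquisition_config()
  expect_equal(cfg$exposure, 8)
  expect_equal(cfg$n_repeats, 10L)

  sm <- tiny_matrix()
  src <- fixture_phantom("tiny")[2, ]
  s1 <- simulate_acquisition(src, sm, acquisition_config(seed = 31))
  s2 <- simulate_acquisition(src, sm, acquisition_config(seed = 31))
  expect_identical(s1$images, s2$images)
  s3 <- simulate_acquisition(src, sm, acquisition_config(seed = 32))
  expect_false(identical(s1$images, s3$images))
})

test_that("expected counts scale with exposure and penetration mass is conserved", {
  sm <- tiny_matrix()
  src <- fixture_phantom("tiny")[5, ]
  lam1 <- simulate_acquisition(src, sm, acquisition_config(
    exposure = 8, penetration_fraction = 0, n_repeats = 1))$lambda
  lam2 <- simulate_acquisition(src, sm, acquisition_config(
    exposure = 16, penetration_fraction = 0, n_repeats = 1))$lambda
  expect_equal(lam2, 2 * lam1)

  lam_pen <- simulate_acquisition(src, sm, acquisition_config(
    exposure = 8, penetration_fraction = 0.075, n_repeats = 1))$lambda
  expect_equal(sum(lam_pen), (1 + 0.075) * sum(lam1))
  # the smear is uniform over every pixel, footprint included
  off <- lam_pen[lam1 == 0]
  expect_equal(max(off), min(off))
  expect_equal(max(off), 0.075 * sum(lam1) / sm$n_pixels)
})

test_that("a hot background volume adds its forward-projected rate", {
  sm <- tiny_matrix()
  src <- fixture_phantom("tiny")[5, ]
  hb <- list(activity_mbq = 120,
             extent = list(x = c(-10, 10), y = c(-20, 20), z = c(50, 110)))
  lam0 <- simulate_acquisition(src, sm, acquisition_config(
    penetration_fraction = 0, n_repeats = 1))$lambda
  lam <- simulate_acquisition(src, sm, acquisition_config(
    penetration_fraction = 0, hot_background = hb, n_repeats = 1))$lambda
  expect_true(sum(lam) > sum(lam0))
  vb <- slnf:::voxels_in_box(sm$geometry$grid, hb$extent)
  u_bg <- replace(numeric(sm$n_voxels), vb, 120 / length(vb) * 8 * 10)
  expect_equal(image_to_vector(lam - lam0), forward_project(sm, u_bg))
})

test_that("the phantom grid reproduces the stated pair distances", {
  ph <- generate_grid_phantom(spacing = 20)
  xyz <- as.matrix(ph[, c("x_mm", "y_mm", "z_mm")])
  expect_equal(unname(l2_error(xyz[1, ], xyz[2, ])), 20)     # adjacent
  expect_equal(unname(l2_error(xyz[1, ], xyz[3, ])), 40)     # row ends
  expect_equal(unname(l2_error(xyz[1, ], xyz[5, ])), 28.28,  # diagonal
               tolerance = 2e-4)
  expect_equal(unname(l2_error(xyz[5, ], xyz[9, ])), 28.28, tolerance = 2e-4)

  # all nine positions fall inside the reduced and full-scale grids
  for (prof in c("tiny", "default", "full_scale")) {
    g <- fixture_geometry(prof)$grid
    ext <- slnf:::grid_extent(g)
    p <- fixture_phantom(prof)
    expect_true(all(p$x_mm >= ext$x[1] & p$x_mm <= ext$x[2]))
    expect_true(all(p$y_mm >= ext$y[1] & p$y_mm <= ext$y[2]))
    expect_true(all(p$z_mm >= ext$z[1] & p$z_mm <= ext$z[2]))
  }
})

test_that("sources outside the grid or with negative activity are rejected", {
  sm <- tiny_matrix()
  out <- tibble::tibble(x_mm = 500, y_mm = 0, z_mm = 60, activity_mbq = 1)
  expect_error(simulate_acquisition(out, sm), "outside")
  neg <- tibble::tibble(x_mm = 0, y_mm = 0, z_mm = 60, activity_mbq = -1)
  expect_error(simulate_acquisition(neg, sm), "activity")
})

test_that("binning sums neighborhoods and conserves counts", {
  expect_equal(bin_image(matrix(1, 4, 6)), matrix(4, 2, 3))
  set.seed(8)
  raw <- matrix(stats::rpois(514 * 1030, 3), 514, 1030)
  b <- bin_image(raw)
  expect_equal(dim(b), c(257L, 515L))
  expect_equal(sum(b), sum(raw))
  # a specific block
  expect_equal(b[10, 20], sum(raw[19:20, 39:40]))
  expect_error(bin_image(matrix(0, 5, 6)), "divisible")
})

test_that("sensor-artifact and blur options act as documented", {
  sm <- tiny_matrix()
  src <- fixture_phantom("tiny")[5, ]
  st <- simulate_acquisition(src, sm, acquisition_config(
    n_repeats = 1, artifact_column = 7L, seed = 3))
  expect_true(all(st$images[[1]][, 7] == 65535))

  st_b <- simulate_acquisition(src, sm, acquisition_config(
    n_repeats = 1, aperture_blur_sigma = 1, penetration_fraction = 0, seed = 3))
  st_0 <- simulate_acquisition(src, sm, acquisition_config(
    n_repeats = 1, penetration_fraction = 0, seed = 3))
  expect_equal(sum(st_b$images[[1]]), sum(st_0$images[[1]]), tolerance = 0.05)
  expect_gt(max(st_0$images[[1]]), max(st_b$images[[1]]))  # blur spreads peaks
})

test_that("detector images round-trip through 16-bit TIFF", {
  set.seed(21)
  img <- matrix(stats::rpois(64 * 128, 40), 64, 128)
  path <- withr::local_tempfile(fileext = ".tif")
  write_detector_image(img, path)
  expect_equal(read_detector_image(path), img)
  expect_warning(write_detector_image(matrix(70000, 2, 2), path), "clipped")
  expect_equal(read_detector_image(path), matrix(65535, 2, 2))
})

test_that("off-grid sources snap to the nearest voxel with the distance recorded", {
  sm <- tiny_matrix()
  src <- tibble::tibble(x_mm = 1, y_mm = 0, z_mm = 80, activity_mbq = 15)
  st <- simulate_acquisition(src, sm, acquisition_config(n_repeats = 1))
  expect_equal(st$truth$snap_mm, 1)
  expect_equal(st$truth$x_snap, 0)
})
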