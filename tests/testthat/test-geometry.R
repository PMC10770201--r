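test_that("voxel_center places a single-voxel grid on the axis, one spacing deep", {
  g <- volume_grid(1, 1, 1, spacing = 2)
  expect_equal(voxel_center(g, 1), cbind(x = 0, y = 0, z = 2))
})

test_that("voxel_center agrees with nested-loop enumeration and round-trips", {
  g <- volume_grid(3, 3, 3, spacing = 2)
  enum <- oracle_enumerate_centers(g)
  got <- voxel_center(g, seq_len(27))
  expect_equal(unname(got), unname(enum))
  expect_identical(nearest_voxel(g, got), 1:27)

  # random grids, random probe points snap back to the enumerated nearest
  set.seed(42)
  for (rep in 1:10) {
    g <- volume_grid(sample(1:6, 1), sample(1:6, 1), sample(1:6, 1),
                     spacing = stats::runif(1, 0.5, 5))
    idx <- seq_len(g$n_voxels)
    expect_identical(nearest_voxel(g, voxel_center(g, idx)), as.integer(idx))
  }
})

test_that("the full-scale grid has 1.2 million voxels and the binned detector 132355 pixels", {
  g <- volume_grid()  # 60 x 100 x 200 @ 2 mm
  expect_equal(g$n_voxels, 1200000)
  d <- detector_spec()
  expect_equal(d$n_rows * d$n_cols, 515 * 257)
  expect_equal(c(d$n_rows, d$n_cols), c(257L, 515L))
  expect_equal(d$raw_shape, c(514L, 1030L))
})

test_that("voxel index bounds are enforced", {
  g <- volume_grid(2, 2, 2, spacing = 1)
  expect_error(voxel_center(g, 0), "out of range")
  expect_error(voxel_center(g, 9), "out of range")
})

test_that("an on-axis ray hits next to the detector center", {
  det <- detector_spec(64L, 64L, pixel_pitch = 1, raw_shape = c(128L, 128L))
  pin <- list(x_mm = 0, y_mm = 0, fov_half_angle_deg = 45)
  px <- trace_ray(c(0, 0, 100), pin, det)
  # the axis passes through the detector center, a pixel-boundary corner:
  # the containing pixel is the one just below-right of it
  expect_equal(px, (32L) * 64L + 33L)
  expect_equal(px, oracle_trace_ray(c(0, 0, 100), pin, det))
})

test_that("off-center pinholes follow the similar-triangles closed form", {
  # source (0,0,100), pinhole at x=10, detector 30 behind: hit at x = 13 mm
  det <- detector_spec(64L, 64L, pixel_pitch = 1, raw_shape = c(128L, 128L),
                       plane_offset = 30)
  pin <- list(x_mm = 10, y_mm = 0, fov_half_angle_deg = 45)
  px <- trace_ray(c(0, 0, 100), pin, det)
  col <- (px - 1L) %% 64L + 1L
  # x = 13 lies in the column covering [13, 14) mm
  expect_equal(col, floor(13 + 32) + 1)
  expect_equal(px, oracle_trace_ray(c(0, 0, 100), pin, det))
})

test_that("rays outside the field of view or plate plane are rejected", {
  det <- detector_spec(64L, 64L, pixel_pitch = 1, raw_shape = c(128L, 128L))
  pin <- list(x_mm = 0, y_mm = 0, fov_half_angle_deg = 45)
  expect_true(is.na(trace_ray(c(300, 0, 10), pin, det)))
  expect_error(trace_ray(c(0, 0, 0), pin, det), "degenerate")
  expect_error(trace_ray(c(0, 0, -5), pin, det), "z > 0")
})

test_that("trace_ray matches the scalar oracle on 1000 random configurations", {
  set.seed(7)
  det <- detector_spec(48L, 96L, pixel_pitch = 0.8, raw_shape = c(96L, 192L),
                       plane_offset = 25)
  for (i in 1:1000) {
    pin <- list(x_mm = stats::runif(1, -30, 30), y_mm = stats::runif(1, -15, 15),
                fov_half_angle_deg = stats::runif(1, 20, 60))
    s <- c(stats::runif(1, -60, 60), stats::runif(1, -40, 40),
           stats::runif(1, 5, 200))
    expect_identical(trace_ray(s, pin, det),
                     oracle_trace_ray(s, pin, det))
  }
})

test_that("the pinhole image is point-inverted and scales with lateral offset", {
  det <- detector_spec(200L, 200L, pixel_pitch = 0.1,
                       raw_shape = c(400L, 400L), plane_offset = 30)
  pin <- list(x_mm = 0, y_mm = 0, fov_half_angle_deg = 60)
  col_of <- function(px) (px - 1L) %% 200L + 1L
  p0 <- col_of(trace_ray(c(0, 0, 60), pin, det))
  p1 <- col_of(trace_ray(c(4, 0, 60), pin, det))
  p2 <- col_of(trace_ray(c(8, 0, 60), pin, det))
  expect_true(p1 < p0)                      # +x source moves hit -x
  expect_equal(p2 - p0, 2L * (p1 - p0))     # doubling offset doubles shift
})

test_that("geometry YAML round-trips with an identical content hash", {
  geom <- fixture_geometry("tiny")
  path <- withr::local_tempfile(fileext = ".yaml")
  write_geometry(geom, path)
  back <- read_geometry(path)
  expect_identical(geometry_hash(back), geometry_hash(geom))
})

test_that("spec invariants of the building blocks are enforced", {
  expect_error(detector_spec(10, 10, raw_shape = c(21, 20)), "exactly")
  expect_error(volume_grid(0, 1, 1), "n_x")
  expect_error(collimator_spec(tibble::tibble(x_mm = 100, y_mm = 0)),
               "plate_extent")
  expect_error(
    collimator_spec(tibble::tibble(x_mm = 0, y_mm = 0),
                    penetration_fraction = 1),
    "penetration")
})
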