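# system matrices are deterministic and moderately expensive; build each
# profile once per test run
.matrix_cache <- new.env(parent = emptyenv())

cached_matrix <- function(profile) {
  if (is.null(.matrix_cache[[profile]])) {
    .matrix_cache[[profile]] <- build_system_matrix(fixture_geometry(profile))
  }
  .matrix_cache[[profile]]
}

tiny_matrix <- function() cached_matrix("tiny")
default_matrix <- function() cached_matrix("default")

# voxels with non-empty footprints not contained in any other voxel's
# footprint: the set exactly identifiable from a noiseless fingerprint
unique_footprint_voxels <- function(sm) {
  setdiff(which(Matrix::colSums(sm$A) > 0), dominated_footprints(sm))
}

# a small random geometry for property tests
random_geometry <- function(n_pinholes = 4L, grid = volume_grid(5L, 5L, 5L, 4)) {
  pin <- tibble::tibble(
    x_mm = stats::runif(n_pinholes, -20, 20),
    y_mm = stats::runif(n_pinholes, -10, 10)
  )
  geometry_model(
    detector_spec(32L, 64L, pixel_pitch = 1.2, raw_shape = c(64L, 128L),
                  plane_offset = 25),
    collimator_spec(pin, plate_extent = c(50, 25)),
    grid
  )
}
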