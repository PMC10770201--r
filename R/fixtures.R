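#' Geometry and phantom presets for self-contained fixtures
#'
#' Three profiles sharing the plate-centered frame: `"tiny"` (64 x 128
#' detector, 9 pinholes, 9 x 17 x 28 grid at 4 mm — under 5,000 voxels so
#' exhaustive reference scans finish in well under a second), `"default"`
#' (same detector and collimator, 15 x 31 x 56 grid at 2 mm — the reduced
#' geometry used for the noisy localization studies) and `"full_scale"`
#' (the physical dimensions: 257 x 515 binned detector and 60 x 100 x 200
#' grid at 2 mm, M = 1,200,000; for performance checks only).
#'
#' `fixture_phantom()` returns the matching 3 x 3, 20 mm-spacing phantom.
#' Its standoff (60 mm for the reduced profiles, 100 mm at full scale) keeps
#' all nine positions inside every pinhole's field of view, so each carries
#' a multi-pixel fingerprint, as in the bench setup where the phantom sits
#' well in front of the plate.
#'
#' @param profile One of `"tiny"`, `"default"`, `"full_scale"`.
#' @return `fixture_geometry()`: an `slnf_geometry`; `fixture_phantom()`: a
#'   source tibble.
#' @export
fixture_geometry <- function(profile = c("tiny", "default", "full_scale")) {
  profile <- match.arg(profile)
  reduced_detector <- detector_spec(64L, 128L, pixel_pitch = 0.6,
                                    raw_shape = c(128L, 256L), bin_factor = 2L,
                                    plane_offset = 30)
  reduced_collimator <- collimator_spec(default_pinhole_pattern(),
                                        plate_extent = c(60, 30))
  switch(profile,
    tiny = geometry_model(reduced_detector, reduced_collimator,
                          volume_grid(9L, 17L, 28L, spacing = 4)),
    default = geometry_model(reduced_detector, reduced_collimator,
                             volume_grid(15L, 31L, 56L, spacing = 2)),
    full_scale = geometry_model(detector_spec(), collimator_spec(),
                                volume_grid(60L, 100L, 200L, spacing = 2))
  )
}

#' @rdname fixture_geometry
#' @param activity_mbq Activity per phantom position in MBq.
#' @export
fixture_phantom <- function(profile = c("tiny", "default", "full_scale"),
                            activity_mbq = 15) {
  profile <- match.arg(profile)
  standoff <- if (profile == "full_scale") 100 else 60
  generate_grid_phantom(spacing = 20, origin_offset = c(0, 0, standoff),
                        activity_mbq = activity_mbq)
}

#' Write a self-contained fixture bundle
#'
#' One command producing everything a downstream test or demo needs, with no
#' external data: the geometry config (YAML), the system-matrix cache
#' (MatrixMarket + JSON sidecar), the phantom source list (CSV), a seeded
#' simulated image stack for the central phantom position (16-bit TIFFs plus
#' a JSON ground-truth sidecar), and expected outputs computed by the
#' independent reference implementations in `oracle_*()` — never by the main
#' code paths. Bundles are bit-identical for a fixed (profile, seed).
#'
#' For the `"full_scale"` profile only the geometry config and phantom CSV
#' are written (the profile exists to exercise the physical problem size,
#' not to ship large fixtures).
#'
#' @param profile One of `"tiny"`, `"default"`, `"full_scale"`.
#' @param seed Integer seed for the simulated stack.
#' @param out_dir Output directory (created if missing).
#' @param n_repeats Repeats in the simulated stack (default 3).
#' @return Invisibly, a list with the written `paths` and the in-memory
#'   `geometry`, `matrix` (`NULL` at full scale), `phantom` and `expected`.
#' @export
make_fixture <- function(profile = c("tiny", "default", "full_scale"),
                         seed = 7L, out_dir = tempfile("fixture_"),
                         n_repeats = 3L) {
  profile <- match.arg(profile)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  geom <- fixture_geometry(profile)
  phantom <- fixture_phantom(profile)
  paths <- list(geometry = file.path(out_dir, "geometry.yaml"),
                phantom = file.path(out_dir, "phantom.csv"))
  write_geometry(geom, paths$geometry)
  utils::write.csv(phantom, paths$phantom, row.names = FALSE)

  if (profile == "full_scale") {
    return(invisible(list(paths = paths, geometry = geom, matrix = NULL,
                          phantom = phantom, expected = NULL)))
  }

  sm <- build_system_matrix(geom)
  paths$matrix <- file.path(out_dir, "A")
  write_system_matrix(sm, paths$matrix)

  cfg <- acquisition_config(n_repeats = n_repeats, seed = seed)
  stack <- simulate_acquisition(phantom[5, ], sm, cfg)
  paths$images <- file.path(out_dir, sprintf("stack_%03d.tif",
                                             seq_len(n_repeats)))
  for (r in seq_len(n_repeats)) {
    write_detector_image(stack$images[[r]], paths$images[r])
  }
  paths$truth <- file.path(out_dir, "truth.json")
  jsonlite::write_json(
    list(seed = seed, profile = profile,
         geometry_hash = sm$geometry_hash,
         truth = stack$truth[, c("id", "x_snap", "y_snap", "z_snap",
                                 "voxel", "snap_mm")]),
    paths$truth, auto_unbox = TRUE, digits = 10)

  # expected outputs from the independent reference implementations only
  fps <- oracle_footprints(geom)
  expected <- list(
    planted_voxel = stack$truth$voxel,
    per_repeat = lapply(seq_len(n_repeats), function(r) {
      oracle_argmax_round(image_to_vector(read_detector_image(paths$images[r])),
                          fps)
    }),
    footprint_nnz_max = max(lengths(fps))
  )
  paths$expected <- file.path(out_dir, "expected.json")
  jsonlite::write_json(expected, paths$expected, auto_unbox = TRUE, digits = 10)

  invisible(list(paths = paths, geometry = geom, matrix = sm,
                 phantom = phantom, expected = expected))
}
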