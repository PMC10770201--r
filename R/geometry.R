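#' Detector specification
#'
#' Describes the (binned) pixelated gamma detector. The physical detector is
#' read out at `raw_shape` resolution and binned by summing `bin_factor` x
#' `bin_factor` pixel neighborhoods, so the binned shape must divide exactly.
#' The detector plane sits parallel to the collimator plate at
#' `z = -plane_offset` (the plate is at `z = 0`, sources live at `z > 0`).
#'
#' Defaults reproduce a CdTe hybrid photon-counting detector with 1030 x 514
#' raw pixels of 75 micrometre pitch, binned 2x2 to 515 x 257 pixels, and a
#' quantum efficiency of 10% at the 140.5 keV line of 99mTc.
#'
#' @param n_rows,n_cols Binned pixel counts (rows x columns).
#' @param pixel_pitch Binned pixel pitch in mm.
#' @param raw_shape Integer vector `c(rows, cols)` before binning.
#' @param bin_factor Integer binning factor (applied to both axes).
#' @param plane_offset Distance from collimator plate to detector plane in mm
#'   (positive, behind the plate).
#' @param quantum_efficiency Fraction of incident photons detected, in (0, 1].
#' @return An object of class `detector_spec`.
#' @examples
#' detector_spec()            # the full-scale binned detector, N = 132355
#' detector_spec(64, 128, pixel_pitch = 0.6, raw_shape = c(128, 256))
#' @export
detector_spec <- function(n_rows = 257L, n_cols = 515L, pixel_pitch = 0.15,
                          raw_shape = c(514L, 1030L), bin_factor = 2L,
                          plane_offset = 30, quantum_efficiency = 0.1) {
  n_rows <- as.integer(n_rows)
  n_cols <- as.integer(n_cols)
  bin_factor <- as.integer(bin_factor)
  raw_shape <- as.integer(raw_shape)
  stopifnot(length(raw_shape) == 2L, n_rows >= 1L, n_cols >= 1L)
  if (raw_shape[1] != n_rows * bin_factor || raw_shape[2] != n_cols * bin_factor) {
    stop("raw_shape must equal bin_factor * (n_rows, n_cols) exactly", call. = FALSE)
  }
  if (pixel_pitch <= 0) stop("pixel_pitch must be > 0", call. = FALSE)
  if (plane_offset <= 0) stop("plane_offset must be > 0", call. = FALSE)
  if (quantum_efficiency <= 0 || quantum_efficiency > 1) {
    stop("quantum_efficiency must be in (0, 1]", call. = FALSE)
  }
  structure(
    list(n_rows = n_rows, n_cols = n_cols, pixel_pitch = pixel_pitch,
         raw_shape = raw_shape, bin_factor = bin_factor,
         plane_offset = plane_offset, quantum_efficiency = quantum_efficiency),
    class = "detector_spec"
  )
}

#' Multi-pinhole collimator specification
#'
#' A tungsten plate at `z = 0` pierced by small pinhole channels. Each pinhole
#' accepts rays within `fov_half_angle` of the plate normal; rays through the
#' pinhole center are treated as ideal (point aperture), the physical 1 mm
#' diameter only enters the simulator as optional blur. Thin septal walls leak
#' a `penetration_fraction` of photons, modelled downstream as a uniform
#' background smear.
#'
#' @param pinholes A data frame (tibble) with columns `x_mm`, `y_mm` giving
#'   pinhole centers on the plate, and optionally `diameter_mm`,
#'   `channel_length_mm`, `fov_half_angle_deg` (recycled defaults 1, 1, 45).
#' @param plate_extent Numeric `c(width, height)` of the plate in mm; all
#'   pinhole centers must fall inside.
#' @param penetration_fraction Fraction of photons penetrating the plate walls,
#'   in `[0, 1)`. The physical plate leaks 5-10%; default 0.075.
#' @return An object of class `collimator_spec`; `$pinholes` is a tibble.
#' @seealso [default_pinhole_pattern()]
#' @export
collimator_spec <- function(pinholes = default_pinhole_pattern(),
                            plate_extent = c(80, 40),
                            penetration_fraction = 0.075) {
  pinholes <- tibble::as_tibble(pinholes)
  stopifnot(all(c("x_mm", "y_mm") %in% names(pinholes)), nrow(pinholes) >= 1L)
  if (is.null(pinholes[["diameter_mm"]])) pinholes$diameter_mm <- 1
  if (is.null(pinholes[["channel_length_mm"]])) pinholes$channel_length_mm <- 1
  if (is.null(pinholes[["fov_half_angle_deg"]])) pinholes$fov_half_angle_deg <- 45
  pinholes <- pinholes[, c("x_mm", "y_mm", "diameter_mm",
                           "channel_length_mm", "fov_half_angle_deg")]
  if (any(pinholes$diameter_mm <= 0)) stop("pinhole diameter must be > 0", call. = FALSE)
  if (any(pinholes$fov_half_angle_deg <= 0 | pinholes$fov_half_angle_deg >= 90)) {
    stop("fov_half_angle_deg must be in (0, 90)", call. = FALSE)
  }
  if (penetration_fraction < 0 || penetration_fraction >= 1) {
    stop("penetration_fraction must be in [0, 1)", call. = FALSE)
  }
  if (any(abs(pinholes$x_mm) > plate_extent[1] / 2 |
          abs(pinholes$y_mm) > plate_extent[2] / 2)) {
    stop("all pinhole centers must lie within plate_extent", call. = FALSE)
  }
  structure(
    list(pinholes = pinholes, plate_extent = plate_extent,
         penetration_fraction = penetration_fraction),
    class = "collimator_spec"
  )
}

#' Default nine-pinhole pattern
#'
#' Nine pinholes on a jittered 3 x 3 grid spanning the central region of the
#' plate. The jitter (deterministic for a given `seed`) breaks the symmetry of
#' a regular grid so that distinct voxels project to distinct pixel
#' footprints, which is what the fingerprinting reconstruction needs. The
#' pattern is a configuration input: any pinhole table can be supplied to
#' [collimator_spec()] instead.
#'
#' @param n_side Pinholes per side of the square layout (default 3, i.e. 9).
#' @param span Numeric `c(width, height)` in mm covered by the nominal grid.
#' @param jitter_sd Standard deviation of the Gaussian positional jitter, mm.
#' @param seed Integer seed making the jitter reproducible.
#' @return A tibble with columns `x_mm`, `y_mm`.
#' @export
default_pinhole_pattern <- function(n_side = 3L, span = c(48, 24),
                                    jitter_sd = 1.5, seed = 20210907L) {
  xs <- seq(-span[1] / 2, span[1] / 2, length.out = n_side)
  ys <- seq(-span[2] / 2, span[2] / 2, length.out = n_side)
  grid <- expand.grid(x_mm = xs, y_mm = ys)
  jit <- withr_rng(seed, function() {
    matrix(stats::rnorm(2L * nrow(grid), sd = jitter_sd), ncol = 2L)
  })
  # micrometre rounding: machining precision, and exact config round-trips
  tibble::tibble(x_mm = round(grid$x_mm + jit[, 1], 3),
                 y_mm = round(grid$y_mm + jit[, 2], 3))
}

# run fn under a local RNG state seeded with `seed`, restoring the caller's
withr_rng <- function(seed, fn) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  fn()
}

#' Reconstruction volume grid
#'
#' The 3D subspace in front of the collimator plate, sampled on a regular
#' grid. The grid is centered on the plate in x and y; z planes start one
#' spacing in front of the plate (`z = spacing, 2*spacing, ...`). Voxels are
#' linearized x-fastest, then y, then z, with 1-based indices.
#'
#' The full-scale default is 60 x 100 x 200 sampling points at 2 mm spacing
#' (M = 1,200,000 voxels).
#'
#' @param n_x,n_y,n_z Sampling-point counts per axis.
#' @param spacing Spatial sampling distance in mm (isotropic).
#' @return An object of class `volume_grid`.
#' @examples
#' g <- volume_grid(3, 3, 3, spacing = 2)
#' voxel_center(g, 1)
#' @export
volume_grid <- function(n_x = 60L, n_y = 100L, n_z = 200L, spacing = 2) {
  n_x <- as.integer(n_x); n_y <- as.integer(n_y); n_z <- as.integer(n_z)
  stopifnot(n_x >= 1L, n_y >= 1L, n_z >= 1L)
  if (spacing <= 0) stop("spacing must be > 0", call. = FALSE)
  structure(
    list(n_x = n_x, n_y = n_y, n_z = n_z, spacing = spacing,
         n_voxels = as.double(n_x) * n_y * n_z),
    class = "volume_grid"
  )
}

#' Voxel index to world coordinate, and back
#'
#' `voxel_center()` maps 1-based linear voxel indices (x-fastest ordering) to
#' the world coordinates (mm) of the voxel centers; `nearest_voxel()` is its
#' inverse for arbitrary points, snapping to the closest grid voxel. The two
#' round-trip exactly on grid points.
#'
#' @param grid A [volume_grid()].
#' @param index Vector of linear voxel indices in `1..n_voxels`.
#' @return `voxel_center()`: a numeric matrix with columns `x`, `y`, `z` (mm);
#'   `nearest_voxel()`: an integer vector of linear indices.
#' @examples
#' g <- volume_grid(3, 3, 3, spacing = 2)
#' nearest_voxel(g, voxel_center(g, 14))  # 14
#' @export
voxel_center <- function(grid, index) {
  stopifnot(inherits(grid, "volume_grid"))
  index <- as.double(index)
  if (any(index < 1 | index > grid$n_voxels | index != floor(index))) {
    stop("voxel index out of range", call. = FALSE)
  }
  i0 <- index - 1
  ix <- i0 %% grid$n_x
  iy <- (i0 %/% grid$n_x) %% grid$n_y
  iz <- i0 %/% (as.double(grid$n_x) * grid$n_y)
  s <- grid$spacing
  cbind(
    x = (ix - (grid$n_x - 1) / 2) * s,
    y = (iy - (grid$n_y - 1) / 2) * s,
    z = (iz + 1) * s
  )
}

#' @rdname voxel_center
#' @param xyz A numeric matrix (or length-3 vector) of points, columns x, y, z
#'   in mm.
#' @export
nearest_voxel <- function(grid, xyz) {
  stopifnot(inherits(grid, "volume_grid"))
  if (is.null(dim(xyz))) xyz <- matrix(xyz, ncol = 3L)
  s <- grid$spacing
  clamp <- function(v, n) pmin(pmax(v, 0), n - 1)
  ix <- clamp(round(xyz[, 1] / s + (grid$n_x - 1) / 2), grid$n_x)
  iy <- clamp(round(xyz[, 2] / s + (grid$n_y - 1) / 2), grid$n_y)
  iz <- clamp(round(xyz[, 3] / s - 1), grid$n_z)
  as.integer(ix + grid$n_x * (iy + grid$n_y * iz) + 1)
}

#' Geometry model
#'
#' Bundles detector, collimator and reconstruction grid in the shared
#' coordinate frame: origin at the center of the collimator plate, z pointing
#' into the scene (towards the sources), detector behind the plate at
#' `z = -plane_offset`. Detector row 1 / column 1 is the top-left pixel
#' (largest y, smallest x).
#'
#' @param detector A [detector_spec()].
#' @param collimator A [collimator_spec()].
#' @param grid A [volume_grid()].
#' @return An object of class `slnf_geometry`.
#' @export
geometry_model <- function(detector = detector_spec(),
                           collimator = collimator_spec(),
                           grid = volume_grid()) {
  stopifnot(inherits(detector, "detector_spec"),
            inherits(collimator, "collimator_spec"),
            inherits(grid, "volume_grid"))
  structure(list(detector = detector, collimator = collimator, grid = grid),
            class = "slnf_geometry")
}

#' @export
print.slnf_geometry <- function(x, ...) {
  d <- x$detector; g <- x$grid
  cat("<slnf_geometry>\n")
  cat(sprintf("  detector:   %d x %d binned pixels (pitch %.3g mm), plane at z = -%g mm\n",
              d$n_rows, d$n_cols, d$pixel_pitch, d$plane_offset))
  cat(sprintf("  collimator: %d pinholes, plate %g x %g mm, penetration %.1f%%\n",
              nrow(x$collimator$pinholes), x$collimator$plate_extent[1],
              x$collimator$plate_extent[2], 100 * x$collimator$penetration_fraction))
  cat(sprintf("  grid:       %d x %d x %d voxels @ %g mm (M = %s)\n",
              g$n_x, g$n_y, g$n_z, g$spacing,
              format(g$n_voxels, big.mark = ",")))
  invisible(x)
}

#' Trace source-to-detector rays through pinholes
#'
#' Intersects the straight line from each source point through a pinhole
#' center with the detector plane at `z = -plane_offset` and returns the
#' 1-based linear index (row-major: `(row - 1) * n_cols + col`) of the binned
#' pixel containing the intersection, or `NA` when the ray's angle to the
#' plate normal exceeds the pinhole field of view or the intersection misses
#' the detector. The pinhole geometry inverts the image: a source moving +x
#' moves its hit -x relative to the pinhole axis.
#'
#' @param source Numeric matrix of source points (columns x, y, z in mm) or a
#'   single length-3 vector; all z must be > 0 (in front of the plate).
#' @param pinhole A list/row with `x_mm`, `y_mm` and `fov_half_angle_deg`.
#' @param detector A [detector_spec()].
#' @return Integer vector of pixel indices, `NA` for misses.
#' @export
trace_ray <- function(source, pinhole, detector) {
  if (is.null(dim(source))) source <- matrix(source, ncol = 3L)
  if (any(source[, 3] == 0)) {
    stop("degenerate geometry: source on the collimator plate plane (z = 0)",
         call. = FALSE)
  }
  if (any(source[, 3] < 0)) {
    stop("source must be in front of the plate (z > 0)", call. = FALSE)
  }
  px <- pinhole$x_mm; py <- pinhole$y_mm
  # angle between ray (source -> pinhole) and plate normal
  lat <- sqrt((source[, 1] - px)^2 + (source[, 2] - py)^2)
  ang <- atan2(lat, source[, 3])
  ok <- ang <= pinhole$fov_half_angle_deg * pi / 180
  # similar triangles: continue the ray a further plane_offset behind the plate
  f <- detector$plane_offset / source[, 3]
  xd <- px + f * (px - source[, 1])
  yd <- py + f * (py - source[, 2])
  pixel_at(xd, yd, detector, ok)
}

# world (x, y) on the detector plane -> 1-based linear pixel index (row-major)
pixel_at <- function(xd, yd, detector, ok = TRUE) {
  w <- detector$n_cols * detector$pixel_pitch
  h <- detector$n_rows * detector$pixel_pitch
  col <- floor((xd + w / 2) / detector$pixel_pitch) + 1
  row <- floor((h / 2 - yd) / detector$pixel_pitch) + 1
  hit <- ok & col >= 1 & col <= detector$n_cols & row >= 1 & row <= detector$n_rows
  out <- rep(NA_integer_, length(xd))
  out[hit] <- as.integer((row[hit] - 1) * detector$n_cols + col[hit])
  out
}

#' Read or write a geometry model as a YAML config
#'
#' The config has three blocks: `detector` (rows, cols, pitch_mm, raw_rows,
#' raw_cols, bin_factor, offset_mm, quantum_efficiency), `collimator`
#' (pinholes as a list of x/y, diameter_mm, fov_deg, penetration) and `grid`
#' (nx, ny, nz, spacing_mm).
#'
#' @param path File path of the YAML config.
#' @param geometry An `slnf_geometry` object.
#' @return `read_geometry()` returns an `slnf_geometry`;
#'   `write_geometry()` returns `path` invisibly.
#' @export
read_geometry <- function(path) {
  cfg <- yaml::read_yaml(path)
  det <- cfg$detector
  col <- cfg$collimator
  grd <- cfg$grid
  pin <- tibble::tibble(
    x_mm = vapply(col$pinholes, function(p) p$x, numeric(1)),
    y_mm = vapply(col$pinholes, function(p) p$y, numeric(1)),
    diameter_mm = col$diameter_mm %||% 1,
    fov_half_angle_deg = (col$fov_deg %||% 90) / 2
  )
  geometry_model(
    detector = detector_spec(
      n_rows = det$rows, n_cols = det$cols, pixel_pitch = det$pitch_mm,
      raw_shape = c(det$raw_rows %||% (det$rows * (det$bin_factor %||% 2L)),
                    det$raw_cols %||% (det$cols * (det$bin_factor %||% 2L))),
      bin_factor = det$bin_factor %||% 2L,
      plane_offset = det$offset_mm %||% 30,
      quantum_efficiency = det$quantum_efficiency %||% 0.1
    ),
    collimator = collimator_spec(
      pinholes = pin,
      plate_extent = unlist(col$plate_extent_mm %||% list(80, 40)),
      penetration_fraction = col$penetration %||% 0.075
    ),
    grid = volume_grid(grd$nx, grd$ny, grd$nz, spacing = grd$spacing_mm)
  )
}

#' @rdname read_geometry
#' @export
write_geometry <- function(geometry, path) {
  stopifnot(inherits(geometry, "slnf_geometry"))
  d <- geometry$detector; c_ <- geometry$collimator; g <- geometry$grid
  cfg <- list(
    detector = list(rows = d$n_rows, cols = d$n_cols, pitch_mm = d$pixel_pitch,
                    raw_rows = d$raw_shape[1], raw_cols = d$raw_shape[2],
                    bin_factor = d$bin_factor, offset_mm = d$plane_offset,
                    quantum_efficiency = d$quantum_efficiency),
    collimator = list(
      pinholes = lapply(seq_len(nrow(c_$pinholes)), function(i) {
        list(x = c_$pinholes$x_mm[i], y = c_$pinholes$y_mm[i])
      }),
      diameter_mm = c_$pinholes$diameter_mm[1],
      fov_deg = 2 * c_$pinholes$fov_half_angle_deg[1],
      plate_extent_mm = as.list(c_$plate_extent),
      penetration = c_$penetration_fraction
    ),
    grid = list(nx = g$n_x, ny = g$n_y, nz = g$n_z, spacing_mm = g$spacing)
  )
  yaml::write_yaml(cfg, path, precision = 12L)
  invisible(path)
}

#' Stable content hash of a geometry model
#'
#' MD5 of a canonical JSON serialization; used to key system-matrix caches.
#'
#' @param geometry An `slnf_geometry` object.
#' @return A 32-character hex string.
#' @export
geometry_hash <- function(geometry) {
  stopifnot(inherits(geometry, "slnf_geometry"))
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(
    list(detector = unclass(geometry$detector),
         collimator = list(pinholes = as.data.frame(geometry$collimator$pinholes),
                           plate_extent = geometry$collimator$plate_extent,
                           penetration = geometry$collimator$penetration_fraction),
         grid = unclass(geometry$grid)),
    tf, digits = 10, auto_unbox = TRUE)
  unname(tools::md5sum(tf))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
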