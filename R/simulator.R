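#' Point-source lists
#'
#' Sources are plain tibbles with columns `x_mm`, `y_mm`, `z_mm` (position in
#' the plate-centered frame) and `activity_mbq`; an `id` column is added when
#' missing. `source_set()` validates and normalizes such a table.
#'
#' @param sources A data frame with at least `x_mm`, `y_mm`, `z_mm`,
#'   `activity_mbq`.
#' @return A tibble with columns `id`, `x_mm`, `y_mm`, `z_mm`, `activity_mbq`.
#' @export
source_set <- function(sources) {
  sources <- tibble::as_tibble(sources)
  need <- c("x_mm", "y_mm", "z_mm", "activity_mbq")
  if (!all(need %in% names(sources))) {
    stop("sources needs columns ", paste(need, collapse = ", "), call. = FALSE)
  }
  if (any(sources$activity_mbq < 0)) {
    stop("activity must be >= 0 MBq", call. = FALSE)
  }
  if (is.null(sources[["id"]])) sources$id <- seq_len(nrow(sources))
  sources[, c("id", need)]
}

#' Nine-position phantom grid
#'
#' The 3 x 3 vial phantom used throughout: nine positions in the y-z plane at
#' `x = origin_offset[1]`, indexed 1..9 row by row. Within a row (indices
#' 1-2-3, 4-5-6, 7-8-9) positions step `spacing` mm along y; rows step
#' `spacing` mm along z, starting at the standoff `origin_offset[3]`. Adjacent
#' positions are therefore 20 mm apart (default), same-row end pairs 40 mm,
#' and diagonal neighbors `sqrt(2) * spacing` = 28.28 mm.
#'
#' @param spacing Grid spacing in mm (default 20).
#' @param origin_offset Length-3 numeric: world position of the phantom
#'   (x of the plane, y of the middle column, z standoff of the first row).
#' @param activity_mbq Activity assigned to every position (vials of 5, 15,
#'   30 or 60 MBq in the experiments; default 15).
#' @return A source tibble (see [source_set()]) with 9 rows.
#' @examples
#' p <- generate_grid_phantom()
#' dist(p[c(1, 2), c("x_mm", "y_mm", "z_mm")])  # 20 mm
#' @export
generate_grid_phantom <- function(spacing = 20, origin_offset = c(0, 0, 100),
                                  activity_mbq = 15) {
  if (spacing <= 0) stop("spacing must be > 0", call. = FALSE)
  i <- 1:9
  col <- (i - 1) %% 3   # y within a row
  row <- (i - 1) %/% 3  # z between rows
  source_set(tibble::tibble(
    id = i,
    x_mm = origin_offset[1],
    y_mm = origin_offset[2] + (col - 1) * spacing,
    z_mm = origin_offset[3] + row * spacing,
    activity_mbq = activity_mbq
  ))
}

#' Acquisition configuration
#'
#' Parameters of one simulated measurement series. `counts_per_mbq_s` is the
#' calibration constant: expected detected counts per MBq of source activity,
#' per second of exposure, per open ray (pixel of the source's footprint). It
#' stands in for the real detector's full efficiency chain (10% quantum
#' efficiency, solid angle, decay branching); its default of 10 makes a
#' 15 MBq source at 8 s exposure deposit about 1e4 counts over a 9-pinhole
#' footprint, the regime of the physical acquisitions.
#'
#' @param exposure Exposure time per measurement in seconds (default 8).
#' @param n_repeats Number of measurements per configuration (default 10).
#' @param counts_per_mbq_s Calibration constant, counts / (MBq s ray).
#' @param penetration_fraction Fraction of source counts leaked uniformly
#'   across the detector by septal penetration; `NA` (default) takes the
#'   collimator's own value.
#' @param hot_background `NULL`, or a list with `activity_mbq` and `extent`
#'   (a list of `x`, `y`, `z` ranges in mm) describing a uniform volume of
#'   activity, e.g. tracer soaked into the phantom block.
#' @param aperture_blur_sigma Gaussian blur applied to each noisy image, in
#'   binned pixels (0 = ideal point aperture, the default).
#' @param artifact_column `NULL`, or a detector column index rendered
#'   saturated in every repeat (emulates a readout artifact; for robustness
#'   testing only).
#' @param poisson If `FALSE`, skip the Poisson draw and return the expected
#'   image itself in every repeat (a noiseless acquisition).
#' @param seed Integer seed; fixed seed implies bit-identical stacks.
#' @return An object of class `acq_config`.
#' @export
acquisition_config <- function(exposure = 8, n_repeats = 10L,
                               counts_per_mbq_s = 10,
                               penetration_fraction = NA_real_,
                               hot_background = NULL,
                               aperture_blur_sigma = 0,
                               artifact_column = NULL,
                               poisson = TRUE,
                               seed = 1L) {
  if (exposure <= 0) stop("exposure must be > 0", call. = FALSE)
  n_repeats <- as.integer(n_repeats)
  if (n_repeats < 1L) stop("n_repeats must be >= 1", call. = FALSE)
  if (!is.na(penetration_fraction) &&
      (penetration_fraction < 0 || penetration_fraction >= 1)) {
    stop("penetration_fraction must be in [0, 1)", call. = FALSE)
  }
  structure(
    list(exposure = exposure, n_repeats = n_repeats,
         counts_per_mbq_s = counts_per_mbq_s,
         penetration_fraction = penetration_fraction,
         hot_background = hot_background,
         aperture_blur_sigma = aperture_blur_sigma,
         artifact_column = artifact_column,
         poisson = isTRUE(poisson),
         seed = as.integer(seed)),
    class = "acq_config"
  )
}

#' Simulate a stack of detector images
#'
#' Builds the expected detector image of the given sources under the forward
#' model and draws `n_repeats` independent Poisson realizations from it.
#' The expected image is
#' `lambda = sum_s activity_s * exposure * counts_per_mbq_s * column(voxel_s)`
#' plus a uniform penetration smear carrying `penetration_fraction` of the
#' source mass, plus (optionally) the forward projection of a uniform hot
#' background volume. Sources are snapped to the nearest grid voxel; the snap
#' distance is recorded in the returned truth table.
#'
#' @param sources A source tibble (see [source_set()]).
#' @param sm An `slnf_matrix` from [build_system_matrix()].
#' @param cfg An [acquisition_config()].
#' @return An object of class `slnf_stack`: list with `images` (list of
#'   `n_repeats` numeric `n_rows x n_cols` matrices), `lambda` (expected
#'   image, same shape), `truth` (tibble: source id, requested and snapped
#'   positions, voxel index, snap distance in mm), `cfg` and `seed`.
#' @export
simulate_acquisition <- function(sources, sm, cfg = acquisition_config()) {
  stopifnot(inherits(sm, "slnf_matrix"), inherits(cfg, "acq_config"))
  sources <- source_set(sources)
  geom <- sm$geometry
  grid <- geom$grid
  det <- geom$detector
  ext <- grid_extent(grid)
  inside <- sources$x_mm >= ext$x[1] & sources$x_mm <= ext$x[2] &
    sources$y_mm >= ext$y[1] & sources$y_mm <= ext$y[2] &
    sources$z_mm >= ext$z[1] & sources$z_mm <= ext$z[2]
  if (!all(inside)) {
    stop("source(s) ", paste(sources$id[!inside], collapse = ", "),
         " lie outside the reconstruction grid", call. = FALSE)
  }
  pen <- cfg$penetration_fraction
  if (is.na(pen)) pen <- geom$collimator$penetration_fraction

  xyz <- as.matrix(sources[, c("x_mm", "y_mm", "z_mm")])
  vox <- nearest_voxel(grid, xyz)
  snapped <- voxel_center(grid, vox)
  snap_mm <- sqrt(rowSums((xyz - snapped)^2))

  rate <- cfg$exposure * cfg$counts_per_mbq_s
  lambda <- numeric(sm$n_pixels)
  for (s in seq_len(nrow(sources))) {
    fp <- column_footprint(sm, vox[s])
    lambda[fp] <- lambda[fp] + sources$activity_mbq[s] * rate
  }
  # septal penetration: a uniform smear carrying pen * (source mass)
  lambda <- lambda + pen * sum(lambda) / sm$n_pixels

  hb <- cfg$hot_background
  if (!is.null(hb)) {
    vb <- voxels_in_box(grid, hb$extent)
    if (length(vb)) {
      u_bg <- numeric(sm$n_voxels)
      u_bg[vb] <- hb$activity_mbq / length(vb) * rate
      lambda <- lambda + forward_project(sm, u_bg)
    }
  }

  images <- withr_rng(cfg$seed, function() {
    lapply(seq_len(cfg$n_repeats), function(r) {
      d <- if (cfg$poisson) stats::rpois(length(lambda), lambda) else lambda
      img <- vector_to_image(d, det)
      if (cfg$aperture_blur_sigma > 0) {
        img <- gaussian_blur(img, cfg$aperture_blur_sigma)
      }
      if (!is.null(cfg$artifact_column)) img[, cfg$artifact_column] <- 65535
      img
    })
  })

  truth <- dplyr::bind_cols(
    sources,
    tibble::tibble(voxel = vox,
                   x_snap = unname(snapped[, "x"]),
                   y_snap = unname(snapped[, "y"]),
                   z_snap = unname(snapped[, "z"]),
                   snap_mm = unname(snap_mm))
  )
  structure(list(images = images, lambda = vector_to_image(lambda, det),
                 truth = truth, cfg = cfg, seed = cfg$seed),
            class = "slnf_stack")
}

#' @export
print.slnf_stack <- function(x, ...) {
  cat(sprintf("<slnf_stack> %d repeat(s) of %d x %d counts, %d source(s), seed %d\n",
              length(x$images), nrow(x$images[[1]]), ncol(x$images[[1]]),
              nrow(x$truth), x$seed))
  invisible(x)
}

# world-extent of the voxel grid (voxel centers)
grid_extent <- function(grid) {
  s <- grid$spacing
  list(x = c(-1, 1) * (grid$n_x - 1) / 2 * s,
       y = c(-1, 1) * (grid$n_y - 1) / 2 * s,
       z = c(1, grid$n_z) * s)
}

# linear indices of voxels whose centers fall in the box extent
voxels_in_box <- function(grid, extent) {
  idx <- seq_len(as.integer(grid$n_voxels))
  ctr <- voxel_center(grid, idx)
  keep <- ctr[, "x"] >= extent$x[1] & ctr[, "x"] <= extent$x[2] &
    ctr[, "y"] >= extent$y[1] & ctr[, "y"] <= extent$y[2] &
    ctr[, "z"] >= extent$z[1] & ctr[, "z"] <= extent$z[2]
  idx[keep]
}

#' Convert between detector matrices and vectorized images
#'
#' Detector images are `n_rows x n_cols` matrices (row 1 = top). The
#' vectorized form used by the linear model is row-major:
#' `d[(row - 1) * n_cols + col] = img[row, col]`.
#'
#' @param d Numeric vector of length `n_rows * n_cols`.
#' @param img Numeric matrix of shape `n_rows x n_cols`.
#' @param detector A [detector_spec()].
#' @return `vector_to_image()` a matrix; `image_to_vector()` a vector.
#' @export
vector_to_image <- function(d, detector) {
  matrix(d, nrow = detector$n_rows, ncol = detector$n_cols, byrow = TRUE)
}

#' @rdname vector_to_image
#' @export
image_to_vector <- function(img) {
  as.numeric(t(img))
}

#' Bin a raw detector image by summation
#'
#' Sums `factor x factor` pixel neighborhoods, e.g. a raw 514 x 1030 image to
#' the working 257 x 515 resolution. Total counts are conserved exactly.
#'
#' @param raw Numeric matrix; both dimensions must be divisible by `factor`.
#' @param factor Integer binning factor (default 2).
#' @return The binned matrix of shape `dim(raw) / factor`.
#' @examples
#' bin_image(matrix(1, 4, 6))  # 2 x 3 matrix of fours
#' @export
bin_image <- function(raw, factor = 2L) {
  factor <- as.integer(factor)
  if (any(dim(raw) %% factor != 0L)) {
    stop("image dimensions must be divisible by the binning factor", call. = FALSE)
  }
  nr <- nrow(raw) %/% factor
  nc <- ncol(raw) %/% factor
  # sum factor x factor blocks via two reshapes
  m <- matrix(colSums(matrix(raw, nrow = factor)), nrow = nr, ncol = ncol(raw))
  t(matrix(colSums(matrix(t(m), nrow = factor)), nrow = nc, ncol = nr))
}

# separable Gaussian blur with zero padding; kernel radius 3 sigma
gaussian_blur <- function(img, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  conv1 <- function(x) {
    xp <- c(numeric(r), x, numeric(r))
    vapply(seq_along(x), function(i) sum(xp[i:(i + 2 * r)] * k), numeric(1))
  }
  out <- apply(img, 2, conv1)
  t(apply(out, 1, conv1))
}

#' Read and write detector images as 16-bit grayscale TIFF
#'
#' Counts are stored losslessly as 16-bit unsigned samples; values above
#' 65535 are clipped with a warning. Row 1 of the matrix is the top image
#' row.
#'
#' @param img Numeric matrix of non-negative counts.
#' @param path TIFF file path.
#' @return `read_detector_image()` returns an integer matrix;
#'   `write_detector_image()` returns `path` invisibly.
#' @export
write_detector_image <- function(img, path) {
  img <- round(img)
  if (any(img > 65535)) {
    warning("counts above 65535 clipped in 16-bit TIFF output")
    img[img > 65535] <- 65535
  }
  img[img < 0] <- 0
  tiff::writeTIFF(img / 65535, path, bits.per.sample = 16L,
                  compression = "none")
  invisible(path)
}

#' @rdname write_detector_image
#' @export
read_detector_image <- function(path) {
  m <- tiff::readTIFF(path)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  storage.mode(m) <- "double"
  round(m * 65535)
}
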