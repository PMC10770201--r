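#' Correlation objective between projected and observed images
#'
#' The matched-filter score `C(d_proj, d_obs) = sum_i d_proj_i * d_obs_i`.
#' For a binary projection this is simply the observed counts collected on
#' the projection's footprint.
#'
#' @param d_proj,d_obs Numeric vectors of equal length (vectorized detector
#'   images).
#' @return A single numeric score.
#' @export
correlation <- function(d_proj, d_obs) {
  if (length(d_proj) != length(d_obs)) {
    stop("d_proj and d_obs must have equal length", call. = FALSE)
  }
  sum(d_proj * d_obs)
}

#' SLNF greedy source localization
#'
#' Sentinel lymph node fingerprinting: localizes a known number of point
#' sources from a single detector image. Each round (1) scores every grid
#' voxel by the correlation of its binary detector fingerprint (column of A)
#' with the current observed image, (2) selects the maximizing voxel, and
#' (3) masks the image, zeroing every pixel of the selected footprint so the
#' next-strongest source dominates the following round. The number of sources
#' is assumed known and must be supplied.
#'
#' Ties at the argmax are broken deterministically towards the lowest linear
#' voxel index, and the number of tied voxels is reported per round. An
#' all-zero observed image yields a degenerate result (every voxel ties at
#' score 0), flagged rather than silently resolved.
#'
#' @param d_obs Observed detector image: an `n_rows x n_cols` matrix or an
#'   already-vectorized numeric vector of length `n_pixels`.
#' @param sm An `slnf_matrix` from [build_system_matrix()].
#' @param n_sources Number of sources to extract (>= 1).
#' @param stop_score_fraction Optional early-stopping heuristic: stop when a
#'   round's best score falls below this fraction of the first round's best
#'   score. `NULL` (default) disables it, matching the known-source-count
#'   assumption.
#' @return An object of class `slnf_recon`; see [tidy.slnf_recon()]. Fields:
#'   `sources` (tibble: rank, voxel, x/y/z mm, score, n_ties), `residual`
#'   (masked image after the last extraction), `degenerate` flag, `n_pixels`,
#'   `grid`.
#' @examples
#' # recover a planted voxel from its own noiseless fingerprint
#' geom <- geometry_model(
#'   detector_spec(16, 32, pixel_pitch = 1, raw_shape = c(32, 64)),
#'   collimator_spec(tibble::tibble(x_mm = c(-3, 0, 3), y_mm = c(0, 1, -1)),
#'                   plate_extent = c(10, 10)),
#'   volume_grid(3, 3, 3, spacing = 4))
#' sm <- build_system_matrix(geom)
#' d <- forward_project(sm, replace(numeric(sm$n_voxels), 14, 1))
#' slnf_reconstruct(d, sm, n_sources = 1)$sources$voxel  # 14
#' @export
slnf_reconstruct <- function(d_obs, sm, n_sources,
                             stop_score_fraction = NULL) {
  stopifnot(inherits(sm, "slnf_matrix"))
  if (n_sources < 1) stop("n_sources must be >= 1", call. = FALSE)
  if (is.matrix(d_obs)) d_obs <- image_to_vector(d_obs)
  if (length(d_obs) != sm$n_pixels) {
    stop(sprintf("d_obs has length %d, expected %d pixels",
                 length(d_obs), sm$n_pixels), call. = FALSE)
  }
  grid <- sm$geometry$grid
  d <- as.numeric(d_obs)
  degenerate <- FALSE
  rows <- vector("list", n_sources)
  first_score <- NA_real_
  for (r in seq_len(n_sources)) {
    scores <- as.numeric(Matrix::crossprod(sm$A, d))  # one score per voxel
    best <- max(scores)
    ties <- which(scores == best)
    v <- ties[1L]  # lowest linear index wins
    if (best == 0 && length(ties) == sm$n_voxels) degenerate <- TRUE
    if (r == 1L) first_score <- best
    if (!is.null(stop_score_fraction) && r > 1L &&
        best < stop_score_fraction * first_score) {
      rows <- rows[seq_len(r - 1L)]
      break
    }
    ctr <- voxel_center(grid, v)
    rows[[r]] <- tibble::tibble(
      rank = r, voxel = v,
      x_mm = ctr[, "x"], y_mm = ctr[, "y"], z_mm = ctr[, "z"],
      score = best, n_ties = length(ties)
    )
    d[column_footprint(sm, v)] <- 0  # mask the found source's fingerprint
  }
  structure(
    list(sources = dplyr::bind_rows(rows),
         residual = vector_to_image(d, sm$geometry$detector),
         degenerate = degenerate, n_pixels = sm$n_pixels, grid = grid),
    class = "slnf_recon"
  )
}

#' @export
print.slnf_recon <- function(x, ...) {
  cat(sprintf("<slnf_recon> %d source(s)%s\n", nrow(x$sources),
              if (x$degenerate) " [degenerate: all-zero image]" else ""))
  print(x$sources)
  invisible(x)
}

#' Positions of reconstructed sources
#'
#' Maps the extracted voxels of a reconstruction to world coordinates (mm)
#' via the grid's voxel centers.
#'
#' @param recon An `slnf_recon` from [slnf_reconstruct()].
#' @return A numeric matrix with columns `x`, `y`, `z` (one row per source,
#'   in extraction order).
#' @export
voxel_to_position <- function(recon) {
  stopifnot(inherits(recon, "slnf_recon"))
  voxel_center(recon$grid, recon$sources$voxel)
}

#' Tidy an SLNF reconstruction
#'
#' @param x An `slnf_recon`.
#' @param ... Unused.
#' @return `tidy()`: one row per extracted source (rank, voxel, position in
#'   mm, correlation score, tie count). `glance()`: a one-row summary.
#' @export
tidy.slnf_recon <- function(x, ...) {
  x$sources
}

#' @rdname tidy.slnf_recon
#' @export
glance.slnf_recon <- function(x, ...) {
  tibble::tibble(
    n_sources = nrow(x$sources),
    top_score = if (nrow(x$sources)) x$sources$score[1] else NA_real_,
    residual_counts = sum(x$residual),
    degenerate = x$degenerate
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Plot a reconstruction over its residual image
#'
#' Displays the masked residual detector image with the extracted source
#' footprint positions of each round marked by rank.
#'
#' @param object An `slnf_recon`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.slnf_recon <- function(object, ...) {
  img <- object$residual
  df <- tibble::tibble(
    row = rep(seq_len(nrow(img)), times = ncol(img)),
    col = rep(seq_len(ncol(img)), each = nrow(img)),
    counts = as.vector(img)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$counts)) +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = "SLNF residual after masking",
                  x = "detector column", y = "detector row") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
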