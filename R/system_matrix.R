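#' Build the sparse binary system matrix
#'
#' Constructs the N x M binary operator A of the forward model `A u = d_proj`:
#' entry (i, j) is 1 when a straight line exists from the center of voxel j
#' through some pinhole center to detector pixel i, and 0 otherwise. N is the
#' number of binned detector pixels, M the number of grid voxels. Column j is
#' the detector "fingerprint" of a unit point source in voxel j; with an ideal
#' point aperture it holds at most one pixel per pinhole, and an entry hit
#' through two pinholes stays 1 (the matrix is binary, not a count).
#'
#' The build is deterministic: two builds from the same geometry are
#' identical. For repeated use, cache with [write_system_matrix()].
#'
#' @param geometry An [geometry_model()].
#' @return An object of class `slnf_matrix`: a list with `A` (a
#'   `Matrix::dgCMatrix` of 0/1), `n_pixels`, `n_voxels`, `geometry_hash`, and
#'   the `geometry` itself.
#' @examples
#' geom <- geometry_model(
#'   detector_spec(16, 32, pixel_pitch = 1, raw_shape = c(32, 64)),
#'   collimator_spec(tibble::tibble(x_mm = 0, y_mm = 0), plate_extent = c(10, 10)),
#'   volume_grid(3, 3, 3, spacing = 4))
#' sm <- build_system_matrix(geom)
#' Matrix::colSums(sm$A)  # pixels hit per voxel, at most 1 per pinhole
#' @export
build_system_matrix <- function(geometry) {
  stopifnot(inherits(geometry, "slnf_geometry"))
  grid <- geometry$grid
  det <- geometry$detector
  if (grid$n_voxels < 1) stop("grid has zero voxels", call. = FALSE)
  if (grid$n_voxels > .Machine$integer.max) {
    stop("grid too large for 32-bit voxel indices", call. = FALSE)
  }
  M <- as.integer(grid$n_voxels)
  N <- det$n_rows * det$n_cols
  centers <- voxel_center(grid, seq_len(M))
  pin <- geometry$collimator$pinholes
  rows <- vector("list", nrow(pin))
  cols <- vector("list", nrow(pin))
  for (k in seq_len(nrow(pin))) {
    hit <- trace_ray(centers, pin[k, ], det)
    keep <- !is.na(hit)
    rows[[k]] <- hit[keep]
    cols[[k]] <- which(keep)
  }
  A <- Matrix::sparseMatrix(
    i = unlist(rows), j = unlist(cols), x = 1,
    dims = c(N, M), use.last.ij = TRUE  # duplicate (pixel, voxel) stays 1
  )
  structure(
    list(A = A, n_pixels = N, n_voxels = M,
         geometry_hash = geometry_hash(geometry), geometry = geometry),
    class = "slnf_matrix"
  )
}

#' @export
print.slnf_matrix <- function(x, ...) {
  cat(sprintf("<slnf_matrix> %d pixels x %d voxels, %s nonzeros (binary)\n",
              x$n_pixels, x$n_voxels,
              format(Matrix::nnzero(x$A), big.mark = ",")))
  cat(sprintf("  geometry hash %s\n", x$geometry_hash))
  invisible(x)
}

#' Forward-project a source indicator to the detector
#'
#' Computes `A u`, the expected (noise-free, unit-rate) detector image of a
#' non-negative source vector `u` of length M. For a one-hot `u` this is the
#' corresponding column of A.
#'
#' @param sm An `slnf_matrix` from [build_system_matrix()].
#' @param u Non-negative numeric vector of length `n_voxels`.
#' @return A numeric vector of length `n_pixels` (the vectorized detector
#'   image, row-major).
#' @export
forward_project <- function(sm, u) {
  stopifnot(inherits(sm, "slnf_matrix"))
  if (length(u) != sm$n_voxels) {
    stop(sprintf("u has length %d, expected %d voxels", length(u), sm$n_voxels),
         call. = FALSE)
  }
  if (any(u < 0)) stop("u must be non-negative", call. = FALSE)
  as.numeric(sm$A %*% u)
}

#' Pixel footprint of a voxel
#'
#' The set of detector pixels illuminated by a unit source in the given voxel:
#' the nonzero rows of column `voxel` of A. At most one pixel per pinhole.
#'
#' @inheritParams forward_project
#' @param voxel A single 1-based linear voxel index.
#' @return A sorted integer vector of 1-based pixel indices (possibly empty).
#' @export
column_footprint <- function(sm, voxel) {
  stopifnot(inherits(sm, "slnf_matrix"), length(voxel) == 1L)
  if (voxel < 1 || voxel > sm$n_voxels) {
    stop("voxel index out of range", call. = FALSE)
  }
  A <- sm$A
  p <- A@p
  sort(A@i[seq.int(p[voxel] + 1L, length.out = p[voxel + 1L] - p[voxel])] + 1L)
}

# all footprints as a list of sorted pixel-index vectors (internal fast path)
footprint_list <- function(sm) {
  A <- sm$A
  p <- A@p
  i1 <- A@i + 1L
  lapply(seq_len(sm$n_voxels), function(j) {
    i1[seq.int(p[j] + 1L, length.out = p[j + 1L] - p[j])]
  })
}

#' Diagnose duplicate voxel footprints
#'
#' Voxels whose detector footprints are identical cannot be distinguished by
#' the reconstruction; this reports them rather than hiding the degeneracy.
#' Voxels with empty footprints (invisible to the detector) are grouped
#' together as well.
#'
#' @inheritParams forward_project
#' @return A tibble with columns `voxel`, `group` (voxels sharing a group id
#'   have identical footprints), `n_pixels`; only voxels belonging to a
#'   duplicated (or empty) footprint group are listed.
#' @export
duplicate_footprints <- function(sm) {
  stopifnot(inherits(sm, "slnf_matrix"))
  A <- sm$A
  p <- A@p
  keys <- vapply(seq_len(sm$n_voxels), function(j) {
    idx <- seq.int(p[j] + 1L, length.out = p[j + 1L] - p[j])
    paste(A@i[idx], collapse = ",")
  }, character(1))
  grp <- match(keys, unique(keys))
  dup_groups <- unique(grp[duplicated(grp) | keys == ""])
  keep <- grp %in% dup_groups
  tibble::tibble(
    voxel = which(keep),
    group = grp[keep],
    n_pixels = (p[-1] - p[-length(p)])[keep]
  )
}

#' Diagnose dominated voxel footprints
#'
#' A voxel whose footprint is contained in (or equal to) another voxel's
#' footprint scores an exact tie with it on its own noiseless projection
#' under the plain inner-product objective, so its reconstruction rests on
#' the tie-break. This reports every such voxel; [duplicate_footprints()]
#' lists the identical-footprint subset of these. Voxels outside this set
#' (and with non-empty footprints) are exactly identifiable from their own
#' noiseless fingerprint.
#'
#' @inheritParams forward_project
#' @return An integer vector of dominated voxel indices.
#' @export
dominated_footprints <- function(sm) {
  stopifnot(inherits(sm, "slnf_matrix"))
  S <- methods::as(Matrix::crossprod(sm$A), "CsparseMatrix")  # pairwise overlaps
  nnz <- Matrix::colSums(sm$A)
  p <- S@p; i <- S@i + 1L; x <- S@x
  dom <- logical(sm$n_voxels)
  for (v in seq_len(sm$n_voxels)) {
    if (nnz[v] == 0) next
    idx <- seq.int(p[v] + 1L, length.out = p[v + 1L] - p[v])
    others <- i[idx] != v
    if (any(x[idx][others] == nnz[v])) dom[v] <- TRUE
  }
  which(dom)
}

#' Cache a system matrix on disk, and load it back
#'
#' The cache is text-only and versioned: a MatrixMarket file (`<stem>.mtx`)
#' holding the sparse pattern, next to a JSON sidecar (`<stem>.json`) with the
#' format version, dimensions and the geometry hash. `read_system_matrix()`
#' refuses a cache whose geometry hash does not match the supplied geometry.
#'
#' @inheritParams forward_project
#' @param stem Path stem (without extension) for the two cache files.
#' @param geometry The `slnf_geometry` the cache must correspond to.
#' @return `write_system_matrix()` returns `stem` invisibly;
#'   `read_system_matrix()` returns an `slnf_matrix`.
#' @export
write_system_matrix <- function(sm, stem) {
  stopifnot(inherits(sm, "slnf_matrix"))
  Matrix::writeMM(methods::as(sm$A, "nMatrix"), paste0(stem, ".mtx"))
  jsonlite::write_json(
    list(format = "slnf-matrix-cache", version = 1L,
         n_pixels = sm$n_pixels, n_voxels = sm$n_voxels,
         geometry_hash = sm$geometry_hash),
    paste0(stem, ".json"), auto_unbox = TRUE)
  invisible(stem)
}

#' @rdname write_system_matrix
#' @export
read_system_matrix <- function(stem, geometry) {
  meta <- jsonlite::read_json(paste0(stem, ".json"))
  if (!identical(meta$format, "slnf-matrix-cache")) {
    stop("not a system-matrix cache: ", stem, call. = FALSE)
  }
  h <- geometry_hash(geometry)
  if (!identical(meta$geometry_hash, h)) {
    stop("cache geometry hash mismatch; rebuild with build_system_matrix()",
         call. = FALSE)
  }
  A <- methods::as(methods::as(Matrix::readMM(paste0(stem, ".mtx")), "CsparseMatrix"),
                   "dMatrix")
  A@x[] <- 1
  structure(
    list(A = A, n_pixels = meta$n_pixels, n_voxels = meta$n_voxels,
         geometry_hash = h, geometry = geometry),
    class = "slnf_matrix"
  )
}
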