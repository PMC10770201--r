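# Independent reference implementations ("oracles") used to cross-validate
# the package's vectorized algorithms. These deliberately share no code with
# the implementation paths: scalar arithmetic, nested loops and explicit
# matrix algebra only. They are exported so fixture bundles and the test
# suite can regenerate expected outputs from them.

#' Reference single-ray projection (scalar)
#'
#' Closed-form similar-triangles intersection of the line from one source
#' point through one pinhole center with the detector plane, mapped to a
#' pixel via explicit boundary search. Independent of [trace_ray()].
#'
#' @param source Length-3 numeric (x, y, z) in mm, z > 0.
#' @param pinhole A list/row with `x_mm`, `y_mm`, `fov_half_angle_deg`.
#' @param detector A [detector_spec()].
#' @return A single 1-based pixel index, or `NA` for a miss.
#' @keywords internal
#' @export
oracle_trace_ray <- function(source, pinhole, detector) {
  sx <- source[[1]]; sy <- source[[2]]; sz <- source[[3]]
  hx <- pinhole$x_mm; hy <- pinhole$y_mm
  # ray direction source -> pinhole; angle to the inward plate normal (0,0,-1)
  dx <- hx - sx; dy <- hy - sy; dz <- -sz
  cosang <- -dz / sqrt(dx^2 + dy^2 + dz^2)
  if (acos(cosang) > pinhole$fov_half_angle_deg * pi / 180) return(NA_integer_)
  # P(t) = S + t (H - S); solve P_z(t) = -plane_offset
  t <- (sz + detector$plane_offset) / sz
  xd <- sx + t * dx
  yd <- sy + t * dy
  xb <- seq(-detector$n_cols / 2, detector$n_cols / 2) * detector$pixel_pitch
  yb <- seq(-detector$n_rows / 2, detector$n_rows / 2) * detector$pixel_pitch
  col <- findInterval(xd, xb)
  # rows count downward from the top edge; flip the axis before the search
  row <- findInterval(-yd, yb)
  if (col < 1 || col > detector$n_cols || row < 1 || row > detector$n_rows) {
    return(NA_integer_)
  }
  as.integer((row - 1L) * detector$n_cols + col)
}

#' Reference voxel-center enumeration (nested loops)
#'
#' Enumerates all voxel centers of a grid by three nested loops in x-fastest
#' order. Independent of [voxel_center()].
#'
#' @param grid A [volume_grid()].
#' @return A matrix with columns x, y, z; row i is linear voxel i.
#' @keywords internal
#' @export
oracle_enumerate_centers <- function(grid) {
  s <- grid$spacing
  out <- matrix(NA_real_, nrow = grid$n_x * grid$n_y * grid$n_z, ncol = 3L)
  i <- 0L
  for (kz in seq_len(grid$n_z)) {
    for (ky in seq_len(grid$n_y)) {
      for (kx in seq_len(grid$n_x)) {
        i <- i + 1L
        out[i, ] <- c((kx - 1 - (grid$n_x - 1) / 2) * s,
                      (ky - 1 - (grid$n_y - 1) / 2) * s,
                      kz * s)
      }
    }
  }
  colnames(out) <- c("x", "y", "z")
  out
}

#' Reference system-matrix footprints (per-ray loop)
#'
#' Builds the pixel footprint of every voxel by looping over voxels and
#' pinholes with [oracle_trace_ray()]. Independent of
#' [build_system_matrix()].
#'
#' @param geometry An `slnf_geometry`.
#' @return A list of sorted unique pixel-index vectors, one per voxel.
#' @keywords internal
#' @export
oracle_footprints <- function(geometry) {
  centers <- oracle_enumerate_centers(geometry$grid)
  pin <- geometry$collimator$pinholes
  out <- vector("list", nrow(centers))
  for (v in seq_len(nrow(centers))) {
    hits <- integer(0)
    for (k in seq_len(nrow(pin))) {
      h <- oracle_trace_ray(centers[v, ], pin[k, ], geometry$detector)
      if (!is.na(h)) hits <- c(hits, h)
    }
    out[[v]] <- sort(unique(hits))
  }
  out
}

#' Reference correlation (elementwise loop)
#'
#' @param a,b Equal-length numeric vectors.
#' @return Their elementwise-product sum.
#' @keywords internal
#' @export
oracle_correlation <- function(a, b) {
  s <- 0
  for (i in seq_along(a)) s <- s + a[i] * b[i]
  s
}

#' Reference exhaustive argmax round of the greedy localization
#'
#' Scans every voxel footprint, summing the observed counts it covers, and
#' returns the best voxel (lowest index on ties) with its score. Independent
#' of [slnf_reconstruct()].
#'
#' @param d_obs Vectorized observed image.
#' @param footprints List of pixel-index vectors (e.g. from
#'   [oracle_footprints()]).
#' @return A list with `voxel`, `score`, `n_ties`.
#' @keywords internal
#' @export
oracle_argmax_round <- function(d_obs, footprints) {
  scores <- vapply(footprints,
                   function(fp) if (length(fp)) sum(d_obs[fp]) else 0,
                   numeric(1))
  best <- max(scores)
  ties <- which(scores == best)
  list(voxel = ties[1L], score = best, n_ties = length(ties))
}

#' Reference greedy localization (exhaustive scan + masking)
#'
#' Repeats [oracle_argmax_round()] `n_sources` times, zeroing the selected
#' footprint's pixels after each round.
#'
#' @inheritParams oracle_argmax_round
#' @param n_sources Number of rounds.
#' @return A list of per-round results as in [oracle_argmax_round()].
#' @keywords internal
#' @export
oracle_greedy <- function(d_obs, footprints, n_sources) {
  d <- as.numeric(d_obs)
  out <- vector("list", n_sources)
  for (r in seq_len(n_sources)) {
    out[[r]] <- oracle_argmax_round(d, footprints)
    fp <- footprints[[out[[r]]$voxel]]
    if (length(fp)) d[fp] <- 0
  }
  out
}

#' Reference assessability score (explicit rank-1 trace)
#'
#' Forms the full matrix `d (d'd)^-2 d'` and takes its trace. Independent of
#' the closed form in [assessability()]; only usable for short vectors.
#'
#' @param d Numeric vector with at least one nonzero entry.
#' @return The explicit trace.
#' @keywords internal
#' @export
oracle_assessability <- function(d) {
  d <- matrix(as.numeric(d), ncol = 1L)
  g <- as.numeric(t(d) %*% d)
  if (g == 0) stop("all-zero fingerprint", call. = FALSE)
  m <- d %*% solve(matrix(g)) %*% solve(matrix(g)) %*% t(d)
  sum(diag(m))
}
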