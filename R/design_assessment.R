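#' Assessability score of a detector fingerprint
#'
#' The A-optimal-design statistic of a candidate point-source position with
#' detector fingerprint `d` (a column of the system matrix):
#' `V(d) = trace(d (d'd)^-2 d')`, which for any vector reduces in closed form
#' to `1 / (d'd)` and, for a binary fingerprint, to the reciprocal of the
#' number of illuminated pixels. A higher score means fewer informative
#' pixels and therefore a harder position to localize.
#'
#' The closed form is used here; the explicit rank-1 trace is kept as an
#' independent reference in [oracle_assessability()].
#'
#' @param d Numeric vector with at least one nonzero entry (the fingerprint).
#' @return The scalar score `1 / (d'd)`.
#' @examples
#' assessability(c(0, 1, 0, 1, 1))  # 1/3
#' @export
assessability <- function(d) {
  ss <- sum(d * d)
  if (ss == 0) {
    stop("all-zero fingerprint: position invisible to the detector",
         call. = FALSE)
  }
  1 / ss
}

#' Rank candidate positions by localization difficulty
#'
#' Computes the assessability score of each candidate source position
#' (snapped to its nearest grid voxel) and ranks positions from hardest
#' (highest score, rank 1) to easiest. Positions whose fingerprints are empty
#' are flagged `invisible` and carry `NA` scores instead of being dropped.
#'
#' @param positions A source tibble (see [source_set()]); `activity_mbq` is
#'   ignored and may be omitted (defaults to 0).
#' @param sm An `slnf_matrix` from [build_system_matrix()].
#' @return A tibble with columns `id`, `x_mm`, `y_mm`, `z_mm`, `voxel`,
#'   `n_pixels` (footprint size), `score`, `invisible`, `rank` (descending
#'   score; ties share the minimum rank).
#' @export
rank_positions <- function(positions, sm) {
  stopifnot(inherits(sm, "slnf_matrix"))
  positions <- tibble::as_tibble(positions)
  if (is.null(positions[["activity_mbq"]])) positions$activity_mbq <- 0
  positions <- source_set(positions)
  vox <- nearest_voxel(sm$geometry$grid,
                       as.matrix(positions[, c("x_mm", "y_mm", "z_mm")]))
  nnz <- vapply(vox, function(v) length(column_footprint(sm, v)), integer(1))
  score <- ifelse(nnz > 0, 1 / nnz, NA_real_)
  out <- tibble::tibble(
    id = positions$id,
    x_mm = positions$x_mm, y_mm = positions$y_mm, z_mm = positions$z_mm,
    voxel = vox, n_pixels = nnz, score = score,
    invisible = nnz == 0L
  )
  out$rank <- rank(-out$score, ties.method = "min", na.last = "keep")
  dplyr::arrange(out, .data$rank)
}

#' Plot an assessability ranking
#'
#' @param object A tibble from [rank_positions()].
#' @param ... Unused.
#' @return A ggplot bar chart of scores by position.
#' @export
plot_assessability <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = factor(.data$id), y = .data$score)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "position index", y = "assessability score",
                  title = "Higher score = harder to localize") +
    ggplot2::theme_minimal()
}
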