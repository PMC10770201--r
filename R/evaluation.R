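#' Euclidean localization error
#'
#' The l2 distance in mm between an estimated and a true source position.
#'
#' @param estimate,truth Numeric length-3 vectors or matrices with columns
#'   x, y, z (mm).
#' @return Numeric vector of distances in mm.
#' @examples
#' l2_error(c(22, 78, 157), c(22, 76, 157))  # 2
#' @export
l2_error <- function(estimate, truth) {
  if (is.null(dim(estimate))) estimate <- matrix(estimate, ncol = 3L)
  if (is.null(dim(truth))) truth <- matrix(truth, ncol = 3L)
  sqrt(rowSums((estimate - truth)^2))
}

#' Pair reconstructed sources with ground truth
#'
#' One-to-one assignment of estimates to truths minimizing the total l2
#' error, found by exhaustive enumeration of permutations (exact; intended
#' for the small source counts of this problem, guarded at n <= 8).
#'
#' @param estimates,truths Numeric matrices with columns x, y, z (mm) and an
#'   equal number of rows.
#' @return A tibble with columns `estimate` (row in `estimates`), `truth`
#'   (assigned row in `truths`) and `error_mm`.
#' @export
match_sources <- function(estimates, truths) {
  if (is.null(dim(estimates))) estimates <- matrix(estimates, ncol = 3L)
  if (is.null(dim(truths))) truths <- matrix(truths, ncol = 3L)
  n <- nrow(estimates)
  if (n != nrow(truths)) {
    stop("estimates and truths must have equal length", call. = FALSE)
  }
  if (n > 8L) stop("exhaustive matching supports at most 8 sources", call. = FALSE)
  cost <- outer(seq_len(n), seq_len(n),
                Vectorize(function(i, j) l2_error(estimates[i, ], truths[j, ])))
  perms <- permutations(n)
  totals <- vapply(perms, function(p) sum(cost[cbind(seq_len(n), p)]), numeric(1))
  best <- perms[[which.min(totals)]]
  tibble::tibble(estimate = seq_len(n), truth = best,
                 error_mm = cost[cbind(seq_len(n), best)])
}

# all permutations of 1..n as a list
permutations <- function(n) {
  if (n == 1L) return(list(1L))
  do.call(c, lapply(seq_len(n), function(k) {
    lapply(permutations(n - 1L), function(p) {
      c(k, ifelse(p >= k, p + 1L, p))
    })
  }))
}

#' Median and third quartile of an error sequence
#'
#' Both statistics use linear interpolation of order statistics at rank
#' `p * (n - 1) + 1` (the default quantile convention, type 7).
#'
#' @param errors Non-empty numeric vector of errors (mm).
#' @return Named numeric vector `c(median = ..., q3 = ...)`.
#' @examples
#' median_q3(c(1, 2, 3, 4, 5))  # median 3, q3 4
#' @export
median_q3 <- function(errors) {
  if (!length(errors)) stop("empty error sequence", call. = FALSE)
  q <- stats::quantile(errors, c(0.5, 0.75), type = 7, names = FALSE)
  c(median = q[1], q3 = q[2])
}

#' Run a repeated-acquisition localization experiment
#'
#' The in-silico analogue of the bench protocol: for each configuration
#' (a set of simultaneous sources), simulate `n_repeats` detector images,
#' reconstruct each with the source count known, pair estimates to ground
#' truth by minimum-total-error assignment, and summarize the per-repeat l2
#' errors per source position by median and third quartile.
#'
#' Scenarios follow the bench experiments: `"single_source"` (one vial per
#' run), `"two_sources"` (two simultaneous vials) and `"two_sources_hot_bg"`
#' (two vials plus a uniform hot background volume, which must be supplied in
#' the acquisition config).
#'
#' @param configurations A list of source tibbles (see [source_set()]), one
#'   per run; each must contain the number of sources its scenario implies.
#' @param sm An `slnf_matrix`.
#' @param cfg An [acquisition_config()]; defaults follow the bench protocol
#'   (10 repeats of 8 s exposure).
#' @param scenario One of `"single_source"`, `"two_sources"`,
#'   `"two_sources_hot_bg"`.
#' @return A tibble with one row per (run, source): run index, source id,
#'   true (snapped) position, `errors_mm` (list column of per-repeat errors),
#'   `median_mm`, `q3_mm`, and `snap_mm` (ground-truth quantization floor).
#' @export
run_experiment <- function(configurations, sm, cfg = acquisition_config(),
                           scenario = c("single_source", "two_sources",
                                        "two_sources_hot_bg")) {
  scenario <- match.arg(scenario)
  stopifnot(inherits(sm, "slnf_matrix"), is.list(configurations))
  n_expected <- if (scenario == "single_source") 1L else 2L
  if (scenario == "two_sources_hot_bg" && is.null(cfg$hot_background)) {
    stop("scenario 'two_sources_hot_bg' needs cfg$hot_background", call. = FALSE)
  }
  out <- vector("list", length(configurations))
  for (ci in seq_along(configurations)) {
    sources <- source_set(configurations[[ci]])
    if (nrow(sources) != n_expected) {
      stop(sprintf("run %d has %d sources; scenario '%s' expects %d",
                   ci, nrow(sources), scenario, n_expected), call. = FALSE)
    }
    run_cfg <- cfg
    run_cfg$seed <- cfg$seed + ci - 1L  # independent repeats per run
    stack <- simulate_acquisition(sources, sm, run_cfg)
    truth_xyz <- as.matrix(stack$truth[, c("x_snap", "y_snap", "z_snap")])
    errs <- matrix(NA_real_, nrow = cfg$n_repeats, ncol = n_expected)
    for (r in seq_len(cfg$n_repeats)) {
      rec <- slnf_reconstruct(stack$images[[r]], sm, n_sources = n_expected)
      est <- voxel_to_position(rec)
      m <- match_sources(est, truth_xyz)
      errs[r, m$truth] <- m$error_mm
    }
    out[[ci]] <- dplyr::bind_rows(lapply(seq_len(n_expected), function(s) {
      mq <- median_q3(errs[, s])
      tibble::tibble(
        run = ci, id = stack$truth$id[s],
        x_mm = truth_xyz[s, 1], y_mm = truth_xyz[s, 2], z_mm = truth_xyz[s, 3],
        errors_mm = list(errs[, s]),
        median_mm = mq[["median"]], q3_mm = mq[["q3"]],
        snap_mm = stack$truth$snap_mm[s]
      )
    }))
  }
  dplyr::bind_rows(out)
}

#' Plot an experiment error summary
#'
#' @param object A tibble from [run_experiment()].
#' @param ... Unused.
#' @return A ggplot of per-position medians with Q3 whiskers.
#' @export
plot_error_summary <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = factor(.data$id))) +
    ggplot2::geom_col(ggplot2::aes(y = .data$median_mm), fill = "grey40") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$median_mm,
                                        ymax = .data$q3_mm),
                           width = 0.25, color = "firebrick") +
    ggplot2::labs(x = "position index", y = "localization error (mm)",
                  title = "Median (bar) and Q3 (whisker) per position") +
    ggplot2::theme_minimal()
}

#' Footprint overlap between two candidate positions
#'
#' Number of detector pixels shared by the fingerprints of two positions
#' (snapped to grid voxels). Zero means the sources are non-overlapping on
#' the detector and the greedy masking cannot interfere.
#'
#' @param sm An `slnf_matrix`.
#' @param pos_a,pos_b Length-3 positions (mm).
#' @return Integer overlap count.
#' @export
footprint_overlap <- function(sm, pos_a, pos_b) {
  g <- sm$geometry$grid
  fa <- column_footprint(sm, nearest_voxel(g, pos_a))
  fb <- column_footprint(sm, nearest_voxel(g, pos_b))
  length(intersect(fa, fb))
}
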