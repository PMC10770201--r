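test_that("the correlation objective is the elementwise-product sum", {
  expect_equal(correlation(c(1, 0, 1), c(0, 0, 0)), 0)
  d_obs <- c(1, 0, 1, 1, 0)
  expect_equal(correlation(as.numeric(d_obs > 0), d_obs), 3)  # footprint size
  set.seed(10)
  for (i in 1:20) {
    a <- stats::rpois(50, 2); b <- stats::rpois(50, 2)
    expect_equal(correlation(a, b), oracle_correlation(a, b))
  }
  expect_error(correlation(1:3, 1:4), "equal length")
})

test_that("a noiseless fingerprint is recovered exactly with an empty residual", {
  sm <- tiny_matrix()
  v <- unique_footprint_voxels(sm)[100]
  d <- forward_project(sm, replace(numeric(sm$n_voxels), v, 5))
  rec <- slnf_reconstruct(d, sm, n_sources = 1)
  expect_equal(rec$sources$voxel, v)
  expect_equal(sum(rec$residual), 0)
  expect_false(rec$degenerate)
})

test_that("two disjoint sources are extracted strongest-first", {
  sm <- tiny_matrix()
  uv <- unique_footprint_voxels(sm)
  # find a disjoint pair with equal footprint sizes
  set.seed(2)
  pair <- NULL
  for (i in 1:500) {
    ab <- sample(uv, 2)
    fa <- column_footprint(sm, ab[1]); fb <- column_footprint(sm, ab[2])
    if (length(fa) == length(fb) && !length(intersect(fa, fb))) { pair <- ab; break }
  }
  expect_false(is.null(pair))
  u <- numeric(sm$n_voxels)
  u[pair[1]] <- 5; u[pair[2]] <- 3
  rec <- slnf_reconstruct(forward_project(sm, u), sm, n_sources = 2)
  expect_equal(rec$sources$voxel, pair)        # stronger source first
  expect_true(all(diff(rec$sources$score) <= 0))
})

test_that("every extraction round equals the exhaustive reference scan", {
  sm <- tiny_matrix()
  fps <- slnf:::footprint_list(sm)
  set.seed(17)
  for (i in 1:5) {
    src <- fixture_phantom("tiny")[sample(9, 2), ]
    st <- simulate_acquisition(src, sm, acquisition_config(
      n_repeats = 1, counts_per_mbq_s = 0.05, seed = 100 + i))
    d <- image_to_vector(st$images[[1]])
    rec <- slnf_reconstruct(d, sm, n_sources = 2)
    ref <- oracle_greedy(d, fps, 2)
    for (r in 1:2) {
      expect_equal(rec$sources$voxel[r], ref[[r]]$voxel)
      expect_equal(rec$sources$score[r], ref[[r]]$score)
      expect_equal(rec$sources$n_ties[r], ref[[r]]$n_ties)
    }
  }
})

test_that("masking zeroes the extracted fingerprint's pixels completely", {
  sm <- tiny_matrix()
  v <- unique_footprint_voxels(sm)[50]
  d <- forward_project(sm, replace(numeric(sm$n_voxels), v, 4)) + 1  # flat offset
  rec <- slnf_reconstruct(d, sm, n_sources = 1)
  col_v <- forward_project(sm, replace(numeric(sm$n_voxels), rec$sources$voxel[1], 1))
  expect_equal(correlation(col_v, image_to_vector(rec$residual)), 0)
})

test_that("an all-zero image is flagged degenerate instead of silently resolved", {
  sm <- tiny_matrix()
  rec <- slnf_reconstruct(numeric(sm$n_pixels), sm, n_sources = 1)
  expect_true(rec$degenerate)
  expect_equal(rec$sources$voxel, 1L)  # deterministic lowest-index tie-break
  expect_equal(rec$sources$n_ties, sm$n_voxels)
  expect_error(slnf_reconstruct(numeric(sm$n_pixels), sm, n_sources = 0),
               "n_sources")
})

test_that("argmax ties break to the lowest voxel index and are counted", {
  sm <- tiny_matrix()
  dup <- duplicate_footprints(sm)
  grp <- dup[dup$n_pixels > 0, ]
  g1 <- grp$voxel[grp$group == grp$group[1]]  # >= 2 voxels, same fingerprint
  d <- forward_project(sm, replace(numeric(sm$n_voxels), g1[2], 3))
  rec <- slnf_reconstruct(d, sm, n_sources = 1)
  expect_equal(rec$sources$voxel, min(g1))
  expect_gte(rec$sources$n_ties, length(g1))
})

test_that("extracted voxels map back to grid coordinates", {
  sm <- tiny_matrix()
  v <- unique_footprint_voxels(sm)[7]
  rec <- slnf_reconstruct(
    forward_project(sm, replace(numeric(sm$n_voxels), v, 1)), sm, 1)
  pos <- voxel_to_position(rec)
  expect_equal(unname(pos), unname(voxel_center(sm$geometry$grid, v)))
  expect_equal(nearest_voxel(sm$geometry$grid, pos), v)
})

test_that("tidy, glance and autoplot expose the reconstruction", {
  sm <- tiny_matrix()
  v <- unique_footprint_voxels(sm)[1]
  rec <- slnf_reconstruct(
    forward_project(sm, replace(numeric(sm$n_voxels), v, 2)), sm, 1)
  td <- tidy(rec)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("rank", "voxel", "x_mm", "y_mm", "z_mm", "score", "n_ties"))
  gl <- glance(rec)
  expect_equal(gl$n_sources, 1L)
  expect_s3_class(autoplot(rec), "ggplot")
})

test_that("the optional stopping heuristic truncates weak extra rounds", {
  sm <- tiny_matrix()
  v <- unique_footprint_voxels(sm)[20]
  d <- forward_project(sm, replace(numeric(sm$n_voxels), v, 100))
  rec <- slnf_reconstruct(d, sm, n_sources = 3, stop_score_fraction = 0.5)
  expect_equal(nrow(rec$sources), 1L)  # nothing left after masking the source
})
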