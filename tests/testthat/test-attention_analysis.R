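test_that("attention thresholding counts and bounds behave", {
  m <- array(c(0, 0.2, 0.7, 0.9, rep(0, 4)), c(2, 2, 2))
  expect_equal(sum(threshold_attention(m, 0.5)), 2)
  expect_equal(sum(threshold_attention(m, 1.0)), 0)
  expect_equal(sum(threshold_attention(m, -1)), 8)
  # monotonicity: a higher threshold never adds voxels
  set.seed(1)
  a <- array(runif(6^3), c(6, 6, 6))
  counts <- vapply(seq(0, 1, 0.1), function(t) sum(threshold_attention(a, t)), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("blob analysis matches hand-built and flood-fill cases", {
  m <- array(FALSE, c(10, 10, 10))
  m[2:3, 2:3, 2:3] <- TRUE
  m[7:8, 7:8, 7:8] <- TRUE
  bs <- blob_analysis(m, 26)
  expect_equal(bs$n_blobs, 2)
  expect_equal(sort(bs$blob_volumes), c(8, 8))

  # cubes meeting only at a corner: one blob at 26-connectivity, two at 6
  corner <- array(FALSE, c(8, 8, 8))
  corner[2:3, 2:3, 2:3] <- TRUE
  corner[4:5, 4:5, 4:5] <- TRUE
  expect_equal(blob_analysis(corner, 26)$n_blobs, 1)
  expect_equal(blob_analysis(corner, 6)$n_blobs, 2)

  empty <- array(FALSE, c(4, 4, 4))
  expect_equal(blob_analysis(empty)$n_blobs, 0)
  expect_length(blob_analysis(empty)$blob_volumes, 0)

  set.seed(5)
  for (rep in 1:6) {
    dims <- sample(6:12, 3, replace = TRUE)
    mask <- array(runif(prod(dims)) < 0.25, dims)
    for (conn in c(6, 26)) {
      got <- blob_analysis(mask, conn)
      ora <- oracle_flood_fill(mask, conn)
      expect_equal(max(got$labels), max(ora))
      expect_equal(got$n_blobs, max(ora))
      # identical partitions: labels agree up to renumbering, and scan-order
      # numbering makes them agree exactly
      expect_identical(got$labels, ora)
      expect_equal(sort(got$blob_volumes), sort(tabulate(ora[ora > 0])))
    }
  }
})

test_that("texture quantization fills 32 levels and zeroes background", {
  d <- c(32, 8, 8)
  mask <- array(0L, d); mask[, 3:6, 3:6] <- 1L
  ramp <- array(rep(seq(0, 1, length.out = 32), 64), d)  # in-mask uniform ramp
  v <- new_volume(ramp, mask = mask)
  q <- quantize_for_texture(v)
  expect_setequal(unique(q[mask > 0]), 1:32)
  expect_true(all(q[mask == 0] == 0))
  # value at the high percentile maps to the top level
  qs <- quantile(ramp[mask > 0], 0.99, names = FALSE)
  at <- which(abs(ramp - qs) < 1e-9 & mask > 0)
  if (length(at)) expect_true(all(q[at] == 32))
  expect_warning(qc <- quantize_for_texture(new_volume(array(1, c(3, 3, 3)),
                                                       mask = array(1L, c(3, 3, 3)))),
                 "constant")
  expect_true(all(qc == 1))
})

test_that("Haralick features of degenerate patches are exact", {
  q <- array(7L, c(4, 4, 4))
  f <- haralick_patch(q, n_levels = 32)
  expect_equal(unname(f["angular_second_moment"]), 1)
  expect_equal(unname(f["contrast"]), 0)
  expect_equal(unname(f["entropy"]), 0)
  expect_equal(unname(f["inverse_difference_moment"]), 1)
  expect_equal(unname(f["correlation"]), 0)  # zero-variance convention
  # a patch with a single nonzero voxel has no valid pair in any direction
  q2 <- array(0L, c(3, 3, 3)); q2[2, 2, 2] <- 5L
  expect_null(haralick_patch(q2, 32))
})

test_that("checkerboard contrast along one axis is the squared level step", {
  g <- expand.grid(z = 1:6, y = 1:6, x = 1:6)
  q <- array(ifelse(g$x %% 2 == 0, 9L, 4L), c(6, 6, 6))  # levels 4 and 9
  P <- bovw3d:::glcm_3d(q, c(0, 0, 1), 32)  # pure x direction
  expect_equal(sum(P), 1)
  f <- bovw3d:::haralick_features_from_glcm(P)
  expect_equal(unname(f["contrast"]), (9 - 4)^2)
  # along z the pattern is constant: contrast 0 in that direction
  Pz <- bovw3d:::glcm_3d(q, c(1, 0, 0), 32)
  expect_equal(unname(bovw3d:::haralick_features_from_glcm(Pz)["contrast"]), 0)
})

test_that("Haralick features match the brute-force pair-counting oracle", {
  set.seed(17)
  for (rep in 1:8) {
    q <- array(sample(0:6, 5^3, replace = TRUE, prob = c(0.3, rep(0.1, 6))),
               c(5, 5, 5))
    got <- haralick_patch(q, n_levels = 8)
    ora <- oracle_haralick(q, n_levels = 8)
    if (is.null(ora)) {
      expect_null(got)
    } else {
      expect_equal(as.vector(got), as.vector(ora), tolerance = 1e-8)
      expect_equal(names(got), names(ora))
    }
  }
})

test_that("a level-0 shell leaves Haralick features unchanged", {
  set.seed(19)
  q <- array(sample(1:8, 4^3, replace = TRUE), c(4, 4, 4))
  shell <- array(0L, c(8, 8, 8))
  shell[3:6, 3:6, 3:6] <- q
  expect_equal(haralick_patch(q, 8), haralick_patch(shell, 8),
               ignore_attr = TRUE)
})

test_that("per-direction GLCMs are normalized", {
  set.seed(23)
  q <- array(sample(0:4, 6^3, replace = TRUE), c(6, 6, 6))
  for (r in seq_len(nrow(bovw3d:::haralick_offsets()))) {
    P <- bovw3d:::glcm_3d(q, bovw3d:::haralick_offsets()[r, ], 8)
    if (!is.null(P)) expect_equal(sum(P), 1, tolerance = 1e-12)
  }
})

test_that("texture pooling averages per image and builds KDEs", {
  f1 <- c(angular_second_moment = 0.5, contrast = 2)
  df <- data.frame(image_id = c("a", "a", "b"), condition = c("A", "A", "B"),
                   angular_second_moment = c(0.4, 0.6, 0.9),
                   contrast = c(1, 3, 7), stringsAsFactors = FALSE)
  pt <- pool_texture(df)
  expect_equal(pt$per_image$angular_second_moment[pt$per_image$image_id == "a"], 0.5)
  expect_equal(pt$per_image$contrast[pt$per_image$image_id == "a"], 2)
  # single-patch image: the mean is the patch itself
  expect_equal(pt$per_image$contrast[pt$per_image$image_id == "b"], 7)
  # centered pair averages to zero
  df2 <- data.frame(image_id = "c", condition = "A",
                    angular_second_moment = c(0.2, -0.2), contrast = c(5, -5))
  expect_equal(unlist(pool_texture(df2)$per_image[, c("angular_second_moment", "contrast")]),
               c(angular_second_moment = 0, contrast = 0))
  # KDE table covers condition A's features (B has a single point, skipped)
  expect_true(all(c("condition", "feature", "x", "density") %in% names(pt$kde)))
  expect_true(all(pt$kde$condition == "A"))
})
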