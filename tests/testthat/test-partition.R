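# Region partitioning: binning, labeling, exclusion, classification.

test_that("partition_phase bins the principal interval into six disjoint pieces", {
  ph <- array(c(0.5, pi, -pi + 1e-6, -0.01, 2.2, 1.3, -1.3, -2.5), c(2, 2, 2))
  v <- wrapped_volume(ph)
  bins <- partition_phase(v)
  bin <- attr(bins, "bin")
  expect_equal(bin[1, 1, 1], 4L)  # 0.5 in (0, pi/3]
  expect_equal(bin[2, 1, 1], 6L)  # pi closes the last bin
  expect_equal(bin[1, 2, 1], 1L)
  expect_equal(bin[2, 2, 1], 3L)  # -0.01 in (-pi/3, 0]
  # boundary values land in the lower bin (upper-closed intervals)
  b2 <- attr(partition_phase(array(c(-pi / 3, 0, pi / 3, 2 * pi / 3,
                                     -2 * pi / 3, pi, 0.1, 0.1),
                                   c(2, 2, 2))), "bin")
  expect_equal(as.integer(b2)[1:6], c(2L, 3L, 4L, 5L, 1L, 6L))
  # partition property on a random volume
  set.seed(21)
  ph <- array(runif(17 * 13 * 9, -pi, pi), c(17, 13, 9)); ph[ph <= -pi] <- pi
  masks <- partition_phase(wrapped_volume(ph))
  tot <- Reduce(`+`, lapply(masks, function(m) m * 1L))
  expect_true(all(tot == 1L))
  expect_error(partition_phase(wrapped_volume(ph, mask = array(FALSE, dim(ph)))),
               "ROI|mask")
})

test_that("label_components agrees with a flood-fill oracle on sparse masks", {
  set.seed(22)
  for (conn in c(26, 6)) {
    mask <- array(FALSE, c(9, 9, 9))
    mask[sample(9^3, 50)] <- TRUE
    got <- label_components(mask, conn)
    want <- oracle_label(mask, conn)
    expect_true(same_partitioning(got, want))
  }
})

test_that("label_components honors corner adjacency under 26 but not 6", {
  mask <- array(FALSE, c(6, 6, 6))
  mask[1:2, 1:2, 1:2] <- TRUE
  mask[3:4, 3:4, 3:4] <- TRUE  # touches the first cube only at a corner
  expect_equal(attr(label_components(mask, 26), "n_components"), 1L)
  expect_equal(attr(label_components(mask, 6), "n_components"), 2L)
  mask2 <- array(FALSE, c(7, 7, 7))
  mask2[1:2, 1:2, 1:2] <- TRUE
  mask2[4:5, 4:5, 4:5] <- TRUE  # one-voxel gap in every axis
  expect_equal(attr(label_components(mask2, 26), "n_components"), 2L)
  full <- array(TRUE, c(4, 5, 6))
  expect_equal(attr(label_components(full, 26), "n_components"), 1L)
  expect_equal(attr(label_components(array(FALSE, c(3, 3, 3)), 26),
                    "n_components"), 0L)
})

test_that("exclude_noisy_voxels removes isolated and bridge voxels, keeps interiors", {
  # single isolated voxel: edge + out-of-region on all three axes
  m <- array(FALSE, c(9, 9, 9)); m[5, 5, 5] <- TRUE
  ex <- exclude_noisy_voxels(m)
  expect_true(ex$excluded[5, 5, 5])
  expect_false(any(ex$cleaned))
  # interior voxel of a solid cube at >= 4 voxels from every face: retained
  cube <- array(FALSE, c(12, 12, 12)); cube[2:11, 2:11, 2:11] <- TRUE
  ex <- exclude_noisy_voxels(cube)
  expect_true(all(ex$cleaned[5:8, 5:8, 5:8]))
  # excluded voxels are always on the region edge (6-neighbor exposure)
  inner <- array(FALSE, dim(cube))
  inner[3:10, 3:10, 3:10] <- cube[3:10, 3:10, 3:10]
  is_edge <- cube & !inner
  expect_true(all(is_edge[ex$excluded]))
  # two cubes joined by a thin bridge: bridge excised, two components remain
  bb <- array(FALSE, c(20, 9, 9))
  bb[2:8, 2:8, 2:8] <- TRUE
  bb[13:19, 2:8, 2:8] <- TRUE
  bb[9:12, 5, 5] <- TRUE
  ex <- exclude_noisy_voxels(bb)
  expect_true(all(ex$excluded[9:12, 5, 5]))
  lab <- label_components(ex$cleaned, 26)
  expect_equal(attr(lab, "n_components"), 2L)
})

test_that("classify_regions applies the strict size threshold", {
  lab <- array(0L, c(30, 12, 10))
  lab[1:10, 1:10, 1] <- 1L  # exactly 100 voxels -> block (threshold strict)
  lab[1:9, 1:11, 3] <- 2L   # 99 voxels -> second residual
  p <- classify_regions(lab, size_threshold = 100)
  expect_equal(length(p$blocks), 1L)
  expect_equal(p$blocks[[1]]$size, 100)
  expect_equal(length(p$second_residual), 99L)
  expect_error(classify_regions(array(0L, c(4, 4, 4)), 100), "region")
})

test_that("build_partition satisfies completeness and no-hidden-wrap invariants", {
  params <- unwrap_params(size_threshold = 50)
  # constant-phase cube: one block (minus excluded border shell), no second
  ph <- array(0.1, c(20, 20, 20))
  p <- build_partition(wrapped_volume(ph), params)
  expect_equal(length(p$blocks), 1L)
  expect_equal(length(p$second_residual), 0L)
  expect_equal(length(p$blocks[[1]]$voxels) + length(p$first_residual),
               20^3)
  # excluded shell is exactly the voxels within reach 3 of >= 2 borders
  # smooth bump, with noise, random fields: completeness and wrap-freeness
  set.seed(23)
  fixtures <- list(
    wrap_to_principal(bump_truth(c(24, 24, 24), peak = 9, sd = 6)),
    array(runif(15^3, -pi, pi), c(15, 15, 15)),
    wrap_to_principal(ramp_truth(0.7, c(18, 12, 10))))
  for (ph in fixtures) {
    ph[ph <= -pi] <- pi
    p <- build_partition(wrapped_volume(ph), params, strict = FALSE)
    nb <- sum(vapply(p$blocks, function(b) b$size, numeric(1)))
    expect_equal(nb + length(p$first_residual) + length(p$second_residual),
                 length(ph))
    # disjointness
    all_idx <- c(unlist(lapply(p$blocks, function(b) b$voxels)),
                 p$first_residual, p$second_residual)
    expect_equal(anyDuplicated(all_idx), 0L)
    # no hidden wraps: raw span within a block stays below one bin width
    for (b in p$blocks)
      expect_lt(max(ph[b$voxels]) - min(ph[b$voxels]), 2 * pi / 3)
  }
  # determinism
  p1 <- build_partition(wrapped_volume(fixtures[[1]]), params)
  p2 <- build_partition(wrapped_volume(fixtures[[1]]), params)
  expect_identical(p1$labels, p2$labels)
  expect_identical(p1$first_residual, p2$first_residual)
})

test_that("a hidden-wrap phantom is split by noisy-voxel exclusion", {
  # two smooth areas differing by > 2*pi joined by a thin noisy bridge;
  # the bins put both areas in the same subinterval, the bridge voxels are
  # the only connectors, and exclusion must sever them
  shape <- c(24, 11, 11)
  truth <- array(0, shape)
  truth[1:10, , ] <- 0.15
  truth[15:24, , ] <- 0.15 + 2 * pi  # same principal value, one wrap apart
  ph <- wrap_to_principal(truth)
  ph[11:14, , ] <- 1.5               # bridge zone in another bin
  ph[11:14, 6, 6] <- 0.15            # thin connector in the areas' bin
  p <- build_partition(wrapped_volume(ph), unwrap_params(size_threshold = 50))
  # connector voxels land in first_residual
  bridge_idx <- 11:14 + 24 * 5 + 24 * 11 * 5
  expect_true(all(ph[bridge_idx] == 0.15))
  expect_true(all(bridge_idx %in% p$first_residual))
  # and the two areas are distinct blocks
  blocks_bin4 <- Filter(function(b) b$bin == 4, p$blocks)
  expect_gte(length(blocks_bin4), 2L)
})
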