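# The unwrapping engine: quality map, seeding, block merging, residual
# growing, and the composed pipeline.

test_that("quality map scores constant, outlier and ramp fields correctly", {
  const <- wrapped_volume(array(0.7, c(6, 6, 6)))
  q <- compute_quality_map(const)
  expect_true(all(q$quality == 0))
  # single outlier is the strict local maximum of the score
  ph <- array(0, c(7, 7, 7)); ph[4, 4, 4] <- pi / 2
  q2 <- compute_quality_map(wrapped_volume(ph))$quality
  outlier <- which.max(q2)
  expect_equal(outlier, 4L + 7L * 3L + 49L * 3L)
  expect_gt(q2[outlier], max(q2[-outlier]))
  # linear ramp a*x: interior score computed by hand from the 26 diffs
  a <- 0.4
  ramp <- wrap_to_principal(ramp_truth(a, c(5, 5, 5)))
  q3 <- compute_quality_map(wrapped_volume(ramp))$quality
  # interior voxel: 18 neighbors differ in x by +-1 (diff a), 8 by 0
  expect_equal(q3[3, 3, 3], sqrt(18 * a^2 / 26), tolerance = 1e-12)
})

test_that("seed_state picks the largest block with deterministic ties", {
  ph <- array(0.1, c(12, 12, 4))
  lab <- array(0L, dim(ph))
  lab[1:5, 1:10, 1] <- 1L   # 50
  lab[1:10, 1:10, 2] <- 2L  # 100
  lab[1:8, 1:10, 3] <- 3L   # 80
  p <- classify_regions(lab, size_threshold = 10)
  st <- seed_state(p, wrapped_volume(ph))
  expect_equal(attr(st, "seed_block"), 2L)
  expect_true(all(st$done[p$blocks[[2]]$voxels]))
  expect_equal(sum(st$done), 100)
  expect_equal(st$unwrapped[p$blocks[[2]]$voxels],
               ph[p$blocks[[2]]$voxels])
  # tie on size -> smaller id
  lab2 <- array(0L, dim(ph))
  lab2[1:5, 1:10, 1] <- 1L
  lab2[1:5, 1:10, 3] <- 2L
  p2 <- classify_regions(lab2, size_threshold = 10)
  st2 <- seed_state(p2, wrapped_volume(ph))
  expect_equal(attr(st2, "seed_block"), 1L)
})

test_that("nearest_block ranks blocks by closest-voxel distance with ties", {
  ph <- array(0.1, c(40, 7, 7))
  lab <- array(0L, dim(ph))
  lab[1:10, , ] <- 1L    # seed (largest)
  lab[13:14, , ] <- 2L   # gap 2
  lab[20:22, , ] <- 3L   # gap 5 from block 2
  p <- classify_regions(lab, size_threshold = 10)
  st <- seed_state(p, wrapped_volume(ph))
  expect_equal(as.integer(nearest_block(st, p)), 2L)
  # adjacent block always beats a gapped one
  lab[11:12, , ] <- 4L
  p2 <- classify_regions(lab, size_threshold = 10)
  st2 <- seed_state(p2, wrapped_volume(ph))
  nb <- nearest_block(st2, p2)
  expect_equal(p2$blocks[[as.integer(nb)]]$voxels[1],
               which(lab == 4L)[1])
  expect_equal(sqrt(attr(nb, "dist2")), 1)
  # three-block chain: merge order matches hand-computed distances
  st2$done[p2$blocks[[as.integer(nb)]]$voxels] <- TRUE
  nb2 <- nearest_block(st2, p2)  # now block at gap 1 from newly done set
  expect_equal(sqrt(attr(nb2, "dist2")), 1)
})

test_that("select_fitting_voxels matches a brute-force nearest-pair oracle", {
  ph <- array(0.1, c(16, 8, 8))
  lab <- array(0L, dim(ph))
  lab[1:8, , ] <- 1L
  lab[9:16, , ] <- 2L
  p <- classify_regions(lab, size_threshold = 10)
  st <- seed_state(p, wrapped_volume(ph))  # block 1 seeds (512 voxels each; tie -> 1)
  blk <- p$blocks[[2]]$voxels
  sets <- select_fitting_voxels(st, blk, fitting_count = 40)
  expect_length(sets$fit_set, 40)
  expect_length(sets$target_set, 40)
  # oracle: all-pairs distances
  co_done <- index_to_coord_test(which(st$done), dim(ph))
  co_blk <- index_to_coord_test(blk, dim(ph))
  dmat_done <- apply(co_done, 1, function(r)
    min(sqrt(colSums((t(co_blk) - r)^2))))
  want_fit <- which(st$done)[order(dmat_done, which(st$done))[1:40]]
  expect_setequal(sets$fit_set, want_fit)
  dmat_blk <- apply(co_blk, 1, function(r)
    min(sqrt(colSums((t(co_done) - r)^2))))
  want_tgt <- blk[order(dmat_blk, blk)[1:40]]
  expect_setequal(sets$target_set, want_tgt)
  # truncation: done set smaller than fitting_count is returned whole
  sets2 <- select_fitting_voxels(st, blk, fitting_count = 10000)
  expect_length(sets2$fit_set, sum(st$done))
  expect_setequal(sets2$target_set, blk)
})

test_that("estimate_block_offset recovers a deliberate 2*pi displacement", {
  # smooth quadratic truth over two half-volumes
  shape <- c(20, 10, 10)
  truth <- array(0, shape)
  for (x in 1:20) truth[x, , ] <- 0.002 * x^2 + 0.05 * x
  v <- wrapped_volume(wrap_to_principal(truth))
  lab <- array(0L, shape)
  lab[1:10, , ] <- 1L
  lab[11:20, , ] <- 2L
  p <- classify_regions(lab, size_threshold = 10)
  st <- seed_state(p, v)
  # store the first half unwrapped with its true values (k = 0 there since
  # truth < pi on that side)
  expect_true(all(abs(truth[1:10, , ]) < pi))
  blk <- p$blocks[[2]]$voxels
  k <- estimate_block_offset(st, blk, v, unwrap_params(size_threshold = 10))
  kref <- round((truth[blk] - v$phase[blk]) / (2 * pi))
  expect_equal(as.integer(k), as.integer(names(sort(table(kref),
                                                    decreasing = TRUE))[1]))
  # identical phase across the interface -> k = 0
  cst <- wrapped_volume(array(0.3, shape))
  st0 <- seed_state(p, cst)
  expect_equal(as.integer(estimate_block_offset(st0, blk, cst,
                                                unwrap_params(size_threshold = 10))),
               0L)
})

test_that("merged block offsets match the exhaustive-search oracle on a ramp", {
  # four adjacent slabs along x; the truth is a steady ramp crossing several
  # wraps, aligned so each slab is internally wrap-free (a constant k per
  # slab exists) while neighboring slabs differ by whole wraps
  shape <- c(32, 6, 6)
  a <- pi / 8
  truth <- ramp_truth(a, shape) - 0.05
  ph <- wrap_to_principal(truth)
  v <- wrapped_volume(ph)
  lab <- array(0L, shape)
  slabs <- list(1:8, 9:16, 17:24, 25:32)
  for (i in seq_along(slabs)) lab[slabs[[i]], , ] <- i
  for (s in slabs)  # each slab wrap-free: raw span below 2*pi, no cut inside
    expect_lt(max(ph[s, , ]) - min(ph[s, , ]), 2 * pi - 0.5)
  p <- classify_regions(lab, size_threshold = 10)
  st <- seed_state(p, v)
  params <- unwrap_params(size_threshold = 10)
  st <- merge_all_blocks(st, p, v, params)
  expect_true(all(st$done[lab > 0]))
  # oracle: exhaustive search over k in [-3,3]^3 relative to the seed block
  seed <- attr(seed_state(p, v), "seed_block")
  kbest <- oracle_block_offsets(ph, p, krange = -3:3, fix = seed)
  kbest <- kbest - kbest[seed] + st$k[p$blocks[[seed]]$voxels[1]]
  for (i in seq_along(p$blocks))
    expect_equal(st$k[p$blocks[[i]]$voxels[1]], kbest[i],
                 info = paste("block", i))
  # block rigidity: one k per block
  for (b in p$blocks)
    expect_length(unique(st$k[b$voxels]), 1L)
})

test_that("unwrap_residuals fills a residual island and respects 2*pi consistency", {
  shape <- c(16, 8, 8)
  truth <- array(0, shape)
  for (x in 1:16) truth[x, , ] <- 0.45 * x
  v <- wrapped_volume(wrap_to_principal(truth))
  lab <- array(0L, shape)
  lab[1:6, , ] <- 1L
  lab[11:16, , ] <- 2L
  p <- classify_regions(lab, size_threshold = 10)
  p$second_residual <- which(array(seq_len(prod(shape)), shape) > 0 &
                               lab == 0L)
  params <- unwrap_params(size_threshold = 10, window = 5)
  st <- seed_state(p, v)
  st <- merge_all_blocks(st, p, v, params)
  st <- unwrap_residuals(st, p, v, params = params)
  expect_true(all(st$done))
  expect_length(attr(st, "unreached"), 0L)
  d <- st$unwrapped - truth
  g <- round(mean(d) / (2 * pi))
  expect_lt(max(abs(d - 2 * pi * g)), 1e-9)
  # exact 2*pi consistency
  expect_lt(max(abs(st$unwrapped - v$phase - 2 * pi * st$k)), 1e-9)
  # zero residual voxels: state unchanged
  p0 <- classify_regions(array(rep(1L, prod(shape)), shape),
                         size_threshold = 10)
  st0 <- seed_state(p0, v)
  st00 <- unwrap_residuals(st0, p0, v, params = params)
  expect_identical(st00$k, st0$k)
})

test_that("unwrap recovers smooth phantoms exactly and reports honestly", {
  # noiseless wrapped Gaussian bump
  truth <- bump_truth(c(28, 28, 28), peak = 11, sd = 6)
  v <- wrapped_volume(wrap_to_principal(truth))
  fit <- unwrap(v)
  expect_s3_class(fit, "unwrap3d")
  expect_true(all(fit$done))
  expect_lt(gauge_error(fit$unwrapped, truth), 1e-9)
  expect_lt(fit$report$consistency_rad, 1e-9)
  # no wraps anywhere: output equals input up to a global constant
  ph <- array(-0.2, c(10, 10, 10)); ph[3:7, 3:7, 3:7] <- -0.1
  fitn <- unwrap(wrapped_volume(ph), unwrap_params(size_threshold = 20))
  expect_equal(fitn$unwrapped - 2 * pi * fitn$k[1, 1, 1], ph,
               ignore_attr = TRUE)
  # disconnected ROI: the unreachable island is reported, not invented
  mask <- array(FALSE, c(20, 6, 6))
  mask[1:8, , ] <- TRUE
  mask[15:20, , ] <- TRUE  # island >= 6 voxels away, outside any window
  vz <- wrapped_volume(array(0.2, c(20, 6, 6)), mask = mask)
  fit2 <- suppressWarnings(unwrap(vz, unwrap_params(size_threshold = 20,
                                                    window = 5)))
  expect_gt(fit2$report$n_unreached, 0)
  expect_false(any(fit2$done[15:20, , ]))
})

test_that("property: random smooth Gaussian-bump fields are recovered exactly", {
  set.seed(41)
  for (i in 1:4) {
    shape <- c(24, 24, 16)
    truth <- array(0, shape)
    for (b in 1:3) {
      ctr <- c(runif(1, 6, 18), runif(1, 6, 18), runif(1, 4, 12))
      pk <- runif(1, -8, 8)
      sd <- runif(1, 5, 9)
      d2 <- outer(outer((seq_len(shape[1]) - ctr[1])^2,
                        (seq_len(shape[2]) - ctr[2])^2, "+"),
                  (seq_len(shape[3]) - ctr[3])^2, "+")
      truth <- truth + pk * exp(-d2 / (2 * sd^2))
    }
    # voxelwise gradient below pi by construction (peaks and widths bounded)
    v <- wrapped_volume(wrap_to_principal(truth))
    fit <- suppressWarnings(unwrap(v, unwrap_params(size_threshold = 50)))
    expect_lt(gauge_error(fit$unwrapped, truth), 1e-9)
    expect_lt(fit$report$consistency_rad, 1e-9)
  }
})

test_that("the engine is deterministic", {
  ds <- simulate_gaussian_dataset(shape = c(24, 24, 24), gaussian_sd = 6,
                                  peak = 10, magnitude = 100, noise_sd = 20,
                                  seed = 99)
  f1 <- suppressWarnings(unwrap(wrapped_volume(ds$wrapped_phase)))
  f2 <- suppressWarnings(unwrap(wrapped_volume(ds$wrapped_phase)))
  expect_identical(f1$k, f2$k)
  expect_identical(f1$unwrapped, f2$unwrapped)
})
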