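# Fixtures and independent oracles shared across the test files.
# All fixtures are built in code; nothing is read from disk.

# linear ramp truth a*x over an (nx, ny, nz) grid (x is 1-based here; the
# constant offset is irrelevant for unwrapping up to gauge)
ramp_truth <- function(a, shape) {
  truth <- array(0, shape)
  for (x in seq_len(shape[1])) truth[x, , ] <- a * x
  truth
}

# small centered Gaussian-bump truth
bump_truth <- function(shape, peak, sd) {
  ctr <- (shape - 1) / 2
  d2 <- function(n, c) (seq_len(n) - 1 - c)^2
  r2 <- outer(outer(d2(shape[1], ctr[1]), d2(shape[2], ctr[2]), "+"),
              d2(shape[3], ctr[3]), "+")
  peak * exp(-r2 / (2 * sd^2))
}

# maximum deviation from truth after removing the best global 2*pi multiple
gauge_error <- function(unwrapped, truth) {
  d <- unwrapped - truth
  g <- round(mean(d, na.rm = TRUE) / (2 * pi))
  max(abs(d - 2 * pi * g), na.rm = TRUE)
}

# 1-based linear index -> 0-based (x, y, z) coordinates
index_to_coord_test <- function(idx, shape) {
  idx0 <- idx - 1L
  cbind(idx0 %% shape[1],
        (idx0 %/% shape[1]) %% shape[2],
        idx0 %/% (shape[1] * shape[2]))
}

# ---- independent oracles ----

# brute-force flood fill labeling (queue-based, R only), for checking the
# C++ component labeler up to label permutation
oracle_label <- function(mask, connectivity = 26) {
  shape <- dim(mask)
  offs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  l1 <- abs(offs$dx) + abs(offs$dy) + abs(offs$dz)
  offs <- offs[l1 > 0 & l1 <= switch(as.character(connectivity),
                                     "6" = 1, "18" = 2, "26" = 3), ]
  lab <- array(0L, shape)
  nxt <- 0L
  for (s in which(mask)) {
    if (lab[s] != 0L) next
    nxt <- nxt + 1L
    queue <- s
    lab[s] <- nxt
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      v0 <- v - 1L
      cx <- v0 %% shape[1]; cy <- (v0 %/% shape[1]) %% shape[2]
      cz <- v0 %/% (shape[1] * shape[2])
      for (i in seq_len(nrow(offs))) {
        x <- cx + offs$dx[i]; y <- cy + offs$dy[i]; z <- cz + offs$dz[i]
        if (x < 0 || x >= shape[1] || y < 0 || y >= shape[2] ||
            z < 0 || z >= shape[3]) next
        w <- x + shape[1] * (y + shape[2] * z) + 1L
        if (mask[w] && lab[w] == 0L) {
          lab[w] <- nxt
          queue <- c(queue, w)
        }
      }
    }
  }
  lab
}

# are two labelings identical up to a relabeling?
same_partitioning <- function(a, b) {
  if (!all((a > 0) == (b > 0))) return(FALSE)
  pos <- a > 0
  !anyDuplicated(unique(cbind(a[pos], b[pos]))[, 1]) &&
    !anyDuplicated(unique(cbind(a[pos], b[pos]))[, 2])
}

# minimum-norm least-squares solution via an independent route (MASS ginv)
oracle_minnorm <- function(X, y) {
  as.numeric(MASS::ginv(X) %*% y)
}

# exhaustive search over per-block integer offsets minimizing the summed
# squared discontinuity across 26-adjacent voxel pairs from different
# blocks; returns the offsets relative to block `fix` (held at 0)
oracle_block_offsets <- function(phase, partition, krange = -3:3, fix = 1) {
  nb <- length(partition$blocks)
  blocks <- partition$blocks
  shape <- dim(phase)
  # collect inter-block adjacent pairs
  lab <- partition$labels
  pairs <- list()
  offs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  offs <- offs[rowSums(abs(offs)) > 0, ]
  for (b in seq_len(nb)) {
    for (v in blocks[[b]]$voxels) {
      v0 <- v - 1L
      cx <- v0 %% shape[1]; cy <- (v0 %/% shape[1]) %% shape[2]
      cz <- v0 %/% (shape[1] * shape[2])
      for (i in seq_len(nrow(offs))) {
        x <- cx + offs$dx[i]; y <- cy + offs$dy[i]; z <- cz + offs$dz[i]
        if (x < 0 || x >= shape[1] || y < 0 || y >= shape[2] ||
            z < 0 || z >= shape[3]) next
        w <- x + shape[1] * (y + shape[2] * z) + 1L
        if (lab[w] > 0 && lab[w] != b && lab[w] > b)
          pairs[[length(pairs) + 1L]] <- c(v, w, b, lab[w])
      }
    }
  }
  P <- do.call(rbind, pairs)
  free <- setdiff(seq_len(nb), fix)
  grid <- as.matrix(do.call(expand.grid,
                            rep(list(krange), length(free))))
  best <- NULL; best_cost <- Inf
  for (r in seq_len(nrow(grid))) {
    k <- integer(nb); k[free] <- grid[r, ]
    u1 <- phase[P[, 1]] + 2 * pi * k[P[, 3]]
    u2 <- phase[P[, 2]] + 2 * pi * k[P[, 4]]
    cost <- sum((u1 - u2)^2)
    if (cost < best_cost) { best_cost <- cost; best <- k }
  }
  best
}
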