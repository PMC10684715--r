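# The unwrapping engine: seeding, nearest-first block merging with a single
# integer offset per block, and quality-guided residual growing.

#' Parameters of the unwrapping engine
#'
#' Defaults follow the algorithm's standard operating point: blocks need at
#' least 100 voxels, inter-block fits use the 100 closest voxels on each side
#' of the interface, residual fits use an 11-voxel window, the polynomial
#' orders are (2,2,2) per axis, and components are labeled with 26-connected
#' neighborhoods so phase changes in all directions are considered.
#'
#' @param size_threshold Minimum block size in voxels (>= 1).
#' @param fitting_count Fitting voxels per side for inter-block offsets.
#' @param window Odd edge length (>= 3) of the residual fitting window.
#' @param fit_cap Maximum number of (nearest) done voxels used by one
#'   residual window fit; default `window^3 - 1`, i.e. every done voxel in
#'   the window. Lowering it trades accuracy at low SNR for speed.
#' @param orders Per-axis polynomial orders `(L, M, N)`.
#' @param connectivity Neighborhood for component labeling and growing
#'   adjacency: 6, 18 or 26.
#' @param exclusion_reach Axis distance probed by the noisy-voxel test.
#' @param exclusion_conjunctive,exclusion_iterate Switches of
#'   [exclude_noisy_voxels()].
#' @param fallback_linear_min,fallback_mean_min Point-count thresholds of
#'   [reduce_orders()].
#' @param strict_passes Grow all second residual voxels strictly before any
#'   first residual voxel (default `FALSE`: one interleaved quality-guided
#'   pass in which the class ordering is emergent).
#' @return A classed list of validated parameters.
#' @export
unwrap_params <- function(size_threshold = 100, fitting_count = 100,
                          window = 11, fit_cap = window^3 - 1,
                          orders = c(2, 2, 2),
                          connectivity = 26,
                          exclusion_reach = 3,
                          exclusion_conjunctive = FALSE,
                          exclusion_iterate = FALSE,
                          fallback_linear_min = 2 * prod(orders + 1),
                          fallback_mean_min = 16,
                          strict_passes = FALSE) {
  stopifnot(size_threshold >= 1, fitting_count >= 1,
            window >= 3, window %% 2 == 1, fit_cap >= 1,
            length(orders) == 3, all(orders >= 0), all(orders <= 6),
            connectivity %in% c(6, 18, 26),
            exclusion_reach >= 1)
  structure(list(size_threshold = as.integer(size_threshold),
                 fitting_count = as.integer(fitting_count),
                 window = as.integer(window),
                 fit_cap = as.integer(fit_cap),
                 orders = as.integer(orders),
                 connectivity = as.integer(connectivity),
                 exclusion_reach = as.integer(exclusion_reach),
                 exclusion_conjunctive = isTRUE(exclusion_conjunctive),
                 exclusion_iterate = isTRUE(exclusion_iterate),
                 fallback_linear_min = as.integer(fallback_linear_min),
                 fallback_mean_min = as.integer(fallback_mean_min),
                 strict_passes = isTRUE(strict_passes)),
            class = "unwrap_params")
}

#' Phase-derivative quality map
#'
#' Per-voxel reliability score: the root-mean-square principal phase
#' difference to the in-mask 26-neighbors. Lower is more reliable; constant
#' phase scores 0; a voxel with no in-mask neighbor receives the worst
#' attainable score (pi). Residual voxels are grown in increasing order of
#' this score.
#'
#' @param vol A [wrapped_volume()] (or 3D phase array).
#' @return A `quality_map` object with elements `quality` (3D array, `NA`
#'   outside the ROI) and `shape`.
#' @export
compute_quality_map <- function(vol) {
  vol <- as_wrapped_volume(vol)
  q <- cpp_quality_map(vol$phase, vol$mask, vol$shape)
  structure(list(quality = array(q, vol$shape), shape = vol$shape),
            class = "quality_map")
}

# empty unwrapping state over a volume shape
new_unwrap_state <- function(shape) {
  structure(list(unwrapped = array(NA_real_, shape),
                 k = array(0L, shape),
                 done = array(FALSE, shape),
                 shape = as.integer(shape)),
            class = "unwrap_state")
}

#' @export
print.unwrap_state <- function(x, ...) {
  cat(sprintf("unwrap_state: %d / %d voxels done\n", sum(x$done),
              prod(x$shape)))
  invisible(x)
}

#' Seed the unwrapping state from the largest block
#'
#' The block with the highest voxel count starts the merge: its raw wrapped
#' phase is wrap-free by construction, so its voxels are marked done with
#' offset `k = 0`. Size ties are broken toward the smallest block id.
#'
#' @param partition A `region_partition` with at least one block.
#' @param vol The corresponding [wrapped_volume()].
#' @return An `unwrap_state`.
#' @export
seed_state <- function(partition, vol) {
  vol <- as_wrapped_volume(vol)
  if (length(partition$blocks) == 0L) stop("partition has no blocks to seed")
  sizes <- vapply(partition$blocks, function(b) b$size, numeric(1))
  seed <- which.max(sizes)  # first maximum = smallest id
  state <- new_unwrap_state(vol$shape)
  idx <- partition$blocks[[seed]]$voxels
  state$done[idx] <- TRUE
  state$unwrapped[idx] <- vol$phase[idx]
  attr(state, "seed_block") <- seed
  state
}

# leverage x' (Xf'Xf)^+ x of query points under a poly_fit's basis
target_leverage <- function(fit, fit_coords, query_coords) {
  Xf <- polynomial_basis(fit_coords, fit$orders, fit$center, fit$scale)
  Xq <- polynomial_basis(query_coords, fit$orders, fit$center, fit$scale)
  sv <- svd(Xf)
  pos <- sv$d > 1e-10 * max(sv$d)
  W <- Xq %*% sv$v[, pos, drop = FALSE]
  W <- sweep(W, 2, sv$d[pos], "/")
  rowSums(W^2)
}

# per-block done status (a block is merged atomically)
block_done <- function(state, partition) {
  vapply(partition$blocks, function(b) state$done[b$voxels[1]], logical(1))
}

#' Next block to merge
#'
#' Among blocks not yet unwrapped, returns the one whose closest voxel is
#' nearest (Euclidean, voxel units) to the already-unwrapped set; ties go to
#' the larger block, then the smaller id.
#'
#' @param state An `unwrap_state`.
#' @param partition A `region_partition`.
#' @return The block id, with the squared distance as attribute `dist2`.
#' @export
nearest_block <- function(state, partition) {
  undone <- which(!block_done(state, partition))
  if (length(undone) == 0L) stop("all blocks are already unwrapped")
  d2 <- cpp_edt_sq(state$done, state$shape)
  pick_nearest_block(d2, partition, undone)
}

pick_nearest_block <- function(d2, partition, undone) {
  dmin <- vapply(undone, function(i) min(d2[partition$blocks[[i]]$voxels]),
                 numeric(1))
  sizes <- vapply(undone, function(i) partition$blocks[[i]]$size, numeric(1))
  sel <- order(dmin, -sizes, undone)[1L]
  structure(undone[sel], dist2 = dmin[sel])
}

#' Fitting and target voxels across a block interface
#'
#' For a growing block, selects the `fitting_count` already-unwrapped voxels
#' closest to the block (the fit set) and the `fitting_count` block voxels
#' closest to the unwrapped set (the target set); smaller sets are returned
#' whole. Distances are Euclidean between closest voxels; ties resolve by
#' linear voxel index, so the selection is deterministic.
#'
#' @param state An `unwrap_state` with a nonempty done set.
#' @param block_voxels Integer vector of the block's linear voxel indices.
#' @param fitting_count Voxels per side (default 100).
#' @return List with `fit_set` and `target_set` (linear indices, nearest
#'   first).
#' @export
select_fitting_voxels <- function(state, block_voxels, fitting_count = 100) {
  if (!any(state$done)) stop("done set is empty")
  d2done <- cpp_edt_sq(state$done, state$shape)
  blockmask <- array(FALSE, state$shape)
  blockmask[block_voxels] <- TRUE
  d2block <- cpp_edt_sq(blockmask, state$shape)
  list(fit_set = cpp_select_smallest(d2block, which(state$done),
                                     as.integer(fitting_count)),
       target_set = cpp_select_smallest(d2done, as.integer(block_voxels),
                                        as.integer(fitting_count)))
}

#' Integer offset of a growing block
#'
#' Fits the local polynomial to the unwrapped phases of the fit set,
#' evaluates it at the target voxels of the growing block, converts each
#' prediction to a per-voxel integer offset, and takes the modal value; a
#' tie is resolved by rounding the mean of the real-valued (pre-rounding)
#' offsets. Polynomial orders fall back per [reduce_orders()] when the fit
#' set is small.
#'
#' @param state An `unwrap_state`.
#' @param block_voxels Integer vector of the block's linear voxel indices.
#' @param vol The [wrapped_volume()].
#' @param params An [unwrap_params()].
#' @param sets Optional precomputed result of [select_fitting_voxels()].
#' @return Integer `k` for the whole block, with per-voxel offsets as
#'   attribute `k_voxel`. `NA` signals a degenerate fit.
#' @export
estimate_block_offset <- function(state, block_voxels, vol,
                                  params = unwrap_params(), sets = NULL) {
  vol <- as_wrapped_volume(vol)
  if (is.null(sets))
    sets <- select_fitting_voxels(state, block_voxels, params$fitting_count)
  fit_idx <- sets$fit_set
  tgt_idx <- sets$target_set
  orders <- reduce_orders(length(fit_idx), params$orders,
                          params$fallback_linear_min, params$fallback_mean_min)
  fco <- index_to_coord(fit_idx, state$shape)
  tco <- index_to_coord(tgt_idx, state$shape)
  # The interface geometry (thin, curved shells) can leave the polynomial
  # nearly unconstrained in the direction of the growing block; demote the
  # order while the median target leverage exceeds 1 (extrapolation beyond
  # the data support), down to a plain mean.
  repeat {
    fit <- fit_local_polynomial(fco, state$unwrapped[fit_idx], orders)
    pred <- predict(fit, tco)
    if (all(orders == 0L)) break
    h <- target_leverage(fit, fco, tco)
    if (all(is.finite(pred)) && stats::median(h) <= 1) break
    orders <- if (any(orders > 1L)) pmin(orders, 1L) else c(0L, 0L, 0L)
  }
  if (any(!is.finite(pred))) return(NA_integer_)
  raw <- (pred - vol$phase[tgt_idx]) / (2 * pi)
  kv <- as.integer(round(raw))
  tab <- table(kv)
  top <- which(tab == max(tab))
  k <- if (length(top) == 1L) as.integer(names(tab)[top])
       else as.integer(round(mean(raw)))
  structure(k, k_voxel = kv)
}

#' Merge all blocks into the unwrapped state
#'
#' Repeats nearest-block selection, interface fitting-voxel selection and
#' block-offset estimation until every block is unwrapped. Each block
#' receives one rigid offset, preserving its wrap-free interior. Blocks with
#' degenerate fits are deferred and, after two failed attempts, demoted to
#' residual handling.
#'
#' @param state A seeded `unwrap_state`.
#' @param partition The `region_partition`.
#' @param vol The [wrapped_volume()].
#' @param params An [unwrap_params()].
#' @return The updated `unwrap_state`; attributes `merge_order` (block ids in
#'   merge order) and `demoted_voxels` (voxels handed to residual growing).
#' @export
merge_all_blocks <- function(state, partition, vol, params = unwrap_params()) {
  vol <- as_wrapped_volume(vol)
  done_blk <- block_done(state, partition)
  defer <- integer(length(partition$blocks))
  demoted <- integer(0)
  merge_order <- integer(0)
  while (any(!done_blk)) {
    d2done <- cpp_edt_sq(state$done, state$shape)
    gi <- pick_nearest_block(d2done, partition, which(!done_blk))
    blk <- partition$blocks[[gi]]
    if (sqrt(attr(gi, "dist2")) > params$window) {
      # island block: the interface gap exceeds the fitting-window scale, so
      # a single extrapolated offset is meaningless; hand the voxels to
      # quality-guided growing, which crosses the gap voxel by voxel
      demoted <- c(demoted, blk$voxels)
      done_blk[gi] <- TRUE
      next
    }
    blockmask <- array(FALSE, state$shape)
    blockmask[blk$voxels] <- TRUE
    d2block <- cpp_edt_sq(blockmask, state$shape)
    sets <- list(fit_set = cpp_select_smallest(d2block, which(state$done),
                                               params$fitting_count),
                 target_set = cpp_select_smallest(d2done, blk$voxels,
                                                  params$fitting_count))
    k <- estimate_block_offset(state, blk$voxels, vol, params, sets)
    if (is.na(k)) {
      defer[gi] <- defer[gi] + 1L
      if (defer[gi] > 2L) {
        demoted <- c(demoted, blk$voxels)
        done_blk[gi] <- TRUE  # out of the merge queue
      }
      next
    }
    idx <- blk$voxels
    state$done[idx] <- TRUE
    state$k[idx] <- as.integer(k)
    state$unwrapped[idx] <- vol$phase[idx] + 2 * pi * as.integer(k)
    done_blk[gi] <- TRUE
    merge_order <- c(merge_order, gi)
  }
  attr(state, "merge_order") <- merge_order
  attr(state, "demoted_voxels") <- demoted
  state
}

#' Unwrap residual voxels by quality-guided growing
#'
#' Residual voxels are unwrapped one at a time, best quality first, each by
#' a polynomial fit to the nearest already-unwrapped voxels inside the
#' centered window. Second residual voxels (members of small regions) are
#' grown first, then first residual voxels (excluded noisy connectors), then
#' a final sweep picks up voxels that only became reachable after the
#' earlier passes. Residual islands with no unwrapped voxel in their
#' connected component remain not-done and are reported.
#'
#' @param state An `unwrap_state` with all blocks merged.
#' @param partition The `region_partition`.
#' @param vol The [wrapped_volume()].
#' @param quality A `quality_map` from [compute_quality_map()] (computed
#'   internally when `NULL`).
#' @param params An [unwrap_params()].
#' @param extra_second Additional voxel indices to treat as second residual
#'   (e.g. demoted blocks).
#' @param trace Record the processing order (attribute `grow_order`).
#' @return The updated `unwrap_state`; attribute `unreached` lists voxels no
#'   pass could reach.
#' @export
unwrap_residuals <- function(state, partition, vol, quality = NULL,
                             params = unwrap_params(),
                             extra_second = integer(0), trace = FALSE) {
  vol <- as_wrapped_volume(vol)
  if (is.null(quality)) quality <- compute_quality_map(vol)
  q <- if (inherits(quality, "quality_map")) quality$quality else quality
  if (isTRUE(params$strict_passes)) {
    passes <- list(second = unique(c(partition$second_residual, extra_second)),
                   first = partition$first_residual)
  } else {
    # one interleaved pass: the front-aware quality priority already makes
    # second residual voxels (small coherent regions) precede first residual
    # voxels (noisy connectors), without forcing the growth to cross steep
    # interfaces just to stay within one class
    passes <- list(all = unique(c(partition$second_residual, extra_second,
                                  partition$first_residual)))
  }
  grow_order <- integer(0)
  for (p in seq_along(passes)) {
    idxs <- passes[[p]]
    if (length(idxs) == 0L) next
    pm <- array(FALSE, state$shape)
    pm[idxs] <- TRUE
    pm <- pm & !state$done
    if (!any(pm)) next
    res <- cpp_grow_pass(vol$phase, q, pm, state$done, state$unwrapped,
                         state$k, state$shape, params$window,
                         params$fit_cap, params$orders,
                         params$fallback_linear_min, params$fallback_mean_min,
                         trace)
    state$done <- array(res$done, state$shape)
    state$unwrapped <- array(res$unwrapped, state$shape)
    state$k <- array(res$k, state$shape)
    if (trace) grow_order <- c(grow_order, res$order)
  }
  # final sweep: residuals of either class reachable only via the other
  left <- vol$mask & !state$done
  if (any(left)) {
    res <- cpp_grow_pass(vol$phase, q, left, state$done, state$unwrapped,
                         state$k, state$shape, params$window,
                         params$fit_cap, params$orders,
                         params$fallback_linear_min, params$fallback_mean_min,
                         trace)
    state$done <- array(res$done, state$shape)
    state$unwrapped <- array(res$unwrapped, state$shape)
    state$k <- array(res$k, state$shape)
    if (trace) grow_order <- c(grow_order, res$order)
  }
  attr(state, "unreached") <- which(vol$mask & !state$done)
  if (trace) attr(state, "grow_order") <- grow_order
  state
}

#' Unwrap a 3D wrapped-phase volume
#'
#' The full pipeline: region partitioning with noisy-voxel exclusion,
#' seeding from the largest block, nearest-first block merging with one
#' integer 2*pi offset per block, and quality-guided growing of the residual
#' voxels. When no region reaches the block-size threshold (very low SNR),
#' the largest connected cleaned region seeds the growth instead, and all
#' other small regions are handled as second residual voxels; if even that
#' fails, the single most reliable ROI voxel seeds.
#'
#' @param vol A [wrapped_volume()], or a 3D array of wrapped phase in
#'   radians.
#' @param params An [unwrap_params()].
#' @return An object of class `unwrap3d`: elements `unwrapped` (3D array,
#'   radians, `NA` where not unwrapped), `k` (3D integer array of 2*pi
#'   offsets), `done` (3D logical), `partition`, `quality`, `params` and
#'   `report` (block/residual counts, unreached voxels, consistency check,
#'   per-stage timings, warnings).
#' @examples
#' truth <- array(0, c(16, 16, 8))
#' for (x in 1:16) truth[x, , ] <- 0.45 * x
#' v <- wrapped_volume(wrap_to_principal(truth))
#' fit <- unwrap(v, unwrap_params(size_threshold = 20, window = 5))
#' max(abs(fit$unwrapped - truth - fit$unwrapped[1] + truth[1]))  # ~0
#' @export
unwrap <- function(vol, params = unwrap_params()) {
  vol <- as_wrapped_volume(vol)
  t0 <- proc.time()[["elapsed"]]
  warnings <- character(0)
  timings <- c()

  quality <- compute_quality_map(vol)
  timings["quality"] <- proc.time()[["elapsed"]] - t0

  t1 <- proc.time()[["elapsed"]]
  partition <- build_partition(vol, params, strict = FALSE)
  if (length(partition$blocks) == 0L) {
    # low-SNR fallback: no region reaches the threshold
    p1 <- params
    p1$size_threshold <- 1L
    partition <- build_partition(vol, p1, strict = FALSE)
    if (length(partition$blocks) > 0L) {
      sizes <- vapply(partition$blocks, function(b) b$size, numeric(1))
      keep <- which.max(sizes)
      drop <- setdiff(seq_along(partition$blocks), keep)
      extra <- unlist(lapply(partition$blocks[drop],
                             function(b) b$voxels), use.names = FALSE)
      partition$second_residual <- sort(c(partition$second_residual,
                                          as.integer(extra)))
      lv <- partition$labels
      lv[extra] <- 0L
      blk <- partition$blocks[[keep]]
      blk$id <- 1L
      lv[blk$voxels] <- 1L
      partition$labels <- lv
      partition$blocks <- list(blk)
      warnings <- c(warnings, sprintf(
        "no region reached size_threshold = %d; seeded from the largest cleaned region (%d voxels)",
        params$size_threshold, blk$size))
    } else {
      # every ROI voxel was excluded: seed from the most reliable voxel
      roi <- which(vol$mask)
      seed <- roi[which.min(quality$quality[roi])]
      partition$blocks <- list(list(id = 1L, bin = NA_integer_,
                                    voxels = seed, size = 1L))
      partition$labels[seed] <- 1L
      partition$first_residual <- setdiff(partition$first_residual, seed)
      warnings <- c(warnings,
                    "no cleaned region available; seeded from the most reliable ROI voxel")
    }
  }
  timings["partition"] <- proc.time()[["elapsed"]] - t1

  t2 <- proc.time()[["elapsed"]]
  state <- seed_state(partition, vol)
  state <- merge_all_blocks(state, partition, vol, params)
  demoted <- attr(state, "demoted_voxels")
  if (length(demoted))
    warnings <- c(warnings, sprintf(
      "%d block voxels demoted to residual growing (isolated blocks or degenerate interface fits)",
      length(demoted)))
  timings["merge"] <- proc.time()[["elapsed"]] - t2

  t3 <- proc.time()[["elapsed"]]
  state <- unwrap_residuals(state, partition, vol, quality, params,
                            extra_second = demoted)
  timings["residuals"] <- proc.time()[["elapsed"]] - t3

  unreached <- attr(state, "unreached")
  if (length(unreached))
    warnings <- c(warnings, sprintf(
      "%d ROI voxels unreachable from the unwrapped set (isolated islands)",
      length(unreached)))

  # 2*pi-consistency audit: unwrapped must equal phase + 2*pi*k exactly
  di <- state$done
  consistency <- if (any(di))
    max(abs(state$unwrapped[di] - vol$phase[di] -
              2 * pi * state$k[di])) else 0
  report <- list(n_roi = sum(vol$mask),
                 n_blocks = length(partition$blocks),
                 block_sizes = vapply(partition$blocks,
                                      function(b) b$size, numeric(1)),
                 n_first_residual = length(partition$first_residual),
                 n_second_residual = length(partition$second_residual),
                 n_demoted = length(demoted),
                 n_unreached = length(unreached),
                 unreached = unreached,
                 merge_order = attr(state, "merge_order"),
                 consistency_rad = consistency,
                 timings = timings,
                 warnings = warnings)
  for (w in warnings) warning(w, call. = FALSE)
  structure(list(unwrapped = state$unwrapped, k = state$k, done = state$done,
                 partition = partition, quality = quality,
                 params = params, report = report),
            class = "unwrap3d")
}

#' @export
print.unwrap3d <- function(x, ...) {
  r <- x$report
  cat("3D phase unwrapping by region partitioning + local polynomial model\n")
  cat(sprintf("  ROI voxels:        %s\n", format(r$n_roi, big.mark = ",")))
  cat(sprintf("  blocks:            %d (largest %s voxels)\n", r$n_blocks,
              if (length(r$block_sizes))
                format(max(r$block_sizes), big.mark = ",") else "0"))
  cat(sprintf("  residual voxels:   %s first, %s second\n",
              format(r$n_first_residual, big.mark = ","),
              format(r$n_second_residual, big.mark = ",")))
  cat(sprintf("  unwrapped:         %s / %s (%d unreachable)\n",
              format(sum(x$done), big.mark = ","),
              format(r$n_roi, big.mark = ","), r$n_unreached))
  cat(sprintf("  2*pi consistency:  %.2e rad\n", r$consistency_rad))
  cat(sprintf("  elapsed:           %.1f s\n", sum(r$timings)))
  invisible(x)
}

#' @export
summary.unwrap3d <- function(object, ...) {
  print(object)
  r <- object$report
  cat("  stage timings (s): ",
      paste(sprintf("%s %.2f", names(r$timings), r$timings),
            collapse = ", "), "\n")
  kk <- object$k[object$done]
  cat(sprintf("  offset range:      k in [%d, %d]\n", min(kk), max(kk)))
  if (length(r$warnings))
    cat("  warnings:\n", paste("   -", r$warnings, collapse = "\n"), "\n")
  invisible(object)
}
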