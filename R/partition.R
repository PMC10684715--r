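# Region partitioning: principal-interval binning, noisy-voxel exclusion,
# component labeling and block/residual classification.

#' Split the ROI into six principal-value subintervals
#'
#' The principal interval is divided into six evenly spaced bins,
#' `(-pi, -2pi/3], (-2pi/3, -pi/3], (-pi/3, 0], (0, pi/3], (pi/3, 2pi/3],
#' (2pi/3, pi]`, each half-open and closed at the upper end so that every
#' boundary value belongs to exactly one bin. Any region made of voxels from
#' a single bin is wrap-free by construction: its raw phase span is below
#' one bin width, far less than `2*pi`.
#'
#' @param vol A [wrapped_volume()] (or 3D phase array).
#' @return List of six logical arrays, pairwise disjoint, whose union equals
#'   the ROI mask. Attribute `bin` holds the integer bin-index array
#'   (0 outside the ROI).
#' @export
partition_phase <- function(vol) {
  vol <- as_wrapped_volume(vol)
  if (!any(vol$mask)) stop("empty ROI: mask has no TRUE voxel")
  bin <- array(0L, vol$shape)
  # the small backoff keeps exact boundary values (e.g. -pi/3) in the bin
  # they close, despite floating-point rounding of the division
  b <- ceiling((vol$phase[vol$mask] + pi) / (pi / 3) - 1e-9)
  b[b < 1L] <- 1L  # guard against fp underflow just above -pi
  bin[vol$mask] <- as.integer(b)
  masks <- lapply(1:6, function(i) bin == i)
  attr(masks, "bin") <- bin
  masks
}

#' Label connected components of a 3D mask
#'
#' Deterministic flood-fill labeling under 6-, 18- or 26-connectivity.
#' Components are numbered from 1 in first-encounter (column-major scan)
#' order; 0 is background.
#'
#' @param region_mask 3D logical array.
#' @param connectivity One of 6, 18, 26 (default 26).
#' @return 3D integer array of labels with attribute `n_components`.
#' @export
label_components <- function(region_mask, connectivity = 26) {
  stopifnot(is.array(region_mask), length(dim(region_mask)) == 3L)
  connectivity <- match.arg(as.character(connectivity), c("26", "18", "6"))
  lab <- cpp_label_components(as.logical(region_mask), dim(region_mask),
                              as.integer(connectivity))
  n <- attr(lab, "n_components")
  lab <- array(lab, dim(region_mask))
  attr(lab, "n_components") <- n
  lab
}

#' Exclude noisy connector voxels from a subinterval region
#'
#' Removes the voxels through which two areas with a hidden wrap can be
#' spuriously connected. A voxel is excluded iff (i) it lies on the region
#' edge (at least one face neighbor outside the region, with the volume
#' border counting as outside) and (ii) on at least two of the three axes it
#' has an out-of-region neighbor within `reach` voxels. With
#' `conjunctive = TRUE` condition (ii) instead requires all `reach` neighbors
#' on one side of an axis to be outside (the stricter reading).
#'
#' @param region_mask 3D logical array: one subinterval's region.
#' @param reach Neighbor distance probed along each axis (default 3).
#' @param conjunctive Use the conjunctive reading of (ii) (default `FALSE`).
#' @param iterate Repeat the exclusion until a fixed point (default `FALSE`,
#'   a single pass).
#' @return List with `cleaned` (the region minus excluded voxels) and
#'   `excluded` (logical array of removed voxels).
#' @export
exclude_noisy_voxels <- function(region_mask, reach = 3, conjunctive = FALSE,
                                 iterate = FALSE) {
  stopifnot(is.array(region_mask), length(dim(region_mask)) == 3L)
  cleaned <- as.logical(region_mask)
  dim(cleaned) <- dim(region_mask)
  excluded <- array(FALSE, dim(region_mask))
  repeat {
    ex <- cpp_exclude_noisy(cleaned, dim(region_mask), as.integer(reach),
                            isTRUE(conjunctive))
    ex <- array(ex, dim(region_mask))
    if (!any(ex)) break
    excluded <- excluded | ex
    cleaned <- cleaned & !ex
    if (!iterate) break
  }
  list(cleaned = cleaned, excluded = excluded)
}

#' Classify labeled regions into blocks and residual voxels
#'
#' Components with at least `size_threshold` voxels become blocks, unwrapped
#' later by a single rigid integer offset; smaller components contribute all
#' their voxels to the second residual class. Previously excluded connector
#' voxels form the first residual class.
#'
#' @param labeled 3D integer label array (0 background), e.g. from
#'   [label_components()] applied per cleaned subinterval.
#' @param size_threshold Minimum block size in voxels (default 100; strictly
#'   smaller components are demoted).
#' @param bin_of_label Optional integer vector mapping label id to the
#'   subinterval index it came from.
#' @param first_residual Integer vector of linear voxel indices excluded as
#'   noisy connectors.
#' @param strict Error when no component reaches the threshold (default
#'   `TRUE`); with `FALSE` the caller receives zero blocks.
#' @return A `region_partition` object; see [build_partition()].
#' @export
classify_regions <- function(labeled, size_threshold = 100,
                             bin_of_label = NULL,
                             first_residual = integer(0), strict = TRUE) {
  stopifnot(size_threshold >= 1)
  shape <- dim(labeled)
  counts <- tabulate(labeled[labeled > 0L])
  if (length(counts) == 0L && strict)
    stop("no connected regions found in the ROI")
  keep <- which(counts >= size_threshold)
  if (length(keep) == 0L && strict)
    stop("no region reaches size_threshold = ", size_threshold,
         "; no block available for merging (consider lowering the threshold)")
  labels <- array(0L, shape)
  blocks <- vector("list", length(keep))
  second <- integer(0)
  if (length(counts)) {
    old2new <- integer(length(counts))
    old2new[keep] <- seq_along(keep)
    pos <- which(labeled > 0L)
    old <- labeled[pos]
    new <- old2new[old]
    labels[pos] <- new
    second <- pos[new == 0L]
    for (i in seq_along(keep)) {
      blocks[[i]] <- list(id = i,
                          bin = if (is.null(bin_of_label)) NA_integer_
                                else bin_of_label[keep[i]],
                          voxels = pos[new == i],
                          size = counts[keep[i]])
    }
  }
  structure(list(labels = labels, blocks = blocks,
                 first_residual = as.integer(first_residual),
                 second_residual = as.integer(second),
                 size_threshold = size_threshold, shape = shape),
            class = "region_partition")
}

#' Partition a wrapped-phase volume into blocks and residual voxels
#'
#' End-to-end region partitioning: the ROI is split into six phase
#' subintervals, noisy connector voxels are excluded per subinterval, the
#' cleaned connected components are reidentified, and components are
#' classified into blocks (wrap-free regions of at least `size_threshold`
#' voxels) plus first residual voxels (excluded connectors) and second
#' residual voxels (members of small regions). Blocks, first and second
#' residual voxels partition the ROI exactly.
#'
#' @param vol A [wrapped_volume()] (or 3D phase array).
#' @param params An [unwrap_params()] list (threshold, connectivity,
#'   exclusion switches).
#' @param strict Passed to [classify_regions()]; with `FALSE` a partition
#'   with zero blocks is returned instead of an error.
#' @return A `region_partition` object: `labels` (3D integer array, 1..R for
#'   block ids, 0 elsewhere), `blocks` (list of id/bin/voxels/size records),
#'   `first_residual` and `second_residual` (linear voxel indices).
#' @export
build_partition <- function(vol, params = unwrap_params(), strict = TRUE) {
  vol <- as_wrapped_volume(vol)
  bins <- partition_phase(vol)
  shape <- vol$shape
  labeled <- array(0L, shape)
  bin_of_label <- integer(0)
  first <- integer(0)
  offset <- 0L
  for (b in 1:6) {
    ex <- exclude_noisy_voxels(bins[[b]], reach = params$exclusion_reach,
                               conjunctive = params$exclusion_conjunctive,
                               iterate = params$exclusion_iterate)
    first <- c(first, which(ex$excluded))
    if (!any(ex$cleaned)) next
    lab <- label_components(ex$cleaned, params$connectivity)
    n <- attr(lab, "n_components")
    if (n > 0L) {
      pos <- which(lab > 0L)
      labeled[pos] <- lab[pos] + offset
      bin_of_label <- c(bin_of_label, rep.int(b, n))
      offset <- offset + n
    }
  }
  part <- classify_regions(labeled, size_threshold = params$size_threshold,
                           bin_of_label = bin_of_label,
                           first_residual = sort(first), strict = strict)
  part
}

#' @export
print.region_partition <- function(x, ...) {
  sizes <- vapply(x$blocks, function(b) b$size, numeric(1))
  cat(sprintf(paste0("region_partition: %d blocks (%s voxels), ",
                     "%d first-residual, %d second-residual voxels\n"),
              length(x$blocks),
              if (length(sizes)) format(sum(sizes), big.mark = ",") else "0",
              length(x$first_residual), length(x$second_residual)))
  invisible(x)
}

#' Export a partition as a single label volume
#'
#' Encodes the partition for inspection (e.g. written to NIfTI): block ids
#' `1..R`, `-1` for first residual voxels, `-2` for second residual voxels,
#' `0` outside the ROI.
#'
#' @param partition A `region_partition`.
#' @return 3D integer array.
#' @export
as_label_volume <- function(partition) {
  stopifnot(inherits(partition, "region_partition"))
  out <- partition$labels
  out[partition$first_residual] <- -1L
  out[partition$second_residual] <- -2L
  out
}
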