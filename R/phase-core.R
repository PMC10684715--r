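# Principal-value phase arithmetic and the wrapped-volume container.

#' Wrap angles to the principal interval (-pi, pi]
#'
#' Maps any finite angle (scalar or array, voxelwise) to its principal value.
#' The boundary convention follows `atan2`: the representative of the
#' branch-cut class is +pi, so `wrap_to_principal(-pi)` is `pi`.
#'
#' @param x Numeric scalar or array of angles in radians; must be finite.
#' @return Object of the same shape with all values in `(-pi, pi]`, congruent
#'   to the input modulo `2*pi`.
#' @examples
#' wrap_to_principal(2.5 * pi)   # 0.5 * pi
#' wrap_to_principal(-pi)        # pi
#' @export
wrap_to_principal <- function(x) {
  if (!is.numeric(x)) stop("`x` must be numeric")
  if (anyNA(x) || !all(is.finite(x)))
    stop("`x` contains non-finite values; phase angles must be finite")
  x - 2 * pi * ceiling((x - pi) / (2 * pi))
}

#' Principal difference of two phase maps
#'
#' `wrap_to_principal(a - b)`, elementwise; the signed phase difference as an
#' angle in `(-pi, pi]`, i.e. the difference measured across the nearest
#' branch cut.
#'
#' @param a,b Numeric scalars or arrays of identical shape, in radians.
#' @return Array of the common shape, values in `(-pi, pi]`.
#' @export
principal_difference <- function(a, b) {
  if (length(a) != length(b) || !identical(dim(a), dim(b)))
    stop("`a` and `b` must have identical shape")
  wrap_to_principal(a - b)
}

#' Apply integer 2*pi offsets to a wrapped phase volume
#'
#' Recovers an unwrapped phase as `phase + 2*pi*k`. This is the defining
#' relation between a wrapped phase and any unwrapping of it: the two must
#' agree modulo `2*pi` voxelwise, with `k` the per-voxel wrap count.
#'
#' @param phase Numeric array of wrapped phase in radians.
#' @param k Integer-valued array of the same shape.
#' @return `phase + 2*pi*k`.
#' @export
apply_offsets <- function(phase, k) {
  if (length(phase) != length(k) || !identical(dim(phase), dim(k)))
    stop("`phase` and `k` must have identical shape")
  if (max(abs(k - round(k))) > 1e-9)
    stop("`k` must be integer-valued")
  phase + 2 * pi * round(k)
}

#' Construct a wrapped-phase volume
#'
#' Bundles a 3D wrapped phase array with an optional co-registered magnitude
#' volume and a binary region-of-interest mask. Phase values must lie in the
#' principal interval `(-pi, pi]`; use [wrap_to_principal()] first if they do
#' not.
#'
#' @param phase 3D numeric array, radians, each masked value in `(-pi, pi]`.
#' @param magnitude Optional 3D numeric array of nonnegative signal
#'   intensities, same shape as `phase`.
#' @param mask Optional 3D logical array, `TRUE` inside the ROI; defaults to
#'   the full volume.
#' @return An object of class `wrapped_volume` with elements `phase`,
#'   `magnitude`, `mask` and `shape`.
#' @export
wrapped_volume <- function(phase, magnitude = NULL, mask = NULL) {
  if (!is.array(phase) || length(dim(phase)) != 3L)
    stop("`phase` must be a 3D array")
  shape <- dim(phase)
  if (is.null(mask)) {
    mask <- array(TRUE, shape)
  } else {
    if (!identical(dim(mask), shape)) stop("`mask` shape differs from `phase`")
    mask <- array(as.logical(mask), shape)
    if (anyNA(mask)) stop("`mask` contains NA")
  }
  pv <- phase[mask]
  if (anyNA(pv) || !all(is.finite(pv)))
    stop("masked phase contains non-finite values")
  if (length(pv) && (min(pv) <= -pi || max(pv) > pi))
    stop("masked phase outside (-pi, pi]; apply wrap_to_principal() first")
  if (!is.null(magnitude)) {
    if (!identical(dim(magnitude), shape))
      stop("`magnitude` shape differs from `phase`")
    if (any(magnitude[mask] < 0, na.rm = TRUE))
      stop("`magnitude` must be nonnegative")
  }
  structure(list(phase = phase, magnitude = magnitude, mask = mask,
                 shape = as.integer(shape)),
            class = "wrapped_volume")
}

#' @export
print.wrapped_volume <- function(x, ...) {
  cat(sprintf("wrapped_volume: %d x %d x %d voxels, %d in ROI (%.1f%%)%s\n",
              x$shape[1], x$shape[2], x$shape[3], sum(x$mask),
              100 * mean(x$mask),
              if (is.null(x$magnitude)) "" else ", with magnitude"))
  invisible(x)
}

# coerce plain arrays for convenience in the top-level API
as_wrapped_volume <- function(x) {
  if (inherits(x, "wrapped_volume")) return(x)
  if (is.array(x)) return(wrapped_volume(x))
  stop("expected a `wrapped_volume` or a 3D array")
}

# 1-based linear index -> (x, y, z) 0-based voxel coordinates, n x 3 matrix
index_to_coord <- function(idx, shape) {
  idx0 <- idx - 1L
  cbind(x = idx0 %% shape[1],
        y = (idx0 %/% shape[1]) %% shape[2],
        z = idx0 %/% (shape[1] * shape[2]))
}
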