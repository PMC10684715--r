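# Local 3D polynomial phase model: tensor-product basis, least-squares fit,
# and rounding of predictions to integer 2*pi offsets.

#' Tensor-product polynomial basis at voxel coordinates
#'
#' Builds the `(L+1)(M+1)(N+1)` monomials `x^l * y^m * z^n` of normalized
#' coordinates, ordered lexicographically by `(l, m, n)`; the first term is
#' the constant 1. Coordinates are normalized affinely as
#' `(coord - center) / scale` per axis before the monomials are formed.
#'
#' @param coords Numeric matrix `n x 3` of voxel coordinates (columns
#'   x, y, z), or a length-3 vector for a single voxel.
#' @param orders Integer vector `(L, M, N)` of per-axis orders.
#' @param center,scale Length-3 numeric vectors of the affine normalization
#'   (defaults: identity).
#' @return Numeric matrix `n x (L+1)(M+1)(N+1)`.
#' @export
polynomial_basis <- function(coords, orders = c(2, 2, 2),
                             center = c(0, 0, 0), scale = c(1, 1, 1)) {
  if (is.null(dim(coords))) coords <- matrix(coords, nrow = 1)
  stopifnot(ncol(coords) == 3, all(is.finite(coords)),
            length(orders) == 3, all(orders >= 0))
  u <- sweep(sweep(coords, 2, center, "-"), 2, scale, "/")
  ex <- expand_orders(orders)
  X <- matrix(1, nrow(coords), nrow(ex))
  for (t in seq_len(nrow(ex)))
    X[, t] <- u[, 1]^ex[t, 1] * u[, 2]^ex[t, 2] * u[, 3]^ex[t, 3]
  X
}

# exponent table, lexicographic in (l, m, n)
expand_orders <- function(orders) {
  g <- expand.grid(n = 0:orders[3], m = 0:orders[2], l = 0:orders[1])
  as.matrix(g[, c("l", "m", "n")])
}

#' Reduce polynomial orders for sparse fits
#'
#' Guards against wild extrapolation when few fitting points are available:
#' with fewer than `linear_min` points (default twice the full term count)
#' the orders drop to `(1,1,1)`; with fewer than `mean_min` (default 16,
#' twice the trilinear term count) to `(0,0,0)`, a plain mean.
#'
#' @param n_points Number of fitting points available.
#' @param orders Requested orders `(L, M, N)`.
#' @param linear_min,mean_min Fallback thresholds.
#' @return Integer vector of effective orders.
#' @export
reduce_orders <- function(n_points, orders = c(2, 2, 2),
                          linear_min = 2 * prod(orders + 1), mean_min = 16) {
  if (n_points < mean_min) return(c(0L, 0L, 0L))
  if (n_points < linear_min) return(pmin(as.integer(orders), 1L))
  as.integer(orders)
}

#' Fit the local 3D polynomial phase model by least squares
#'
#' Estimates the coefficients of the tensor-product polynomial that best
#' reproduces already-unwrapped phase values at the given voxels, in the
#' least-squares sense. Coordinates are recentered on the centroid of the
#' fitting points and scaled by `max(1, half-extent)` per axis before the
#' design matrix is formed, keeping high-order monomials well conditioned.
#' Rank-deficient designs (coplanar or sparse point sets) yield the
#' minimum-norm solution: singular values below `1e-10` times the largest
#' are truncated.
#'
#' @param coords Numeric matrix `n x 3` of voxel coordinates.
#' @param phases Numeric vector of length `n`: unwrapped phase values at the
#'   coordinates, radians.
#' @param orders Per-axis polynomial orders `(L, M, N)` (default `c(2,2,2)`).
#' @param center,scale Optional explicit normalization overriding the
#'   centroid/half-extent default.
#' @return An object of class `poly_fit`: `coeffs`, `orders`, `center`,
#'   `scale`, `fit_rms` (root-mean-square residual over the fitting points)
#'   and `n_points`.
#' @export
fit_local_polynomial <- function(coords, phases, orders = c(2, 2, 2),
                                 center = NULL, scale = NULL) {
  if (is.null(dim(coords))) coords <- matrix(coords, ncol = 3)
  n <- nrow(coords)
  if (n < 1L) stop("at least one fitting point is required")
  stopifnot(length(phases) == n, all(is.finite(phases)),
            all(is.finite(coords)))
  if (is.null(center)) center <- colMeans(coords)
  if (is.null(scale)) {
    half <- apply(coords, 2, function(v) (max(v) - min(v)) / 2)
    scale <- pmax(1, half)
  }
  X <- polynomial_basis(coords, orders, center, scale)
  sv <- svd(X)
  tol <- 1e-10 * max(sv$d)
  pos <- sv$d > tol
  coeffs <- if (any(pos)) {
    sv$v[, pos, drop = FALSE] %*%
      ((crossprod(sv$u[, pos, drop = FALSE], phases)) / sv$d[pos])
  } else {
    matrix(0, ncol(X), 1)
  }
  resid <- phases - as.numeric(X %*% coeffs)
  structure(list(coeffs = as.numeric(coeffs), orders = as.integer(orders),
                 center = as.numeric(center), scale = as.numeric(scale),
                 fit_rms = sqrt(mean(resid^2)), n_points = n),
            class = "poly_fit")
}

#' @export
print.poly_fit <- function(x, ...) {
  cat(sprintf("poly_fit: orders (%d,%d,%d), %d coefficients, %d points, RMS %.3g rad\n",
              x$orders[1], x$orders[2], x$orders[3], length(x$coeffs),
              x$n_points, x$fit_rms))
  invisible(x)
}

#' Evaluate a fitted local polynomial
#'
#' @param object A `poly_fit`.
#' @param coords Numeric matrix `n x 3` (or length-3 vector) of voxel
#'   coordinates.
#' @param ... Unused.
#' @return Numeric vector of predicted phase values, radians.
#' @export
predict.poly_fit <- function(object, coords, ...) {
  X <- polynomial_basis(coords, object$orders, object$center, object$scale)
  as.numeric(X %*% object$coeffs)
}

#' Integer 2*pi offset of a voxel from a local model prediction
#'
#' Rounds the gap between the model prediction and the wrapped value to the
#' nearest whole number of 2*pi cycles:
#' `k = round((predicted - wrapped) / (2*pi))`. The offset is exactly
#' correct whenever the prediction errs by less than pi.
#'
#' @param fit A `poly_fit`.
#' @param voxel Length-3 numeric vector (or `n x 3` matrix) of coordinates.
#' @param wrapped_phase Wrapped phase value(s) at the voxel(s), in
#'   `(-pi, pi]`.
#' @return Integer offset(s) `k`; the unwrapped value is
#'   `wrapped_phase + 2*pi*k`.
#' @export
estimate_voxel_offset <- function(fit, voxel, wrapped_phase) {
  pred <- predict(fit, voxel)
  if (any(!is.finite(pred))) stop("non-finite model prediction")
  as.integer(round((pred - wrapped_phase) / (2 * pi)))
}
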