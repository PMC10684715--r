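# NIfTI reading/writing and ROI-mask generation.

#' Read a wrapped-phase volume from NIfTI
#'
#' Reads a 3D real-valued NIfTI image as wrapped phase in radians. Values
#' outside `(-pi, pi]` are re-wrapped with a warning; with
#' `rescale = TRUE` the stored intensity range is first mapped linearly onto
#' `(-pi, pi]` (for scanners exporting scaled-integer phase). The NIfTI
#' header/affine is retained in attribute `nifti_header` for round-tripping.
#'
#' @param path Path to a `.nii` / `.nii.gz` file.
#' @param magnitude_path,mask_path Optional co-registered magnitude and
#'   binary mask volumes.
#' @param rescale Linearly map the stored range to `(-pi, pi]`.
#' @return A [wrapped_volume()] with attribute `nifti_header`.
#' @export
read_phase_volume <- function(path, magnitude_path = NULL, mask_path = NULL,
                              rescale = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) == 4L && dim(arr)[4] == 1L)
    arr <- array(arr, dim(arr)[1:3])
  if (length(dim(arr)) != 3L)
    stop("expected a 3D image, got dimensions ",
         paste(dim(arr), collapse = " x "))
  mask <- NULL
  if (!is.null(mask_path)) {
    m <- as.array(RNifti::readNifti(mask_path))
    if (!identical(dim(m), dim(arr))) stop("mask shape differs from phase")
    mask <- array(m != 0, dim(arr))
  }
  chk <- if (is.null(mask)) arr else arr[mask]
  if (anyNA(chk) || !all(is.finite(chk)))
    stop("phase volume contains non-finite values inside the ROI")
  if (isTRUE(rescale)) {
    lo <- min(arr); hi <- max(arr)
    if (hi > lo)
      arr <- wrap_to_principal(-pi + (arr - lo) / (hi - lo) * 2 * pi)
  }
  if (min(arr) <= -pi || max(arr) > pi) {
    warning("phase values outside (-pi, pi]; re-wrapping to the principal interval")
    arr <- wrap_to_principal(arr)
  }
  magnitude <- NULL
  if (!is.null(magnitude_path)) {
    magnitude <- as.array(RNifti::readNifti(magnitude_path))
    if (!identical(dim(magnitude), dim(arr)))
      stop("magnitude shape differs from phase")
  }
  vol <- wrapped_volume(arr, magnitude = magnitude, mask = mask)
  attr(vol, "nifti_header") <- img
  vol
}

#' Write a 3D array as NIfTI
#'
#' @param x 3D numeric or integer array (`NA` written as 0 for integer
#'   data).
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param template Optional NIfTI image or header whose geometry (affine,
#'   pixel dimensions) is copied.
#' @param datatype Storage type, e.g. `"double"` or `"int32"` (default
#'   `"double"`).
#' @return The path, invisibly.
#' @export
write_volume <- function(x, path, template = NULL, datatype = "double") {
  if (datatype %in% c("int16", "int32")) {
    x[is.na(x)] <- 0L
    storage.mode(x) <- "integer"
  }
  img <- if (is.null(template)) RNifti::asNifti(x)
         else RNifti::asNifti(x, reference = template)
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

# Otsu threshold on a histogram of intensities.  Attribute `bimodal` flags
# whether the histogram actually has a valley at the split: thresholding a
# unimodal image (no air background) would cut the object in half, so the
# caller falls back to a full mask in that case.
otsu_threshold <- function(x, nbins = 256) {
  x <- x[is.finite(x)]
  h <- hist(x, breaks = seq(min(x), max(x), length.out = nbins + 1),
            plot = FALSE)
  w <- h$counts / sum(h$counts)
  mids <- h$mids
  w1 <- cumsum(w)
  mu <- cumsum(w * mids)
  mu_t <- mu[length(mu)]
  sigma_b <- (mu_t * w1 - mu)^2 / (w1 * (1 - w1))
  sigma_b[!is.finite(sigma_b)] <- 0
  # midpoint of the plateau of maximal between-class variance
  top <- which(sigma_b >= max(sigma_b) * (1 - 1e-9))
  i <- as.integer(round(mean(range(top))))
  # valley test: the density at the split against the modes on either side
  d <- stats::filter(w, rep(1 / 5, 5), sides = 2)
  d[is.na(d)] <- w[is.na(d)]
  below <- max(d[seq_len(i)]); above <- max(d[i:length(d)])
  structure(mids[i], bimodal = d[i] < 0.5 * min(below, above))
}

#' Generate an ROI mask from a magnitude volume
#'
#' A magnitude-threshold surrogate for object masking: threshold at
#' `fraction` times the Otsu level, keep the largest 26-connected component,
#' and fill in-plane holes slice by slice. The `"full"` strategy returns an
#' all-true mask; a user-provided mask should always take precedence over
#' either strategy.
#'
#' @param magnitude 3D numeric array of signal magnitude.
#' @param strategy `"threshold"` (default) or `"full"`.
#' @param fraction Multiplier on the Otsu threshold (default 1).
#' @return 3D logical mask.
#' @export
generate_mask <- function(magnitude, strategy = c("threshold", "full"),
                          fraction = 1) {
  strategy <- match.arg(strategy)
  stopifnot(is.array(magnitude), length(dim(magnitude)) == 3L)
  if (strategy == "full") return(array(TRUE, dim(magnitude)))
  rng <- range(magnitude, finite = TRUE)
  if (rng[1] == rng[2]) return(array(TRUE, dim(magnitude)))
  thr <- otsu_threshold(magnitude)
  if (!isTRUE(attr(thr, "bimodal"))) return(array(TRUE, dim(magnitude)))
  mask <- magnitude >= fraction * as.numeric(thr)
  if (!any(mask))
    stop("mask empty after thresholding; lower `fraction` or supply a mask")
  lab <- label_components(mask, 26)
  counts <- tabulate(lab[lab > 0L])
  mask <- lab == which.max(counts)
  # fill enclosed holes per axial slice: background connected to the slice
  # border stays background
  for (k in seq_len(dim(mask)[3])) {
    sl <- mask[, , k, drop = FALSE]
    bg <- !sl
    labbg <- label_components(bg, 6)
    border <- unique(c(labbg[1, , 1], labbg[dim(sl)[1], , 1],
                       labbg[, 1, 1], labbg[, dim(sl)[2], 1]))
    border <- border[border > 0L]
    hole <- bg & !array(labbg %in% border, dim(bg))
    mask[, , k] <- sl | hole
  }
  mask
}

#' Write unwrapping results alongside their audit trail
#'
#' Writes the unwrapped phase, the integer offset map (`k`, as int32 so the
#' `2*pi`-consistency of the output is externally auditable) and a JSON run
#' report.
#'
#' @param fit An `unwrap3d` result.
#' @param unwrapped_path,k_path,report_path Output paths (`NULL` skips).
#' @param template Optional NIfTI geometry template.
#' @return Named character vector of the files written, invisibly.
#' @export
write_unwrap_results <- function(fit, unwrapped_path, k_path = NULL,
                                 report_path = NULL, template = NULL) {
  stopifnot(inherits(fit, "unwrap3d"))
  written <- c(unwrapped = unwrapped_path)
  out <- fit$unwrapped
  out[is.na(out)] <- 0
  write_volume(out, unwrapped_path, template)
  if (!is.null(k_path)) {
    write_volume(fit$k, k_path, template, datatype = "int32")
    written["k"] <- k_path
  }
  if (!is.null(report_path)) {
    rep <- fit$report
    rep$timings <- as.list(rep$timings)
    rep$params <- unclass(fit$params)
    rep$unreached <- NULL
    jsonlite::write_json(rep, report_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    written["report"] <- report_path
  }
  invisible(written)
}
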