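# Synthetic phantom generators with complex Gaussian noise, and the
# noise-corrected reference phase used for scoring.

new_simulated_dataset <- function(true_phase, complex_data, magnitude,
                                  noise_sd, seed, extra = list()) {
  wrapped <- Arg(complex_data)     # principal argument, (-pi, pi]
  ref <- reference_phase(true_phase, wrapped)
  structure(c(list(true_phase = true_phase,
                   complex_data = complex_data,
                   wrapped_phase = wrapped,
                   reference_phase = ref,
                   magnitude_setting = magnitude,
                   noise_sd = noise_sd,
                   snr = if (noise_sd > 0) magnitude / noise_sd else Inf,
                   seed = seed,
                   shape = dim(true_phase)),
              extra),
            class = "simulated_dataset")
}

#' @export
print.simulated_dataset <- function(x, ...) {
  cat(sprintf("simulated_dataset (%s): %d x %d x %d, magnitude %g, noise SD %g, SNR %g, seed %s\n",
              x$model, x$shape[1], x$shape[2], x$shape[3],
              x$magnitude_setting, x$noise_sd, x$snr,
              if (is.null(x$seed)) "none" else x$seed))
  invisible(x)
}

# complex Gaussian noise: independent real/imaginary channels, each with the
# stated SD (standard MR simulation convention); SNR = magnitude / noise_sd
add_complex_noise <- function(true_phase, magnitude, noise_sd, seed) {
  signal <- magnitude * exp(1i * true_phase)
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    n <- length(true_phase)
    signal <- signal + complex(real = rnorm(n, 0, noise_sd),
                               imaginary = rnorm(n, 0, noise_sd))
    dim(signal) <- dim(true_phase)
  }
  signal
}

#' Simulate the Gaussian-bump phase phantom
#'
#' A smooth radially symmetric true phase,
#' `peak * exp(-||v - center||^2 / (2 * gaussian_sd^2))` with the bump
#' centered on the volume, converted to complex data
#' `magnitude * exp(i * phase)` plus independent complex Gaussian noise
#' (each channel SD `noise_sd`). The wrapped phase is the principal argument
#' of the noisy complex data; SNR is `magnitude / noise_sd`. With the
#' default 100-voxel cube, bump SD of 20 voxels and noise SD 20, magnitudes
#' 10 to 100 give SNRs 0.5 to 5.
#'
#' @param shape Volume dimensions (default `c(100, 100, 100)`).
#' @param gaussian_sd SD of the phase bump in voxels (default 20).
#' @param peak Peak phase at the center, radians (default 20, about three
#'   wraps from center to edge).
#' @param magnitude Noise-free signal magnitude, arbitrary units.
#' @param noise_sd Per-channel SD of the complex Gaussian noise (default 20).
#' @param seed RNG seed; a fixed seed reproduces the dataset bitwise.
#' @return A `simulated_dataset`: `true_phase`, `complex_data`,
#'   `wrapped_phase`, `reference_phase`, `magnitude_setting`, `noise_sd`,
#'   `snr`, `seed`.
#' @export
simulate_gaussian_dataset <- function(shape = c(100, 100, 100),
                                      gaussian_sd = 20, peak = 20,
                                      magnitude = 100, noise_sd = 20,
                                      seed = NULL) {
  stopifnot(length(shape) == 3, all(shape >= 1),
            gaussian_sd > 0, magnitude > 0, noise_sd >= 0)
  center <- (shape - 1) / 2
  d2 <- function(n, c) (seq_len(n) - 1 - c)^2
  r2 <- outer(outer(d2(shape[1], center[1]), d2(shape[2], center[2]), "+"),
              d2(shape[3], center[3]), "+")
  true_phase <- peak * exp(-r2 / (2 * gaussian_sd^2))
  cx <- add_complex_noise(true_phase, magnitude, noise_sd, seed)
  new_simulated_dataset(true_phase, cx, magnitude, noise_sd, seed,
                        extra = list(model = "gaussian", peak = peak,
                                     gaussian_sd = gaussian_sd))
}

#' Simulate the variable-gradient phase phantom
#'
#' A separable sinusoidal true phase whose gradient direction and strength
#' change along the slice axis:
#' `height * ((sin(x)/pi) * (1.50 - z) + (sin(y)/pi) * (0.49 + z))`,
#' where `x` and `y` are the raw voxel indices taken as radians and `z` is
#' the slice index normalized to `[0, 1]`. Noise is added as in
#' [simulate_gaussian_dataset()]. The defaults (101 x 101 x 51, height 5,
#' magnitude 50, noise SD 10) give SNR 5 with phase-change levels varying
#' along z.
#'
#' @param shape Volume dimensions (default `c(101, 101, 51)`).
#' @param height Amplitude factor of the phase surface (default 5).
#' @param magnitude Signal magnitude (default 50).
#' @param noise_sd Per-channel noise SD (default 10).
#' @param seed RNG seed.
#' @param xy_scale Radians per voxel index for the sine arguments
#'   (default 1).
#' @return A `simulated_dataset`.
#' @export
simulate_variable_gradient_dataset <- function(shape = c(101, 101, 51),
                                               height = 5, magnitude = 50,
                                               noise_sd = 10, seed = NULL,
                                               xy_scale = 1) {
  stopifnot(length(shape) == 3, all(shape >= 1),
            magnitude > 0, noise_sd >= 0)
  x <- (seq_len(shape[1]) - 1) * xy_scale
  y <- (seq_len(shape[2]) - 1) * xy_scale
  z <- if (shape[3] > 1) (seq_len(shape[3]) - 1) / (shape[3] - 1) else 0
  sx <- sin(x) / pi
  sy <- sin(y) / pi
  true_phase <- array(0, shape)
  for (k in seq_len(shape[3])) {
    true_phase[, , k] <- height *
      (outer(sx * (1.50 - z[k]), rep(1, shape[2])) +
       outer(rep(1, shape[1]), sy * (0.49 + z[k])))
  }
  cx <- add_complex_noise(true_phase, magnitude, noise_sd, seed)
  new_simulated_dataset(true_phase, cx, magnitude, noise_sd, seed,
                        extra = list(model = "variable_gradient",
                                     height = height, xy_scale = xy_scale))
}

#' Noise-corrected reference phase
#'
#' The scoring reference: the generated original phase plus the principal
#' phase change caused by noise,
#' `true + principal_difference(wrapped_noisy, wrap(true))`. It is congruent
#' to the noisy wrapped phase modulo `2*pi` at every voxel, and within pi of
#' the true phase; with no noise it equals the true phase. An unwrapper that
#' assigns every voxel its correct integer offset reproduces this reference
#' exactly.
#'
#' @param true_phase 3D array of noise-free true phase, radians.
#' @param wrapped_noisy 3D array of the noisy wrapped phase, same shape.
#' @return 3D array of the reference phase.
#' @export
reference_phase <- function(true_phase, wrapped_noisy) {
  if (!identical(dim(true_phase), dim(wrapped_noisy)))
    stop("`true_phase` and `wrapped_noisy` must have identical shape")
  true_phase + principal_difference(wrapped_noisy,
                                    wrap_to_principal(true_phase))
}
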