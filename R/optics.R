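#' Widefield optics parameters
#'
#' Parameterises the forward imaging model: emitters are binned to pixels,
#' blurred with an isotropic Gaussian point-spread function, and offset by
#' a constant background, with optional Poisson shot noise and Gaussian
#' read noise. The defaults describe a 20x widefield configuration: 325 nm
#' pixels (6.5 um camera pixel / 20x) and a 170 nm PSF standard deviation
#' (green emission at moderate numerical aperture). None of these are
#' measured quantities; they are documented modelling assumptions.
#'
#' @param pixel_size pixel pitch at the sample, nm per pixel.
#' @param psf_sigma Gaussian PSF standard deviation, nm.
#' @param background constant background level, photons per pixel.
#' @param read_noise_sd Gaussian read-noise standard deviation, photons.
#' @param image_shape integer (rows, cols) of the rendered image.
#' @return an `optics_params` list.
#' @export
optics_params <- function(pixel_size = 325, psf_sigma = 170, background = 10,
                          read_noise_sd = 3, image_shape = c(64, 64)) {
  check_scalar(pixel_size, "pixel_size", lower = 0, lower_open = TRUE)
  check_scalar(psf_sigma, "psf_sigma", lower = 0)
  check_scalar(background, "background", lower = 0)
  check_scalar(read_noise_sd, "read_noise_sd", lower = 0)
  image_shape <- as.integer(image_shape)
  if (length(image_shape) != 2 || any(image_shape < 1))
    stop("`image_shape` must be two positive integers (rows, cols)")
  structure(list(pixel_size = pixel_size, psf_sigma = psf_sigma,
                 background = background, read_noise_sd = read_noise_sd,
                 image_shape = image_shape),
            class = "optics_params")
}

#' Widefield image container
#'
#' A `micro_image` is a 2D grid of nonnegative pixel intensities (photons)
#' with its pixel size attached. Row index increases with the physical y
#' coordinate and column index with x; a position (x, y) in nm falls in the
#' half-open pixel bin `[k * pixel_size, (k + 1) * pixel_size)` on each
#' axis.
#'
#' @param pixels numeric matrix of nonnegative intensities.
#' @param pixel_size nm per pixel.
#' @return an object of class `micro_image`.
#' @export
micro_image <- function(pixels, pixel_size) {
  pixels <- as.matrix(pixels)
  if (!is.numeric(pixels) || anyNA(pixels) || any(pixels < 0))
    stop("`pixels` must be a nonnegative numeric matrix")
  check_scalar(pixel_size, "pixel_size", lower = 0, lower_open = TRUE)
  structure(list(pixels = pixels, pixel_size = pixel_size),
            class = "micro_image")
}

#' @export
print.micro_image <- function(x, ...) {
  cat(sprintf("<micro_image> %d x %d px @ %.0f nm/px, range [%.2f, %.2f] photons\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_size,
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' @export
plot.micro_image <- function(x, ...) {
  graphics::image(t(x$pixels), asp = nrow(x$pixels) / ncol(x$pixels),
                  col = grDevices::hcl.colors(64, "inferno"),
                  axes = FALSE, ...)
  invisible(x)
}

# Direct 2D convolution with zero padding via shift-and-add; kernels here
# are small (a few sigma of a sub-pixel to ~1 px PSF) so this beats FFT
# bookkeeping at these image sizes.
conv2_zeropad <- function(x, kernel) {
  kr <- (nrow(kernel) - 1L) %/% 2L
  kc <- (ncol(kernel) - 1L) %/% 2L
  nr <- nrow(x); nc <- ncol(x)
  out <- matrix(0, nr, nc)
  for (i in seq_len(nrow(kernel))) {
    di <- i - kr - 1L
    sr <- max(1L, 1L - di):min(nr, nr - di)
    if (length(sr) == 0) next
    for (j in seq_len(ncol(kernel))) {
      w <- kernel[i, j]
      if (w == 0) next
      dj <- j - kc - 1L
      sc <- max(1L, 1L - dj):min(nc, nc - dj)
      if (length(sc) == 0) next
      out[sr + di, sc + dj] <- out[sr + di, sc + dj] + w * x[sr, sc]
    }
  }
  out
}

gaussian_kernel <- function(sigma_px) {
  r <- max(1L, ceiling(4 * sigma_px))
  k <- dnorm(seq(-r, r), sd = sigma_px)
  k <- k / sum(k)  # unit mass: blur conserves flux away from image edges
  outer(k, k)
}

#' Render a widefield image from an emission field
#'
#' Emissive fluorophores are binned to pixels (half-open bins), convolved
#' with a normalised Gaussian PSF, and offset by the constant background.
#' With `noise_on`, Poisson shot noise is drawn on the expected photon
#' image and zero-mean Gaussian read noise added, clipping at zero.
#'
#' @param emission an `emission_field` from [aie_emission()] or
#'   [conventional_emission()].
#' @param optics an [optics_params()].
#' @param noise_on logical; render the noiseless expectation if `FALSE`.
#' @param rng_seed integer seed; required when `noise_on`.
#' @param offset length-2 numeric (nm) added to emitter positions before
#'   binning, e.g. to centre a footprint in the frame.
#' @return a [micro_image()].
#' @export
render_image <- function(emission, optics, noise_on = TRUE, rng_seed = NULL,
                         offset = c(0, 0)) {
  stopifnot(inherits(emission, "emission_field"),
            inherits(optics, "optics_params"))
  check_flag(noise_on, "noise_on")
  if (noise_on && is.null(rng_seed))
    stop("`rng_seed` is required when `noise_on = TRUE`")
  nr <- optics$image_shape[1]; nc <- optics$image_shape[2]
  expected <- matrix(0, nr, nc)
  keep <- emission$brightness > 0
  if (any(keep)) {
    x <- emission$positions[keep, 1] + offset[1]
    y <- emission$positions[keep, 2] + offset[2]
    col <- floor(x / optics$pixel_size) + 1L
    row <- floor(y / optics$pixel_size) + 1L
    bad <- which(col < 1 | col > nc | row < 1 | row > nr)
    if (length(bad) > 0)
      stop(sprintf("emitter %d at (%.1f, %.1f) nm maps outside the %d x %d image",
                   which(keep)[bad[1]], x[bad[1]], y[bad[1]], nr, nc))
    idx <- (col - 1L) * nr + row
    acc <- rowsum(emission$brightness[keep], idx)
    expected[as.integer(rownames(acc))] <- acc[, 1]
    if (optics$psf_sigma > 0)
      expected <- conv2_zeropad(expected,
                                gaussian_kernel(optics$psf_sigma / optics$pixel_size))
  }
  expected <- expected + optics$background
  pixels <- if (noise_on) {
    with_seed(rng_seed, {
      shot <- rpois(length(expected), expected)
      pmax(0, shot + rnorm(length(expected), 0, optics$read_noise_sd))
    })
  } else expected
  micro_image(matrix(pixels, nr, nc), optics$pixel_size)
}
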