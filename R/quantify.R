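#' Segmentation parameters for the edge-detection ROI
#'
#' The cell-area mask is obtained with a classical edge-detection pipeline:
#' Gaussian smoothing, Sobel gradient magnitude, a threshold on the
#' gradient map (Otsu by default), morphological closing with a disc,
#' hole filling, and removal of small components. The Sobel kernels are
#' `1/8 * [[-1,0,1],[-2,0,2],[-1,0,1]]` (x) and its transpose (y).
#'
#' The thresholded gradient forms a band straddling the true boundary, so
#' the filled mask extends to the band's outer edge; a final erosion of
#' `edge_erosion_radius` pixels (by default `ceiling(smooth_sigma) + 1`,
#' about half the band width) recenters the mask on the boundary.
#'
#' @param smooth_sigma Gaussian pre-smoothing sigma, px (0 disables).
#' @param gradient_threshold_method `"otsu"` or `"fixed"`.
#' @param fixed_threshold gradient threshold (photons/px) when
#'   `gradient_threshold_method = "fixed"`.
#' @param closing_radius disc radius for morphological closing, px.
#' @param min_object_area minimum connected-component area kept, px.
#' @param edge_erosion_radius final erosion radius, px; `NULL` for the
#'   automatic choice, 0 to disable.
#' @return a `segmentation_params` list.
#' @export
segmentation_params <- function(smooth_sigma = 3,
                                gradient_threshold_method = c("otsu", "fixed"),
                                fixed_threshold = NULL,
                                closing_radius = 3, min_object_area = 50,
                                edge_erosion_radius = NULL) {
  check_scalar(smooth_sigma, "smooth_sigma", lower = 0)
  gradient_threshold_method <- match.arg(gradient_threshold_method)
  if (gradient_threshold_method == "fixed") {
    if (is.null(fixed_threshold))
      stop("`fixed_threshold` is required with the \"fixed\" method")
    check_scalar(fixed_threshold, "fixed_threshold", lower = 0)
  }
  check_scalar(closing_radius, "closing_radius", lower = 0)
  check_scalar(min_object_area, "min_object_area", lower = 0)
  if (is.null(edge_erosion_radius))
    edge_erosion_radius <- ceiling(smooth_sigma) + 1
  check_scalar(edge_erosion_radius, "edge_erosion_radius", lower = 0)
  structure(list(smooth_sigma = smooth_sigma,
                 gradient_threshold_method = gradient_threshold_method,
                 fixed_threshold = fixed_threshold,
                 closing_radius = closing_radius,
                 min_object_area = min_object_area,
                 edge_erosion_radius = edge_erosion_radius),
            class = "segmentation_params")
}

new_roi_mask <- function(mask) {
  mask <- matrix(as.logical(mask), nrow(mask), ncol(mask))  # drop Image class
  structure(list(mask = mask, area_px = sum(mask)), class = "roi_mask")
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("<roi_mask> %d x %d px, %d foreground px (%.1f%%)\n",
              nrow(x$mask), ncol(x$mask), x$area_px,
              100 * x$area_px / length(x$mask)))
  invisible(x)
}

disc_brush <- function(radius) {
  EBImage::makeBrush(2L * as.integer(radius) + 1L, shape = "disc")
}

#' Segment the cell area of a widefield image
#'
#' Edge-detection region-of-interest pipeline (see
#' [segmentation_params()]). A constant image has no edges; with the Otsu
#' method it yields an empty mask with a warning rather than an error, so
#' per-well failures stay visible but non-fatal.
#'
#' @param image a [micro_image()].
#' @param params a [segmentation_params()].
#' @return an `roi_mask` (logical pixel mask plus its area).
#' @export
segment_cells <- function(image, params = segmentation_params()) {
  stopifnot(inherits(image, "micro_image"),
            inherits(params, "segmentation_params"))
  x <- image$pixels
  if (params$smooth_sigma > 0)
    x <- EBImage::gblur(x, sigma = params$smooth_sigma)
  sx <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3) / 8
  grad <- sqrt(conv2_zeropad(x, sx)^2 + conv2_zeropad(x, t(sx))^2)
  # the Sobel stencil is undefined on the frame border (no outside pixels);
  # zero it so the border is never mistaken for an edge
  grad[c(1, nrow(grad)), ] <- 0
  grad[, c(1, ncol(grad))] <- 0
  if (params$gradient_threshold_method == "otsu") {
    rng <- max(grad) - min(grad)
    if (rng <= 0) {
      warning("image has no intensity gradients; returning an empty mask")
      return(new_roi_mask(matrix(FALSE, nrow(grad), ncol(grad))))
    }
    gn <- (grad - min(grad)) / rng
    edges <- gn > EBImage::otsu(EBImage::Image(gn))
  } else {
    edges <- grad > params$fixed_threshold
  }
  m <- edges
  if (params$closing_radius > 0)
    m <- EBImage::closing(m, disc_brush(params$closing_radius))
  m <- EBImage::fillHull(m)
  lab <- EBImage::bwlabel(m)
  if (params$min_object_area > 0 && max(lab) > 0) {
    sizes <- tabulate(lab[lab > 0])
    m <- matrix(lab %in% which(sizes >= params$min_object_area),
                nrow(lab), ncol(lab))
  }
  if (params$edge_erosion_radius > 0 && sum(m > 0) > 0)
    m <- EBImage::erode(m > 0, disc_brush(params$edge_erosion_radius))
  new_roi_mask(m > 0)
}

#' Masked mean intensity of an image
#'
#' The core readout of the assay: the summed pixel intensity over the
#' segmented cell area divided by the number of masked pixels, i.e. the
#' average fluorescence per pixel of cell.
#'
#' @param image a [micro_image()].
#' @param mask an `roi_mask` (or logical matrix) of the same shape.
#' @return a list with `sum_intensity`, `area_px` and `mean_intensity`.
#' @export
mean_masked_intensity <- function(image, mask) {
  stopifnot(inherits(image, "micro_image"))
  m <- if (inherits(mask, "roi_mask")) mask$mask else mask
  if (!identical(dim(m), dim(image$pixels)))
    stop("mask and image shapes differ")
  area <- sum(m)
  if (area == 0)
    stop("mean intensity is undefined for an empty mask")
  s <- sum(image$pixels[m])
  list(sum_intensity = s, area_px = area, mean_intensity = s / area)
}

#' Signal-to-noise ratio of a masked image
#'
#' `SNR = (mean(foreground) - mean(background)) / sd(background)`, with
#' foreground the masked pixels and background the complement of the mask
#' dilated by `bg_exclusion_radius` pixels (excluding the PSF halo around
#' the cell). An SNR above 1 marks a detectable signal by the usual
#' convention. This background-referenced definition is this package's
#' documented choice of SNR statistic; comparisons across conditions are
#' internally consistent under it.
#'
#' @param image a [micro_image()].
#' @param mask an `roi_mask` (or logical matrix) of the same shape.
#' @param bg_exclusion_radius dilation radius (px) separating foreground
#'   from the background annulus.
#' @return SNR, dimensionless.
#' @export
compute_snr <- function(image, mask, bg_exclusion_radius = 5) {
  stopifnot(inherits(image, "micro_image"))
  m <- if (inherits(mask, "roi_mask")) mask$mask else mask
  if (!identical(dim(m), dim(image$pixels)))
    stop("mask and image shapes differ")
  if (sum(m) == 0) stop("SNR is undefined for an empty mask")
  check_scalar(bg_exclusion_radius, "bg_exclusion_radius", lower = 0)
  dil <- if (bg_exclusion_radius > 0)
    EBImage::dilate(m, disc_brush(bg_exclusion_radius)) > 0 else m
  bg <- !dil
  if (sum(bg) < 2) stop("background region is empty; cannot estimate noise")
  sdb <- sd(image$pixels[bg])
  if (sdb == 0) stop("background has zero spread; SNR is undefined")
  (mean(image$pixels[m]) - mean(image$pixels[bg])) / sdb
}
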