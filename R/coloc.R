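#' Pearson colocalization of two channels
#'
#' Pixel-wise Pearson correlation between two channels over the masked
#' (cell-area) pixels — the standard colocalization statistic for
#' co-targeting probes. With `mask = NULL` the whole frame is used.
#'
#' @param channel_a,channel_b [micro_image()]s of equal shape.
#' @param mask an `roi_mask`, a logical matrix, or `NULL` for whole-frame.
#' @return the Pearson correlation coefficient, in `[-1, 1]`.
#' @export
pearson_coloc <- function(channel_a, channel_b, mask = NULL) {
  stopifnot(inherits(channel_a, "micro_image"),
            inherits(channel_b, "micro_image"))
  if (!identical(dim(channel_a$pixels), dim(channel_b$pixels)))
    stop("channel shapes differ")
  m <- coerce_mask(mask, dim(channel_a$pixels))
  a <- channel_a$pixels[m]; b <- channel_b$pixels[m]
  if (length(a) < 2) stop("mask must select at least 2 pixels")
  if (sd(a) == 0 || sd(b) == 0)
    stop("a channel is constant within the mask; correlation is undefined")
  cor(a, b)
}

coerce_mask <- function(mask, dims) {
  if (is.null(mask)) return(matrix(TRUE, dims[1], dims[2]))
  m <- if (inherits(mask, "roi_mask")) mask$mask else mask
  if (!identical(dim(m), dims)) stop("mask and image shapes differ")
  m
}

#' Joint 2D intensity histogram of two channels
#'
#' Counts masked pixel pairs over `bins` equal-width bins per channel
#' spanning each channel's masked min-max range; bins are half-open with
#' the last bin closed, so every masked pixel is counted exactly once.
#'
#' @inheritParams pearson_coloc
#' @param bins number of bins per channel (>= 2).
#' @return a list with `hist2d` (`bins x bins` count matrix, channel A on
#'   rows), `edges_a`, `edges_b` (bin edges) and `n_pixels`.
#' @export
intensity_histogram_2d <- function(channel_a, channel_b, mask = NULL, bins = 64) {
  stopifnot(inherits(channel_a, "micro_image"),
            inherits(channel_b, "micro_image"))
  if (!identical(dim(channel_a$pixels), dim(channel_b$pixels)))
    stop("channel shapes differ")
  if (!is.numeric(bins) || length(bins) != 1 || bins < 2)
    stop("`bins` must be a single integer >= 2")
  m <- coerce_mask(mask, dim(channel_a$pixels))
  if (sum(m) == 0) stop("mask selects no pixels")
  a <- channel_a$pixels[m]; b <- channel_b$pixels[m]
  bin_one <- function(v) {
    if (min(v) == max(v)) {
      list(idx = rep(1L, length(v)), edges = c(min(v), min(v) + 1))
    } else {
      edges <- seq(min(v), max(v), length.out = bins + 1)
      list(idx = findInterval(v, edges, rightmost.closed = TRUE), edges = edges)
    }
  }
  ba <- bin_one(a); bb <- bin_one(b)
  h <- matrix(0L, bins, bins)
  tab <- table(factor(ba$idx, levels = seq_len(bins)),
               factor(bb$idx, levels = seq_len(bins)))
  h[] <- as.integer(tab)
  list(hist2d = h, edges_a = ba$edges, edges_b = bb$edges, n_pixels = length(a))
}

#' Full two-channel colocalization summary
#'
#' Convenience wrapper returning the Pearson coefficient together with the
#' joint intensity histogram used to visualise it.
#'
#' @inheritParams intensity_histogram_2d
#' @return a `coloc_result` list: `pcc`, `n_pixels`, `hist2d`, `edges_a`,
#'   `edges_b`.
#' @export
coloc_analysis <- function(channel_a, channel_b, mask = NULL, bins = 64) {
  h <- intensity_histogram_2d(channel_a, channel_b, mask, bins)
  structure(c(list(pcc = pearson_coloc(channel_a, channel_b, mask)), h),
            class = "coloc_result")
}

#' @export
print.coloc_result <- function(x, ...) {
  cat(sprintf("<coloc_result> PCC = %.3f over %d masked pixels (%d x %d histogram)\n",
              x$pcc, x$n_pixels, nrow(x$hist2d), ncol(x$hist2d)))
  invisible(x)
}
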