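#' Cell footprint polygons
#'
#' A `cell_footprint` is a simple (non-self-intersecting) closed polygon in
#' the membrane plane, in nanometre coordinates, standing in for the
#' projected area of one adherent cell. Receptor point patterns are
#' generated inside it and the widefield forward model images it.
#'
#' @param boundary two-column numeric matrix of vertices (x, y) in nm, in
#'   order, without a repeated closing vertex.
#' @return an object of class `cell_footprint` with elements `boundary`
#'   (vertices shifted so the bounding box's lower-left corner is the
#'   origin), `area` (nm^2) and `bounding_box` (width, height in nm).
#' @export
cell_footprint <- function(boundary) {
  boundary <- as.matrix(boundary)
  if (ncol(boundary) != 2 || nrow(boundary) < 3 || !is.numeric(boundary))
    stop("`boundary` must be a numeric matrix with >= 3 rows and 2 columns")
  if (anyNA(boundary)) stop("`boundary` contains missing coordinates")
  if (!is_simple_polygon(boundary))
    stop("`boundary` is self-intersecting; footprints must be simple polygons")
  boundary <- sweep(boundary, 2, apply(boundary, 2, min))
  colnames(boundary) <- c("x", "y")
  area <- polygon_area(boundary)
  if (area <= 0) stop("footprint area must be positive")
  structure(list(boundary = boundary,
                 area = area,
                 bounding_box = apply(boundary, 2, max)),
            class = "cell_footprint")
}

#' @export
print.cell_footprint <- function(x, ...) {
  cat(sprintf("<cell_footprint> %d vertices, area %.1f um^2, bbox %.2f x %.2f um\n",
              nrow(x$boundary), x$area / 1e6,
              x$bounding_box[1] / 1e3, x$bounding_box[2] / 1e3))
  invisible(x)
}

# Shoelace formula; sign-free because vertex order is arbitrary.
polygon_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  j <- c(nrow(poly), seq_len(nrow(poly) - 1))
  abs(sum(x[j] * y - x * y[j])) / 2
}

# Brute-force O(n^2) proper-intersection test between non-adjacent edges.
is_simple_polygon <- function(poly) {
  n <- nrow(poly)
  nxt <- c(seq_len(n)[-1], 1)
  seg_intersect <- function(p1, p2, p3, p4) {
    d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
    d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
    d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
    (d1 * d2 < 0) && (d3 * d4 < 0)
  }
  for (i in seq_len(n - 2)) {
    for (j in (i + 1):n) {
      if (j == i || j == i %% n + 1 || i == j %% n + 1) next
      if (seg_intersect(poly[i, ], poly[nxt[i], ], poly[j, ], poly[nxt[j], ]))
        return(FALSE)
    }
  }
  TRUE
}

#' Sample a synthetic cell footprint
#'
#' Draws a star-shaped polygon by radially perturbing a circle: the radius
#' at angle theta is `mean_radius * (1 + irregularity * z(theta))`, where
#' `z` is a smooth random harmonic series rescaled to `max |z| = 1`. Because
#' the radial function is single-valued and strictly positive for
#' `irregularity < 1`, the polygon is simple by construction (the test suite
#' still verifies this against a brute-force segment-intersection oracle).
#'
#' @param rng_seed integer seed; identical seeds give identical polygons.
#' @param mean_radius mean radius in nm (default 5000 nm, a 10 um cell).
#' @param irregularity perturbation amplitude in `[0, 1)`; 0 gives a circle.
#' @param n_vertices number of polygon vertices.
#' @return a [cell_footprint()].
#' @examples
#' fp <- sample_cell_footprint(1, mean_radius = 5000, irregularity = 0.3)
#' fp$area / 1e6  # um^2
#' @export
sample_cell_footprint <- function(rng_seed, mean_radius = 5000,
                                  irregularity = 0.25, n_vertices = 72) {
  check_scalar(mean_radius, "mean_radius", lower = 0, lower_open = TRUE)
  check_scalar(irregularity, "irregularity", lower = 0, upper = 1, upper_open = TRUE)
  stopifnot(n_vertices >= 8)
  theta <- seq(0, 2 * pi, length.out = n_vertices + 1)[-(n_vertices + 1)]
  r <- with_seed(rng_seed, {
    if (irregularity == 0) rep(mean_radius, n_vertices) else {
      harmonics <- 2:5  # low order only: lobed outlines, no spikes
      a <- rnorm(length(harmonics)) / harmonics
      b <- rnorm(length(harmonics)) / harmonics
      z <- drop(cos(outer(theta, harmonics)) %*% a + sin(outer(theta, harmonics)) %*% b)
      z <- z / max(abs(z))
      mean_radius * (1 + irregularity * z)
    }
  })
  cell_footprint(cbind(r * cos(theta), r * sin(theta)))
}

#' Point-in-polygon test
#'
#' Vectorised even-odd (ray casting) rule. Used by all generators to
#' enforce the containment invariant.
#'
#' @param x,y point coordinates in nm.
#' @param footprint a [cell_footprint()] or a 2-column vertex matrix.
#' @return logical vector, `TRUE` for points inside.
#' @export
points_in_footprint <- function(x, y, footprint) {
  poly <- if (inherits(footprint, "cell_footprint")) footprint$boundary else as.matrix(footprint)
  px <- poly[, 1]; py <- poly[, 2]
  n <- nrow(poly)
  j <- c(n, seq_len(n - 1))
  inside <- logical(length(x))
  for (k in seq_len(n)) {
    xi <- px[k]; yi <- py[k]; xj <- px[j[k]]; yj <- py[j[k]]
    crosses <- ((yi > y) != (yj > y)) &
      (x < (xj - xi) * (y - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
  }
  inside
}

# Uniform points inside a footprint by rejection from the bounding box.
# Uses the current RNG stream (callers wrap in with_seed).
runif_in_footprint <- function(n, footprint) {
  out <- matrix(numeric(0), ncol = 2)
  bb <- footprint$bounding_box
  while (nrow(out) < n) {
    m <- max(16, ceiling((n - nrow(out)) * 1.8))
    cand <- cbind(runif(m, 0, bb[1]), runif(m, 0, bb[2]))
    keep <- points_in_footprint(cand[, 1], cand[, 2], footprint)
    out <- rbind(out, cand[keep, , drop = FALSE])
  }
  out[seq_len(n), , drop = FALSE]
}
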