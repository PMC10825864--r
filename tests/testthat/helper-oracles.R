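# Independent oracles and small builders used across the suite. These are
# deliberately written as naive brute-force algorithms, distinct from the
# package's implementations, so agreement is evidence rather than tautology.

# Winding-number point-in-polygon (the package uses even-odd ray casting).
oracle_point_in_polygon <- function(x, y, poly) {
  n <- nrow(poly)
  vapply(seq_along(x), function(i) {
    dx <- poly[, 1] - x[i]; dy <- poly[, 2] - y[i]
    ang <- atan2(dy, dx)
    d <- diff(c(ang, ang[1]))
    d <- ifelse(d > pi, d - 2 * pi, ifelse(d < -pi, d + 2 * pi, d))
    abs(sum(d)) > pi  # winding number != 0
  }, logical(1))
}

# Exhaustive O(n^2) segment-intersection simplicity check, written from the
# parametric line form rather than orientation tests.
oracle_is_simple_polygon <- function(poly) {
  n <- nrow(poly)
  seg <- function(i) rbind(poly[i, ], poly[i %% n + 1, ])
  intersects <- function(s1, s2) {
    d1 <- s1[2, ] - s1[1, ]; d2 <- s2[2, ] - s2[1, ]
    den <- d1[1] * d2[2] - d1[2] * d2[1]
    if (abs(den) < 1e-12) return(FALSE)
    b <- s2[1, ] - s1[1, ]
    t <- (b[1] * d2[2] - b[2] * d2[1]) / den
    u <- (b[1] * d1[2] - b[2] * d1[1]) / den
    t > 1e-9 && t < 1 - 1e-9 && u > 1e-9 && u < 1 - 1e-9
  }
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    adjacent <- j == i + 1 || (i == 1 && j == n)
    if (!adjacent && intersects(seg(i), seg(j))) return(FALSE)
  }
  TRUE
}

# Per-point nearest-neighbour distance by explicit double loop.
oracle_nn_distances <- function(pos) {
  n <- nrow(pos)
  out <- numeric(n)
  for (i in seq_len(n)) {
    best <- Inf
    for (j in seq_len(n)) {
      if (i == j) next
      d <- sqrt((pos[i, 1] - pos[j, 1])^2 + (pos[i, 2] - pos[j, 2])^2)
      if (d < best) best <- d
    }
    out[i] <- best
  }
  out
}

# Brute-force AIE rule: loops over all ordered pairs of labeled points.
oracle_aie_emissive <- function(pos, labeled, d_min, d_max) {
  n <- nrow(pos)
  out <- logical(n)
  for (i in seq_len(n)) {
    if (!labeled[i]) next
    for (j in seq_len(n)) {
      if (j == i || !labeled[j]) next
      d <- sqrt(sum((pos[i, ] - pos[j, ])^2))
      if (d >= d_min && d <= d_max) { out[i] <- TRUE; break }
    }
  }
  out
}

# Builders ------------------------------------------------------------------

circle_footprint <- function(radius = 5000, n = 96) {
  theta <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cell_footprint(cbind(radius * cos(theta), radius * sin(theta)))
}

square_footprint <- function(side = 1000) {
  cell_footprint(cbind(c(0, side, side, 0), c(0, 0, side, side)))
}

# Wrap nonnegative positions in a square footprint just big enough for them.
make_field <- function(pos, cluster_id = rep(-1L, nrow(pos)),
                       side = max(pos, 1) + 50) {
  receptor_field(pos, cluster_id, square_footprint(side))
}

disk_pixels <- function(nr, nc, cx, cy, r, fg, bg) {
  d2 <- outer(seq_len(nr) - cy, seq_len(nc) - cx, function(i, j) i^2 + j^2)
  matrix(ifelse(d2 <= r^2, fg, bg), nr, nc)
}

centering_offset <- function(footprint, optics) {
  (optics$image_shape * optics$pixel_size - footprint$bounding_box) / 2
}

# A one-cell AIE/conventional well; returns per-channel quantification.
# The clustered membrane carries the same dispersed pool as the dispersed
# one, so the two conditions differ only in the presence of clusters.
simulate_one_cell <- function(seed, clustered = TRUE, optics = optics_params(),
                              csr_intensity = 15, cl = cluster_params()) {
  fp <- sample_cell_footprint(derive_seed(seed, "fp"), 5000, 0.25)
  field <- if (clustered) {
    thomas <- sample_receptors_clustered(fp, cl, derive_seed(seed, "field"))
    bg <- sample_receptors_csr(fp, csr_intensity, derive_seed(seed, "bg"), 0)
    pos <- rbind(thomas$positions, bg$positions)
    keep <- aieclust:::enforce_hardcore(pos, cl$hardcore)
    receptor_field(pos[keep, , drop = FALSE],
                   c(thomas$cluster_id, bg$cluster_id)[keep], fp, cl$hardcore)
  } else sample_receptors_csr(fp, csr_intensity, derive_seed(seed, "field"),
                              cl$hardcore)
  off <- centering_offset(fp, optics)
  em_a <- aie_emission(field, rng_seed = derive_seed(seed, "la"))
  em_c <- conventional_emission(field, rng_seed = derive_seed(seed, "lc"))
  img_a <- render_image(em_a, optics, TRUE, derive_seed(seed, "na"), off)
  img_c <- render_image(em_c, optics, TRUE, derive_seed(seed, "nc"), off)
  mask <- segment_cells(img_c)
  list(field = field, img_aie = img_a, img_conv = img_c, mask = mask,
       mean_aie = mean_masked_intensity(img_a, mask)$mean_intensity,
       mean_conv = mean_masked_intensity(img_c, mask)$mean_intensity,
       snr_aie = compute_snr(img_a, mask),
       snr_conv = compute_snr(img_c, mask))
}
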