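#' Receptor point patterns
#'
#' A `receptor_field` is a planar point set of membrane receptors inside a
#' cell footprint, with a per-point cluster label (`-1` for dispersed
#' points, i.e. points not generated by or no longer belonging to a
#' cluster). Coordinates are continuous nanometres with the origin at the
#' footprint bounding box's lower-left corner.
#'
#' @param positions two-column numeric matrix (x, y) in nm.
#' @param cluster_id integer vector, `-1` or a non-negative parent index.
#' @param footprint the [cell_footprint()] the points live in.
#' @param hardcore hard-core (minimum separation) distance in nm that the
#'   generator enforced; stored for downstream reference.
#' @return an object of class `receptor_field`.
#' @export
receptor_field <- function(positions, cluster_id, footprint, hardcore = 0) {
  positions <- matrix(as.numeric(positions), ncol = 2,
                      dimnames = list(NULL, c("x", "y")))
  cluster_id <- as.integer(cluster_id)
  if (nrow(positions) != length(cluster_id))
    stop("`positions` and `cluster_id` lengths differ")
  if (!inherits(footprint, "cell_footprint"))
    stop("`footprint` must be a cell_footprint")
  if (nrow(positions) > 0 &&
      !all(points_in_footprint(positions[, 1], positions[, 2], footprint)))
    stop("all receptor positions must lie inside the footprint")
  structure(list(positions = positions, cluster_id = cluster_id,
                 footprint = footprint, hardcore = hardcore),
            class = "receptor_field")
}

#' @export
print.receptor_field <- function(x, ...) {
  n <- nrow(x$positions)
  ncl <- sum(x$cluster_id >= 0)
  cat(sprintf("<receptor_field> %d receptors (%d clustered in %d clusters, %d dispersed)\n",
              n, ncl, length(unique(x$cluster_id[x$cluster_id >= 0])), n - ncl))
  invisible(x)
}

#' @export
plot.receptor_field <- function(x, ...) {
  plot(x$footprint$boundary, type = "l", asp = 1,
       xlab = "x (nm)", ylab = "y (nm)", ...)
  graphics::polygon(x$footprint$boundary, border = "grey40")
  if (nrow(x$positions) > 0)
    graphics::points(x$positions, pch = 16, cex = 0.4,
                     col = ifelse(x$cluster_id >= 0, "firebrick", "grey30"))
  invisible(x)
}

#' @export
as.data.frame.receptor_field <- function(x, ...) {
  data.frame(x_nm = x$positions[, 1], y_nm = x$positions[, 2],
             cluster_id = x$cluster_id)
}

#' Thomas-process parameters for clustered receptor fields
#'
#' @param kappa parent (cluster centre) intensity, parents per um^2.
#' @param mu mean number of offspring receptors per cluster.
#' @param sigma isotropic Gaussian offspring scatter, nm.
#' @param hardcore minimum receptor separation, nm; antibody-bound
#'   receptors are sterically excluded from coinciding, and a positive
#'   value keeps the AIE lower distance bound meaningful.
#' @return a `cluster_params` list.
#' @export
cluster_params <- function(kappa = 0.4, mu = 25, sigma = 30, hardcore = 2) {
  check_scalar(kappa, "kappa", lower = 0)
  check_scalar(mu, "mu", lower = 0, lower_open = TRUE)
  check_scalar(sigma, "sigma", lower = 0, lower_open = TRUE)
  check_scalar(hardcore, "hardcore", lower = 0)
  structure(list(kappa = kappa, mu = mu, sigma = sigma, hardcore = hardcore),
            class = "cluster_params")
}

# Sequential (greedy) hard-core thinning in point order.
enforce_hardcore <- function(positions, h) {
  n <- nrow(positions)
  if (h <= 0 || n < 2) return(rep(TRUE, n))
  keep <- logical(n)
  keep[1] <- TRUE
  h2 <- h * h
  for (i in 2:n) {
    kept <- positions[keep, , drop = FALSE]
    d2 <- (kept[, 1] - positions[i, 1])^2 + (kept[, 2] - positions[i, 2])^2
    keep[i] <- all(d2 >= h2)
  }
  keep
}

#' Sample a dispersed (CSR) receptor field
#'
#' Homogeneous Poisson point pattern inside the footprint, thinned
#' sequentially to respect the hard-core distance. Models a low-clustering
#' membrane (e.g. a HER2-low cell line) where receptors sit far apart
#' relative to the AIE interaction window.
#'
#' @param footprint a [cell_footprint()].
#' @param intensity receptor intensity, receptors per um^2.
#' @param rng_seed integer seed.
#' @param hardcore minimum separation, nm.
#' @return a [receptor_field()] with all `cluster_id = -1`.
#' @export
sample_receptors_csr <- function(footprint, intensity, rng_seed, hardcore = 2) {
  check_scalar(intensity, "intensity", lower = 0)
  pos <- with_seed(rng_seed, {
    n <- rpois(1, intensity * footprint$area / 1e6)
    runif_in_footprint(n, footprint)
  })
  pos <- pos[enforce_hardcore(pos, hardcore), , drop = FALSE]
  receptor_field(pos, rep(-1L, nrow(pos)), footprint, hardcore)
}

#' Sample a clustered receptor field (Thomas process)
#'
#' Poisson parents of intensity `kappa` are placed uniformly in the
#' footprint; each parent draws a Poisson(`mu`) number of offspring
#' receptors scattered isotropically with standard deviation `sigma`.
#' Offspring falling outside the footprint are discarded and the hard-core
#' distance is enforced by sequential rejection, so realised counts run
#' slightly below `kappa * mu * area`.
#'
#' @param footprint a [cell_footprint()].
#' @param params a [cluster_params()].
#' @param rng_seed integer seed.
#' @return a [receptor_field()] with `cluster_id` = parent index (1-based).
#' @export
sample_receptors_clustered <- function(footprint, params = cluster_params(),
                                       rng_seed) {
  stopifnot(inherits(params, "cluster_params"))
  res <- with_seed(rng_seed, {
    n_par <- rpois(1, params$kappa * footprint$area / 1e6)
    if (n_par == 0) {
      list(pos = matrix(numeric(0), ncol = 2), id = integer(0))
    } else {
      parents <- runif_in_footprint(n_par, footprint)
      n_off <- rpois(n_par, params$mu)
      pos <- cbind(rep(parents[, 1], n_off) + rnorm(sum(n_off), 0, params$sigma),
                   rep(parents[, 2], n_off) + rnorm(sum(n_off), 0, params$sigma))
      id <- rep(seq_len(n_par), n_off)
      keep <- if (nrow(pos) > 0)
        points_in_footprint(pos[, 1], pos[, 2], footprint) else logical(0)
      list(pos = pos[keep, , drop = FALSE], id = id[keep])
    }
  })
  keep <- enforce_hardcore(res$pos, params$hardcore)
  receptor_field(res$pos[keep, , drop = FALSE], res$id[keep],
                 footprint, params$hardcore)
}

#' Disruption model parameters
#'
#' Separable dose/time model for therapeutic disruption of receptor
#' clusters: a clustered receptor is relocated to a uniform position in
#' the footprint (losing its cluster membership, not its existence) with
#' probability
#' `p(dose, time) = p_max * (1 - exp(-time / tau)) * dose^hill / (dose^hill + ec50^hill)`.
#' Hill-in-dose captures saturating occupancy of the drug target;
#' saturating-exponential-in-time captures first-order approach to the
#' treated steady state.
#'
#' @param p_max maximum relocation probability, in `[0, 1]`.
#' @param ec50 dose of half-maximal effect, ug/mL.
#' @param hill Hill coefficient (> 0, dimensionless).
#' @param tau time constant, hours.
#' @return a `disruption_params` list.
#' @export
disruption_params <- function(p_max = 0.8, ec50 = 1, hill = 1, tau = 8) {
  check_scalar(p_max, "p_max", lower = 0, upper = 1)
  check_scalar(ec50, "ec50", lower = 0, lower_open = TRUE)
  check_scalar(hill, "hill", lower = 0, lower_open = TRUE)
  check_scalar(tau, "tau", lower = 0, lower_open = TRUE)
  structure(list(p_max = p_max, ec50 = ec50, hill = hill, tau = tau),
            class = "disruption_params")
}

#' Relocation probability of the disruption model
#'
#' @param dose dose in ug/mL (vectorised).
#' @param time exposure time in hours (vectorised).
#' @param params a [disruption_params()].
#' @return probability in `[0, 1]`.
#' @export
disruption_probability <- function(dose, time, params) {
  stopifnot(inherits(params, "disruption_params"))
  dh <- dose^params$hill
  ifelse(dose <= 0 | time <= 0, 0,
         params$p_max * (1 - exp(-time / params$tau)) * dh / (dh + params$ec50^params$hill))
}

#' Apply dose/time-dependent cluster disruption
#'
#' Each clustered receptor is independently relocated to a uniform
#' position inside the footprint, with its `cluster_id` set to `-1`, with
#' probability [disruption_probability()]. The total receptor count is
#' conserved exactly: the drug disperses clusters, it does not remove
#' receptors, matching a proximity-insensitive control channel that stays
#' flat under treatment. `dose = 0` or `time = 0` returns the field
#' unchanged.
#'
#' The per-point relocation uniforms are drawn for every point before any
#' destination is drawn, so for a fixed seed the set of relocated points is
#' nested and monotone in the relocation probability (common-random-numbers
#' coupling across doses).
#'
#' @param field a [receptor_field()].
#' @param dose dose in ug/mL (>= 0).
#' @param time exposure time in hours (>= 0).
#' @param params a [disruption_params()].
#' @param rng_seed integer seed.
#' @return a [receptor_field()] with the same number of points.
#' @export
apply_disruption <- function(field, dose, time, params, rng_seed) {
  stopifnot(inherits(field, "receptor_field"),
            inherits(params, "disruption_params"))
  check_scalar(dose, "dose", lower = 0)
  check_scalar(time, "time", lower = 0)
  p <- disruption_probability(dose, time, params)
  if (p == 0) return(field)
  n <- nrow(field$positions)
  if (n == 0) return(field)
  with_seed(rng_seed, {
    u <- runif(n)
    move <- field$cluster_id >= 0 & u < p
    pos <- field$positions
    id <- field$cluster_id
    if (any(move)) {
      pos[move, ] <- runif_in_footprint(sum(move), field$footprint)
      id[move] <- -1L
    }
    receptor_field(pos, id, field$footprint, field$hardcore)
  })
}

#' Nearest-neighbour distances of a receptor field
#'
#' @param field a [receptor_field()] with at least two points.
#' @return numeric vector, per-point distance (nm) to its nearest other
#'   point.
#' @export
nearest_neighbor_distances <- function(field) {
  stopifnot(inherits(field, "receptor_field"))
  n <- nrow(field$positions)
  if (n < 2)
    stop("nearest-neighbour distances are undefined for fields with fewer than 2 points")
  dm <- as.matrix(dist(field$positions))
  diag(dm) <- Inf
  unname(apply(dm, 1, min))
}

#' Write / read a receptor field as CSV
#'
#' Columns `x_nm`, `y_nm`, `cluster_id`; coordinates are printed with full
#' double precision so the round trip is lossless.
#'
#' @param field a [receptor_field()].
#' @param path file path.
#' @rdname receptor_csv
#' @export
write_receptor_csv <- function(field, path) {
  df <- as.data.frame(field)
  df$x_nm <- format(df$x_nm, digits = 17, trim = TRUE, scientific = FALSE)
  df$y_nm <- format(df$y_nm, digits = 17, trim = TRUE, scientific = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @param footprint the [cell_footprint()] the stored points belong to.
#' @rdname receptor_csv
#' @export
read_receptor_csv <- function(path, footprint) {
  df <- read.csv(path)
  need <- c("x_nm", "y_nm", "cluster_id")
  if (!all(need %in% names(df)))
    stop("receptor CSV must have columns x_nm, y_nm, cluster_id")
  receptor_field(cbind(df$x_nm, df$y_nm), df$cluster_id, footprint)
}
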