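#' AIE emission-rule parameters
#'
#' The AIE fluorophore turns on only when its intramolecular motion is
#' restricted by a nearby partner fluorophore. Ground-state geometry of the
#' dye bounds the distance window over which two antibody-borne
#' fluorophores can restrict each other: 2.13 nm when the short faces
#' interact, 6.62 nm tip-to-tip. The defaults encode that window.
#'
#' @param d_min minimum interaction distance, nm.
#' @param d_max maximum interaction distance, nm.
#' @param unit_brightness expected photons emitted per emissive fluorophore
#'   per exposure.
#' @return an `aie_params` list.
#' @export
aie_params <- function(d_min = 2.13, d_max = 6.62, unit_brightness = 150) {
  check_scalar(d_min, "d_min", lower = 0)
  check_scalar(d_max, "d_max", lower = d_min, lower_open = TRUE)
  check_scalar(unit_brightness, "unit_brightness", lower = 0, lower_open = TRUE)
  structure(list(d_min = d_min, d_max = d_max,
                 unit_brightness = unit_brightness),
            class = "aie_params")
}

new_emission_field <- function(positions, labeled, emissive, brightness) {
  structure(list(positions = positions, labeled = labeled,
                 emissive = emissive, brightness = brightness),
            class = "emission_field")
}

#' @export
print.emission_field <- function(x, ...) {
  cat(sprintf("<emission_field> %d fluorophore sites, %d labeled, %d emissive, total brightness %.0f photons\n",
              nrow(x$positions), sum(x$labeled), sum(x$emissive),
              sum(x$brightness)))
  invisible(x)
}

# Labeling is Bernoulli per receptor; optionally the number of dyes carried
# by each labeled antibody is Poisson with the measured mean dye-to-antibody
# ratio, all dyes co-located at the receptor position.
draw_labels <- function(n, labeling_efficiency, dye_mode, dar) {
  labeled <- runif(n) < labeling_efficiency
  n_dyes <- if (dye_mode == "poisson_dar") rpois(n, dar) else rep(1L, n)
  n_dyes[!labeled] <- 0L
  list(labeled = labeled & n_dyes > 0, n_dyes = n_dyes)
}

#' Proximity-gated (AIE) emission of a receptor field
#'
#' Each receptor is labeled with probability `labeling_efficiency`. A
#' labeled fluorophore is emissive iff at least one *other* labeled
#' fluorophore lies within the closed distance window
#' `[d_min, d_max]` — the geometric footprint of mutual motion
#' restriction. Emission is binary: emissive fluorophores contribute
#' `unit_brightness` photons (times their dye count in `"poisson_dar"`
#' mode), the rest contribute nothing. Co-located dyes on one antibody sit
#' at distance 0 < `d_min` and do not gate each other.
#'
#' @param field a [receptor_field()].
#' @param params an [aie_params()].
#' @param labeling_efficiency probability in `(0, 1]` that a receptor
#'   carries a labeled antibody.
#' @param rng_seed integer seed (labeling randomness).
#' @param dye_mode `"single"` (one fluorophore per labeled receptor) or
#'   `"poisson_dar"` (Poisson dye count with mean `dar`).
#' @param dar mean dye-to-antibody ratio for `"poisson_dar"` mode.
#' @return an `emission_field`.
#' @export
aie_emission <- function(field, params = aie_params(), labeling_efficiency = 0.9,
                         rng_seed, dye_mode = c("single", "poisson_dar"),
                         dar = 1.35) {
  stopifnot(inherits(field, "receptor_field"), inherits(params, "aie_params"))
  check_scalar(labeling_efficiency, "labeling_efficiency",
               lower = 0, upper = 1, lower_open = TRUE)
  dye_mode <- match.arg(dye_mode)
  n <- nrow(field$positions)
  lab <- with_seed(rng_seed, draw_labels(n, labeling_efficiency, dye_mode, dar))
  emissive <- logical(n)
  idx <- which(lab$labeled)
  if (length(idx) >= 2) {
    dm <- as.matrix(dist(field$positions[idx, , drop = FALSE]))
    diag(dm) <- Inf
    # closed interval, with a 1e-9 relative guard so distances constructed
    # to sit exactly on a boundary are not lost to floating rounding
    tol <- 1e-9 * params$d_max
    emissive[idx] <- apply(dm >= params$d_min - tol & dm <= params$d_max + tol,
                           1, any)
  }
  brightness <- ifelse(emissive, params$unit_brightness * lab$n_dyes, 0)
  new_emission_field(field$positions, lab$labeled, emissive, brightness)
}

#' Proximity-insensitive (conventional dye) emission
#'
#' Control-channel rule: every labeled fluorophore is emissive regardless
#' of geometry, so total brightness tracks receptor count, not receptor
#' arrangement.
#'
#' @inheritParams aie_emission
#' @param unit_brightness photons per emissive fluorophore per exposure.
#' @return an `emission_field`.
#' @export
conventional_emission <- function(field, unit_brightness = 150,
                                  labeling_efficiency = 0.9, rng_seed,
                                  dye_mode = c("single", "poisson_dar"),
                                  dar = 1.35) {
  stopifnot(inherits(field, "receptor_field"))
  check_scalar(unit_brightness, "unit_brightness", lower = 0, lower_open = TRUE)
  check_scalar(labeling_efficiency, "labeling_efficiency",
               lower = 0, upper = 1, lower_open = TRUE)
  dye_mode <- match.arg(dye_mode)
  n <- nrow(field$positions)
  lab <- with_seed(rng_seed, draw_labels(n, labeling_efficiency, dye_mode, dar))
  new_emission_field(field$positions, lab$labeled, lab$labeled,
                     ifelse(lab$labeled, unit_brightness * lab$n_dyes, 0))
}
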