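#' Dye-to-antibody ratio from a MALDI mass shift
#'
#' The average number of dye molecules conjugated per antibody is the
#' observed mass shift between the bare and conjugated antibody divided by
#' the mass added per coupled dye. The result is truncated (not rounded)
#' to two decimal places, matching the convention under which
#' 1015 / 749 = 1.3551... is reported as 1.35.
#'
#' @param mass_shift observed m/z shift, Da.
#' @param dye_mass mass added per conjugated dye, Da.
#' @return the dye-to-antibody ratio, truncated to two decimals.
#' @examples
#' dye_antibody_ratio(1015, 749)  # 1.35
#' @export
dye_antibody_ratio <- function(mass_shift, dye_mass) {
  check_scalar(mass_shift, "mass_shift", lower = 0)
  check_scalar(dye_mass, "dye_mass", lower = 0, lower_open = TRUE)
  trunc(100 * mass_shift / dye_mass) / 100
}

#' Stokes shift of a fluorophore
#'
#' Difference between the emission and absorption maxima. Anti-Stokes
#' (emission bluer than absorption) is rejected rather than signed.
#'
#' @param absorption_max absorption maximum, nm.
#' @param emission_max emission maximum, nm.
#' @return Stokes shift, nm.
#' @examples
#' stokes_shift(354, 518)  # 164
#' @export
stokes_shift <- function(absorption_max, emission_max) {
  check_scalar(absorption_max, "absorption_max", lower = 0, lower_open = TRUE)
  check_scalar(emission_max, "emission_max", lower = 0, lower_open = TRUE)
  if (emission_max < absorption_max)
    stop("emission maximum below absorption maximum: anti-Stokes shifts are out of scope")
  emission_max - absorption_max
}
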