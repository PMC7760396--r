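#' Physical constants for hemodynamic post-processing
#'
#' Bundles the fluid properties and cycle timing used throughout the package.
#' Internally everything is SI (m, s, Pa); reporting units (cm\eqn{^2}, mL,
#' mmHg, mW) are applied only at output boundaries via [mmHgFromPa()] and
#' friends.
#'
#' @param density Blood density in kg/m^3.
#' @param kinematic_viscosity Kinematic viscosity in m^2/s.
#' @param cycle_period Cardiac cycle duration in s.
#' @return An object of class `physical_constants`.
#' @examples
#' physicalConstants()
#' @export
physicalConstants <- function(density = 1000,
                              kinematic_viscosity = 3.5e-6,
                              cycle_period = 0.86) {
  stopifnot(density > 0, kinematic_viscosity > 0, cycle_period > 0)
  structure(
    list(
      density = density,
      kinematic_viscosity = kinematic_viscosity,
      dynamic_viscosity = density * kinematic_viscosity,
      cycle_period = cycle_period,
      pa_per_mmHg = 133.322
    ),
    class = "physical_constants"
  )
}

#' @export
print.physical_constants <- function(x, ...) {
  cat("Physical constants:\n")
  cat(sprintf("  density             %g kg/m^3\n", x$density))
  cat(sprintf("  kinematic viscosity %g m^2/s\n", x$kinematic_viscosity))
  cat(sprintf("  cycle period        %g s\n", x$cycle_period))
  invisible(x)
}

#' Unit conversions at reporting boundaries
#'
#' Pressures are held in Pa internally and reported in mmHg; powers in W,
#' reported in mW. The conversions are exact inverses of each other.
#'
#' @param p Pressure in Pa (`mmHgFromPa`) or mmHg (`paFromMmHg`).
#' @param w Power in W (`mWFromW`) or mW (`wFromMW`).
#' @return Converted numeric vector.
#' @export
mmHgFromPa <- function(p) p / 133.322

#' @rdname mmHgFromPa
#' @export
paFromMmHg <- function(p) p * 133.322

#' @rdname mmHgFromPa
#' @export
mWFromW <- function(w) w * 1000

#' @rdname mmHgFromPa
#' @export
wFromMW <- function(w) w / 1000
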