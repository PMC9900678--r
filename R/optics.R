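#' Optical properties of a tissue region
#'
#' Bundles an absorption coefficient \eqn{\mu_a} and a reduced scattering
#' coefficient \eqn{\mu_s'} (both in 1/mm) and derives the diffusion
#' coefficient \eqn{D = 1/(3(\mu_a + \mu_s'))} (mm) used by the
#' frequency-domain diffusion model.
#'
#' @param mu_a Absorption coefficient, 1/mm. Must be positive.
#' @param mu_s_prime Reduced scattering coefficient, 1/mm. Must be positive.
#' @return An object of class `optical_properties` with fields `mu_a`,
#'   `mu_s_prime` and the derived `D`.
#' @examples
#' op <- optical_properties(0.0059, 0.69)
#' op$D  # 1 / (3 * (0.0059 + 0.69))
#' @export
optical_properties <- function(mu_a, mu_s_prime) {
  stopifnot(is.numeric(mu_a), length(mu_a) == 1L, is.finite(mu_a),
            is.numeric(mu_s_prime), length(mu_s_prime) == 1L,
            is.finite(mu_s_prime))
  if (mu_a <= 0) stop("mu_a must be > 0")
  if (mu_s_prime <= 0) stop("mu_s_prime must be > 0")
  structure(
    list(mu_a = mu_a, mu_s_prime = mu_s_prime,
         D = 1 / (3 * (mu_a + mu_s_prime))),
    class = "optical_properties"
  )
}

#' @export
print.optical_properties <- function(x, ...) {
  cat(sprintf("optical properties: mu_a = %.4g /mm, mu_s' = %.4g /mm, D = %.4g mm\n",
              x$mu_a, x$mu_s_prime, x$D))
  invisible(x)
}

# Vacuum light speed in mm/s.
C_VACUUM_MM_S <- 2.99792458e11

#' Acquisition configuration for a circular FD-DOT system
#'
#' Describes the source/detector layout on the phantom circumference and the
#' physical constants of the frequency-domain measurement. `m` sources sit at
#' equally spaced angles \eqn{2\pi k/m} (counter-clockwise, starting near 0
#' degrees); for each source the remaining `m - 1` positions act as detectors,
#' giving `m * (m - 1)` amplitude and phase observations.
#'
#' @param n_sources Number of source positions `m` (>= 4). The reference
#'   layouts are 16, 20 and 36.
#' @param frequency_mhz Modulation frequency in MHz (0 for CW).
#' @param refractive_index Tissue refractive index; the light speed inside the
#'   medium is `c_vacuum / refractive_index`.
#' @param boundary_coefficient Robin boundary-condition coefficient `A`
#'   (dimensionless); `A = 1` means no refractive-index mismatch at the
#'   surface.
#' @param noise_level Relative standard deviation of the measurement noise
#'   added by [add_noise()]; the reference setting is 0.15.
#' @return An `acquisition_config` object. `n_detectors` is always
#'   `n_sources - 1`; `c_medium` is in mm/s and `omega` in rad/s.
#' @export
acquisition_config <- function(n_sources = 16L,
                               frequency_mhz = 20,
                               refractive_index = 1.4,
                               boundary_coefficient = 1,
                               noise_level = 0.15) {
  n_sources <- as.integer(n_sources)
  if (n_sources < 4L) stop("n_sources must be >= 4")
  if (frequency_mhz < 0) stop("frequency_mhz must be >= 0")
  if (noise_level < 0) stop("noise_level must be >= 0")
  structure(
    list(n_sources = n_sources,
         n_detectors = n_sources - 1L,
         frequency_mhz = frequency_mhz,
         omega = 2 * pi * frequency_mhz * 1e6,
         refractive_index = refractive_index,
         c_medium = C_VACUUM_MM_S / refractive_index,
         boundary_coefficient = boundary_coefficient,
         noise_level = noise_level),
    class = "acquisition_config"
  )
}

#' @export
print.acquisition_config <- function(x, ...) {
  cat(sprintf("FD-DOT acquisition: %d sources x %d detectors, %g MHz, A = %g, noise %g\n",
              x$n_sources, x$n_detectors, x$frequency_mhz,
              x$boundary_coefficient, x$noise_level))
  invisible(x)
}

# Source positions (angles, radians) for an acquisition on a circle.
source_angles <- function(acq) 2 * pi * (seq_len(acq$n_sources) - 1L) / acq$n_sources
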