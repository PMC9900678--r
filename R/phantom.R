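#' Specification of a circular phantom with circular inclusions
#'
#' A phantom is a disk of given diameter with homogeneous background optical
#' properties and up to two disjoint circular inclusions strictly inside the
#' boundary. The modulation frequency is part of the specification because
#' each simulated sample carries its own driving frequency.
#'
#' @param diameter_mm Phantom diameter, mm.
#' @param background [optical_properties()] of the background medium.
#' @param inclusions List of inclusions, each a list with fields
#'   `center` (length-2 numeric, mm, relative to the phantom center),
#'   `radius` (mm) and `props` ([optical_properties()]).
#' @param frequency_mhz Modulation frequency, MHz.
#' @param margin_mm Minimal clearance required between an inclusion and the
#'   phantom boundary (validation only).
#' @return A `phantom_spec` object.
#' @export
phantom_spec <- function(diameter_mm, background, inclusions = list(),
                         frequency_mhz = 20, margin_mm = 0) {
  stopifnot(inherits(background, "optical_properties"),
            is.numeric(diameter_mm), diameter_mm > 0)
  R <- diameter_mm / 2
  for (inc in inclusions) {
    stopifnot(length(inc$center) == 2L, inc$radius > 0,
              inherits(inc$props, "optical_properties"))
    if (sqrt(sum(inc$center^2)) + inc$radius + margin_mm >= R)
      stop("inclusion touches or crosses the phantom boundary")
  }
  if (length(inclusions) == 2L) {
    d <- sqrt(sum((inclusions[[1L]]$center - inclusions[[2L]]$center)^2))
    if (d <= inclusions[[1L]]$radius + inclusions[[2L]]$radius)
      stop("inclusions overlap")
  }
  if (length(inclusions) > 2L) stop("at most two inclusions are supported")
  structure(
    list(diameter_mm = diameter_mm, radius_mm = R, background = background,
         inclusions = inclusions, frequency_mhz = frequency_mhz),
    class = "phantom_spec"
  )
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("phantom: diameter %g mm, %d inclusion(s), %g MHz\n",
              x$diameter_mm, length(x$inclusions), x$frequency_mhz))
  cat(sprintf("  background mu_a %.4g, mu_s' %.4g\n",
              x$background$mu_a, x$background$mu_s_prime))
  for (inc in x$inclusions)
    cat(sprintf("  inclusion r %.3g mm at (%.3g, %.3g), mu_a %.4g, mu_s' %.4g\n",
                inc$radius, inc$center[1], inc$center[2],
                inc$props$mu_a, inc$props$mu_s_prime))
  invisible(x)
}

#' Sampling ranges for random phantom specifications
#'
#' Defaults follow the simulation-study protocol: phantom diameters 60--150
#' mm, frequencies 10--100 MHz, background absorption 0.005--0.03 /mm and
#' background reduced scattering 0.05--3 /mm. Inclusion radii are uniform on
#' 2.5--15 mm (clamped so the disk fits with a 2 mm margin) and inclusion
#' properties are the background scaled by an independent uniform contrast in
#' 1.2--4 per coefficient.
#'
#' @param diameter,frequency,mu_a,mu_s_prime,inclusion_radius,contrast
#'   Length-2 numeric ranges (min, max).
#' @param margin_mm Clearance between inclusion and boundary, mm.
#' @return A list of ranges used by [sample_spec()].
#' @export
spec_ranges <- function(diameter = c(60, 150),
                        frequency = c(10, 100),
                        mu_a = c(0.005, 0.03),
                        mu_s_prime = c(0.05, 3),
                        inclusion_radius = c(2.5, 15),
                        contrast = c(1.2, 4),
                        margin_mm = 2) {
  rng <- list(diameter = diameter, frequency = frequency, mu_a = mu_a,
              mu_s_prime = mu_s_prime, inclusion_radius = inclusion_radius,
              contrast = contrast, margin_mm = margin_mm)
  for (nm in setdiff(names(rng), "margin_mm"))
    stopifnot(length(rng[[nm]]) == 2L, rng[[nm]][1] <= rng[[nm]][2])
  rng
}

runif1 <- function(range) stats::runif(1L, range[1], range[2])

#' Draw a random phantom specification
#'
#' Uniformly samples diameter, frequency and background properties from the
#' configured ranges, then places `n_inclusions` random disks with uniform
#' radius (clamped to fit inside the boundary with a margin) and center
#' uniform over the admissible region. For two inclusions, disjointness is
#' enforced by rejection sampling.
#'
#' @param seed Integer seed; the draw is fully reproducible.
#' @param n_inclusions 1 or 2.
#' @param ranges Sampling ranges from [spec_ranges()].
#' @param max_attempts Rejection-sampling budget for the disjointness
#'   constraint.
#' @return A [phantom_spec()].
#' @export
sample_spec <- function(seed, n_inclusions = 1L, ranges = spec_ranges(),
                        max_attempts = 1000L) {
  stopifnot(n_inclusions %in% c(1L, 2L))
  with_local_seed(seed, {
    diameter <- runif1(ranges$diameter)
    R <- diameter / 2
    freq <- runif1(ranges$frequency)
    bg <- optical_properties(runif1(ranges$mu_a), runif1(ranges$mu_s_prime))
    draw_inclusion <- function() {
      r_max <- min(ranges$inclusion_radius[2], R - ranges$margin_mm - 1e-6)
      r <- stats::runif(1L, min(ranges$inclusion_radius[1], r_max), r_max)
      rho_max <- R - ranges$margin_mm - r
      rho <- rho_max * sqrt(stats::runif(1L))
      th <- stats::runif(1L, 0, 2 * pi)
      list(center = rho * c(cos(th), sin(th)), radius = r,
           props = optical_properties(bg$mu_a * runif1(ranges$contrast),
                                      bg$mu_s_prime * runif1(ranges$contrast)))
    }
    incs <- list(draw_inclusion())
    if (n_inclusions == 2L) {
      ok <- FALSE
      for (i in seq_len(max_attempts)) {
        cand <- draw_inclusion()
        d <- sqrt(sum((cand$center - incs[[1L]]$center)^2))
        if (d > cand$radius + incs[[1L]]$radius + 0.5) {
          incs[[2L]] <- cand; ok <- TRUE; break
        }
      }
      if (!ok) stop("could not place disjoint inclusions after ", max_attempts,
                    " attempts")
    }
    phantom_spec(diameter, bg, incs, frequency_mhz = freq,
                 margin_mm = ranges$margin_mm / 2)
  })
}

#' Rasterize a phantom onto the 64x64 ground-truth grid
#'
#' The raster covers the phantom's bounding square exactly, so the pixel size
#' is `diameter / 64`. Each pixel takes the property values of the region its
#' center point falls in (inclusion, background, or 0 outside the phantom
#' disk); there is no anti-aliasing, mirroring how ground-truth images are
#' formed directly from the phantom parameters on a rectangular grid.
#'
#' @param spec A [phantom_spec()].
#' @param size Grid size per side (default 64).
#' @return A `property_image`: list with `mu_a` and `mu_s_prime` 64x64
#'   matrices (row index = x, column index = y, both increasing), logical
#'   `mask` of in-phantom pixels, and `pixel_mm`.
#' @export
rasterize <- function(spec, size = 64L) {
  R <- spec$radius_mm
  px <- spec$diameter_mm / size
  centers <- -R + (seq_len(size) - 0.5) * px
  X <- matrix(centers, size, size)
  Y <- matrix(centers, size, size, byrow = TRUE)
  mask <- X^2 + Y^2 <= R^2
  mu_a <- ifelse(mask, spec$background$mu_a, 0)
  mu_s <- ifelse(mask, spec$background$mu_s_prime, 0)
  for (inc in spec$inclusions) {
    inside <- (X - inc$center[1])^2 + (Y - inc$center[2])^2 <= inc$radius^2
    mu_a[inside] <- inc$props$mu_a
    mu_s[inside] <- inc$props$mu_s_prime
  }
  structure(list(mu_a = mu_a, mu_s_prime = mu_s, mask = mask, pixel_mm = px),
            class = "property_image")
}
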