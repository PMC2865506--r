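# Cuboidal sensorium geometry: the detection volume around the fish is
# idealized as a cuboid of height H, length L and width W; its frontal
# silhouette in the direction of travel is A(alpha) = W (L sin a + H cos a)
# for body pitch alpha.

#' Cuboidal sensorium
#'
#' Construct the cuboidal idealization of the volume within which a prey item
#' is detectable. The default dimensions are the electrosensory detection
#' cuboid of a 19 cm black ghost knifefish for a ~3 mm *Daphnia* prey:
#' height 12.5 cm, length 26.9 cm, width 11.6 cm.
#'
#' @param height_m cuboid height in metres (vertical extent at zero pitch).
#' @param length_m cuboid length in metres (along the body axis).
#' @param width_m cuboid width in metres (left-right extent).
#' @param label free-text label carried through outputs.
#'
#' @return An object of class `cuboid_sensorium`.
#' @seealso [projected_area()], [with_elongation()], [moroko_sensorium()]
#' @examples
#' cub <- cuboid_sensorium()
#' projected_area(cub, 0)   # W * H
#' elongation_factor(cub)   # ~2.15, printed as 2.2
#' @export
cuboid_sensorium <- function(height_m = 0.125, length_m = 0.269,
                             width_m = 0.116, label = "electrosensory") {
  dims <- c(height_m = height_m, length_m = length_m, width_m = width_m)
  if (!is.numeric(dims) || !all(is.finite(dims)) || any(dims <= 0)) {
    stop_domain("all cuboid dimensions must be finite and strictly positive")
  }
  structure(
    list(height_m = height_m, length_m = length_m, width_m = width_m,
         label = as.character(label)[1]),
    class = "cuboid_sensorium"
  )
}

#' Stone moroko visual sensorium preset
#'
#' Cuboidal approximation of the measured visual detection volume of the stone
#' moroko (*Pseudorasbora parva*), a visually guided predator of *Daphnia*:
#' 11.9 cm high, 12.0 cm long (eye to leading edge), 18.7 cm wide. Its
#' pitch-relevant elongation factor (length/height) is essentially 1, so the
#' projected area barely changes with pitch; its azimuthal elongation
#' (width/height ~1.57) is the relevant ratio for left-right sweeping, which
#' this package does not model. The cuboid overestimates the effect of
#' pitching the animal's roughly conical visual volume.
#'
#' @return A `cuboid_sensorium`.
#' @export
moroko_sensorium <- function() {
  cuboid_sensorium(height_m = 0.119, length_m = 0.120, width_m = 0.187,
                   label = "stone moroko visual")
}

#' @export
print.cuboid_sensorium <- function(x, ...) {
  cat(sprintf("Cuboidal sensorium (%s)\n", x$label))
  cat(sprintf("  H = %.3f m, L = %.3f m, W = %.3f m\n",
              x$height_m, x$length_m, x$width_m))
  cat(sprintf("  elongation factor e = L/H = %.3f\n", elongation_factor(x)))
  cat(sprintf("  area-maximizing pitch = %.2f deg (max ratio %.3f)\n",
              area_maximizing_pitch(x), sqrt(1 + elongation_factor(x)^2)))
  invisible(x)
}

check_cuboid <- function(cuboid) {
  if (!inherits(cuboid, "cuboid_sensorium")) {
    stop_domain("`cuboid` must be a cuboid_sensorium object")
  }
  invisible(cuboid)
}

#' Elongation factor of a sensorium
#'
#' Ratio of cuboid length to height, the shape parameter that controls how
#' much the projected frontal area grows as the body pitches.
#'
#' @param cuboid a [cuboid_sensorium()].
#' @return Dimensionless length/height ratio.
#' @export
elongation_factor <- function(cuboid) {
  check_cuboid(cuboid)
  cuboid$length_m / cuboid$height_m
}

#' Projected frontal area of the sensorium
#'
#' Area of the cuboid silhouette on a plane perpendicular to the direction of
#' travel when the body (and with it the sensorium) is pitched by
#' `pitch_deg`: `A(alpha) = W * (L * sin(alpha) + H * cos(alpha))`.
#' This area, times swimming distance, is the volume of water scanned for
#' prey.
#'
#' @param cuboid a [cuboid_sensorium()].
#' @param pitch_deg body pitch angle magnitude in degrees, in \[0, 90\].
#'   Vectorized.
#' @return Projected area in m^2.
#' @examples
#' projected_area(cuboid_sensorium(), c(0, 30, 90))
#' @export
projected_area <- function(cuboid, pitch_deg) {
  check_cuboid(cuboid)
  check_pitch(pitch_deg)
  a <- deg2rad(pitch_deg)
  cuboid$width_m * (cuboid$length_m * sin(a) + cuboid$height_m * cos(a))
}

#' Projected-area ratio relative to neutral pitch
#'
#' `A(alpha) / A(0) = e * sin(alpha) + cos(alpha)` with elongation factor
#' `e = L/H`; independent of the cuboid width. This equals the factor by
#' which the prey encounter rate per unit distance increases at pitch
#' `alpha`.
#'
#' @inheritParams projected_area
#' @return Dimensionless ratio (1 at zero pitch).
#' @export
area_ratio <- function(cuboid, pitch_deg) {
  projected_area(cuboid, pitch_deg) / projected_area(cuboid, 0)
}

#' Pitch angle maximizing the projected area
#'
#' The projected area increases with pitch up to `atan(L/H)` and decreases
#' beyond it; the maximal area ratio there is `sqrt(1 + e^2)`.
#'
#' @inheritParams elongation_factor
#' @return Angle in degrees.
#' @export
area_maximizing_pitch <- function(cuboid) {
  check_cuboid(cuboid)
  rad2deg(atan(cuboid$length_m / cuboid$height_m))
}

#' Rescale the sensorium to a given elongation factor
#'
#' Returns a cuboid whose length is `e` times its height, with height and
#' width unchanged. Used for the shape thought experiments (blunt `e = 1`
#' versus elongated `e = 4` sensoria).
#'
#' @inheritParams elongation_factor
#' @param e target elongation factor (length/height), strictly positive.
#' @return A new `cuboid_sensorium`.
#' @export
with_elongation <- function(cuboid, e) {
  check_cuboid(cuboid)
  if (!is.numeric(e) || length(e) != 1L || !is.finite(e) || e <= 0) {
    stop_domain("elongation factor `e` must be a single finite positive number")
  }
  cuboid_sensorium(height_m = cuboid$height_m,
                   length_m = e * cuboid$height_m,
                   width_m = cuboid$width_m,
                   label = sprintf("%s (e = %g)", cuboid$label, e))
}

#' Projected-area curve over a pitch grid
#'
#' @inheritParams projected_area
#' @param pitch_deg grid of pitch angles in degrees (default 0--90 at 0.1).
#' @return A data frame with columns `pitch_deg`, `area_m2`, `ratio`,
#'   suitable for CSV export with [utils::write.csv()].
#' @export
area_curve <- function(cuboid, pitch_deg = seq(0, 90, by = 0.1)) {
  a <- projected_area(cuboid, pitch_deg)
  data.frame(pitch_deg = pitch_deg, area_m2 = a, ratio = a / a[1])
}
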