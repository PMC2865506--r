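# Ribbon-fin thrust. The mean propulsive force of a sinusoidally undulating
# ribbon fin follows the correlation
#   F_surge = C * rho * f^2 * theta_max^2 * L_fin * h^2 * lambda * g(lambda)
# with C = 86.03. The combination C rho f^2 theta^2 L h^2 carries units N/m;
# the traveling-wave wavelength lambda is the remaining named length scale,
# so it closes the dimensions here and g(lambda) is treated as a
# dimensionless, pluggable shape factor (default constant 1). Absolute
# magnitudes therefore depend on that closure and on theta_max; every
# pitch-dependent result in the package uses thrust ratios, which cancel
# both (see the methods vignette).

#' Ribbon-fin kinematics and thrust-correlation constants
#'
#' @param theta_max_rad maximal angular excursion of the traveling wave, in
#'   radians. Required: no universal default is shipped in code (supply a
#'   measured value or take one from the config layer, see
#'   [default_config()]).
#' @param freq_hz traveling-wave frequency in Hz, >= 0.
#' @param fin_length_m fin length in metres (default 0.127, the fin of the
#'   fish used for the drag measurements).
#' @param fin_height_m fin height in metres (default 0.01).
#' @param wavelength_m traveling-wave wavelength in metres; default two waves
#'   along the fin, `fin_length_m / 2`.
#' @param C_const dimensionless correlation constant (default 86.03).
#' @param rho_water_kg_m3 water density (default 1000).
#' @param heave_ratio heave-to-surge force ratio `eta` in \[0, 1) (default
#'   0.25: the upward heave force is about a quarter of the surge force).
#' @param fin_base_deg fin-base insertion angle `beta` relative to the body
#'   axis, degrees. Defaults to `atan(heave_ratio)` (~14 deg), the angle
#'   that maximizes forward thrust at zero body pitch and matches the
#'   observed insertion angle.
#' @param g_lambda dimensionless shape factor of the wavelength, as a
#'   function of wavelength in metres; pluggable, default constant 1.
#' @param surge_scale dimensionless calibration multiplier applied to the
#'   surge force (see [calibrate_surge()]).
#' @return An object of class `fin_kinematics`.
#' @export
fin_kinematics <- function(theta_max_rad,
                           freq_hz = 3,
                           fin_length_m = 0.127,
                           fin_height_m = 0.01,
                           wavelength_m = fin_length_m / 2,
                           C_const = 86.03,
                           rho_water_kg_m3 = 1000,
                           heave_ratio = 0.25,
                           fin_base_deg = rad2deg(atan(heave_ratio)),
                           g_lambda = function(lambda_m) 1,
                           surge_scale = 1) {
  if (missing(theta_max_rad) || !is.finite(theta_max_rad) || theta_max_rad < 0) {
    stop_domain("`theta_max_rad` must be supplied as a finite non-negative angle in radians")
  }
  if (!is.finite(freq_hz) || freq_hz < 0) stop_domain("`freq_hz` must be >= 0")
  lens <- c(fin_length_m, fin_height_m, wavelength_m)
  if (any(!is.finite(lens)) || any(lens <= 0)) {
    stop_domain("fin lengths and wavelength must be finite and positive")
  }
  if (!is.finite(heave_ratio) || heave_ratio < 0 || heave_ratio >= 1) {
    stop_domain("`heave_ratio` must lie in [0, 1)")
  }
  if (!is.function(g_lambda)) stop_domain("`g_lambda` must be a function")
  if (!is.finite(surge_scale) || surge_scale <= 0) {
    stop_domain("`surge_scale` must be positive")
  }
  structure(
    list(theta_max_rad = theta_max_rad, freq_hz = freq_hz,
         fin_length_m = fin_length_m, fin_height_m = fin_height_m,
         wavelength_m = wavelength_m, C_const = C_const,
         rho_water_kg_m3 = rho_water_kg_m3, heave_ratio = heave_ratio,
         fin_base_deg = fin_base_deg, g_lambda = g_lambda,
         surge_scale = surge_scale),
    class = "fin_kinematics"
  )
}

#' @export
print.fin_kinematics <- function(x, ...) {
  cat("Ribbon-fin kinematics\n")
  cat(sprintf("  f = %g Hz, theta_max = %.3f rad, L = %g m, h = %g m, lambda = %g m\n",
              x$freq_hz, x$theta_max_rad, x$fin_length_m, x$fin_height_m,
              x$wavelength_m))
  cat(sprintf("  C = %g, rho = %g kg/m^3, eta = %g, beta = %.2f deg, scale = %g\n",
              x$C_const, x$rho_water_kg_m3, x$heave_ratio, x$fin_base_deg,
              x$surge_scale))
  cat(sprintf("  surge force = %.4g N, peak forward thrust at pitch %.2f deg\n",
              surge_force(x), peak_thrust(x)$pitch_deg))
  invisible(x)
}

check_fin <- function(fin) {
  if (!inherits(fin, "fin_kinematics")) {
    stop_domain("`fin` must be a fin_kinematics object")
  }
  invisible(fin)
}

#' Surge force of the undulating fin
#'
#' Mean propulsive force parallel to the fin base from the thrust
#' correlation; scales as frequency squared and excursion squared.
#'
#' @param fin a [fin_kinematics()].
#' @return Force in newtons.
#' @export
surge_force <- function(fin) {
  check_fin(fin)
  fin$surge_scale * fin$C_const * fin$rho_water_kg_m3 * fin$freq_hz^2 *
    fin$theta_max_rad^2 * fin$fin_length_m * fin$fin_height_m^2 *
    fin$wavelength_m * fin$g_lambda(fin$wavelength_m)
}

#' Heave force of the undulating fin
#'
#' Force perpendicular to the fin base pushing the body upward;
#' `heave_ratio` times the surge force (about 25% for typical motion
#' patterns).
#'
#' @inheritParams surge_force
#' @return Force in newtons.
#' @export
heave_force <- function(fin) {
  check_fin(fin)
  fin$heave_ratio * surge_force(fin)
}

#' Net forward thrust at a body pitch
#'
#' As the body pitches by `alpha`, the fin base tilts to `alpha + beta` and
#' the forward components of surge and heave combine to
#' `F_surge * (cos(alpha + beta) + eta * sin(alpha + beta))`.
#' Writing this as `F_surge * sqrt(1 + eta^2) * cos(alpha + beta - atan(eta))`
#' shows the maximum over pitch occurs at `alpha = atan(eta) - beta`, which
#' is 0 for the default fin-base angle.
#'
#' @inheritParams surge_force
#' @param pitch_deg body pitch angle(s) in degrees, in \[0, 90\].
#' @return Force in newtons.
#' @export
net_forward_thrust <- function(fin, pitch_deg) {
  check_fin(fin)
  check_pitch(pitch_deg)
  ang <- deg2rad(pitch_deg + fin$fin_base_deg)
  surge_force(fin) * (cos(ang) + fin$heave_ratio * sin(ang))
}

#' Pitch angle and value of maximal forward thrust
#'
#' @inheritParams surge_force
#' @return List with `pitch_deg` (the thrust-maximizing body pitch, clamped
#'   to \[0, 90\]) and `thrust_N`.
#' @export
peak_thrust <- function(fin) {
  check_fin(fin)
  a_star <- rad2deg(atan(fin$heave_ratio)) - fin$fin_base_deg
  a_star <- min(max(a_star, 0), 90)
  list(pitch_deg = a_star, thrust_N = net_forward_thrust(fin, a_star))
}

#' Fractional loss of propulsive effectiveness with pitch
#'
#' `1 - thrust(alpha) / max_alpha' thrust(alpha')`, in \[0, 1\]. With the
#' default kinematics the drop reaches 25% near a 41.5-degree pitch and
#' about 29% at 45 degrees.
#'
#' @inheritParams net_forward_thrust
#' @return Dimensionless fraction.
#' @export
thrust_drop_fraction <- function(fin, pitch_deg) {
  1 - net_forward_thrust(fin, pitch_deg) / peak_thrust(fin)$thrust_N
}

#' Calibrate the surge magnitude against a known force
#'
#' The absolute surge magnitude depends on the dimensional closure of the
#' thrust correlation and on `theta_max`; this helper rescales it so that
#' the net forward thrust at a stated pitch equals a stated force (for
#' example, the drag measured at that condition). Pitch-dependent thrust
#' ratios are unaffected.
#'
#' @inheritParams net_forward_thrust
#' @param target_N desired net forward thrust in newtons at `at_pitch_deg`.
#' @param at_pitch_deg pitch at which to match (default 0).
#' @return The `fin_kinematics` object with `surge_scale` adjusted.
#' @export
calibrate_surge <- function(fin, target_N, at_pitch_deg = 0) {
  check_fin(fin)
  if (!is.finite(target_N) || target_N <= 0) {
    stop_domain("`target_N` must be positive")
  }
  cur <- net_forward_thrust(fin, at_pitch_deg)
  if (cur <= 0) stop_domain("net thrust at the calibration pitch is not positive")
  fin$surge_scale <- fin$surge_scale * target_N / cur
  fin
}

#' Thrust-versus-pitch curves for a family of undulation frequencies
#'
#' @inheritParams surge_force
#' @param freq_hz vector of traveling-wave frequencies in Hz.
#' @param pitch_deg pitch grid in degrees.
#' @return Data frame with columns `freq_hz`, `pitch_deg`, `thrust_N`,
#'   `relative_thrust` (thrust over that frequency's peak thrust).
#' @export
thrust_curve <- function(fin, freq_hz = c(2, 3, 4, 5, 6),
                         pitch_deg = seq(0, 90, by = 1)) {
  check_fin(fin)
  out <- lapply(freq_hz, function(f) {
    fin$freq_hz <- f
    th <- net_forward_thrust(fin, pitch_deg)
    data.frame(freq_hz = f, pitch_deg = pitch_deg, thrust_N = th,
               relative_thrust = th / peak_thrust(fin)$thrust_N)
  })
  do.call(rbind, out)
}

#' Pitch at which thrust balances drag under fixed power
#'
#' For steady swimming, the net forward thrust must equal the drag; with
#' total swimming power clamped, the drag curve is [drag_at_fixed_power()].
#' This finds pitch angles where the two curves intersect on \[0, 90\] by
#' sign-change bracketing on a fine grid followed by bisection
#' ([stats::uniroot()]) refined well below 0.01 degrees.
#'
#' @inheritParams net_forward_thrust
#' @param fit a [drag_fit()].
#' @param power_W clamped swimming power in watts.
#' @param grid_step_deg bracketing grid resolution (default 0.1 deg).
#' @return An object of class `pitch_equilibrium`: list with `found`
#'   (logical), `pitch_deg` (smallest root, or `NA` if none), `roots_deg`
#'   (all roots), and `residual_N` (|thrust - drag| at the returned root).
#'   No intersection yields `found = FALSE`, not an error.
#' @export
equilibrium_pitch <- function(fin, fit, power_W, grid_step_deg = 0.1) {
  check_fin(fin)
  check_fit(fit)
  h <- function(a) {
    net_forward_thrust(fin, a) - drag_at_fixed_power(fit, a, power_W)
  }
  grid <- seq(0, 90, by = grid_step_deg)
  hv <- h(grid)
  roots <- grid[hv == 0]
  flips <- which(hv[-1] * hv[-length(hv)] < 0)
  for (i in flips) {
    r <- uniroot(h, c(grid[i], grid[i + 1]), tol = 1e-12)$root
    roots <- c(roots, r)
  }
  roots <- sort(unique(roots))
  if (length(roots) == 0L) {
    out <- list(found = FALSE, pitch_deg = NA_real_,
                roots_deg = numeric(0), residual_N = NA_real_)
  } else {
    out <- list(found = TRUE, pitch_deg = roots[1], roots_deg = roots,
                residual_N = abs(h(roots[1])))
  }
  structure(out, class = "pitch_equilibrium")
}

#' @export
print.pitch_equilibrium <- function(x, ...) {
  if (!x$found) {
    cat("No thrust-drag equilibrium on [0, 90] degrees\n")
  } else {
    cat(sprintf("Thrust-drag equilibrium at pitch %.3f deg (residual %.2g N)\n",
                x$pitch_deg, x$residual_N))
    if (length(x$roots_deg) > 1L) {
      cat("  all roots:", paste(sprintf("%.3f", x$roots_deg), collapse = ", "),
          "deg\n")
    }
  }
  invisible(x)
}
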