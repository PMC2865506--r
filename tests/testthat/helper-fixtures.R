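# shared fixtures: the reference cuboid, the drag law interpolating the
# measured tow forces (2.0 / 5.2 / 8.1 mN at 0 / 15 / 30 deg, 15 cm/s), and
# a default-kinematics fin (theta_max cancels out of every ratio assertion)

table1_cuboid <- function() cuboid_sensorium()

ref_fit <- function(...) reference_drag_fit(...)

default_energetics <- function() energetics_config()

default_fin <- function(...) fin_kinematics(theta_max_rad = 0.524, ...)

# drag law rescaled by gamma^3 in force so that the fixed-power drag curve
# scales by exactly gamma (used for the equilibrium rescaling invariance)
scaled_fit <- function(fit, gamma) {
  drag_fit(fit$a_N * gamma^3, fit$b_N_per_degc * gamma^3, fit$c,
           fit$v_ref_m_s, fit$velocity_exponent)
}
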