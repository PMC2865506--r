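test_that("distance per prey is the inverse of density times swept area", {
  cub <- table1_cuboid()
  expect_equal(distance_per_prey(cub, 0, 5000), 1 / (5000 * 0.0145),
               tolerance = 1e-12)
  expect_equal(distance_per_prey(cub, 0, 5000), 0.0137931, tolerance = 1e-5)
  expect_equal(distance_per_prey(cub, 30, 5000), 0.0071024, tolerance = 1e-4)
  expect_equal(distance_per_prey(cub, 17, 10000),
               distance_per_prey(cub, 17, 5000) / 2, tolerance = 1e-12)
  expect_error(distance_per_prey(cub, 0, 0), class = "pitchsense_domain_error")
})

test_that("energy per prey at neutral pitch is ~27.6 uJ from the measured drag", {
  cfg <- default_energetics()
  fit <- ref_fit()
  cub <- table1_cuboid()
  e0 <- energy_per_prey(cfg, fit, cub, 0)
  # P * t with t = d / v reduces to F(0) / (D * A(0)) at the reference point
  expect_equal(e0, 2e-3 / (5000 * 0.0145), tolerance = 1e-9)
  expect_equal(e0 * 1e6, 27.5862, tolerance = 1e-5)
  # the explicit chain equals the collapsed closed form everywhere
  g <- seq(0, 85, by = 2.5)
  expect_equal(energy_per_prey(cfg, fit, cub, g),
               energy_per_prey_closed_form(cfg, fit, cub, g), tolerance = 1e-12)
})

test_that("clamp scenarios obey their algebraic identities exactly", {
  cfg <- default_energetics()
  fit <- ref_fit()
  cub <- table1_cuboid()
  g <- seq(0, 85, by = 5)
  e0 <- energy_per_prey(cfg, fit, cub, 0)

  # movable sensorium: drag frozen, E(a) = E(0) * A(0)/A(a)
  e_cd <- energy_per_prey(cfg, fit, cub, g, "clamp_drag")
  expect_equal(e_cd, e0 / area_ratio(cub, g), tolerance = 1e-12)
  expect_equal(e_cd * projected_area(cub, g), rep(e_cd[1] * 0.0145, length(g)),
               tolerance = 1e-12)

  # body-fixed blunt sensorium: area frozen, E / k^(1/3) constant
  e_ca <- energy_per_prey(cfg, fit, cub, g, "clamp_area")
  expect_equal(e_ca / drag_coefficient(fit, g)^(1 / 3),
               rep(e_ca[1] / drag_coefficient(fit, 0)^(1 / 3), length(g)),
               tolerance = 1e-12)

  # swiveling the sensorium to the area-maximizing pitch cuts the energy by
  # more than a factor of two
  a_max <- area_maximizing_pitch(cub)
  e_swivel <- energy_per_prey(cfg, fit, cub, a_max, "clamp_drag")
  expect_equal(e_swivel * 1e6, 11.625, tolerance = 1e-4)
  expect_equal(e0 / e_swivel, sqrt(1 + elongation_factor(cub)^2),
               tolerance = 1e-12)
  expect_gt(e0 / e_swivel, 2)
})

test_that("energy curves have the expected shape per elongation and scenario", {
  cfg <- default_energetics()
  fit <- ref_fit()
  cub <- table1_cuboid()
  g <- seq(0, 85, by = 0.1)

  # blunt sensorium: no meaningful dip, then rising
  e1 <- energy_curve(cfg, fit, with_elongation(cub, 1), "natural", g)
  expect_lt(abs(min(e1$energy_J) / e1$energy_J[1] - 1), 0.02)
  expect_gt(e1$energy_J[e1$pitch_deg == 60], e1$energy_J[1])

  # body-fixed visual sensorium: cost only, monotone non-decreasing
  eca <- energy_curve(cfg, fit, cub, "clamp_area", g)
  expect_true(all(diff(eca$energy_J) >= 0))

  # highly elongated sensorium: pitching pays over the whole searched range
  e4 <- energy_curve(cfg, fit, with_elongation(cub, 4), "natural", g)
  sub <- e4$energy_J[e4$pitch_deg <= 60]
  expect_true(all(diff(sub) < 0))

  # elongation always helps at positive pitch: the energy ratio between two
  # elongations equals the inverse area ratio (drag unchanged)
  e_nat <- energy_curve(cfg, fit, cub, "natural", g)
  pos <- g > 0
  expect_equal((e4$energy_J / e_nat$energy_J)[pos],
               (projected_area(cub, g) / projected_area(with_elongation(cub, 4), g))[pos],
               tolerance = 1e-12)
  expect_true(all(e4$energy_J[pos] < e_nat$energy_J[pos]))

  # metadata: extrapolation flagged beyond the measured 30 degrees
  expect_false(any(e_nat$extrapolated[g <= 30]))
  expect_true(all(e_nat$extrapolated[g > 30]))
  expect_named(as.data.frame(e_nat)[1, ],
               c("pitch_deg", "velocity_m_s", "distance_m", "time_s",
                 "energy_J", "energy_uJ", "extrapolated"))
})

test_that("optimal pitch per scenario matches the analytic argmin", {
  cfg <- default_energetics()
  fit <- ref_fit()
  cub <- table1_cuboid()
  # movable sensorium: E ~ 1/A, optimum at the area-maximizing pitch
  expect_equal(optimal_pitch(cfg, fit, cub, "clamp_drag"),
               area_maximizing_pitch(cub), tolerance = 0.1)
  # body-fixed area: monotone cost, optimum at zero
  expect_equal(optimal_pitch(cfg, fit, cub, "clamp_area"), 0)
  # natural: strict interior optimum that improves on swimming level
  opt <- optimal_pitch(cfg, fit, cub, "natural")
  expect_gt(opt, 0)
  expect_lt(opt, 85)
  e_opt <- energy_per_prey(cfg, fit, cub, opt)
  expect_lt(e_opt, energy_per_prey(cfg, fit, cub, 0))
  # tens of microjoules against a 1-2 J prey: tiny fraction of the return
  expect_lt(e_opt, 1e-4 * min(cfg$prey_energy_J))
})

test_that("neutral-pitch energy is insensitive to the velocity exponent when
          power matches the reference drag", {
  cfg <- default_energetics()
  cub <- table1_cuboid()
  vals <- sapply(c(1.5, 2, 2.5), function(p) {
    energy_per_prey(cfg, ref_fit(velocity_exponent = p), cub, 0)
  })
  expect_equal(vals, rep(2e-3 / (5000 * 0.0145), 3), tolerance = 1e-12)
})

test_that("active-sensing energy scales as the fourth power of range", {
  expect_equal(active_sensing_energy_factor(0.06, 0.03), 16)
  expect_equal(active_sensing_energy_factor(1, 1), 1)
  expect_equal(active_sensing_energy_factor(3, 1), 81)
  expect_equal(active_sensing_energy_cost(80, 0.06, 0.03), 1280)
  expect_equal(active_sensing_energy_cost(42, 0.05, 0.05), 42)
  # baseline derivation: ~22% of a 350 J/day budget is close to 80 J/day
  expect_equal(0.22 * 350, 80, tolerance = 0.05)
  expect_error(active_sensing_energy_factor(-1, 2),
               class = "pitchsense_domain_error")
  expect_error(active_sensing_energy_cost(0, 1, 1),
               class = "pitchsense_domain_error")
})
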