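test_that("closed-form three-point solve recovers the power law exactly", {
  # printed forces: 2.0, 5.2, 8.1 mN at 0, 15, 30 deg
  s <- three_point_drag_solve(c(0, 15, 30), c(2.0, 5.2, 8.1) * 1e-3)
  expect_equal(s[["a"]], 2.0e-3, tolerance = 1e-12)
  expect_equal(s[["c"]], log(6.1 / 3.2) / log(2), tolerance = 1e-12)
  expect_equal(s[["c"]], 0.930737, tolerance = 1e-6)
  expect_equal(s[["b"]], 2.573463e-4, tolerance = 1e-6)
  # interpolation property on known-linear data
  s2 <- three_point_drag_solve(c(0, 10, 20), 1 + 0.1 * c(0, 10, 20))
  expect_equal(unname(s2), c(1, 0.1, 1), tolerance = 1e-10)
  # general (no zero angle) branch
  s3 <- three_point_drag_solve(c(5, 12, 40), 0.7 + 0.03 * c(5, 12, 40)^1.4)
  expect_equal(unname(s3), c(0.7, 0.03, 1.4), tolerance = 1e-8)
  expect_error(three_point_drag_solve(c(0, 15, 30), c(3, 2, 8)),
               class = "pitchsense_fit_error")
  expect_error(three_point_drag_solve(c(0, 15), c(1, 2)),
               class = "pitchsense_fit_error")
})

test_that("nonlinear fit interpolates noise-free points and matches the closed form", {
  fit <- ref_fit()
  expect_s3_class(fit, "drag_fit")
  expect_equal(fit$a_N, 2.0e-3, tolerance = 1e-7)
  expect_equal(fit$c, 0.930737, tolerance = 1e-6)
  expect_equal(fit$b_N_per_degc, 2.573463e-4, tolerance = 1e-6)
  expect_equal(fit$v_ref_m_s, 0.15)
  expect_lt(fit$rss, 1e-15)
  expect_equal(fit$r2, 1, tolerance = 1e-9)
  expect_equal(fit$max_fit_pitch_deg, 30)

  # iterative LS agrees with the closed-form solve to 6 significant figures
  # for arbitrary strictly increasing force triples
  set.seed(7)
  for (i in 1:5) {
    f0 <- runif(1, 0.5, 3)
    d1 <- runif(1, 0.5, 3)
    d2 <- runif(1, 0.5, 2) * d1  # keeps the implied exponent inside (0.1, 3)
    tri <- c(f0, f0 + d1, f0 + d1 + d2)
    cf <- three_point_drag_solve(c(0, 15, 30), tri)
    m <- tow_measurements(c(0, 15, 30), 0.15, tri)
    ft <- fit_drag_curve(m)
    expect_equal(ft$a_N, cf[["a"]], tolerance = 1e-6)
    expect_equal(ft$b_N_per_degc, cf[["b"]], tolerance = 1e-6)
    expect_equal(ft$c, cf[["c"]], tolerance = 1e-6)
  }
})

test_that("fit preconditions are enforced and flat data fall back gracefully", {
  expect_error(fit_drag_curve(tow_measurements(c(0, 15), c(0.15, 0.15),
                                               c(2e-3, 5e-3))),
               class = "pitchsense_fit_error")
  mixed <- tow_measurements(c(0, 15, 30), c(0.10, 0.12, 0.15),
                            c(1e-3, 3e-3, 8e-3))
  expect_error(fit_drag_curve(mixed), class = "pitchsense_fit_error")
  expect_warning(
    flat <- fit_drag_curve(tow_measurements(c(0, 15, 30), 0.15, rep(2e-3, 3))),
    "flat"
  )
  expect_equal(flat$a_N, 2e-3)
  expect_equal(flat$b_N_per_degc, 0)
  expect_equal(flat$c, 1)
})

test_that("drag force scales quadratically in speed and power-law in pitch", {
  fit <- ref_fit()
  expect_equal(drag_force(fit, 0, 0.15), 2.0e-3, tolerance = 1e-9)
  expect_equal(drag_force(fit, c(15, 30), 0.15), c(5.2e-3, 8.1e-3),
               tolerance = 1e-7)
  expect_equal(drag_force(fit, 37, 0), 0)
  expect_equal(drag_force(fit, 0, 0.30), 8.0e-3, tolerance = 1e-9)
  expect_error(drag_force(fit, 0, -0.1), class = "pitchsense_domain_error")
  # F(alpha) non-decreasing in pitch
  expect_true(all(diff(drag_force(fit, seq(0, 90, 0.5), 0.15)) >= 0))
})

test_that("power-constrained velocity and drag close the 0.3 mW triangle", {
  fit <- ref_fit()
  expect_equal(velocity_at_power(fit, 0, 0.3e-3), 0.150, tolerance = 1e-9)
  expect_equal(velocity_at_power(fit, 30, 0.3e-3), 0.0941036, tolerance = 1e-6)
  expect_equal(velocity_at_power(fit, 20, 2 * 0.3e-3) /
                 velocity_at_power(fit, 20, 0.3e-3), 2^(1 / 3),
               tolerance = 1e-12)
  expect_error(velocity_at_power(fit, 0, 0), class = "pitchsense_domain_error")

  expect_equal(drag_at_fixed_power(fit, 0, 0.3e-3), 2.0e-3, tolerance = 1e-9)
  expect_equal(drag_at_fixed_power(fit, 30, 0.3e-3), 3.187976e-3,
               tolerance = 1e-6)
  # fixed-power drag is monotone increasing in pitch
  expect_true(all(diff(drag_at_fixed_power(fit, seq(0, 90, 0.5), 0.3e-3)) > 0))

  # algebraic identities, arbitrary pitch and power
  set.seed(11)
  alpha <- runif(20, 0, 90)
  P <- 10^runif(20, -5, -2)
  expect_equal(drag_at_fixed_power(fit, alpha, P) * velocity_at_power(fit, alpha, P),
               P, tolerance = 1e-12)
  expect_equal(drag_at_fixed_power(fit, alpha, P),
               drag_force(fit, alpha, velocity_at_power(fit, alpha, P)),
               tolerance = 1e-12)
})

test_that("reference thrust power is zero-pitch drag times reference speed", {
  expect_equal(reference_thrust_power(ref_fit()), 0.3e-3, tolerance = 1e-9)
  expect_equal(reference_thrust_power(drag_fit(1, 0.1, 1, 1)), 1)
  # recovered from noisy synthetic data within recovery tolerance
  p <- tow_protocol(seed = 5L)
  m <- suppressMessages(generate_tow_measurements(p))
  f <- fit_drag_curve(normalize_tow_speed(m, 0.15))
  expect_equal(reference_thrust_power(f), 0.3e-3, tolerance = 0.15)
})

test_that("speed normalization brings mixed-speed tables to one reference", {
  fit <- ref_fit()
  m <- tow_measurements(rep(c(0, 15, 30), each = 3),
                        rep(c(0.10, 0.12, 0.15), 3),
                        drag_force(fit, rep(c(0, 15, 30), each = 3),
                                   rep(c(0.10, 0.12, 0.15), 3)))
  mn <- normalize_tow_speed(m, 0.15)
  expect_equal(unique(mn$speed_m_s), 0.15)
  refit <- fit_drag_curve(mn)
  expect_equal(refit$a_N, fit$a_N, tolerance = 1e-7)
  expect_equal(refit$c, fit$c, tolerance = 1e-6)
  # quadratic scaling: halving speed quarters the force
  one <- tow_measurements(0, 0.30, 8e-3)
  expect_equal(normalize_tow_speed(one, 0.15)$force_N, 2e-3)
})

test_that("drag fits and tow tables round-trip through JSON and CSV", {
  fit <- ref_fit()
  jp <- file.path(tempdir(), "fit.json")
  write_drag_fit(fit, jp)
  back <- read_drag_fit(jp)
  expect_equal(back$a_N, fit$a_N)
  expect_equal(back$c, fit$c)
  expect_equal(back$r2, fit$r2)
  expect_equal(back$velocity_exponent, 2)

  cp <- file.path(tempdir(), "tow.csv")
  write_tow_csv(measured_tow_data(), cp)
  back2 <- read_tow_csv(cp)
  expect_equal(back2$force_N, measured_tow_data()$force_N)

  cfd <- cfd_tow_data()
  expect_equal(cfd$force_N, c(1.0, 6.1, 12.2) * 1e-3)
})
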