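# Torque-balance model: closed-form values, balance identity, scaling laws.

test_that("bead volume and field strength conversions match direct arithmetic", {
  expect_equal(bead_volume(0), 0)
  expect_equal(bead_volume(1), pi / 6)
  # (pi/6) * (4.5e-6)^3, evaluated independently
  expect_equal(bead_volume(4.5e-6), 4.77129e-17, tolerance = 1e-5)
  expect_error(bead_volume(-1), "diameter")

  expect_equal(field_H_from_B(0), 0)
  expect_equal(field_H_from_B(3.4e-3), 2705.634, tolerance = 1e-6)
  expect_equal(field_H_from_B(2.1e-3), 1671.127, tolerance = 1e-6)
  expect_error(field_H_from_B(-1), "flux_density")
})

test_that("magnetic torque evaluates the closed form, linear in N and quadratic in H", {
  b <- bead_spec(chi_imag = 0.1)
  expect_equal(magnetic_torque(1, bead_spec(chi_imag = 0), 2705.6), 0)
  expect_equal(magnetic_torque(1, b, 2705.6), 4.389e-17, tolerance = 1e-3)
  expect_equal(magnetic_torque(7, b, 2705.6), 3.072e-16, tolerance = 1e-3)
  # exact linearity in N at three points
  t1 <- magnetic_torque(1, b, default_H)
  for (n in c(2, 13, 300))
    expect_equal(magnetic_torque(n, b, default_H), n * t1)
  # exact quadratic dependence on H at three points
  for (k in c(2, 3.5, 10))
    expect_equal(magnetic_torque(5, b, k * default_H),
                 k^2 * magnetic_torque(5, b, default_H))
})

test_that("viscous torque matches the disk-drag form and scales cubically in R", {
  expect_equal(viscous_torque(1e-3, 0, 1e-6), 0)
  expect_equal(viscous_torque(1e-3, 10, 20e-6), 8.533e-16, tolerance = 1e-3)
  expect_equal(viscous_torque(2e-3, 7, 2 * 11e-6),
               8 * viscous_torque(2e-3, 7, 11e-6))
  expect_error(viscous_torque(1e-3, 1, 0), "radius")
})

test_that("rotation rate closes the torque balance to 1e-12 relative", {
  b <- bead_spec(chi_imag = 0.1)
  R7 <- radius_from_count(7, b$radius)
  expect_equal(R7, 5.953e-6, tolerance = 1e-3)
  om <- rotation_rate(7, b, 2705.6, 1e-3, R7)
  expect_equal(om, 136.5, tolerance = 1e-3)
  # randomized parameter sweep: balance holds identically
  set.seed(11)
  for (i in 1:25) {
    bb <- bead_spec(diameter_um = runif(1, 1, 10),
                    chi_imag = runif(1, 0.01, 1))
    n <- sample(1:500, 1)
    H <- runif(1, 100, 1e4)
    eta <- 10^runif(1, -3.5, -1)
    R <- radius_from_count(n, bb$radius) * runif(1, 0.5, 2)
    w <- rotation_rate(n, bb, H, eta, R)
    expect_equal(viscous_torque(eta, w, R),
                 magnetic_torque(n, bb, H), tolerance = 1e-12)
  }
  expect_equal(rotation_rate(7, bead_spec(chi_imag = 0), 2705.6, 1e-3), 0)
  expect_error(rotation_rate(7, b, 2705.6, 0), "viscosity")
})

test_that("radius from count follows the planar disk-area estimate", {
  expect_equal(radius_from_count(1, 2.25e-6), 2.25e-6)
  expect_equal(radius_from_count(4, 2.25e-6), 4.5e-6)
  expect_equal(radius_from_count(7, 2.25e-6), 2.25e-6 * sqrt(7))
})

test_that("power is torque times rotation rate, in both model and measured form", {
  expect_equal(wheel_power(0, 10), 0)
  expect_equal(wheel_power(3e-16, 0), 0)
  expect_equal(power_from_measurement(1e-3, 10, 20e-6), 8.533e-15,
               tolerance = 1e-3)
  # the two routes agree when omega comes from the balance
  b <- bead_spec()
  R <- radius_from_count(40, b$radius)
  om <- rotation_rate(40, b, default_H, 1e-3, R)
  expect_equal(power_from_measurement(1e-3, om, R),
               wheel_power(magnetic_torque(40, b, default_H), om))
})

test_that("size scaling laws hold under the R = a sqrt(N) coupling", {
  b <- bead_spec()
  a_um <- b$radius * 1e6
  R_um <- seq(5, 40, length.out = 16)
  N <- (R_um / a_um)^2              # continuous coupling for the sweep
  R <- R_um * 1e-6
  om <- rotation_rate(N, b, default_H, 1e-3, R)
  V <- translation_velocity(om, N)
  P <- wheel_power(magnetic_torque(N, b, default_H), om)
  for (q in list(om * R, P / R, V / R))
    expect_lt(max(abs(q / q[1] - 1)), 1e-9)
  # omega ~ 1/R: doubling R halves omega
  expect_equal(om[1] * R_um[1], om[16] * R_um[16])
  # V ~ 1/eta: halving viscosity doubles V at fixed size
  om_half <- rotation_rate(N, b, default_H, 0.5e-3, R)
  expect_equal(translation_velocity(om_half, N), 2 * V)
})

test_that("rolling direction is the -90 deg rotated in-plane axis component", {
  expect_equal(rolling_direction(c(0, cos(pi / 6), -0.5)), c(1, 0))
  expect_null(rolling_direction(c(0, 0, -1)))
  expect_equal(rolling_direction(c(cos(pi / 6), 0, -0.5)), c(0, -1))
  expect_error(rolling_direction(c(0, 1, 1)), "unit")
})

test_that("micro_wheel assembles consistent steady states", {
  mw <- micro_wheel(c(7, 50), bead_spec(), field_spec(), fluid_spec())
  expect_equal(mw$radius_um, 2.25 * sqrt(c(7, 50)))
  expect_equal(mw$rotation_rate_rad_s[1], 136.5, tolerance = 1e-3)
  expect_equal(mw$velocity_um_s, 0.05 * mw$rotation_rate_rad_s * mw$n_beads)
  expect_error(micro_wheel(0.5), "n_beads")
})
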