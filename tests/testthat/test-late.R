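test_that("contraction count follows the phase duration and period", {
  sch <- cycle_schedule(period_s = 40, phase_duration_min = 140)
  expect_identical(sch$n_cycles, 210L)
  expect_identical(cycle_schedule(period_s = 60,
                                  phase_duration_min = 30)$n_cycles, 30L)
})

test_that("efficiency schedules stay in (0, 1] with the stated endpoints", {
  for (ty in c("linear", "sigmoid", "piecewise", "constant")) {
    phi <- efficiency_schedule(210, ty)
    expect_length(phi, 210)
    expect_true(all(phi > 0 & phi <= 1))
  }
  lin <- efficiency_schedule(210, "linear")
  expect_equal(lin[1], 1)
  expect_equal(lin[210], 0.4)
})

test_that("contraction energy: zero without activation, mirror symmetric,
           quadratic in the activation", {
  geom <- default_geom; mat <- default_mat
  sch0 <- cycle_schedule(gm = 0, ga = 0)
  expect_equal(cycle_contraction_energy(geom, mat, sch0), 0)
  sch <- cycle_schedule()
  wl <- cycle_contraction_energy(geom, mat, sch, pair = "left")
  wr <- cycle_contraction_energy(geom, mat, sch, pair = "right")
  expect_equal(wl, wr, tolerance = 1e-10)
  # muscle-only energy scales with gm^2
  w1 <- cycle_contraction_energy(geom, mat, cycle_schedule(gm = -0.15, ga = 0))
  w2 <- cycle_contraction_energy(geom, mat, cycle_schedule(gm = -0.075, ga = 0))
  expect_equal(w1 / w2, 4, tolerance = 1e-9)
  expect_gt(wl, w2)
})

test_that("relaxation transfer: trivial case, monotone in phi, admissible ga1", {
  geom <- default_geom; mat <- default_mat
  K <- rod_stiffnesses(geom, mat, 1.8)
  h0a <- elongrod:::hoop_load_per_activation(geom, mat, 1.8)
  eps <- (geom$R3_um / sqrt(1.8)) / 90
  expect_error(relaxation_transfer(0.03, 1.5, K, h0a, eps, 90))
  zero <- relaxation_transfer(0, 1, K, h0a, eps, 90)
  expect_equal(zero$delta_zeta_um, 0)
  expect_equal(zero$ga1, 0)
  phis <- seq(0.1, 1, by = 0.1)
  dz <- vapply(phis, function(p) {
    relaxation_transfer(0.03, p, K, h0a, eps, 90)$delta_zeta_um
  }, numeric(1))
  expect_true(all(diff(dz) > 0))
  tr <- relaxation_transfer(0.03, 1, K, h0a, eps, 90)
  expect_lt(tr$ga1, 0)              # loop configuration is contractile
  expect_gt(1 + eps * tr$ga1, 0)    # active tensor stays admissible
})

test_that("full conversion: anchored first increment, growth to ~290 um", {
  wt <- simulate_late_phase(cycle_schedule(efficiency = "constant"))
  expect_equal(nrow(wt), 210L)
  expect_equal(wt$delta_zeta_um[1], 0.5, tolerance = 1e-9)
  expect_true(all(diff(wt$length_um) > 0))
  expect_true(all(diff(wt$delta_zeta_um) > 0))  # increments grow with length
  expect_equal(tail(wt$length_um, 1), 290, tolerance = 10 / 290)
  expect_equal(tail(wt$delta_zeta_um, 1), 1.5, tolerance = 0.15)
  # energy bookkeeping: nothing lost at phi = 1
  expect_equal(sum(wt$Wc_J - wt$Wr_J), 0)
})

test_that("ramped efficiency: increments rise then fall, energy is lost", {
  wt <- simulate_late_phase(cycle_schedule(efficiency = "linear"))
  i_peak <- which.max(wt$delta_zeta_um)
  expect_gt(i_peak, 1)
  expect_lt(i_peak, nrow(wt))
  expect_true(all(wt$Wr_J <= wt$Wc_J + 1e-18))
  loss <- sum(wt$Wc_J - wt$Wr_J)
  expect_gt(loss, 0)
  expect_equal(loss, sum((1 - wt$phi) * wt$Wc_J), tolerance = 1e-12)
  # slower endpoint than full conversion
  full <- simulate_late_phase(cycle_schedule(efficiency = "constant"))
  expect_lt(tail(wt$length_um, 1), tail(full$length_um, 1))
})

test_that("mutant scenarios reproduce arrest and retraction", {
  unc <- simulate_late_phase(scenario = mutant_scenario("unc112"))
  expect_equal(max(abs(unc$length_um - 90)), 0, tolerance = 1e-12)
  expect_equal(max(abs(unc$Wc_J)), 0)
  spc <- simulate_late_phase(scenario = mutant_scenario("spc1_pak1"))
  expect_true(all(diff(spc$length_um) < 0))
  expect_lt(tail(spc$length_um, 1), 90)
  wt <- simulate_late_phase(scenario = mutant_scenario("wild_type"))
  expect_true(all(diff(wt$length_um) > 0))
  expect_equal(tail(wt$length_um, 1) / 90, 210 / 90, tolerance = 0.15)
  expect_error(mutant_scenario("nonsense"))
})

test_that("energy scale: mu cancels in increments, explicit scaling obeys
           the quadratic energy-strain relation", {
  geom <- default_geom
  cal <- calibrate_energy_scale(geom, default_mat)
  # halving every modulus leaves the (dimensionless) response unchanged
  half <- material_map(mu = 5e4)
  wt1 <- simulate_late_phase(cycle_schedule(efficiency = "constant"),
                             mat = default_mat, calibration = cal)
  wt2 <- simulate_late_phase(cycle_schedule(efficiency = "constant"),
                             mat = half, calibration = cal)
  expect_equal(wt1$delta_zeta_um, wt2$delta_zeta_um, tolerance = 1e-9)
  # physical energies do halve
  expect_equal(wt2$Wc_J / wt1$Wc_J, rep(0.5, 210), tolerance = 1e-9)
  # halving the transferred energy scales the first increment by sqrt(1/2)
  wt3 <- simulate_late_phase(cycle_schedule(efficiency = "constant"),
                             calibration = cal / 2)
  expect_equal(wt3$delta_zeta_um[1] / wt1$delta_zeta_um[1], sqrt(0.5),
               tolerance = 1e-9)
})
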