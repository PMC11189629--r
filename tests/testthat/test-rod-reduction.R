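test_that("zeroth order: isochoric radial map and uniform pressure", {
  z <- zeroth_order(1.8)
  expect_equal(z$P0, 1 / 1.8, tolerance = 1e-12)
  expect_equal(z$r0(1), 1 / sqrt(1.8), tolerance = 1e-12)
  R <- seq(0.05, 1, length.out = 20)
  # incompressibility identity r' r / R * lambda = 1 (r' = 1/sqrt(lambda))
  expect_equal((1 / sqrt(1.8)) * z$r0(R) / R * 1.8, rep(1, 20),
               tolerance = 1e-12)
  z1 <- zeroth_order(1)
  expect_equal(z1$r0(R), R, tolerance = 1e-12)
  expect_equal(z1$P0, 1)
  expect_error(zeroth_order(-1), "positive")
})

test_that("first-order constants: published values and incompressibility", {
  q <- first_order_constants(1)
  expect_equal(unname(q), c(-0.125, 0.625), tolerance = 1e-12)
  q18 <- first_order_constants(1.8)
  expect_equal(q18[["q1"]], (1.8^3 - 2) / 8, tolerance = 1e-12)
  expect_equal(q18[["q2"]], (2 + 3 * 1.8^3) / 8, tolerance = 1e-12)
  expect_equal(q18[["q1"]], 0.4790, tolerance = 1e-4)
  expect_equal(q18[["q2"]], 2.4370, tolerance = 1e-4)
  # root of the published q1 at lambda = 2^(1/3)
  expect_equal(first_order_constants(2^(1 / 3))[["q1"]], 0, tolerance = 1e-12)
  # both correctors satisfy the pointwise incompressibility relation
  for (cc in c("published", "variational")) {
    for (l in c(1, 1.4, 1.8, 2.5)) {
      q <- first_order_constants(l, cc)
      expect_equal(3 * q[["q1"]] - q[["q2"]] + 1, 0, tolerance = 1e-12)
    }
  }
})

test_that("homogeneous stiffnesses match classical rod theory at lambda = 1", {
  mh <- homogeneous_mat()
  K <- rod_stiffnesses(default_geom, mh, 1, corrector = "variational")
  # incompressible neo-Hookean: E = 3 mu; A = pi, I = pi/4, J = pi/2 (R = 1)
  expect_equal(K[["K0"]], 3 * pi, tolerance = 0.01)
  expect_equal(K[["K1"]], 3 * pi / 4, tolerance = 0.01)
  expect_equal(K[["K2"]], 3 * pi / 4, tolerance = 0.01)
  expect_equal(K[["K3"]], pi / 2, tolerance = 0.01)
})

test_that("stiffnesses are linear in the shear moduli", {
  m1 <- material_map(mu = 1e5)
  m2 <- material_map(mu = 2e5)  # doubles every region (ratios fixed)
  K1 <- rod_stiffnesses(default_geom, m1, 1.8, mu_ref = 1e5)
  K2 <- rod_stiffnesses(default_geom, m2, 1.8, mu_ref = 1e5)
  expect_equal(unname(K2 / K1), rep(2, 4), tolerance = 1e-9)
})

test_that("quadrature stiffnesses/loads agree with the finite-eps 3D energy", {
  # independent oracle: full nonlinear energy at small eps, central second
  # difference in eps, for a homogeneous section
  mh <- homogeneous_mat()
  lam <- 1.3
  for (cc in c("published", "variational")) {
    K <- rod_stiffnesses(default_geom, mh, lam, corrector = cc)
    # passive: extension + bending + torsion state
    xi <- 0.3; u <- c(0.2, -0.4, 0.5)
    e_num <- numeric_rod_energy(xi, u, lam, corrector = cc) -
      numeric_rod_energy(0, c(0, 0, 0), lam, corrector = cc)
    H0 <- c(H0 = 0, H1 = 0, H2 = 0, H3 = 0)
    expect_equal(e_num, rod_energy(K, H0, xi, u), tolerance = 1e-4)
  }
  # active: hoop fibers in the actin ring couple to extension
  lam <- 1.8
  K <- rod_stiffnesses(default_geom, mh, lam)
  act <- activation_state(ga = -0.3, alpha_a = pi / 2)
  H <- intrinsic_loads(default_geom, mh, act, lam)
  g_ring <- function(R, Theta) ifelse(R > default_geom$R2p, -0.3, 0)
  xi <- 0.25; u <- c(0, 0.3, 0.2)
  e_num <- numeric_rod_energy(xi, u, lam, g_fun = g_ring, alpha = pi / 2) -
    numeric_rod_energy(0, c(0, 0, 0), lam, g_fun = g_ring, alpha = pi / 2)
  expect_equal(e_num, rod_energy(K, H, xi, u), tolerance = 1e-3)
})

test_that("intrinsic loads vanish without activation and respect symmetry", {
  geom <- default_geom; mat <- default_mat
  H0 <- intrinsic_loads(geom, mat, activation_state(), 1.8)
  expect_equal(unname(H0), rep(0, 4))
  # all four muscles active: bending cancels, pure axial effect
  Hall <- intrinsic_loads(geom, mat,
                          activation_state(gm = -0.15, muscle_pair = "all"), 1.8)
  expect_equal(Hall[["H1"]], 0, tolerance = 1e-10)
  expect_equal(Hall[["H2"]], 0, tolerance = 1e-10)
  expect_true(Hall[["H0"]] > 0)
  # left pair with hoop actin: no torsion without fiber tilt
  Hlh <- intrinsic_loads(geom, mat,
                         activation_state(gm = -0.15, muscle_pair = "left",
                                          ga = -0.01, alpha_a = pi / 2), 1.8)
  expect_equal(Hlh[["H3"]], 0, tolerance = 1e-12)
  # left vs right pair: bending load flips sign
  Hl <- intrinsic_loads(geom, mat,
                        activation_state(gm = -0.15, muscle_pair = "left"), 1.8)
  Hr <- intrinsic_loads(geom, mat,
                        activation_state(gm = -0.15, muscle_pair = "right"), 1.8)
  expect_equal(Hl[["H2"]], -Hr[["H2"]], tolerance = 1e-10)
  expect_equal(Hl[["H0"]], Hr[["H0"]], tolerance = 1e-10)
})

test_that("intrinsic strains: deformation modes match the activation type", {
  geom <- default_geom; mat <- default_mat
  K <- rod_stiffnesses(geom, mat, 1.8)
  # no activation: unit extension, straight
  st0 <- intrinsic_strains(K, c(H0 = 0, H1 = 0, H2 = 0, H3 = 0))
  expect_equal(st0$zeta_hat, 1)
  expect_equal(st0$kappa_hat, 0)
  expect_equal(st0$tau_hat, 0)
  # left muscles: pure bending (u1 = u3 = 0, kappa = |u2|, tau = 0)
  Hm <- intrinsic_loads(geom, mat,
                        activation_state(gm = -0.15, muscle_pair = "left"), 1.8)
  stm <- intrinsic_strains(K, Hm)
  expect_equal(stm$u_hat[1], 0)
  expect_equal(stm$u_hat[3], 0)
  expect_equal(stm$kappa_hat, abs(stm$u_hat[2]))
  expect_equal(stm$tau_hat, 0)
  expect_lt(stm$zeta_hat, 1)  # muscle contraction shortens
  # tilted actin: pure torsion (u1 = u2 = 0, kappa = 0)
  Ha <- intrinsic_loads(geom, mat,
                        activation_state(ga = -0.01, alpha_a = pi / 3), 1.8)
  sta <- intrinsic_strains(K, Ha)
  expect_equal(sta$u_hat[1], 0)
  expect_equal(sta$u_hat[2], 0)
  expect_equal(sta$kappa_hat, 0)
  expect_true(abs(sta$tau_hat) > 0)
  # hoop actin contraction elongates
  Hh <- intrinsic_loads(geom, mat,
                        activation_state(ga = -0.01, alpha_a = pi / 2), 1.8)
  expect_gt(intrinsic_strains(K, Hh)$zeta_hat, 1)
  expect_error(intrinsic_strains(c(K0 = 0, K1 = 1, K2 = 1, K3 = 1), Hm),
               "positive")
})

test_that("curvature grows monotonically with muscle activation", {
  geom <- default_geom; mat <- default_mat
  K <- rod_stiffnesses(geom, mat, 1.8)
  gms <- seq(0, -0.1, by = -0.02)
  kap <- vapply(gms, function(g) {
    if (g == 0) return(0)
    H <- intrinsic_loads(geom, mat,
                         activation_state(gm = g, muscle_pair = "left"), 1.8)
    intrinsic_strains(K, H)$kappa_hat
  }, numeric(1))
  expect_true(all(diff(kap) > 0))
})

test_that("torsion peaks at an interior actin tilt near 45 degrees", {
  geom <- default_geom; mat <- default_mat
  K <- rod_stiffnesses(geom, mat, 1.8)
  al <- seq(0.1, pi / 2 - 0.02, length.out = 80)
  tau <- vapply(al, function(a) {
    H <- intrinsic_loads(geom, mat, activation_state(ga = -0.01, alpha_a = a),
                         1.8)
    abs(intrinsic_strains(K, H)$tau_hat)
  }, numeric(1))
  amax <- al[which.max(tau)]
  expect_gt(amax, pi / 6)
  expect_lt(amax, pi / 3)
  # interior maximum: endpoints strictly below the peak
  expect_gt(max(tau), tau[1])
  expect_gt(max(tau), tau[length(tau)])
})

test_that("accumulated energy is the depth of the quadratic minimum", {
  geom <- default_geom; mat <- default_mat
  K <- rod_stiffnesses(geom, mat, 1.8)
  expect_equal(accumulated_energy(K, c(H0 = 0, H1 = 0, H2 = 0, H3 = 0)), 0)
  act <- activation_state(gm = -0.15, muscle_pair = "left", ga = -0.01,
                          alpha_a = pi / 4)
  H <- intrinsic_loads(geom, mat, act, 1.8)
  Wc <- accumulated_energy(K, H)
  expect_gt(Wc, 0)
  st <- intrinsic_strains(K, H)
  e_min <- rod_energy(K, H, st$zeta_hat - 1, st$u_hat)
  expect_equal(Wc, -e_min, tolerance = 1e-12)
  # minimum property against random perturbations
  withr::with_seed(42, {
    for (k in 1:100) {
      d <- stats::rnorm(4, sd = 0.05)
      e_pert <- rod_energy(K, H, st$zeta_hat - 1 + d[1], st$u_hat + d[2:4])
      expect_gte(e_pert, e_min)
    }
  })
  # physical scale conversion
  Wc_J <- accumulated_energy(K, H, eps = 0.09, L_um = 90, mu_ref = 1e5)
  expect_equal(Wc_J, 0.09^4 * 1e5 * (90e-6)^3 * Wc, tolerance = 1e-12)
})

test_that("pointwise energy density: relaxed state, positivity, and
           consistency with the integrated coefficients", {
  # relaxed state has zero density everywhere
  expect_equal(second_order_density(c(0.2, 0.6, 0.95), c(0, 1, 2)), rep(0, 3))
  # passive density is non-negative pointwise at lambda = 1 (both correctors)
  pts_R <- runif(50); pts_T <- runif(50, 0, 2 * pi)
  for (cc in c("published", "variational")) {
    v <- second_order_density(pts_R, pts_T, xi = 0.2, u = c(0.1, -0.3, 0.25),
                              lambda_pre = 1, corrector = cc,
                              mat = homogeneous_mat())
    expect_true(all(v >= 0))
  }
  # activation-linear part vanishes at zero activation for any strain state
  act0 <- activation_state()
  v1 <- second_order_density(0.5, 0.3, xi = 0.1, u = c(0, 0.1, 0),
                             activation = act0)
  v2 <- second_order_density(0.5, 0.3, xi = 0.1, u = c(0, 0.1, 0))
  expect_equal(v1, v2)
  # integrating the density over the section reproduces the rod energy
  geom <- default_geom; mat <- default_mat
  act <- activation_state(gm = -0.15, muscle_pair = "left", ga = -0.01,
                          alpha_a = pi / 4)
  K <- rod_stiffnesses(geom, mat, 1.8)
  H <- intrinsic_loads(geom, mat, act, 1.8)
  xi <- 0.05; u <- c(0.01, -0.02, 0.015)
  dens_int <- integrate_section(function(R, Theta) {
    second_order_density(R, Theta, xi = xi, u = u, lambda_pre = 1.8,
                         activation = act, geom = geom, mat = mat)
  }, geom, tol = 1e-8, jacobian = FALSE)
  expect_equal(dens_int, rod_energy(K, H, xi, u), tolerance = 1e-6)
})
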