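# Shared fixtures and independent oracles for the test suite.

default_geom <- section_geometry()
default_mat <- material_map()

# homogeneous material (all regions share mu) for classical-limit checks
homogeneous_mat <- function(mu = 1e5) {
  m <- material_map(mu = mu, mu_inner = mu, mu_muscle = 2 * mu,
                    kappa_core = mu)
  m$mu_muscle <- mu
  m
}

# Independent oracle for the rod reduction: evaluate the FULL nonlinear
# neo-Hookean energy density (with the slender-cylinder ansatz fields) at
# small finite eps and extract the eps^2 coefficient by a central second
# difference.  Shares nothing with the closed-form densities except the
# kinematic ansatz itself.
#
# g_fun(R, Theta) gives the pointwise activation magnitude of a single
# fiber family at angles (alpha, beta); mu is homogeneous (= 1).
numeric_rod_energy <- function(xi, u, lambda, corrector = "published",
                               g_fun = function(R, Theta) 0,
                               alpha = 0, beta = 0,
                               geom = default_geom, eps = 1e-3) {
  q <- first_order_constants(lambda, corrector)
  q1 <- q[["q1"]]; q2 <- q[["q2"]]
  sl <- sqrt(lambda)

  energy_at_eps <- function(ep) {
    f <- function(R, Theta) {
      vapply(seq_along(R), function(i) {
        Rr <- R[i]; Th <- Theta[i]
        r0 <- Rr / sl
        bend <- u[1] * sin(Th) - u[2] * cos(Th)
        bend2 <- u[1] * cos(Th) + u[2] * sin(Th)
        a1 <- r0 + ep * (-r0 * xi / 2 + q1 * r0^2 * bend)
        a2 <- Th + ep * q2 * r0 * bend2
        a1R <- 1 / sl + ep * (-xi / (2 * sl) + 2 * q1 * r0 * bend / sl)
        a1T <- ep * q1 * r0^2 * (u[1] * cos(Th) + u[2] * sin(Th))
        a2R <- ep * q2 * bend2 / sl
        a2T <- 1 + ep * q2 * r0 * (-u[1] * sin(Th) + u[2] * cos(Th))
        x <- a1 * cos(a2); y <- a1 * sin(a2)
        xR <- a1R * cos(a2) - a1 * sin(a2) * a2R
        xT <- a1T * cos(a2) - a1 * sin(a2) * a2T
        yR <- a1R * sin(a2) + a1 * cos(a2) * a2R
        yT <- a1T * sin(a2) + a1 * cos(a2) * a2T
        zt <- lambda * (1 + ep * xi)
        FF <- matrix(c(
          xR, xT / Rr, ep * zt * (-u[3] * y),
          yR, yT / Rr, ep * zt * (u[3] * x),
          0, 0, zt * (1 + ep * (u[1] * y - u[2] * x))), 3, 3, byrow = TRUE)
        g <- g_fun(Rr, Th)
        m <- fiber_direction(alpha, beta)
        G <- diag(3) + ep * g * tcrossprod(m)
        Fe <- FF %*% solve(G)
        J <- det(Fe)
        0.5 * (sum(Fe^2) - 3) - (1 / lambda) * (J - 1)
      }, numeric(1)) * R
    }
    integrate_section(f, geom, tol = 1e-9, n0 = 16, max_level = 4,
                      jacobian = FALSE)
  }
  e0 <- energy_at_eps(0)
  as.numeric(energy_at_eps(eps) + energy_at_eps(-eps) - 2 * e0) / (2 * eps^2)
}

# discrete geometric checks for a helix centerline with body-frame Darboux
# components u = (0, kappa, tau), zeta = 1, starting frame d1 = ex, d3 = ez
helix_geometry <- function(cl, kappa, tau) {
  nrm <- sqrt(kappa^2 + tau^2)
  axis <- (kappa * c(0, 1, 0) + tau * c(0, 0, 1)) / nrm
  rho <- kappa / nrm^2
  centre <- c(0, 0, 0) + rho * c(1, 0, 0)  # principal normal at Z=0 is +d1
  pts <- cbind(cl$x, cl$y, cl$z)
  rel <- sweep(pts, 2, centre)
  along <- rel %*% axis
  radial <- sqrt(rowSums(rel^2) - along^2)
  list(radial = radial, along = as.numeric(along), rho = rho,
       pitch = 2 * pi * tau / nrm^2, turn_dZ = 2 * pi / nrm)
}
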