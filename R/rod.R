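#' First-order section constants of the rod reduction
#'
#' The first-order in-plane correction of the slender-cylinder expansion has
#' the separable form `a1^(1) ~ q1 r^2 (u1 sinT - u2 cosT)`,
#' `a2^(1) ~ q2 r (u1 cosT + u2 sinT)`, with `q2 = 3 q1 + 1` imposed
#' pointwise by incompressibility.  Two closures for `q1(lambda)` are
#' provided:
#'
#' * `"published"`: `q1 = (lambda^3 - 2)/8`, `q2 = (2 + 3 lambda^3)/8`, the
#'   constants printed with the model; they keep the reduced bending
#'   stiffness positive for every pre-stretch and are used by the
#'   late-elongation machinery.
#' * `"variational"`: `q1 = -(1 + lambda^3)/8`, the energy-stationary
#'   (natural boundary condition) corrector; at `lambda = 1` it reproduces
#'   the classical Saint-Venant section field of an incompressible rod and
#'   the textbook stiffnesses exactly, but it loses bending stability for
#'   `lambda > (2 + sqrt(7))^(1/3) ~ 1.67`.
#'
#' Both satisfy the incompressibility relation `3 q1 - q2 + 1 = 0`.  See the
#' methods vignette for the full discussion.
#'
#' @param lambda_pre Axial pre-stretch (> 0).
#' @param corrector `"published"` (default) or `"variational"`.
#' @return Named vector `c(q1 = , q2 = )`.
#' @examples
#' first_order_constants(1)    # q1 = -0.125, q2 = 0.625
#' first_order_constants(1.8)  # q1 = 0.479, q2 = 2.437
#' @export
first_order_constants <- function(lambda_pre,
                                  corrector = c("published", "variational")) {
  corrector <- match.arg(corrector)
  if (lambda_pre <= 0) stop("lambda_pre must be positive")
  l3 <- lambda_pre^3
  q1 <- switch(corrector,
               published  = (l3 - 2) / 8,
               variational = -(1 + l3) / 8)
  c(q1 = q1, q2 = 3 * q1 + 1)
}

#' Zeroth-order solution of the slender-cylinder expansion
#'
#' At leading order the pre-stretched incompressible cylinder deforms
#' isochorically: the radial map solves `r' = R / (lambda r)` with
#' `r(0) = 0`, i.e. `r(R) = R / sqrt(lambda)`, and the Lagrange pressure is
#' uniform, `P0 = mu / lambda` (so `P0 = 1/lambda` in units of the local
#' shear modulus, fixed by the traction-free lateral surface).
#'
#' @param lambda_pre Axial pre-stretch (> 0).
#' @return List with the radial map `r0` (a function of `R`) and the
#'   reduced pressure `P0` (units of `mu`).
#' @examples
#' zeroth_order(1.8)$P0   # 1/1.8
#' @export
zeroth_order <- function(lambda_pre) {
  if (lambda_pre <= 0) stop("lambda_pre must be positive")
  force(lambda_pre)
  list(r0 = function(R) R / sqrt(lambda_pre), P0 = 1 / lambda_pre)
}

# --- second-order energy densities -----------------------------------------
# Densities include the dR dTheta Jacobian factor R and are per unit shear
# modulus.  Derived symbolically from the eps-expansion of the neo-Hookean
# energy with the active tensor G = G0 (I + eps g m x m); the linear
# (activation) densities are independent of the corrector choice for the
# fiber families used here except through q1 terms shown explicitly.

v2_quad_density <- function(which, R, Theta, lambda, q1) {
  l3 <- lambda^3
  switch(which,
    A2 = R * (l3 + 2) / (2 * lambda),
    B2 = {
      c2 <- cos(Theta)^2
      R^3 * (4 * l3 * q1 * c2 + 2 * l3 * q1 + l3 * c2 + l3 +
               16 * q1^2 - 4 * q1 * c2 + 6 * q1 - 4 * c2 + 3) / (2 * lambda^2)
    },
    C2 = {
      s2 <- sin(Theta)^2
      R^3 * (4 * l3 * q1 * s2 + 2 * l3 * q1 + l3 * s2 + l3 +
               16 * q1^2 - 4 * q1 * s2 + 6 * q1 - 4 * s2 + 3) / (2 * lambda^2)
    },
    D2 = R^3 * lambda / 2,
    stop("unknown density")
  )
}

v2_lin_density <- function(which, R, Theta, lambda, q1, alpha, beta) {
  l3 <- lambda^3
  sa2 <- sin(alpha)^2
  switch(which,
    A1 = R * (1 - (2 * l3 + 1) * cos(alpha)^2) / lambda,
    B1 = 2 * R^2 * (l3 * sin(Theta) * sa2 - l3 * sin(Theta) +
                      2 * q1 * sin(Theta) * sa2 -
                      4 * q1 * sa2 * sin(beta) * cos(Theta - beta) +
                      sin(Theta) * sa2 - sa2 * sin(beta) * cos(Theta - beta)) /
      lambda^1.5,
    C1 = 2 * R^2 * (-l3 * sa2 * cos(Theta) + l3 * cos(Theta) -
                      4 * q1 * sa2 * sin(beta) * sin(Theta - beta) -
                      2 * q1 * sa2 * cos(Theta) -
                      sa2 * sin(beta) * sin(Theta - beta) - sa2 * cos(Theta)) /
      lambda^1.5,
    D1 = -R^2 * sin(2 * alpha) * cos(beta),
    stop("unknown density")
  )
}

mu_of_region <- function(region, mat) {
  switch(region,
         core = mat$mu_inner, muscle = mat$mu_muscle,
         epidermis = mat$mu_epidermis, actin = mat$mu_actin,
         stop("unknown region"))
}

#' Rod stiffnesses of the heterogeneous section
#'
#' Integrates the second-order energy densities over the cross-section with
#' the per-region shear moduli, returning the extensional (`K0`), bending
#' (`K1`, `K2`) and torsional (`K3`) stiffnesses in the classical
#' convention: energy per unit reference length
#' `= 1/2 K0 xi^2 + 1/2 K1 u1^2 + ...`, so that for a homogeneous section
#' at `lambda = 1` (variational corrector) `K0 = 3 mu pi R^2`,
#' `K1 = K2 = 3 mu pi R^4 / 4` and `K3 = mu pi R^4 / 2` (with `R3 = 1`
#' nondimensional units: energy per unit `mu_ref R3^2`, curvatures per
#' reference length).
#'
#' @param geom A [section_geometry()].
#' @param mat A [material_map()].
#' @param lambda_pre Axial pre-stretch of the maintained state.
#' @param corrector Section corrector, see [first_order_constants()].
#' @param mu_ref Reference modulus used to nondimensionalise (default:
#'   cortical modulus).
#' @param tol Quadrature tolerance passed to [integrate_section()].
#' @return Named vector `c(K0, K1, K2, K3)` (dimensionless, units
#'   `mu_ref * R3^4 / R3^2` as above).
#' @examples
#' K <- rod_stiffnesses(section_geometry(), material_map(), 1.8)
#' @export
rod_stiffnesses <- function(geom, mat, lambda_pre,
                            corrector = c("published", "variational"),
                            mu_ref = mat$mu_epidermis, tol = 1e-8) {
  corrector <- match.arg(corrector)
  q <- first_order_constants(lambda_pre, corrector)
  ks <- c(A2 = "K0", B2 = "K1", C2 = "K2", D2 = "K3")
  out <- numeric(4); names(out) <- ks
  for (nm in names(ks)) {
    tot <- 0
    for (rg in c("core", "muscle", "epidermis", "actin")) {
      dens <- function(R, Theta) {
        v2_quad_density(nm, R, Theta, lambda_pre, q[["q1"]])
      }
      tot <- tot + (mu_of_region(rg, mat) / mu_ref) *
        integrate_section(dens, geom, regions = rg, tol = tol,
                          jacobian = FALSE)
    }
    out[ks[[nm]]] <- 2 * tot   # classical convention: E = 1/2 K x^2
  }
  if (any(out <= 0)) {
    warning(sprintf(
      "non-positive stiffness at lambda = %.3f with the %s corrector: %s",
      lambda_pre, corrector,
      paste(sprintf("%s = %.4g", names(out), out), collapse = ", ")))
  }
  out
}

#' Activation state of the section
#'
#' Collects the active channels driving the rod: the muscle pair(s) with
#' activation `gm` (axial fibers, `alpha = beta = 0`) and the actin
#' bundles in the outer ring with activation `ga` at tilt `alpha_a`
#' (`pi/2` = circumferential "loop" configuration; smaller tilts arise
#' when bending re-orients the bundles and generate twist).  The hoop
#' pre-strain channel (`c = (g0 - 1)/eps` in the actin ring) can be added
#' explicitly; it is off by default so that zero activation means the
#' maintained pre-stretched state.
#'
#' @param gm Muscle activation (negative = contraction; 0 disables).
#' @param muscle_pair `"left"`, `"right"` or `"all"`.
#' @param ga Actin activation (negative = contraction; 0 disables).
#' @param alpha_a Actin fiber tilt angle in `(0, pi/2]`.
#' @param c_prestrain Optional hoop pre-strain amplitude `c` applied in the
#'   actin ring (e.g. `(g0 - 1)/eps`); `NULL` to omit.
#' @return Object of class `activation_state`: a tibble of channels with
#'   columns `label`, `g`, `alpha`, `beta`, `regions`, `pair`.
#' @examples
#' activation_state(gm = -0.15, muscle_pair = "left", ga = -0.01)
#' @export
activation_state <- function(gm = 0, muscle_pair = c("left", "right", "all"),
                             ga = 0, alpha_a = pi / 2, c_prestrain = NULL) {
  muscle_pair <- match.arg(muscle_pair)
  if (abs(gm) > 0.5 || abs(ga) > 0.5) {
    stop("activations are incremental (order eps); |g| must not exceed 0.5")
  }
  rows <- list()
  if (gm != 0) {
    rows[[length(rows) + 1]] <- tibble::tibble(
      label = "muscle", g = gm, alpha = 0, beta = 0,
      regions = "muscle", pair = muscle_pair)
  }
  if (ga != 0) {
    if (!(alpha_a > 0 && alpha_a <= pi / 2)) stop("alpha_a must lie in (0, pi/2]")
    rows[[length(rows) + 1]] <- tibble::tibble(
      label = "actin", g = ga, alpha = alpha_a, beta = 0,
      regions = "actin", pair = "all")
  }
  if (!is.null(c_prestrain) && c_prestrain != 0) {
    rows[[length(rows) + 1]] <- tibble::tibble(
      label = "prestrain", g = c_prestrain, alpha = pi / 2, beta = 0,
      regions = "actin", pair = "all")
  }
  out <- if (length(rows)) dplyr::bind_rows(rows) else
    tibble::tibble(label = character(), g = numeric(), alpha = numeric(),
                   beta = numeric(), regions = character(), pair = character())
  class(out) <- c("activation_state", class(out))
  out
}

# integrate a linear density over the sectors of a muscle pair
integrate_muscle_pair <- function(dens, geom, pair) {
  ctrs <- muscle_sector_centers(geom, pair)
  w <- geom$muscle_halfwidth
  r_lo <- geom$pm - geom$muscle_halfdepth
  r_hi <- geom$pm + geom$muscle_halfdepth
  tot <- 0
  for (ctr in ctrs) {
    gr <- pracma::gaussLegendre(24, r_lo, r_hi)
    gt <- pracma::gaussLegendre(24, ctr - w, ctr + w)
    vals <- outer(gr$x, gt$x, dens)
    tot <- tot + as.numeric(gr$w %*% vals %*% gt$w)
  }
  tot
}

#' Intrinsic loads from the active channels
#'
#' Integrates the activation-linear energy densities over the regions of
#' each active channel, giving the loads `H0..H3` energy-conjugate to
#' extension `xi` and the Darboux components `u1, u2, u3`.  All loads
#' vanish when every activation is zero.
#'
#' @inheritParams rod_stiffnesses
#' @param activation An [activation_state()].
#' @return Named vector `c(H0, H1, H2, H3)` (units `mu_ref R3^2`-scaled,
#'   consistent with [rod_stiffnesses()]).
#' @examples
#' act <- activation_state(gm = -0.15, muscle_pair = "left")
#' intrinsic_loads(section_geometry(), material_map(), act, 1.8)
#' @export
intrinsic_loads <- function(geom, mat, activation, lambda_pre,
                            corrector = c("published", "variational"),
                            mu_ref = mat$mu_epidermis, tol = 1e-8) {
  corrector <- match.arg(corrector)
  q <- first_order_constants(lambda_pre, corrector)
  H <- c(H0 = 0, H1 = 0, H2 = 0, H3 = 0)
  dens_names <- c(H0 = "A1", H1 = "B1", H2 = "C1", H3 = "D1")
  if (nrow(activation) == 0) return(H)
  for (k in seq_len(nrow(activation))) {
    ch <- activation[k, ]
    for (hn in names(dens_names)) {
      dens <- function(R, Theta) {
        v2_lin_density(dens_names[[hn]], R, Theta, lambda_pre, q[["q1"]],
                       ch$alpha, ch$beta)
      }
      val <- if (ch$regions == "muscle") {
        (mat$mu_muscle / mu_ref) * integrate_muscle_pair(dens, geom, ch$pair)
      } else {
        (mu_of_region(ch$regions, mat) / mu_ref) *
          integrate_section(dens, geom, regions = ch$regions, tol = tol,
                            jacobian = FALSE)
      }
      H[hn] <- H[hn] + ch$g * val
    }
  }
  # clean tiny quadrature residue of exact symmetry cancellations
  H[abs(H) < 1e-12 * max(1, max(abs(H)))] <- 0
  H
}

#' Intrinsic strains of the activated rod
#'
#' The spontaneous extension and curvatures the free rod adopts under the
#' active loads: `zeta_hat = 1 - H0/K0`, `u_hat_i = -H_i/K_i`, plus the
#' Frenet curvature `kappa_hat = sqrt(u1^2 + u2^2)` and torsion
#' `tau_hat = u3_hat / zeta_hat` of the resulting space curve.
#'
#' @param K Stiffnesses from [rod_stiffnesses()].
#' @param H Loads from [intrinsic_loads()].
#' @return Object of class `intrinsic_strains`: list with `zeta_hat`,
#'   `u_hat` (length 3), `kappa_hat`, `tau_hat`.
#' @examples
#' geom <- section_geometry(); mat <- material_map()
#' K <- rod_stiffnesses(geom, mat, 1.8)
#' H <- intrinsic_loads(geom, mat, activation_state(gm = -0.15), 1.8)
#' intrinsic_strains(K, H)
#' @export
intrinsic_strains <- function(K, H) {
  if (any(K <= 0)) stop("all stiffnesses must be positive")
  zeta_hat <- 1 - H[["H0"]] / K[["K0"]]
  u_hat <- c(-H[["H1"]] / K[["K1"]], -H[["H2"]] / K[["K2"]], -H[["H3"]] / K[["K3"]])
  structure(list(zeta_hat = zeta_hat, u_hat = u_hat,
                 kappa_hat = sqrt(u_hat[1]^2 + u_hat[2]^2),
                 tau_hat = u_hat[3] / zeta_hat),
            class = "intrinsic_strains")
}

#' @export
print.intrinsic_strains <- function(x, ...) {
  cat(sprintf("intrinsic strains: zeta_hat = %.6g, u_hat = (%.4g, %.4g, %.4g)\n",
              x$zeta_hat, x$u_hat[1], x$u_hat[2], x$u_hat[3]))
  cat(sprintf("  Frenet: kappa_hat = %.6g, tau_hat = %.6g\n", x$kappa_hat, x$tau_hat))
  invisible(x)
}

#' Reduced rod energy of a strain state
#'
#' Quadratic rod energy per the reduction, measured from the maintained
#' pre-stretched state: `E = 1/2 K0 xi^2 + H0 xi + ... ` (nondimensional).
#' Its minimiser is the intrinsic strain state.
#'
#' @param K,H Stiffness and load vectors.
#' @param xi Extension increment (`zeta = 1 + xi` relative units).
#' @param u Length-3 Darboux vector.
#' @return Scalar energy (nondimensional).
#' @export
rod_energy <- function(K, H, xi, u) {
  0.5 * (K[["K0"]] * xi^2 + K[["K1"]] * u[1]^2 + K[["K2"]] * u[2]^2 +
           K[["K3"]] * u[3]^2) +
    H[["H0"]] * xi + H[["H1"]] * u[1] + H[["H2"]] * u[2] + H[["H3"]] * u[3]
}

#' Energy accumulated by a contraction
#'
#' The elastic energy stored when the rod relaxes to the intrinsic strains
#' of the active loads, measured from the pre-contraction state:
#' `Wc_hat = 1/2 sum_i H_i^2 / K_i` (the depth of the quadratic energy
#' minimum).  Optionally converted to joules through the slenderness and
#' physical scale: `Wc = eps^4 * mu_ref * L^3 * Wc_hat`.
#'
#' @param K,H Stiffness and load vectors (nondimensional).
#' @param eps Slenderness used for dimensionalisation (optional).
#' @param L_um Physical length in micrometres (optional).
#' @param mu_ref Reference shear modulus in Pa (optional).
#' @return If `eps`, `L_um` and `mu_ref` are all given, energy in joules;
#'   otherwise the nondimensional `Wc_hat`.
#' @export
accumulated_energy <- function(K, H, eps = NULL, L_um = NULL, mu_ref = NULL) {
  wc_hat <- 0.5 * sum(H^2 / K)
  if (is.null(eps) || is.null(L_um) || is.null(mu_ref)) return(wc_hat)
  eps^4 * mu_ref * (L_um * 1e-6)^3 * wc_hat
}

#' Pointwise second-order energy density of the reduction
#'
#' Evaluates the second-order strain-energy density (including the area
#' Jacobian factor `R`) at a point of the cross-section for a given rod
#' strain state and activation: the quadratic form in
#' `(xi, u1, u2, u3)` plus the activation-linear terms.  Integrating this
#' density over the section gives the reduced rod energy whose coefficients
#' are [rod_stiffnesses()] and [intrinsic_loads()].
#'
#' @param R,Theta Point in the reference section (R in `[0, 1]`).
#' @param xi Extension increment.
#' @param u Length-3 Darboux vector.
#' @param lambda_pre Axial pre-stretch.
#' @param activation An [activation_state()] (default: none).
#' @param geom,mat Geometry and materials (locate the point's region and
#'   modulus).
#' @param corrector Section corrector, see [first_order_constants()].
#' @param mu_ref Reference modulus.
#' @return Density value(s), per unit `mu_ref` (dimensionless).
#' @examples
#' second_order_density(0.5, 0, xi = 0.1, u = c(0, 0.2, 0), lambda_pre = 1)
#' @export
second_order_density <- function(R, Theta, xi = 0, u = c(0, 0, 0),
                                 lambda_pre = 1.8,
                                 activation = activation_state(),
                                 geom = section_geometry(),
                                 mat = material_map(),
                                 corrector = c("published", "variational"),
                                 mu_ref = mat$mu_epidermis) {
  corrector <- match.arg(corrector)
  q1 <- first_order_constants(lambda_pre, corrector)[["q1"]]
  n <- max(length(R), length(Theta))
  R <- rep_len(R, n); Theta <- rep_len(Theta, n)
  reg <- region_of(R, Theta, geom)
  mu_loc <- vapply(reg, mu_of_region, numeric(1), mat = mat) / mu_ref
  quad <- v2_quad_density("A2", R, Theta, lambda_pre, q1) * xi^2 +
    v2_quad_density("B2", R, Theta, lambda_pre, q1) * u[1]^2 +
    v2_quad_density("C2", R, Theta, lambda_pre, q1) * u[2]^2 +
    v2_quad_density("D2", R, Theta, lambda_pre, q1) * u[3]^2
  lin <- rep(0, n)
  if (nrow(activation) > 0) {
    for (k in seq_len(nrow(activation))) {
      ch <- activation[k, ]
      inside <- if (ch$regions == "muscle") {
        ctrs <- muscle_sector_centers(geom, ch$pair)
        th <- Theta %% (2 * pi)
        radial <- R >= geom$pm - geom$muscle_halfdepth &
          R <= geom$pm + geom$muscle_halfdepth
        ang <- rep(FALSE, n)
        for (ctr in ctrs) {
          ang <- ang | abs((th - ctr + pi) %% (2 * pi) - pi) <=
            geom$muscle_halfwidth
        }
        radial & ang
      } else {
        reg == ch$regions
      }
      lin_k <- v2_lin_density("A1", R, Theta, lambda_pre, q1, ch$alpha, ch$beta) * xi +
        v2_lin_density("B1", R, Theta, lambda_pre, q1, ch$alpha, ch$beta) * u[1] +
        v2_lin_density("C1", R, Theta, lambda_pre, q1, ch$alpha, ch$beta) * u[2] +
        v2_lin_density("D1", R, Theta, lambda_pre, q1, ch$alpha, ch$beta) * u[3]
      lin <- lin + ch$g * lin_k * as.numeric(inside)
    }
  }
  unname(mu_loc * (quad + lin))
}
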