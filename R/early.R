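#' Equilibrium of the layered cylinder at given elongation and pre-strain
#'
#' Solves the axisymmetric finite-deformation state of the three-layer
#' cylinder at axial stretch `lambda` with hoop pre-strain `g0` confined to
#' the actin ring: the compressible core deforms uniformly with transverse
#' stretch `a` fixed by the zero axial traction condition on the end face
#' of the (passive, fluid-like) interior; the epidermis and ring are
#' incompressible, so their radial maps follow from radius continuity; the
#' radial Cauchy stress is integrated inward from the traction-free outer
#' surface.  The returned residual is the radial-stress continuity defect
#' at the core boundary — the equation that determines `g0(lambda)` in
#' [solve_prestrain()].
#'
#' @param lambda Axial elongation factor (>= 1).
#' @param g0 Hoop pre-strain eigenvalue in the actin ring, in (0, 1].
#' @param geom A [section_geometry()].
#' @param mat A [material_map()].
#' @param n_quad Radial quadrature points per layer for the stress integral.
#' @return List with the core transverse stretch `a`, core volume ratio
#'   `J_core`, core radial stress `srr_core` (Pa), the radial stress at the
#'   core boundary from the outside `srr_in` (Pa), the continuity
#'   `residual` (Pa), and `radius_um`, the deformed outer radius.
#' @export
early_equilibrium <- function(lambda, g0, geom, mat, n_quad = 200) {
  stopifnot(lambda >= 1, g0 > 0, g0 <= 1)
  mu_i <- mat$mu_inner; kap <- mat$kappa_core
  # core: uniform diag(a, a, lambda); zero axial Cauchy stress:
  # (mu_i/J)(lambda^2 - 1) + kappa * log(J)/J = 0
  J <- exp(-mu_i * (lambda^2 - 1) / kap)
  a <- sqrt(J / lambda)
  srr_core <- mu_i * (a^2 - lambda^2) / J

  R2 <- geom$R2; R2p <- geom$R2p
  r2sq_epi <- function(R) a^2 * R2^2 + (R^2 - R2^2) / lambda
  r2sq_ring <- function(R) r2sq_epi(R2p) + g0 * (R^2 - R2p^2) / lambda

  integrand <- function(R, layer) {
    if (layer == "epidermis") {
      r <- sqrt(r2sq_epi(R)); rp <- R / (lambda * r)
      mat$mu_epidermis * ((r / R)^2 - rp^2) * rp / r
    } else {
      r <- sqrt(r2sq_ring(R)); rp <- g0 * R / (lambda * r)
      mat$mu_actin * ((r / (R * g0))^2 - rp^2) * rp / r
    }
  }
  simpson <- function(f, lo, hi, n) {
    if (n %% 2 == 1) n <- n + 1
    x <- seq(lo, hi, length.out = n + 1)
    w <- c(1, rep(c(4, 2), length.out = n - 1), 1)
    sum(w * f(x)) * (hi - lo) / (3 * n)
  }
  # d srr / dR = (s_theta - s_rr) * r'/r; srr(R3 = 1) = 0
  int_ring <- simpson(function(R) integrand(R, "ring"), R2p, 1, n_quad)
  int_epi <- simpson(function(R) integrand(R, "epidermis"), R2, R2p, n_quad)
  srr_in <- -(int_ring + int_epi)

  list(a = a, J_core = J, srr_core = srr_core, srr_in = srr_in,
       residual = srr_in - srr_core,
       radius_um = sqrt(r2sq_ring(1)) * geom$R3_um)
}

#' Solve the hoop pre-strain sustaining a given elongation
#'
#' Root-solves the radial-stress continuity residual of
#' [early_equilibrium()] for `g0` at the given elongation `lambda`:
#' the unique `g0` in (0, 1] for which radius continuity, radial stress
#' continuity and the zero-traction conditions are simultaneously
#' satisfied.  `g0(1) = 1`, and `g0` decreases as the actomyosin drives
#' the elongation up; with the calibrated default geometry and materials,
#' `g0(1.8)` is approximately 0.88.
#'
#' @inheritParams early_equilibrium
#' @param tol Root tolerance on `g0`.
#' @return The pre-strain eigenvalue `g0`.
#' @examples
#' solve_prestrain(1.8, section_geometry(), material_map())
#' @export
solve_prestrain <- function(lambda, geom = section_geometry(),
                            mat = material_map(), tol = 1e-10) {
  if (lambda < 1) stop("lambda must be >= 1")
  if (lambda == 1) return(1)
  resid <- function(g0) early_equilibrium(lambda, g0, geom, mat)$residual
  lo <- 0.15
  if (resid(1) < 0 || resid(lo) > 0) {
    stop(sprintf("no pre-strain root in (%.2f, 1] at lambda = %.3f; check geometry/materials", lo, lambda))
  }
  stats::uniroot(resid, c(lo, 1), tol = tol)$root
}

#' Predicted outer radius during the early elongation
#'
#' Deformed outer radius of the layered model at elongation `lambda`, with
#' the pre-strain solved self-consistently by [solve_prestrain()].  For a
#' fully incompressible section (no core compressibility, `g0 = 1`) the
#' volume-conserving envelope `R3 / sqrt(lambda)` is recovered; the soft
#' compressible interior squeezed by the contractile ring makes the
#' prediction fall slightly below the envelope.
#'
#' @inheritParams early_equilibrium
#' @param g0 Optional: use this pre-strain instead of solving for it.
#' @return Outer radius in micrometres.
#' @examples
#' predict_radius(1)    # 11.1
#' predict_radius(1.8)  # about 8.2
#' @export
predict_radius <- function(lambda, geom = section_geometry(),
                           mat = material_map(), g0 = NULL) {
  if (lambda == 1) return(geom$R3_um)
  if (is.null(g0)) g0 <- solve_prestrain(lambda, geom, mat)
  early_equilibrium(lambda, g0, geom, mat)$radius_um
}

#' Elongation sustained by a given pre-strain
#'
#' Inverse of [solve_prestrain()]: the elongation `lambda` at which the
#' layered model is in equilibrium with hoop pre-strain `g0`.
#'
#' @param g0 Pre-strain eigenvalue in (0, 1].
#' @inheritParams early_equilibrium
#' @param lambda_max Upper bracket for the root search.
#' @return Elongation factor `lambda >= 1`.
#' @export
lambda_from_g0 <- function(g0, geom = section_geometry(), mat = material_map(),
                           lambda_max = 2.2) {
  stopifnot(g0 > 0, g0 <= 1)
  if (g0 == 1) return(1)
  f <- function(l) solve_prestrain(l, geom, mat) - g0
  stats::uniroot(f, c(1 + 1e-9, lambda_max), tol = 1e-9)$root
}

#' Myosin recruitment parameters
#'
#' Constants of the phenomenological myosin-population dynamics
#' `dXg/dt = (p1 - p2 Xg exp(-p3 Xg)) * tau_v / tau_p` with
#' `Xg = 1 - g0`: recruitment rate `p1` and debonding rate `p2` in 1/min,
#' dimensionless stress-feedback coefficient `p3`, viscoelastic time
#' `tau_v` and myosin activation time `tau_p` in seconds.
#'
#' @param p1 Recruitment rate (1/min).
#' @param p2 Debonding rate (1/min).
#' @param p3 Stress-feedback coefficient (dimensionless).
#' @param tau_v Viscoelastic time (s).
#' @param tau_p Activation time (s).
#' @return Object of class `myosin_params`.
#' @examples
#' myosin_params()
#' @export
myosin_params <- function(p1 = 0.6, p2 = 6, p3 = 0.75, tau_v = 6, tau_p = 1200) {
  stopifnot(p1 >= 0, p2 > 0, p3 > 0, tau_v > 0, tau_p > 0)
  structure(list(p1 = p1, p2 = p2, p3 = p3, tau_v = tau_v, tau_p = tau_p),
            class = "myosin_params")
}

myosin_rhs <- function(Xg, pars) {
  (pars$p1 - pars$p2 * Xg * exp(-pars$p3 * Xg)) * pars$tau_v / pars$tau_p
}

#' Fixed point of the myosin dynamics
#'
#' Solves `p1 = p2 Xg exp(-p3 Xg)` for the stationary bound-myosin fraction
#' `Xg*` (smallest root) and reports its linear stability.
#'
#' @param pars A [myosin_params()].
#' @return List with `Xg_star`, `g0_star = 1 - Xg_star`, and `jacobian`
#'   (the derivative of the right-hand side at the fixed point, 1/min).
#' @examples
#' myosin_fixed_point(myosin_params())$Xg_star  # about 0.109
#' @export
myosin_fixed_point <- function(pars = myosin_params()) {
  if (pars$p1 == 0) {
    return(list(Xg_star = 0, g0_star = 1,
                jacobian = -pars$p2 * pars$tau_v / pars$tau_p))
  }
  peak <- 1 / pars$p3
  if (pars$p1 >= pars$p2 * peak * exp(-1)) {
    stop("no fixed point: recruitment p1 exceeds the maximal debonding flux")
  }
  f <- function(x) pars$p1 - pars$p2 * x * exp(-pars$p3 * x)
  Xg <- stats::uniroot(f, c(0, peak), tol = 1e-12)$root
  jac <- -pars$p2 * exp(-pars$p3 * Xg) * (1 - pars$p3 * Xg) * pars$tau_v / pars$tau_p
  list(Xg_star = Xg, g0_star = 1 - Xg, jacobian = jac)
}

#' Simulate the myosin recruitment dynamics
#'
#' Integrates the bound-myosin fraction `Xg(t)` from `Xg(0) = Xg0` on the
#' supplied time grid (minutes) and returns the pre-strain trajectory
#' `g0(t) = 1 - Xg(t)`.
#'
#' @param pars A [myosin_params()].
#' @param t_grid Time grid in minutes (first entry is the initial time).
#' @param Xg0 Initial condition (default 0: all myosin unbound).
#' @return Tibble with columns `t_min`, `Xg`, `g0`.
#' @examples
#' simulate_myosin(myosin_params(), seq(0, 150, by = 5))
#' @export
simulate_myosin <- function(pars = myosin_params(), t_grid = seq(0, 150, by = 1),
                            Xg0 = 0) {
  stopifnot(length(t_grid) >= 2, !is.unsorted(t_grid))
  sol <- deSolve::ode(
    y = c(Xg = Xg0), times = t_grid,
    func = function(t, y, p) list(myosin_rhs(y[[1]], p)),
    parms = pars, method = "lsoda", rtol = 1e-10, atol = 1e-12)
  if (attr(sol, "istate")[1] < 0) stop("myosin ODE integration failed")
  tibble::tibble(t_min = sol[, "time"], Xg = sol[, "Xg"], g0 = 1 - sol[, "Xg"])
}

#' Fit the myosin dynamics to a pre-strain time series
#'
#' Least-squares estimation of the recruitment rate `p1` and feedback
#' coefficient `p3` from observations of `g0(t)`, with `p2`, `tau_v` and
#' `tau_p` held at their known values.  The forward model is integrated on
#' the observation grid for each candidate parameter pair and the residual
#' sum of squares minimised by Nelder-Mead.
#'
#' @param series Data frame with columns `t_min` and `g0` (observed).
#' @param pars_fixed A [myosin_params()] supplying `p2`, `tau_v`, `tau_p`
#'   (its `p1`, `p3` are ignored).
#' @param start Numeric starting values `c(p1, p3)`.
#' @param Xg0 Initial condition of the forward model.
#' @return Object of class `myosin_fit` with elements `coef` (named vector
#'   `p1`, `p3`), `fitted`, `residuals`, `ssr`, `data`, `convergence`.
#' @examples
#' obs <- simulate_myosin(myosin_params(), seq(0, 150, by = 8))
#' fit <- fit_myosin(obs)
#' coef(fit)
#' @export
fit_myosin <- function(series, pars_fixed = myosin_params(),
                       start = c(p1 = 0.4, p3 = 0.5), Xg0 = 0) {
  if (!all(c("t_min", "g0") %in% names(series))) {
    stop("series must have columns t_min and g0")
  }
  if (nrow(series) < 5) stop("need at least 5 time points to fit (p1, p3)")
  if (stats::sd(series$g0) < 1e-12) stop("degenerate series: g0 is constant")
  t_obs <- series$t_min; y_obs <- series$g0
  fwd <- function(p1, p3) {
    pp <- myosin_params(p1 = p1, p2 = pars_fixed$p2, p3 = p3,
                        tau_v = pars_fixed$tau_v, tau_p = pars_fixed$tau_p)
    grid <- if (t_obs[1] > 0) c(0, t_obs) else t_obs
    sim <- simulate_myosin(pp, grid, Xg0 = Xg0)
    sim$g0[match(t_obs, sim$t_min)]
  }
  obj <- function(theta) {
    if (theta[1] < 0 || theta[2] <= 0) return(1e10)
    pred <- tryCatch(fwd(theta[1], theta[2]), error = function(e) NULL)
    if (is.null(pred)) return(1e10)
    sum((pred - y_obs)^2)
  }
  opt <- stats::optim(start, obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-12, maxit = 2000))
  fitted <- fwd(opt$par[1], opt$par[2])
  structure(list(coef = c(p1 = unname(opt$par[1]), p3 = unname(opt$par[2])),
                 fitted = fitted, residuals = y_obs - fitted,
                 ssr = opt$value, data = tibble::as_tibble(series),
                 pars_fixed = pars_fixed, convergence = opt$convergence),
            class = "myosin_fit")
}

#' @export
coef.myosin_fit <- function(object, ...) object$coef

#' @export
print.myosin_fit <- function(x, ...) {
  cat(sprintf("myosin recruitment fit: p1 = %.4f /min, p3 = %.4f (ssr %.3g, n = %d)\n",
              x$coef[["p1"]], x$coef[["p3"]], x$ssr, nrow(x$data)))
  invisible(x)
}
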