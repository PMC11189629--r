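#' Unit fiber direction from spherical-type angles
#'
#' Fiber directions in the cylindrical frame `(eR, eTheta, eZ)` are
#' parameterised by two angles:
#' `m = sin(a) sin(b) eR + sin(a) cos(b) eTheta + cos(a) eZ`.
#' Muscle fibers run axially (`alpha = beta = 0`); the circumferential
#' ("hoop") actin bundles have `alpha = pi/2, beta = 0`.
#'
#' @param alpha,beta Angles in radians, both in `[-pi/2, pi/2]`.
#' @return Unit 3-vector `c(R = , Theta = , Z = )`.
#' @examples
#' fiber_direction(0, 0)        # muscle: axial
#' fiber_direction(pi / 2, 0)   # hoop actin: circumferential
#' @export
fiber_direction <- function(alpha, beta = 0) {
  if (abs(alpha) > pi / 2 + 1e-12 || abs(beta) > pi / 2 + 1e-12) {
    stop("fiber angles must lie in [-pi/2, pi/2]")
  }
  c(R = sin(alpha) * sin(beta), Theta = sin(alpha) * cos(beta), Z = cos(alpha))
}

#' Hoop pre-strain left by the early elongation
#'
#' The early actomyosin phase leaves the actin ring with a circumferential
#' pre-strain `G0 = diag(1, g0, 1)`, `0 < g0 <= 1`.  For the slender-body
#' expansion the deviation from unity is written `g0 = 1 + eps * c` with
#' `c <= 0`.  Either `g0` or `c` may be supplied; the other is filled in.
#'
#' @param g0 Hoop eigenvalue in `(0, 1]`.
#' @param c Scaled pre-strain amplitude (`g0 = 1 + eps * c`).
#' @param eps Slenderness ratio used for the conversion.
#' @param lambda_pre Axial pre-stretch `lambda >= 1` maintained by the
#'   actomyosin (1.8 at the end of the early phase).
#' @return An object of class `pre_strain` with fields `g0`, `c`, `eps`,
#'   `lambda_pre` and the matrix `G0`.
#' @examples
#' pre_strain(g0 = 0.88, eps = 0.2)
#' @export
pre_strain <- function(g0 = NULL, c = NULL, eps = 0.222, lambda_pre = 1.8) {
  stopifnot(eps > 0, lambda_pre > 0)
  if (is.null(g0) && is.null(c)) stop("supply g0 or c")
  if (is.null(g0)) g0 <- 1 + eps * c
  if (is.null(c)) c <- (g0 - 1) / eps
  if (!(g0 > 0 && g0 <= 1)) stop("g0 must lie in (0, 1]")
  if (abs(g0 - (1 + eps * c)) > 1e-12) stop("inconsistent g0 and c: g0 must equal 1 + eps*c")
  structure(list(g0 = g0, c = c, eps = eps, lambda_pre = lambda_pre,
                 G0 = diag(c(1, g0, 1))),
            class = "pre_strain")
}

#' Active strain tensor of a fiber family
#'
#' The multiplicative active strain of a contractile fiber family with
#' direction `m` and incremental activation `g` (negative for contraction)
#' is `G = G0 (I + eps * g * m %o% m)`, acting on top of the hoop
#' pre-strain `G0` (identity when no pre-strain is supplied).
#'
#' @param g Dimensionless activation (order one; enters at order `eps`).
#' @param m Unit fiber direction (length-3), e.g. from [fiber_direction()].
#' @param eps Slenderness ratio.
#' @param pre Optional [pre_strain()]; defaults to no pre-strain.
#' @return 3x3 matrix of class `active_tensor`.
#' @examples
#' active_tensor(-0.15, fiber_direction(0, 0), eps = 0.222)
#' @export
active_tensor <- function(g, m, eps, pre = NULL) {
  stopifnot(eps > 0)
  if (abs(sqrt(sum(m^2)) - 1) > 1e-8) stop("m must be a unit vector")
  G0 <- if (is.null(pre)) diag(3) else pre$G0
  G <- G0 %*% (diag(3) + eps * g * tcrossprod(m))
  structure(G, class = c("active_tensor", "matrix"))
}

rotate_about <- function(v, axis, angle) {
  # Rodrigues rotation, used only in tests/diagnostics
  axis <- axis / sqrt(sum(axis^2))
  v * cos(angle) + pracma::cross(axis, v) * sin(angle) +
    axis * sum(axis * v) * (1 - cos(angle))
}

gram_schmidt3 <- function(d1, d2, d3) {
  d3 <- d3 / sqrt(sum(d3^2))
  d1 <- d1 - sum(d1 * d3) * d3
  d1 <- d1 / sqrt(sum(d1^2))
  d2 <- pracma::cross(d3, d1)
  list(d1 = d1, d2 = d2, d3 = d3)
}

#' Reconstruct the deformed centerline from intrinsic strains
#'
#' Integrates the director frame equations `di'(Z) = zeta * u x di` and the
#' centerline equation `r'(Z) = zeta * d3` over the reference interval
#' `[0, L]` with a fixed-step 4th-order Runge-Kutta scheme; the frame is
#' re-orthonormalised (Gram-Schmidt) after every step so that the triads
#' stay orthonormal to machine precision over long integrations.
#'
#' @param zeta Axial extension (dimensionless).
#' @param u Darboux curvature components: either a length-3 numeric vector
#'   (constant along the rod) or a function `u(Z)` returning one.
#'   Components are per unit reference length (units `1/L` of `L`).
#' @param L Reference length (any length unit; output shares it).
#' @param n_steps Number of RK4 steps (at least 2).
#' @param r0,d1_0,d3_0 Initial position and frame (defaults: origin,
#'   `d1 = ex`, `d3 = ez`).
#' @return Object of class `centerline_state`: a tibble with columns `Z`,
#'   `x`, `y`, `z` and director components `d1x..d3z`, with attributes
#'   `zeta` and `L`.
#' @examples
#' cl <- integrate_centerline(1, c(0, 0.5, 0), L = 10, n_steps = 200)
#' head(cl)
#' @export
integrate_centerline <- function(zeta, u, L, n_steps = 1000,
                                 r0 = c(0, 0, 0),
                                 d1_0 = c(1, 0, 0), d3_0 = c(0, 0, 1)) {
  stopifnot(n_steps >= 2, L > 0, zeta > 0)
  u_fun <- if (is.function(u)) u else function(Z) u
  h <- L / n_steps
  fr <- gram_schmidt3(d1_0, pracma::cross(d3_0, d1_0), d3_0)

  deriv <- function(Z, state) {
    d1 <- state[1:3]; d2 <- state[4:6]; d3 <- state[7:9]
    uv <- u_fun(Z)
    uu <- uv[1] * d1 + uv[2] * d2 + uv[3] * d3
    c(zeta * pracma::cross(uu, d1),
      zeta * pracma::cross(uu, d2),
      zeta * pracma::cross(uu, d3),
      zeta * d3)
  }

  state <- c(fr$d1, fr$d2, fr$d3, r0)
  out <- matrix(NA_real_, nrow = n_steps + 1, ncol = 13)
  out[1, ] <- c(0, state[10:12], state[1:9])
  Z <- 0
  for (i in seq_len(n_steps)) {
    k1 <- deriv(Z, state)
    k2 <- deriv(Z + h / 2, state + h / 2 * k1)
    k3 <- deriv(Z + h / 2, state + h / 2 * k2)
    k4 <- deriv(Z + h, state + h * k3)
    state <- state + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    g <- gram_schmidt3(state[1:3], state[4:6], state[7:9])
    state[1:9] <- c(g$d1, g$d2, g$d3)
    Z <- Z + h
    out[i + 1, ] <- c(Z, state[10:12], state[1:9])
  }
  colnames(out) <- c("Z", "x", "y", "z",
                     "d1x", "d1y", "d1z", "d2x", "d2y", "d2z",
                     "d3x", "d3y", "d3z")
  res <- tibble::as_tibble(as.data.frame(out))
  attr(res, "zeta") <- zeta
  attr(res, "L") <- L
  class(res) <- c("centerline_state", class(res))
  res
}

#' Arc length of a reconstructed centerline
#' @param cl A [integrate_centerline()] result.
#' @return Total arc length (same unit as `L`).
#' @export
centerline_arclength <- function(cl) {
  dx <- diff(cl$x); dy <- diff(cl$y); dz <- diff(cl$z)
  sum(sqrt(dx^2 + dy^2 + dz^2))
}

#' Export a centerline to CSV
#'
#' Writes the columns `Z, x, y, z, d1x..d3z` in a locale-independent way.
#'
#' @param cl A `centerline_state`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
centerline_to_csv <- function(cl, path) {
  utils::write.csv(as.data.frame(cl), path, row.names = FALSE)
  invisible(path)
}

#' Export a centerline as a Wavefront OBJ tube mesh
#'
#' Builds a tube of radius `radius` around the centerline by sweeping a
#' polygon along the director frame, for quick 3-D inspection in any mesh
#' viewer.
#'
#' @param cl A `centerline_state`.
#' @param path Output `.obj` path.
#' @param radius Tube radius (same unit as the centerline coordinates).
#' @param n_around Number of vertices around the tube.
#' @return `path`, invisibly.
#' @export
centerline_to_obj <- function(cl, path, radius = 1, n_around = 12) {
  ang <- seq(0, 2 * pi, length.out = n_around + 1)[-(n_around + 1)]
  n <- nrow(cl)
  verts <- matrix(NA_real_, nrow = n * n_around, ncol = 3)
  for (i in seq_len(n)) {
    ctr <- c(cl$x[i], cl$y[i], cl$z[i])
    d1 <- c(cl$d1x[i], cl$d1y[i], cl$d1z[i])
    d2 <- c(cl$d2x[i], cl$d2y[i], cl$d2z[i])
    for (j in seq_len(n_around)) {
      verts[(i - 1) * n_around + j, ] <-
        ctr + radius * (cos(ang[j]) * d1 + sin(ang[j]) * d2)
    }
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# elongrod centerline tube", con)
  writeLines(sprintf("v %.8g %.8g %.8g", verts[, 1], verts[, 2], verts[, 3]), con)
  faces <- character(0)
  for (i in seq_len(n - 1)) {
    for (j in seq_len(n_around)) {
      jn <- if (j == n_around) 1 else j + 1
      a <- (i - 1) * n_around + j
      b <- (i - 1) * n_around + jn
      cc <- i * n_around + jn
      d <- i * n_around + j
      faces <- c(faces, sprintf("f %d %d %d %d", a, b, cc, d))
    }
  }
  writeLines(faces, con)
  invisible(path)
}
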