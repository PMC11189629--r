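#' Cross-section geometry of the embryo model
#'
#' Describes the heterogeneous circular cross-section used throughout the
#' package: a central core (internal organs, tissues and fluid), four muscle
#' bands embedded in the core, an epidermis annulus, and a thin outer actin
#' ring where the circumferential actomyosin bundles act.  All radii are
#' stored as fractions of the outer radius `R3`; the physical scale is
#' carried by `R3_um` and `L_um`.
#'
#' The four muscle sectors are centred at angles
#' `theta0, pi - theta0, pi + theta0, 2*pi - theta0`; the two sectors with
#' negative x form the "left" pair.  Each muscle occupies a radial band of
#' half-thickness `muscle_halfdepth` centred at `pm`, and the angular
#' half-width is solved from the pair area fraction `sm` so that each pair
#' covers exactly `sm * pi * R3^2` of the section.
#'
#' @param R3_um Outer radius in micrometres (reference configuration).
#' @param L_um Reference length in micrometres.
#' @param R2 Inner radius of the epidermis layer (fraction of `R3`).
#' @param R2p Inner radius of the actin ring (fraction of `R3`); must
#'   satisfy `R2 < R2p < 1`.
#' @param sm Area of one muscle pair as a fraction of the section area.
#' @param pm Radial position of the muscle band centre (fraction of `R3`).
#' @param muscle_halfdepth Radial half-thickness of the muscle band
#'   (fraction of `R3`).
#' @param theta0 Angular offset of the muscle sector centres (radians).
#'
#' @return An object of class `section_geometry`.
#' @examples
#' geom <- section_geometry()
#' slenderness(geom)
#' @export
section_geometry <- function(R3_um = 11.1, L_um = 50,
                             R2 = 0.82, R2p = 0.8915,
                             sm = 0.025, pm = 0.75,
                             muscle_halfdepth = 0.05,
                             theta0 = pi / 4) {
  stopifnot(R3_um > 0, L_um > 0)
  if (!(0 < R2 && R2 < R2p && R2p < 1)) {
    stop("layer radii must satisfy 0 < R2 < R2p < 1 (fractions of R3)")
  }
  if (!(sm > 0 && sm < 0.5)) stop("sm must lie in (0, 0.5)")
  if (!(pm > 0 && pm < 1)) stop("pm must lie in (0, 1)")
  r_lo <- pm - muscle_halfdepth
  r_hi <- pm + muscle_halfdepth
  if (r_lo <= 0 || r_hi >= R2) {
    stop("muscle band [pm - halfdepth, pm + halfdepth] must lie inside the core (0, R2)")
  }
  # pair area = 2 sectors * w * (r_hi^2 - r_lo^2) = sm * pi
  w <- sm * pi / (2 * (r_hi^2 - r_lo^2))
  if (w >= pi / 4) stop("muscle sectors overlap; reduce sm or widen the radial band")
  centers <- c(theta0, pi - theta0, pi + theta0, 2 * pi - theta0)
  structure(
    list(R3_um = R3_um, L_um = L_um, R2 = R2, R2p = R2p,
         sm = sm, pm = pm, muscle_halfdepth = muscle_halfdepth,
         muscle_centers = centers, muscle_halfwidth = w, theta0 = theta0),
    class = "section_geometry"
  )
}

#' @export
print.section_geometry <- function(x, ...) {
  cat("Embryo cross-section geometry\n")
  cat(sprintf("  outer radius R3 : %.3f um, reference length L: %.3f um (eps = %.4f)\n",
              x$R3_um, x$L_um, slenderness(x)))
  cat(sprintf("  epidermis       : [%.3f, %.3f] R3\n", x$R2, x$R2p))
  cat(sprintf("  actin ring      : [%.3f, 1] R3\n", x$R2p))
  cat(sprintf("  muscles         : 4 sectors at pm = %.2f, half-depth %.3f, half-width %.4f rad\n",
              x$pm, x$muscle_halfdepth, x$muscle_halfwidth))
  invisible(x)
}

#' Slenderness ratio of the reference cylinder
#'
#' The small parameter of the rod reduction, `eps = R3 / L`.  With the
#' default geometry (11.1 um / 50 um) this is 0.222; some published
#' estimates round it to 0.2, which can be selected by overriding `L_um`.
#'
#' @param geom A [section_geometry()].
#' @return A single number.
#' @export
slenderness <- function(geom) geom$R3_um / geom$L_um

#' Shear moduli of the section materials
#'
#' Shear moduli (Pa) for the four material regions.  The epidermis and the
#' actin ring share the cortical modulus `mu`; the interior is far softer
#' (organs and fluid) and the muscles far stiffer.  The inner and muscle
#' ratios are package defaults chosen with the early-elongation calibration
#' (see the methods vignette); all values can be overridden.
#'
#' @param mu Cortical shear modulus in Pa (epidermis and actin ring).
#' @param mu_inner Core shear modulus in Pa.
#' @param mu_muscle Muscle shear modulus in Pa.
#' @param kappa_core Bulk modulus of the compressible core in Pa
#'   (early-elongation model only).
#' @return An object of class `material_map`.
#' @examples
#' material_map()
#' @export
material_map <- function(mu = 1e5, mu_inner = mu / 100, mu_muscle = 10 * mu,
                         kappa_core = 400 * mu_inner) {
  stopifnot(mu > 0, mu_inner > 0, mu_muscle > 0, kappa_core > 0)
  if (mu_muscle <= mu_inner) stop("mu_muscle must exceed mu_inner")
  structure(list(mu_epidermis = mu, mu_actin = mu, mu_inner = mu_inner,
                 mu_muscle = mu_muscle, kappa_core = kappa_core),
            class = "material_map")
}

#' @export
print.material_map <- function(x, ...) {
  cat("Section materials (Pa):\n")
  cat(sprintf("  epidermis %g, actin %g, inner %g, muscle %g, core bulk %g\n",
              x$mu_epidermis, x$mu_actin, x$mu_inner, x$mu_muscle, x$kappa_core))
  invisible(x)
}

in_muscle_sector <- function(R, Theta, geom) {
  th <- Theta %% (2 * pi)
  radial <- R >= geom$pm - geom$muscle_halfdepth & R <= geom$pm + geom$muscle_halfdepth
  ang <- rep(FALSE, length(th))
  for (ctr in geom$muscle_centers) {
    dd <- abs((th - ctr + pi) %% (2 * pi) - pi)
    ang <- ang | dd <= geom$muscle_halfwidth
  }
  radial & ang
}

#' Material region at a point of the cross-section
#'
#' @param R Radial coordinate(s), fraction of the outer radius (0 to 1).
#' @param Theta Angular coordinate(s) in radians.
#' @param geom A [section_geometry()].
#' @return Character vector with values `"core"`, `"muscle"`,
#'   `"epidermis"` or `"actin"`.  Muscle wins over core inside the muscle
#'   sectors.
#' @examples
#' geom <- section_geometry()
#' region_of(0, 0, geom)
#' region_of(geom$pm, geom$theta0, geom)
#' @export
region_of <- function(R, Theta, geom) {
  n <- max(length(R), length(Theta))
  R <- rep_len(R, n); Theta <- rep_len(Theta, n)
  if (any(R < 0 | R > 1)) stop("R must lie in [0, 1] (fraction of the outer radius R3)")
  out <- ifelse(R > geom$R2p, "actin", ifelse(R > geom$R2, "epidermis", "core"))
  mus <- in_muscle_sector(R, Theta, geom)
  out[mus & out == "core"] <- "muscle"
  out
}

muscle_sector_centers <- function(geom, pair = c("all", "left", "right")) {
  pair <- match.arg(pair)
  ctr <- geom$muscle_centers
  if (pair == "all") return(ctr)
  xneg <- cos(ctr) < 0
  if (pair == "left") ctr[xneg] else ctr[!xneg]
}

#' Decompose the cross-section into quadrature patches
#'
#' Internal helper used by [integrate_section()]: the section is cut into
#' annular patches (radial interval x angular interval) on which the
#' material label is constant.
#'
#' @param geom A [section_geometry()].
#' @return A tibble with columns `r_lo`, `r_hi`, `t_lo`, `t_hi`, `region`.
#' @keywords internal
section_patches <- function(geom) {
  m_lo <- geom$pm - geom$muscle_halfdepth
  m_hi <- geom$pm + geom$muscle_halfdepth
  w <- geom$muscle_halfwidth
  ctr <- sort(geom$muscle_centers %% (2 * pi))
  full <- c(0, 2 * pi)

  patch <- function(r_lo, r_hi, t_lo, t_hi, region) {
    tibble::tibble(r_lo = r_lo, r_hi = r_hi, t_lo = t_lo, t_hi = t_hi, region = region)
  }
  out <- list(
    patch(0, m_lo, full[1], full[2], "core"),
    patch(m_hi, geom$R2, full[1], full[2], "core"),
    patch(geom$R2, geom$R2p, full[1], full[2], "epidermis"),
    patch(geom$R2p, 1, full[1], full[2], "actin")
  )
  # muscle band annulus: alternating muscle sectors and core gaps
  bounds <- sort(c((ctr - w) %% (2 * pi), (ctr + w) %% (2 * pi)))
  bounds <- c(bounds, bounds[1] + 2 * pi)
  for (k in seq_len(length(bounds) - 1)) {
    t_lo <- bounds[k]; t_hi <- bounds[k + 1]
    mid <- (t_lo + t_hi) / 2
    lab <- if (any(abs(((mid - ctr) + pi) %% (2 * pi) - pi) <= w)) "muscle" else "core"
    out[[length(out) + 1]] <- patch(m_lo, m_hi, t_lo, t_hi, lab)
  }
  dplyr::bind_rows(out)
}

#' Integrate a function over the cross-section
#'
#' Computes `integral f(R, Theta) dR dTheta` over the section or a subset
#' of its material regions, using tensor-product Gauss-Legendre quadrature
#' on each constant-material patch.  The grid is refined (node doubling)
#' until the relative change between successive levels drops below `tol`.
#' By default the area measure `R dR dTheta` is used (`f = 1` over the
#' whole unit-radius section gives `pi`); with `jacobian = FALSE` the bare
#' `dR dTheta` measure is used instead, for integrands that already carry
#' the Jacobian factor (the rod energy densities do).
#'
#' @param f Function of `(R, Theta)`, vectorised in both arguments.
#' @param geom A [section_geometry()].
#' @param regions Character vector of region labels to include
#'   (default: all).
#' @param tol Relative convergence tolerance between refinement levels.
#' @param n0 Initial number of radial nodes per patch.
#' @param max_level Maximum number of doublings before failing.
#' @param jacobian Include the area Jacobian `R` (default `TRUE`).
#' @return The value of the integral (a single number).
#' @examples
#' geom <- section_geometry()
#' integrate_section(function(R, Theta) 1, geom)  # area pi of the unit disk
#' @export
integrate_section <- function(f, geom,
                              regions = c("core", "muscle", "epidermis", "actin"),
                              tol = 1e-6, n0 = 8, max_level = 6,
                              jacobian = TRUE) {
  patches <- section_patches(geom)
  patches <- patches[patches$region %in% regions & patches$r_hi > patches$r_lo, ]
  if (nrow(patches) == 0) return(0)

  level_value <- function(n) {
    tot <- 0
    for (k in seq_len(nrow(patches))) {
      p <- patches[k, ]
      gr <- pracma::gaussLegendre(n, p$r_lo, p$r_hi)
      nt <- max(4, ceiling(n * (p$t_hi - p$t_lo) / (2 * pi) * 8))
      gt <- pracma::gaussLegendre(nt, p$t_lo, p$t_hi)
      RR <- rep(gr$x, times = nt)
      TT <- rep(gt$x, each = n)
      vals <- matrix(rep_len(f(RR, TT), n * nt), n, nt)
      if (jacobian) vals <- vals * gr$x
      tot <- tot + as.numeric(gr$w %*% vals %*% gt$w)
    }
    tot
  }

  n <- n0
  prev <- level_value(n)
  for (lvl in seq_len(max_level)) {
    n <- n * 2
    cur <- level_value(n)
    denom <- max(abs(cur), abs(prev), .Machine$double.eps)
    rel <- abs(cur - prev) / denom
    if (rel < tol || abs(cur - prev) < 1e-12) {
      return(as.numeric(cur))
    }
    prev <- cur
  }
  stop(sprintf(
    "section quadrature did not converge: relative change %.3g after %d refinements (last value %.8g)",
    abs(cur - prev) / max(abs(cur), .Machine$double.eps), max_level, cur))
}

#' Areas of the section regions
#'
#' @param geom A [section_geometry()].
#' @return Named numeric vector of areas (in units of `R3^2`), one entry
#'   per region plus `"total"`.
#' @export
region_areas <- function(geom) {
  a <- vapply(c("core", "muscle", "epidermis", "actin"),
              function(rg) integrate_section(function(R, Theta) 1, geom,
                                             regions = rg),
              numeric(1))
  c(a, total = sum(a))
}
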