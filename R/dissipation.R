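#' Rotation environment of the embryo in the eggshell
#'
#' Physical constants for the torque and dissipation estimates: the embryo
#' of radius `R` and length `L` rotates at angular velocity `Omega_e`
#' (about 90 degrees per 2 s) in interstitial fluid of viscosity `eta`
#' inside an eggshell of radius `R_egg` and length `L_egg`; `delta_gap` is
#' the small fluid gap when the embryo approaches the shell and `Lc` the
#' contact-zone length.
#'
#' @param eta Fluid viscosity (Pa s); 1.9 mPa s for the sugar-rich
#'   interstitial fluid.
#' @param omega_e Angular velocity (rad/s).
#' @param R_um,L_um Embryo radius and length (micrometres) at the onset of
#'   muscle activity.
#' @param R_egg_um,L_egg_um Eggshell radius and length (micrometres).
#' @param delta_gap_um Small gap for the eccentric (lubrication) estimate.
#' @param Lc_um Contact-zone length; defaults to the shell length.
#' @return Object of class `rotation_environment`; `d_um` is the derived
#'   axis separation `R_egg - delta - R`.
#' @examples
#' rotation_environment()
#' @export
rotation_environment <- function(eta = 1.9e-3, omega_e = pi / 4,
                                 R_um = 8.2, L_um = 90,
                                 R_egg_um = 15, L_egg_um = 54,
                                 delta_gap_um = 0.5, Lc_um = L_egg_um) {
  stopifnot(eta > 0, omega_e > 0, R_um > 0, L_um > 0, R_egg_um > 0,
            delta_gap_um > 0, Lc_um > 0)
  if (R_um >= R_egg_um) stop("embryo radius must be smaller than the eggshell radius")
  d <- R_egg_um - delta_gap_um - R_um
  if (d < 0) stop("axis separation d = R_egg - delta - R must be non-negative")
  structure(list(eta = eta, omega_e = omega_e, R_um = R_um, L_um = L_um,
                 R_egg_um = R_egg_um, L_egg_um = L_egg_um,
                 delta_gap_um = delta_gap_um, Lc_um = Lc_um, d_um = d),
            class = "rotation_environment")
}

#' Muscle torque parameters
#'
#' The muscle sarcomeres attach to the epidermis through dense bodies,
#' crossing the horizontal plane at about 45 degrees with an axial
#' deviation of about 6 degrees; an activated pair therefore contributes an
#' axial torque with geometric factor `ag = sin(beta_dev) * cos(alpha_cross)`.
#'
#' @param mu_muscle Muscle shear modulus (Pa).
#' @param sm Muscle pair area fraction.
#' @param pm Radial position of the muscles (fraction of R).
#' @param beta_dev Deviation of the muscle axis from the anterior-posterior
#'   axis (radians; about 6 degrees).
#' @param alpha_cross Sarcomere crossing angle (radians; about 45 degrees).
#' @param gm Activation magnitude (positive here; enters as `eps * gm`).
#' @param eps Slenderness ratio (default 11.1/50).
#' @return Object of class `muscle_torque_params`.
#' @export
muscle_torque_params <- function(mu_muscle = 1e5, sm = 0.025, pm = 0.75,
                                 beta_dev = 6 * pi / 180,
                                 alpha_cross = pi / 4,
                                 gm = 0.15, eps = 11.1 / 50) {
  stopifnot(mu_muscle > 0, sm > 0, pm > 0, beta_dev >= 0, gm >= 0, eps > 0)
  structure(list(mu_muscle = mu_muscle, sm = sm, pm = pm,
                 beta_dev = beta_dev, alpha_cross = alpha_cross,
                 gm = gm, eps = eps),
            class = "muscle_torque_params")
}

#' Active muscle torque about the body axis
#'
#' Order-of-magnitude estimate of the torque exerted by one active muscle
#' pair: `Lambda_m = mu_m * pi * R^3 * sm * pm * ag * (eps * gm)` with
#' `ag = sin(beta_dev) cos(alpha_cross)`.  With the default parameters the
#' dimensionless prefactor `sm * pm * ag * eps * gm` is about 4.6e-5.
#'
#' @param params A [muscle_torque_params()].
#' @param R_um Embryo radius in micrometres.
#' @return List with `prefactor` (dimensionless) and `torque_Nm`.
#' @examples
#' muscle_torque()
#' @export
muscle_torque <- function(params = muscle_torque_params(), R_um = 8.2) {
  ag <- sin(params$beta_dev) * cos(params$alpha_cross)
  pref <- params$sm * params$pm * ag * params$eps * params$gm
  R <- R_um * 1e-6
  list(prefactor = pref, torque_Nm = pref * params$mu_muscle * pi * R^3)
}

#' Viscous torque on a concentric rotating cylinder
#'
#' Couette-type resisting torque on the embryo rotating coaxially inside
#' the eggshell: `Lambda_v = 4 pi eta Omega_e L R^2 * R_egg^2 / (R_egg^2 - R^2)`.
#' Diverges as the radii approach; reduces to the isolated-cylinder drag
#' `4 pi eta Omega_e L R^2` for a wide shell.
#'
#' @param env A [rotation_environment()].
#' @return Torque in N m.
#' @examples
#' concentric_viscous_torque(rotation_environment())
#' @export
concentric_viscous_torque <- function(env = rotation_environment()) {
  R <- env$R_um * 1e-6; Re <- env$R_egg_um * 1e-6; L <- env$L_um * 1e-6
  if (R >= Re) stop("concentric torque requires R < R_egg")
  4 * pi * env$eta * env$omega_e * L * R^2 * Re^2 / (Re^2 - R^2)
}

#' Viscous torque for an eccentric embryo near the shell (small gap)
#'
#' Lubrication asymptotics of the journal-bearing torque when the rotating
#' embryo approaches the eggshell wall, leaving a small fluid gap `delta`:
#' `Lambda_v~ = 2 sqrt(2) pi eta Omega_e Lc R_egg^2 sqrt(R_egg/delta) (R_egg - d)/d`,
#' with `d = R_egg - delta - R` the axis separation.  Scales as
#' `delta^(-1/2)` and always exceeds the concentric estimate.
#'
#' @param env A [rotation_environment()].
#' @param warn_range Warn when `delta` is not small against the gap range
#'   (outside the asymptotic regime).
#' @return Torque in N m.
#' @examples
#' eccentric_viscous_torque(rotation_environment())
#' @export
eccentric_viscous_torque <- function(env = rotation_environment(),
                                     warn_range = TRUE) {
  if (env$delta_gap_um <= 0) stop("delta must be positive")
  if (warn_range && env$delta_gap_um > 0.2 * (env$R_egg_um - env$R_um)) {
    warning("delta is not small against R_egg - R: outside the small-gap asymptotic range")
  }
  Re <- env$R_egg_um * 1e-6; d <- env$d_um * 1e-6
  Lc <- env$Lc_um * 1e-6; del <- env$delta_gap_um * 1e-6
  if (d <= 0) stop("axis separation d must be positive for the eccentric estimate")
  2 * sqrt(2) * pi * env$eta * env$omega_e * Lc * Re^2 * sqrt(Re / del) *
    (Re - d) / d
}

#' Energy dissipated by one bending event
#'
#' A bending event rotates the embryo by `angle` against the resisting
#' torque: `E_diss = 1/2 * torque * angle^2`.
#'
#' @param torque_Nm Resisting torque (N m).
#' @param angle Rotation angle (radians), default `pi/2`.
#' @return Energy in joules.
#' @examples
#' bending_dissipated_energy(muscle_torque()$torque_Nm)
#' @export
bending_dissipated_energy <- function(torque_Nm, angle = pi / 2) {
  if (angle < 0) stop("angle must be non-negative")
  0.5 * torque_Nm * angle^2
}

#' Full torque and dissipation report
#'
#' Computes the active muscle torque, both viscous torque estimates, their
#' ratios and the per-bend dissipated energy for a given environment.
#'
#' @param env A [rotation_environment()].
#' @param params A [muscle_torque_params()].
#' @return A one-row tibble with columns `Lambda_m_Nm`, `prefactor`,
#'   `Lambda_v_Nm`, `Lambda_v_ecc_Nm`, `ratio_v_m`, `ratio_ecc_m`,
#'   `E_diss_J`.
#' @examples
#' dissipation_report()
#' @export
dissipation_report <- function(env = rotation_environment(),
                               params = muscle_torque_params()) {
  mt <- muscle_torque(params, env$R_um)
  lv <- concentric_viscous_torque(env)
  lve <- eccentric_viscous_torque(env, warn_range = FALSE)
  tibble::tibble(
    Lambda_m_Nm = mt$torque_Nm, prefactor = mt$prefactor,
    Lambda_v_Nm = lv, Lambda_v_ecc_Nm = lve,
    ratio_v_m = lv / mt$torque_Nm, ratio_ecc_m = lve / mt$torque_Nm,
    E_diss_J = bending_dissipated_energy(mt$torque_Nm))
}
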