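#' Per-cycle energy-conversion efficiency schedule
#'
#' Fraction `phi_i` of the accumulated contraction energy `Wc` transferred
#' to elongation at cycle `i`.  The default is a linear ramp from full
#' conversion at the first contraction down to 40 % at the last, matching
#' the observed late-phase slowdown; sigmoid and piecewise alternatives are
#' provided since the loss schedule is not uniquely determined by the data.
#'
#' @param n_cycles Number of cycles.
#' @param type `"linear"`, `"sigmoid"`, `"piecewise"` or `"constant"`.
#' @param phi_start,phi_end Efficiency at the first and last cycle.
#' @param breakpoint For `"piecewise"`: fraction of cycles at `phi_start`
#'   before the drop.
#' @return Numeric vector of length `n_cycles`, values in (0, 1].
#' @examples
#' efficiency_schedule(210)[c(1, 105, 210)]
#' @export
efficiency_schedule <- function(n_cycles, type = c("linear", "sigmoid",
                                                   "piecewise", "constant"),
                                phi_start = 1, phi_end = 0.4,
                                breakpoint = 0.5) {
  type <- match.arg(type)
  stopifnot(n_cycles >= 1, phi_start > 0, phi_start <= 1,
            phi_end > 0, phi_end <= 1)
  i <- seq_len(n_cycles)
  s <- if (n_cycles == 1) 0 else (i - 1) / (n_cycles - 1)
  phi <- switch(type,
    constant = rep(phi_start, n_cycles),
    linear = phi_start + (phi_end - phi_start) * s,
    sigmoid = phi_end + (phi_start - phi_end) / (1 + exp(10 * (s - 0.5))),
    piecewise = ifelse(s <= breakpoint, phi_start, phi_end))
  phi
}

#' Schedule of the late-elongation contraction cycles
#'
#' The muscle-activated phase lasts about 140 min with one contraction
#' roughly every 40 s, i.e. about 210 contractions; pairs on alternating
#' sides contract with `gm = -0.15` while the actin network holds
#' `ga = -0.01`.
#'
#' @param n_cycles Number of contraction cycles; default
#'   `floor(phase_duration_min * 60 / period_s)`.
#' @param period_s Interval between contractions (seconds).
#' @param phase_duration_min Duration of the muscle-activated phase (min).
#' @param gm Muscle activation per contraction (negative).
#' @param ga Actin activation during the contraction (negative).
#' @param alpha_a Actin fiber tilt during the contraction (radians); the
#'   bending re-orients the bundles away from the hoop configuration.
#' @param lambda_pre Maintained pre-stretch entering the rod coefficients.
#' @param efficiency Efficiency values (`phi_i`): a numeric vector of
#'   length `n_cycles`, or a type string passed to [efficiency_schedule()].
#' @param phi_start,phi_end Endpoints for a generated efficiency schedule.
#' @return Object of class `cycle_schedule`.
#' @examples
#' cycle_schedule()$n_cycles  # 210
#' @export
cycle_schedule <- function(n_cycles = NULL, period_s = 40,
                           phase_duration_min = 140,
                           gm = -0.15, ga = -0.01, alpha_a = pi / 4,
                           lambda_pre = 1.8,
                           efficiency = "linear",
                           phi_start = 1, phi_end = 0.4) {
  stopifnot(period_s > 0, phase_duration_min > 0)
  if (is.null(n_cycles)) n_cycles <- floor(phase_duration_min * 60 / period_s)
  n_cycles <- as.integer(n_cycles)
  stopifnot(n_cycles >= 1)
  phi <- if (is.numeric(efficiency)) {
    if (length(efficiency) == 1) rep(efficiency, n_cycles) else efficiency
  } else {
    efficiency_schedule(n_cycles, type = efficiency,
                        phi_start = phi_start, phi_end = phi_end)
  }
  if (length(phi) != n_cycles) stop("efficiency must have one value per cycle")
  if (any(phi <= 0 | phi > 1)) stop("efficiencies must lie in (0, 1]")
  structure(list(n_cycles = n_cycles, period_s = period_s,
                 phase_duration_min = phase_duration_min,
                 gm = gm, ga = ga, alpha_a = alpha_a,
                 lambda_pre = lambda_pre, phi = phi),
            class = "cycle_schedule")
}

#' @export
print.cycle_schedule <- function(x, ...) {
  cat(sprintf(
    "contraction schedule: %d cycles / %g s, gm = %g, ga = %g, phi %g -> %g\n",
    x$n_cycles, x$period_s, x$gm, x$ga, x$phi[1], x$phi[x$n_cycles]))
  invisible(x)
}

#' Named mutant / wild-type scenarios of the late phase
#'
#' * `wild_type`: default activations with the linear efficiency ramp
#'   (full conversion early, 40 % at the end).
#' * `unc112`: muscle attachment knockdown — no muscle activation
#'   (`gm = ga = 0`), arresting elongation at the twofold stage.
#' * `spc1_pak1`: failure to maintain the actomyosin pre-stretch — no
#'   contraction cycles and `lambda` decays exponentially from 1.8,
#'   producing a net retraction.
#'
#' @param name Scenario name.
#' @param decay_tau_min Time constant (minutes) of the pre-stretch decay in
#'   the `spc1_pak1` scenario.
#' @param ... Overrides passed to [cycle_schedule()].
#' @return Object of class `late_scenario`: list with `name`, `schedule`
#'   and (for `spc1_pak1`) the pre-stretch trajectory `lambda_of_t`.
#' @examples
#' mutant_scenario("unc112")$schedule$gm  # 0
#' @export
mutant_scenario <- function(name = c("wild_type", "unc112", "spc1_pak1"),
                            decay_tau_min = 120, ...) {
  name <- match.arg(name)
  args <- list(...)
  if (name != "wild_type") {
    args$gm <- 0
    args$ga <- 0
  }
  sch <- do.call(cycle_schedule, args)
  lam_fn <- NULL
  if (name == "spc1_pak1") {
    l0 <- sch$lambda_pre
    lam_fn <- function(t_min) 1 + (l0 - 1) * exp(-t_min / decay_tau_min)
  }
  structure(list(name = name, schedule = sch, lambda_of_t = lam_fn),
            class = "late_scenario")
}

#' Energy accumulated by one muscle contraction
#'
#' Nondimensional elastic energy stored by a single contraction of one
#' muscle pair (plus the concurrent actin activity), obtained from the rod
#' quadratic form at its activated minimum.
#'
#' @param geom,mat Section geometry and materials.
#' @param schedule A [cycle_schedule()] (supplies `gm`, `ga`, `alpha_a`,
#'   `lambda_pre`).
#' @param pair Which muscle pair contracts.
#' @param corrector Section corrector (see [first_order_constants()]).
#' @return Nondimensional energy `Wc_hat` (units `mu_ref R3^2 L`-scaled).
#' @examples
#' cycle_contraction_energy(section_geometry(), material_map(), cycle_schedule())
#' @export
cycle_contraction_energy <- function(geom = section_geometry(),
                                     mat = material_map(),
                                     schedule = cycle_schedule(),
                                     pair = "left",
                                     corrector = "published") {
  act <- activation_state(gm = schedule$gm, muscle_pair = pair,
                          ga = schedule$ga, alpha_a = schedule$alpha_a)
  K <- rod_stiffnesses(geom, mat, schedule$lambda_pre, corrector = corrector)
  H <- intrinsic_loads(geom, mat, act, schedule$lambda_pre, corrector = corrector)
  accumulated_energy(K, H)
}

# sensitivity of the extensional load to a unit hoop actin activation
hoop_load_per_activation <- function(geom, mat, lambda_pre,
                                     corrector = "published") {
  act <- activation_state(ga = 1e-3, alpha_a = pi / 2)
  H <- intrinsic_loads(geom, mat, act, lambda_pre, corrector = corrector)
  H[["H0"]] / 1e-3
}

#' Relaxation transfer: energy to actin loop strain and elongation
#'
#' After a contraction the muscles relax and a fraction `phi` of the
#' accumulated energy `Wc` is handed to the circumferential actin network,
#' which adopts a loop configuration with activation `ga1` such that the
#' stored rod energy of that configuration equals `phi * Wc`.  The
#' corresponding intrinsic extension gives the length increment.
#'
#' @param Wc_hat Nondimensional accumulated energy of the contraction.
#' @param phi Conversion efficiency in (0, 1].
#' @param K Rod stiffnesses (same nondimensionalisation as `Wc_hat`).
#' @param h0a Extensional load per unit hoop activation, from the same
#'   section (computed internally by [simulate_late_phase()]).
#' @param eps Slenderness of the late-phase state.
#' @param L_um Current body length (micrometres).
#' @return List with `ga1` (post-relaxation actin activation, negative),
#'   `delta_zeta_um` (length increment) and `Wr_hat` (transferred energy).
#' @export
relaxation_transfer <- function(Wc_hat, phi, K, h0a, eps, L_um) {
  stopifnot(phi > 0, phi <= 1, Wc_hat >= 0)
  Wr <- phi * Wc_hat
  if (Wr == 0) return(list(ga1 = 0, delta_zeta_um = 0, Wr_hat = 0))
  ga1 <- -sqrt(2 * Wr * K[["K0"]]) / abs(h0a)
  if (1 + eps * ga1 <= 0) {
    stop(sprintf(
      "no admissible loop activation: eps*ga1 = %.3f <= -1 (active tensor degenerates)",
      eps * ga1))
  }
  xi_hat <- abs(ga1 * h0a) / K[["K0"]]   # intrinsic extension of the loop state
  list(ga1 = ga1, delta_zeta_um = eps * xi_hat * L_um, Wr_hat = Wr)
}

#' Calibration of the absolute energy scale
#'
#' The absolute energy scale of the cycle model depends on shear-modulus
#' values that are only known as ratios, so a single dimensionless factor
#' multiplying `Wc` is anchored once: with full conversion (`phi = 1`) and
#' default parameters the first-cycle length increment is 0.5 um at a body
#' length of 90 um.  The factor is then frozen for every scenario, so all
#' relative predictions (full-conversion endpoint, ramped wild type,
#' mutants) are genuine model outputs.
#'
#' @param geom,mat Section geometry and materials.
#' @param schedule A [cycle_schedule()].
#' @param anchor_dz_um,anchor_length_um The anchored first-cycle increment
#'   and body length.
#' @param corrector Section corrector.
#' @return Dimensionless calibration factor applied to `Wc_hat`.
#' @export
calibrate_energy_scale <- function(geom = section_geometry(),
                                   mat = material_map(),
                                   schedule = cycle_schedule(),
                                   anchor_dz_um = 0.5,
                                   anchor_length_um = 90,
                                   corrector = "published") {
  lam <- schedule$lambda_pre
  eps_late <- (geom$R3_um / sqrt(lam)) / anchor_length_um
  K <- rod_stiffnesses(geom, mat, lam, corrector = corrector)
  Wc <- cycle_contraction_energy(geom, mat, schedule, "left", corrector)
  if (Wc <= 0) stop("cannot calibrate: zero contraction energy")
  k_raw <- eps_late * sqrt(2 * Wc / K[["K0"]])
  (anchor_dz_um / anchor_length_um / k_raw)^2
}

#' Simulate the late (muscle-driven) elongation phase
#'
#' Runs the cyclic contraction-relaxation energy-transfer model: each cycle
#' one muscle pair contracts (alternating sides), storing bending/torsion/
#' compression energy `Wc`; on relaxation a fraction `phi_i` is converted
#' into circumferential actin activity whose intrinsic extension elongates
#' the body by `delta_zeta_i`.  The pre-stretch `lambda` and the
#' nondimensional section are fixed during the phase (they are maintained
#' by the actomyosin), so the per-cycle increment is proportional to the
#' current length; the radius is reported assuming volume conservation.
#'
#' For the `spc1_pak1` scenario no cycles occur and the length follows the
#' decaying pre-stretch trajectory.
#'
#' @param schedule A [cycle_schedule()], or a [mutant_scenario()] via
#'   `scenario`.
#' @param geom,mat Section geometry and materials.
#' @param initial_length_um Body length at the start of the phase.
#' @param scenario Optional [mutant_scenario()]; overrides `schedule`.
#' @param calibration Energy-scale factor; `NULL` (default) uses the frozen
#'   anchor of [calibrate_energy_scale()].
#' @param corrector Section corrector.
#' @return Object of class `elong_late_series`: tibble with columns
#'   `cycle`, `t_min`, `pair`, `phi`, `Wc_J`, `Wr_J`, `ga1`,
#'   `delta_zeta_um`, `length_um`, `radius_um`, with the calibration and
#'   slenderness in attributes.
#' @examples
#' wt <- simulate_late_phase(cycle_schedule(efficiency = "constant"))
#' tail(wt$length_um, 1)  # about 290 under full conversion
#' @export
simulate_late_phase <- function(schedule = cycle_schedule(),
                                geom = section_geometry(),
                                mat = material_map(),
                                initial_length_um = 90,
                                scenario = NULL,
                                calibration = NULL,
                                corrector = "published") {
  if (!is.null(scenario)) {
    stopifnot(inherits(scenario, "late_scenario"))
    schedule <- scenario$schedule
  }
  lam <- schedule$lambda_pre
  eps_late <- (geom$R3_um / sqrt(lam)) / initial_length_um
  n <- schedule$n_cycles
  t_min <- seq_len(n) * schedule$period_s / 60

  if (!is.null(scenario) && scenario$name == "spc1_pak1") {
    lamt <- scenario$lambda_of_t(t_min)
    len <- initial_length_um * lamt / lam
    out <- tibble::tibble(
      cycle = seq_len(n), t_min = t_min, pair = NA_character_,
      phi = schedule$phi, Wc_J = 0, Wr_J = 0, ga1 = 0,
      delta_zeta_um = c(len[1] - initial_length_um, diff(len)),
      length_um = len,
      radius_um = geom$R3_um / sqrt(lamt))
    attr(out, "calibration") <- 0
    attr(out, "eps") <- eps_late
    attr(out, "scenario") <- "spc1_pak1"
    class(out) <- c("elong_late_series", class(out))
    return(out)
  }

  active <- schedule$gm != 0 || schedule$ga != 0
  if (active) {
    K <- rod_stiffnesses(geom, mat, lam, corrector = corrector)
    Wc_hat <- cycle_contraction_energy(geom, mat, schedule, "left", corrector)
    h0a <- hoop_load_per_activation(geom, mat, lam, corrector)
    if (is.null(calibration)) {
      calibration <- calibrate_energy_scale(geom, mat,
        cycle_schedule(n_cycles = schedule$n_cycles,
                       period_s = schedule$period_s,
                       phase_duration_min = schedule$phase_duration_min,
                       alpha_a = schedule$alpha_a,
                       lambda_pre = lam, efficiency = "constant"),
        corrector = corrector)
    }
  } else {
    K <- NULL; Wc_hat <- 0; h0a <- 1; calibration <- 0
  }

  mu_ref <- mat$mu_epidermis
  L <- initial_length_um
  rec <- vector("list", n)
  pairs <- rep(c("left", "right"), length.out = n)
  for (i in seq_len(n)) {
    if (active && Wc_hat > 0) {
      tr <- relaxation_transfer(calibration * Wc_hat, schedule$phi[i], K,
                                h0a, eps_late, L)
      Wc_J <- calibration * Wc_hat * eps_late^4 * mu_ref * (L * 1e-6)^3
      Wr_J <- schedule$phi[i] * Wc_J
      dz <- tr$delta_zeta_um; ga1 <- tr$ga1
    } else {
      Wc_J <- 0; Wr_J <- 0; dz <- 0; ga1 <- 0
    }
    L <- L + dz
    rec[[i]] <- tibble::tibble(
      cycle = i, t_min = t_min[i], pair = pairs[i], phi = schedule$phi[i],
      Wc_J = Wc_J, Wr_J = Wr_J, ga1 = ga1, delta_zeta_um = dz,
      length_um = L,
      radius_um = (geom$R3_um / sqrt(lam)) * sqrt(initial_length_um / L))
  }
  out <- dplyr::bind_rows(rec)
  attr(out, "calibration") <- calibration
  attr(out, "eps") <- eps_late
  attr(out, "scenario") <- if (!is.null(scenario)) scenario$name else "custom"
  class(out) <- c("elong_late_series", class(out))
  out
}
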