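#' Observation-noise specification
#'
#' @param model `"multiplicative_lognormal"` (default; relative scatter as
#'   in embryo measurements) or `"additive_gaussian"`.
#' @param sigma Relative (lognormal) or absolute (gaussian) noise scale;
#'   0 disables noise.
#' @param seed Integer seed; identical seeds give identical series.
#' @return Object of class `noise_spec`.
#' @examples
#' noise_spec(sigma = 0.02, seed = 1)
#' @export
noise_spec <- function(model = c("multiplicative_lognormal", "additive_gaussian"),
                       sigma = 0.02, seed = 1L) {
  model <- match.arg(model)
  if (sigma < 0) stop("sigma must be non-negative")
  structure(list(model = model, sigma = sigma, seed = as.integer(seed)),
            class = "noise_spec")
}

apply_noise <- function(x, noise, stream = 0L) {
  if (noise$sigma == 0) return(x)
  withr::with_seed(noise$seed + stream, {
    if (noise$model == "multiplicative_lognormal") {
      x * exp(stats::rnorm(length(x), 0, noise$sigma))
    } else {
      x + stats::rnorm(length(x), 0, noise$sigma)
    }
  })
}

#' Generate a synthetic early-elongation observation series
#'
#' Runs the forward early-phase model — myosin recruitment dynamics giving
#' `g0(t)`, the layered-cylinder equilibrium giving `lambda(t)` and the
#' radius — and applies observation noise to `g0` and the radius.  With
#' `sigma = 0` the series equals the forward model exactly.
#'
#' @param pars A [myosin_params()] (the "true" generating parameters).
#' @param t_grid Observation times in minutes.
#' @param noise A [noise_spec()].
#' @param geom,mat Geometry and materials of the layered model.
#' @return Object of class `elong_early_series`: tibble with columns
#'   `t_min`, `g0_true`, `lambda`, `radius_true_um`, `g0_obs`,
#'   `radius_obs_um`.
#' @examples
#' gen_early_series(t_grid = seq(0, 150, by = 15), noise = noise_spec(sigma = 0))
#' @export
gen_early_series <- function(pars = myosin_params(),
                             t_grid = seq(0, 150, by = 7.5),
                             noise = noise_spec(),
                             geom = section_geometry(),
                             mat = material_map()) {
  sim <- simulate_myosin(pars, t_grid)
  lam <- vapply(sim$g0, function(g) lambda_from_g0(min(g, 1), geom, mat), numeric(1))
  rad <- vapply(seq_along(lam), function(i) {
    if (lam[i] <= 1) geom$R3_um else
      early_equilibrium(lam[i], min(sim$g0[i], 1), geom, mat)$radius_um
  }, numeric(1))
  out <- tibble::tibble(
    t_min = sim$t_min, g0_true = sim$g0, lambda = lam, radius_true_um = rad,
    g0_obs = apply_noise(sim$g0, noise, 0L),
    radius_obs_um = apply_noise(rad, noise, 1L))
  attr(out, "noise") <- noise
  attr(out, "pars") <- pars
  class(out) <- c("elong_early_series", class(out))
  out
}

#' Generate a synthetic late-elongation length series
#'
#' Simulates the requested scenario with [simulate_late_phase()] and
#' applies observation noise to the length.
#'
#' @param scenario Scenario name (see [mutant_scenario()]).
#' @param noise A [noise_spec()].
#' @param geom,mat Geometry and materials.
#' @param initial_length_um Length at the start of the phase.
#' @param ... Schedule overrides passed to [mutant_scenario()].
#' @return Tibble with columns `t_min`, `length_true_um`, `length_obs_um`.
#' @examples
#' gen_late_series("unc112", noise_spec(sigma = 0))
#' @export
gen_late_series <- function(scenario = c("wild_type", "unc112", "spc1_pak1"),
                            noise = noise_spec(),
                            geom = section_geometry(), mat = material_map(),
                            initial_length_um = 90, ...) {
  scenario <- match.arg(scenario)
  sc <- mutant_scenario(scenario, ...)
  sim <- simulate_late_phase(schedule = sc$schedule, geom = geom, mat = mat,
                             initial_length_um = initial_length_um,
                             scenario = sc)
  out <- tibble::tibble(
    t_min = sim$t_min, length_true_um = sim$length_um,
    length_obs_um = apply_noise(sim$length_um, noise, 2L))
  attr(out, "noise") <- noise
  attr(out, "scenario") <- scenario
  out
}

#' Deterministic centerline fixtures for shape regression
#'
#' Builds the deformed centerline for a given activation set: intrinsic
#' strains from the rod reduction, then frame integration.  Pure function
#' of its parameters, suitable for frozen regression fixtures.
#'
#' @param gm,muscle_pair,ga,alpha_a Activation set (see
#'   [activation_state()]).
#' @param geom,mat Geometry and materials.
#' @param lambda_pre Maintained pre-stretch.
#' @param n_steps Centerline integration steps.
#' @param corrector Section corrector.
#' @return List with `strains` (an `intrinsic_strains`), `centerline`
#'   (a `centerline_state`, coordinates in units of the body length) and
#'   the generating parameters.
#' @examples
#' fx <- gen_shape_fixture(gm = -0.05, alpha_a = pi / 4, ga = -0.01)
#' fx$strains$kappa_hat
#' @export
gen_shape_fixture <- function(gm = 0, muscle_pair = "left", ga = 0,
                              alpha_a = pi / 2,
                              geom = section_geometry(), mat = material_map(),
                              lambda_pre = 1.8, n_steps = 400,
                              corrector = "published") {
  if (abs(gm) > 0.2 || abs(ga) > 0.2) stop("fixture activations limited to |g| <= 0.2")
  act <- activation_state(gm = gm, muscle_pair = muscle_pair,
                          ga = ga, alpha_a = alpha_a)
  K <- rod_stiffnesses(geom, mat, lambda_pre, corrector = corrector)
  H <- intrinsic_loads(geom, mat, act, lambda_pre, corrector = corrector)
  st <- intrinsic_strains(K, H)
  cl <- integrate_centerline(st$zeta_hat, st$u_hat, L = 1, n_steps = n_steps)
  list(strains = st, centerline = cl,
       params = list(gm = gm, muscle_pair = muscle_pair, ga = ga,
                     alpha_a = alpha_a, lambda_pre = lambda_pre,
                     corrector = corrector))
}
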