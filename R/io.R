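#' Write a data table to CSV
#'
#' Locale-independent CSV writer (period decimal separator, no row names).
#'
#' @param df Data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_series_csv <- function(df, path) {
  utils::write.csv(as.data.frame(df), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a schema-checked CSV table
#'
#' Reads a CSV and validates it against an expected schema: the named
#' columns must be present and numeric.  Comma decimal separators and other
#' non-numeric content in a numeric column raise an error naming the
#' column rather than being silently coerced.
#'
#' @param path CSV path.
#' @param schema Character vector of required numeric column names.
#' @return A tibble.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write_series_csv(data.frame(t_min = 0:2, g0 = c(1, 0.99, 0.97)), f)
#' read_series_csv(f, c("t_min", "g0"))
#' @export
read_series_csv <- function(path, schema) {
  if (!file.exists(path)) stop("file not found: ", path)
  nf <- utils::count.fields(path, sep = ",")
  if (length(unique(nf)) > 1) {
    stop("malformed CSV (inconsistent field counts; comma decimal separators?): ",
         path)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0) stop("empty table: ", path)
  missing_cols <- setdiff(schema, names(df))
  if (length(missing_cols)) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  for (cl in schema) {
    if (!is.numeric(df[[cl]])) {
      stop(sprintf(
        "column '%s' is not numeric (comma decimal separators or stray text?)", cl))
    }
  }
  tibble::as_tibble(df)
}

run_config_defaults <- function() {
  list(
    geometry = list(R3_um = 11.1, L_um = 50, R2 = 0.82, R2p = 0.8915,
                    sm = 0.025, pm = 0.75, muscle_halfdepth = 0.05,
                    theta0 = pi / 4),
    materials = list(mu = 1e5, mu_inner = 1e3, mu_muscle = 1e6,
                     kappa_core = 4e5),
    activation = list(gm = -0.15, ga = -0.01, alpha_a = pi / 4,
                      muscle_pair = "left", lambda_pre = 1.8),
    schedule = list(n_cycles = NULL, period_s = 40, phase_duration_min = 140,
                    efficiency = "linear", phi_start = 1, phi_end = 0.4),
    environment = list(eta = 1.9e-3, omega_e = pi / 4, R_um = 8.2, L_um = 90,
                       R_egg_um = 15, L_egg_um = 54, delta_gap_um = 0.5),
    myosin = list(p1 = 0.6, p2 = 6, p3 = 0.75, tau_v = 6, tau_p = 1200),
    scenario = "wild_type",
    noise = list(model = "multiplicative_lognormal", sigma = 0.02),
    units = list(length = "um", time = "min", modulus = "Pa"),
    seed = 1L
  )
}

#' Read and validate a run configuration
#'
#' Loads a YAML or JSON configuration (or takes a list), validates every
#' key against the known configuration blocks (unknown keys are rejected,
#' naming the offender), checks the unit declarations, and merges with the
#' package defaults.
#'
#' @param config Path to a `.yaml`/`.yml`/`.json` file, or a named list.
#' @return The merged configuration list (class `run_config`).
#' @export
read_run_config <- function(config = list()) {
  if (is.character(config)) {
    config <- if (grepl("\\.json$", config, ignore.case = TRUE)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
  }
  if (!is.list(config)) stop("config must be a list or a YAML/JSON file path")
  defaults <- run_config_defaults()
  bad <- setdiff(names(config), names(defaults))
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  for (blk in names(config)) {
    if (is.list(defaults[[blk]]) && !is.null(names(defaults[[blk]]))) {
      if (!is.list(config[[blk]])) stop("config block '", blk, "' must be a mapping")
      badk <- setdiff(names(config[[blk]]), names(defaults[[blk]]))
      if (length(badk)) {
        stop("unknown key(s) in config block '", blk, "': ",
             paste(badk, collapse = ", "))
      }
      defaults[[blk]][names(config[[blk]])] <- config[[blk]]
    } else {
      defaults[[blk]] <- config[[blk]]
    }
  }
  u <- defaults$units
  if (!identical(u$length, "um") || !(u$time %in% c("min", "s")) ||
      !identical(u$modulus, "Pa")) {
    stop("units must declare length 'um', time 'min' or 's', modulus 'Pa'")
  }
  structure(defaults, class = c("run_config", "list"))
}

config_objects <- function(cfg) {
  geom <- do.call(section_geometry, cfg$geometry)
  mat <- do.call(material_map, cfg$materials)
  list(geom = geom, mat = mat)
}

provenance_record <- function(cfg, extra = list()) {
  c(list(
    package = "elongrod",
    version = as.character(utils::packageVersion("elongrod")),
    config_hash = rlang::hash(cfg),
    seed = cfg$seed,
    eps = cfg$geometry$R3_um / cfg$geometry$L_um,
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE)
  ), extra)
}

#' Run a named pipeline task
#'
#' Single entry point binding the pipeline stages, mirroring the analysis
#' workflows: solves, simulations and synthetic-data generation driven by a
#' validated configuration, with artifacts (CSV tables and a JSON report
#' including a provenance record) written to `out_dir` when given.
#'
#' Tasks:
#' * `"early-fit"`: solve the pre-strain and radius across the early phase.
#' * `"myosin-fit"`: fit `(p1, p3)` to a `g0(t)` series (synthetic when no
#'   input table is supplied).
#' * `"rod-solve"`: rod stiffnesses, loads and intrinsic strains for the
#'   configured activation.
#' * `"late-simulate"`: cyclic late-phase simulation for the configured
#'   scenario.
#' * `"dissipation"`: torque and dissipated-energy report.
#' * `"synth"`: write synthetic early and late observation series.
#'
#' @param task Task name.
#' @param config Configuration (list or YAML/JSON path), see
#'   [read_run_config()].
#' @param out_dir Optional output directory for artifacts.
#' @param input Optional input table (data frame or CSV path) for
#'   `"myosin-fit"`.
#' @return A list with the task results and the provenance record.
#' @export
elong_run <- function(task = c("early-fit", "myosin-fit", "rod-solve",
                               "late-simulate", "dissipation", "synth"),
                      config = list(), out_dir = NULL, input = NULL) {
  task <- match.arg(task)
  cfg <- read_run_config(config)
  ob <- config_objects(cfg)
  geom <- ob$geom; mat <- ob$mat
  mp <- do.call(myosin_params, cfg$myosin)
  noise <- noise_spec(model = cfg$noise$model, sigma = cfg$noise$sigma,
                      seed = cfg$seed)

  res <- switch(task,
    "early-fit" = {
      lam <- seq(1, cfg$activation$lambda_pre, length.out = 17)
      g0 <- vapply(lam, solve_prestrain, numeric(1), geom = geom, mat = mat)
      rad <- vapply(seq_along(lam), function(i) {
        predict_radius(lam[i], geom, mat, g0 = g0[i])
      }, numeric(1))
      list(table = tibble::tibble(lambda = lam, g0 = g0, radius_um = rad))
    },
    "myosin-fit" = {
      series <- if (is.null(input)) {
        es <- gen_early_series(mp, noise = noise, geom = geom, mat = mat)
        tibble::tibble(t_min = es$t_min, g0 = es$g0_obs)
      } else if (is.character(input)) {
        read_series_csv(input, c("t_min", "g0"))
      } else {
        tibble::as_tibble(input)
      }
      fit <- fit_myosin(series, pars_fixed = mp)
      list(fit = fit, coef = coef(fit), table = series)
    },
    "rod-solve" = {
      act <- activation_state(gm = cfg$activation$gm,
                              muscle_pair = cfg$activation$muscle_pair,
                              ga = cfg$activation$ga,
                              alpha_a = cfg$activation$alpha_a)
      K <- rod_stiffnesses(geom, mat, cfg$activation$lambda_pre)
      H <- intrinsic_loads(geom, mat, act, cfg$activation$lambda_pre)
      st <- intrinsic_strains(K, H)
      list(K = K, H = H, strains = st,
           table = tibble::tibble(
             quantity = c("zeta_hat", "u1_hat", "u2_hat", "u3_hat",
                          "kappa_hat", "tau_hat"),
             value = c(st$zeta_hat, st$u_hat, st$kappa_hat, st$tau_hat)))
    },
    "late-simulate" = {
      sc <- mutant_scenario(cfg$scenario,
                            period_s = cfg$schedule$period_s,
                            phase_duration_min = cfg$schedule$phase_duration_min,
                            efficiency = cfg$schedule$efficiency,
                            phi_start = cfg$schedule$phi_start,
                            phi_end = cfg$schedule$phi_end,
                            gm = cfg$activation$gm, ga = cfg$activation$ga,
                            alpha_a = cfg$activation$alpha_a,
                            lambda_pre = cfg$activation$lambda_pre)
      if (cfg$scenario != "wild_type") sc <- mutant_scenario(cfg$scenario)
      sim <- simulate_late_phase(schedule = sc$schedule, geom = geom,
                                 mat = mat, scenario = sc,
                                 initial_length_um = cfg$environment$L_um)
      list(table = sim, calibration = attr(sim, "calibration"))
    },
    "dissipation" = {
      env <- do.call(rotation_environment, cfg$environment)
      # the torque estimate uses the cortical-scale modulus (1e5 Pa default)
      prm <- muscle_torque_params(mu_muscle = cfg$materials$mu,
                                  eps = cfg$geometry$R3_um / cfg$geometry$L_um)
      list(table = dissipation_report(env, prm))
    },
    "synth" = {
      early <- gen_early_series(mp, noise = noise, geom = geom, mat = mat)
      late <- gen_late_series(cfg$scenario, noise = noise, geom = geom,
                              mat = mat,
                              initial_length_um = cfg$environment$L_um)
      list(early = early, late = late)
    })

  prov <- provenance_record(cfg, list(task = task))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(res)) {
      if (is.data.frame(res[[nm]])) {
        write_series_csv(res[[nm]], file.path(out_dir, paste0(task, "-", nm, ".csv")))
      }
    }
    report <- list(provenance = prov)
    if (!is.null(res$coef)) report$coef <- as.list(res$coef)
    if (!is.null(res$K)) report$K <- as.list(res$K)
    if (!is.null(res$H)) report$H <- as.list(res$H)
    if (!is.null(res$calibration)) report$calibration <- res$calibration
    jsonlite::write_json(report, file.path(out_dir, paste0(task, "-report.json")),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  c(res, list(provenance = prov))
}
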