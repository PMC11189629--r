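#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a myosin recruitment fit
#'
#' @param x A [fit_myosin()] result.
#' @param ... Unused.
#' @return One row per parameter with `term` and `estimate`.
#' @export
tidy.myosin_fit <- function(x, ...) {
  tibble::tibble(term = names(x$coef), estimate = unname(x$coef))
}

#' One-row summary of a myosin recruitment fit
#'
#' @param x A [fit_myosin()] result.
#' @param ... Unused.
#' @return Tibble with `ssr`, `sigma` (residual SD), `nobs`, `converged`.
#' @export
glance.myosin_fit <- function(x, ...) {
  n <- nrow(x$data)
  tibble::tibble(ssr = x$ssr,
                 sigma = sqrt(x$ssr / max(1, n - length(x$coef))),
                 nobs = n, converged = x$convergence == 0)
}

#' Plot a myosin fit against its data
#'
#' @param object A [fit_myosin()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.myosin_fit <- function(object, ...) {
  df <- dplyr::mutate(object$data, fitted = object$fitted)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t_min)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$g0), colour = "steelblue") +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "black") +
    ggplot2::labs(x = "time (min)", y = "hoop pre-strain g0",
                  title = "Myosin recruitment dynamics fit") +
    ggplot2::theme_minimal()
}

#' Plot an early-elongation series
#'
#' @param object A [gen_early_series()] result.
#' @param ... Unused.
#' @return A ggplot with normalised radius and pre-strain trajectories.
#' @export
autoplot.elong_early_series <- function(object, ...) {
  r0 <- object$radius_true_um[1]
  df <- tidyr::pivot_longer(
    dplyr::transmute(object, t_min = .data$t_min,
                     `g0` = .data$g0_obs,
                     `radius / initial` = .data$radius_obs_um / r0),
    -"t_min", names_to = "quantity", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(.data$t_min, .data$value)) +
    ggplot2::geom_point(size = 0.8, colour = "steelblue") +
    ggplot2::facet_wrap(~quantity, scales = "free_y") +
    ggplot2::labs(x = "time (min)", y = NULL,
                  title = "Early elongation: pre-strain and radius") +
    ggplot2::theme_minimal()
}

#' Plot a late-elongation simulation
#'
#' @param object A [simulate_late_phase()] result.
#' @param ... Unused.
#' @return A ggplot of length versus time.
#' @export
autoplot.elong_late_series <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$t_min, .data$length_um)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::labs(x = "time (min)", y = "length (um)",
                  title = sprintf("Late elongation (%s)",
                                  attr(object, "scenario") %||% "custom")) +
    ggplot2::theme_minimal()
}

#' Plot a reconstructed centerline in projection
#'
#' @param object A `centerline_state`.
#' @param ... Unused.
#' @return A ggplot showing the x-z and y-z projections.
#' @export
autoplot.centerline_state <- function(object, ...) {
  df <- tidyr::pivot_longer(
    dplyr::select(tibble::as_tibble(object), "z", "x", "y"),
    c("x", "y"), names_to = "axis", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(.data$z, .data$value)) +
    ggplot2::geom_path(colour = "steelblue") +
    ggplot2::facet_wrap(~axis) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "z", y = "transverse offset",
                  title = "Deformed centerline (projections)") +
    ggplot2::theme_minimal()
}

#' Plot the cross-section regions
#'
#' @param geom A [section_geometry()].
#' @param n Grid resolution.
#' @return A ggplot of the material regions.
#' @export
plot_section <- function(geom = section_geometry(), n = 201) {
  xs <- seq(-1, 1, length.out = n)
  grid <- expand.grid(x = xs, y = xs)
  grid$R <- sqrt(grid$x^2 + grid$y^2)
  grid$Theta <- atan2(grid$y, grid$x) %% (2 * pi)
  grid <- grid[grid$R <= 1, ]
  grid$region <- region_of(grid$R, grid$Theta, geom)
  ggplot2::ggplot(grid, ggplot2::aes(.data$x, .data$y, fill = .data$region)) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    ggplot2::labs(title = "Embryo cross-section", x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the torsion-versus-tilt map of the actin network
#'
#' Sweeps the actin fiber tilt and plots the intrinsic torsion, showing the
#' interior maximum near 45 degrees.
#'
#' @param geom,mat Geometry and materials.
#' @param ga Actin activation.
#' @param lambda_pre Pre-stretch.
#' @param n Number of tilt values.
#' @return A ggplot.
#' @export
plot_torsion_map <- function(geom = section_geometry(), mat = material_map(),
                             ga = -0.01, lambda_pre = 1.8, n = 40) {
  al <- seq(0.02, pi / 2 - 0.02, length.out = n)
  K <- rod_stiffnesses(geom, mat, lambda_pre)
  tau <- vapply(al, function(a) {
    H <- intrinsic_loads(geom, mat,
                         activation_state(ga = ga, alpha_a = a), lambda_pre)
    intrinsic_strains(K, H)$tau_hat
  }, numeric(1))
  ggplot2::ggplot(tibble::tibble(alpha = al, tau = tau),
                  ggplot2::aes(.data$alpha, .data$tau)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::labs(x = "actin tilt alpha (rad)", y = "intrinsic torsion",
                  title = "Torsion generated by tilted actin bundles") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data %||%
NULL
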