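#' Material card for an isotropic linear-elastic solid
#'
#' Bundles the elastic and strength constants of a dense material. Internal
#' mechanics run in N-mm-MPa; Young's modulus is taken in GPa at this API
#' boundary and converted explicitly where the solver needs MPa.
#'
#' @param name Material name.
#' @param E Young's modulus, GPa.
#' @param nu Poisson ratio (0 < nu < 0.5).
#' @param rho Density, g/cm^3.
#' @param sigma_y 0.2% proof strength, MPa (optional for bone).
#' @param sigma_u Ultimate tensile strength, MPa.
#'
#' @return An object of class `material_card`.
#' @export
material_card <- function(name, E, nu, rho, sigma_y = NA_real_,
                          sigma_u = NA_real_) {
  stopifnot(is.character(name), length(name) == 1)
  if (!is.finite(E) || E <= 0) stop("E must be > 0 (GPa)")
  if (!is.finite(nu) || nu <= 0 || nu >= 0.5) stop("nu must lie in (0, 0.5)")
  if (!is.finite(rho) || rho <= 0) stop("rho must be > 0 (g/cm^3)")
  if (is.finite(sigma_y) && is.finite(sigma_u)) {
    if (sigma_y <= 0 || sigma_y > sigma_u) {
      stop("require 0 < sigma_y <= sigma_u")
    }
  }
  structure(
    list(name = name, E = E, nu = nu, rho = rho,
         sigma_y = sigma_y, sigma_u = sigma_u),
    class = "material_card"
  )
}

#' @exportS3Method base::print
print.material_card <- function(x, ...) {
  cat(sprintf("<material_card> %s: E = %g GPa, nu = %g, rho = %g g/cm^3",
              x$name, x$E, x$nu, x$rho))
  if (is.finite(x$sigma_y)) {
    cat(sprintf(", sigma_y = %g MPa, sigma_u = %g MPa", x$sigma_y, x$sigma_u))
  }
  cat("\n")
  invisible(x)
}

#' Built-in dense Ti-6Al-4V (ELI) card
#'
#' Static properties of the fully dense, hot-isostatically-pressed alloy:
#' E = 110 GPa, nu = 0.33, rho = 4.43 g/cm^3, sigma_y = 880 MPa,
#' sigma_u = 950 MPa.
#'
#' @return A `material_card`.
#' @export
ti6al4v_card <- function() {
  material_card("Ti-6Al-4V (ELI)", E = 110, nu = 0.33, rho = 4.43,
                sigma_y = 880, sigma_u = 950)
}

#' Built-in cortical-bone card
#'
#' Isotropic cortical bone: E = 13 GPa, nu = 0.30. Density is a nominal
#' 1.85 g/cm^3 (used only for mass bookkeeping of bone regions, which never
#' enters the implant objectives).
#'
#' @return A `material_card`.
#' @export
cortical_bone_card <- function() {
  material_card("cortical bone", E = 13, nu = 0.30, rho = 1.85)
}

#' Built-in lattice-coupon calibration table
#'
#' The four experimentally measured (porosity, effective modulus) anchor
#' points for architected Ti-6Al-4V coupons, as a tibble with columns
#' `porosity` (fraction) and `E_eff_GPa`.
#'
#' @return A tibble with 4 rows.
#' @export
lattice_coupon_table <- function() {
  tibble::tibble(
    porosity = c(0.371, 0.300, 0.164, 0.041),
    E_eff_GPa = c(35, 43, 65, 89)
  )
}

#' Read or write a porosity calibration table
#'
#' Delimited-text interchange for (porosity, effective modulus) pairs with
#' header `porosity,E_eff_GPa`.
#'
#' @param path File path.
#' @return `read_calibration_table()` returns a tibble; the writer returns
#'   `path` invisibly.
#' @export
read_calibration_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!all(c("porosity", "E_eff_GPa") %in% names(df))) {
    stop("calibration table needs columns 'porosity' and 'E_eff_GPa'")
  }
  tibble::as_tibble(df[, c("porosity", "E_eff_GPa")])
}

#' @rdname read_calibration_table
#' @param points Tibble/data frame with columns `porosity`, `E_eff_GPa`.
#' @export
write_calibration_table <- function(points, path) {
  utils::write.csv(points[, c("porosity", "E_eff_GPa")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Lattice unit cell for the strut-to-porosity map
#'
#' Relative density of a strut lattice is modelled as
#' `rho_rel = density_coefficient * (d/a)^2`, clipped to (0, 1]. The default
#' coefficient `3*pi/4` is the simple-cubic strut value; other topologies
#' are swapped in by changing the coefficient.
#'
#' @param topology Cell topology label.
#' @param density_coefficient Dimensionless prefactor of `(d/a)^2`.
#' @param da_cap Feasibility cap on the strut slenderness `d/a`; thicker
#'   struts would merge and the point is flagged infeasible.
#' @return An object of class `lattice_cell`.
#' @export
lattice_cell <- function(topology = "simple-cubic-strut",
                         density_coefficient = 3 * pi / 4,
                         da_cap = 0.5) {
  stopifnot(density_coefficient > 0, da_cap > 0)
  structure(
    list(topology = topology,
         density_coefficient = density_coefficient,
         da_cap = da_cap),
    class = "lattice_cell"
  )
}

#' Calibrate the Gibson-Ashby porosity law
#'
#' Fits the open-cell power law `E_eff = C * E_solid * (1 - p)^n` to measured
#' (porosity, effective modulus) pairs by least squares on the log scale:
#' `log(E_eff/E_solid) ~ n * log(1 - p) + log(C)`. The prefactor C is left
#' unconstrained (not forced through `E_solid` at p = 0); predictions are
#' clipped at `E_solid`.
#'
#' @param points Data frame with columns `porosity` (fraction in [0,1)) and
#'   `E_eff_GPa`, e.g. [lattice_coupon_table()].
#' @param E_solid Dense-material modulus, GPa.
#' @return An object of class `porosity_law` with fields `E_solid`, `C`, `n`,
#'   `calibration`, `fit_r2` (R^2 on the log scale).
#' @examples
#' law <- calibrate_porosity_law(lattice_coupon_table(), E_solid = 110)
#' effective_modulus(law, 0.6)
#' @export
calibrate_porosity_law <- function(points, E_solid) {
  points <- tibble::as_tibble(points)
  if (!all(c("porosity", "E_eff_GPa") %in% names(points))) {
    stop("points need columns 'porosity' and 'E_eff_GPa'")
  }
  p <- points$porosity
  E <- points$E_eff_GPa
  if (length(p) < 2) stop("calibration needs at least 2 points")
  if (anyDuplicated(p)) stop("calibration porosities must be distinct")
  if (any(p < 0 | p >= 1)) stop("porosities must lie in [0, 1)")
  if (any(E <= 0)) stop("effective moduli must be > 0")
  if (any(E > E_solid)) {
    stop("effective modulus exceeds E_solid: invalid calibration point")
  }
  fit <- stats::lm(log(E / E_solid) ~ log(1 - p))
  C <- unname(exp(stats::coef(fit)[1]))
  n <- unname(stats::coef(fit)[2])
  r2 <- if (length(p) == 2) 1 else summary(fit)$r.squared
  if (n < 1) {
    warning("fitted exponent n < 1: outside the open-cell regime")
  }
  structure(
    list(E_solid = E_solid, C = C, n = n,
         calibration = points, fit_r2 = r2),
    class = "porosity_law"
  )
}

#' @exportS3Method base::print
print.porosity_law <- function(x, ...) {
  cat(sprintf(
    "<porosity_law> E_eff = %.4f * %.4g GPa * (1 - p)^%.4f  (log-scale R^2 = %.4f, %d points)\n",
    x$C, x$E_solid, x$n, x$fit_r2, nrow(x$calibration)))
  invisible(x)
}

#' Effective modulus of the homogenised lattice
#'
#' Evaluates the calibrated power law, clipped at the dense modulus:
#' `min(E_solid, C * E_solid * (1 - p)^n)`.
#'
#' @param law A `porosity_law`.
#' @param p Porosity fraction(s) in [0, 1); vectorised.
#' @return Effective Young's modulus, GPa.
#' @export
effective_modulus <- function(law, p) {
  stopifnot(inherits(law, "porosity_law"))
  if (any(!is.finite(p)) || any(p < 0 | p >= 1)) {
    stop("porosity must lie in [0, 1)")
  }
  pmin(law$E_solid, law$C * law$E_solid * (1 - p)^law$n)
}

#' Map strut diameter and cell size to porosity
#'
#' `rho_rel = density_coefficient * (d/a)^2` clipped to (0, 1];
#' porosity `p = 1 - rho_rel`. Slenderness `d/a` beyond the cell's cap is
#' geometrically infeasible (merging struts) and is flagged rather than
#' raised, so the DOE quality-control filter can drop the point.
#'
#' @param d Strut diameter, mm (vectorised).
#' @param a Unit-cell size, mm.
#' @param cell A [lattice_cell()].
#' @return A tibble with columns `d`, `a`, `p`, `feasible`.
#' @export
struts_to_porosity <- function(d, a, cell = lattice_cell()) {
  stopifnot(inherits(cell, "lattice_cell"))
  if (any(d <= 0) || any(a <= 0)) stop("d and a must be > 0")
  k <- pmax(length(d), length(a))
  d <- rep_len(d, k); a <- rep_len(a, k)
  da <- d / a
  rho_rel <- pmin(1, cell$density_coefficient * da^2)
  tibble::tibble(
    d = d, a = a,
    p = 1 - rho_rel,
    feasible = da <= cell$da_cap
  )
}

#' Macroscopic elastic strain at a reference stress
#'
#' Elastic strain (percent) of the homogenised lattice under a reference
#' compressive stress: `100 * sigma_ref / E_eff(p)` with sigma_ref in MPa and
#' E_eff converted GPa -> MPa. Increasing in porosity.
#'
#' @param law A `porosity_law`.
#' @param p Porosity fraction(s).
#' @param sigma_ref Reference stress, MPa (default 50).
#' @return Elastic strain in percent.
#' @export
elastic_strain_at_reference <- function(law, p, sigma_ref = 50) {
  if (any(sigma_ref < 0)) stop("sigma_ref must be >= 0")
  E_mpa <- effective_modulus(law, p) * 1000
  100 * sigma_ref / E_mpa
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the calibration of a porosity law
#'
#' One row per calibration point with the law's prediction and relative
#' residual.
#'
#' @param x A `porosity_law`.
#' @param ... Unused.
#' @return A tibble with columns `porosity`, `E_eff_GPa`, `fitted_GPa`,
#'   `rel_error`.
#' @export
tidy.porosity_law <- function(x, ...) {
  pts <- x$calibration
  fitted <- effective_modulus(x, pts$porosity)
  tibble::tibble(
    porosity = pts$porosity,
    E_eff_GPa = pts$E_eff_GPa,
    fitted_GPa = fitted,
    rel_error = (fitted - pts$E_eff_GPa) / pts$E_eff_GPa
  )
}

#' @rdname tidy.porosity_law
#' @export
glance.porosity_law <- function(x, ...) {
  tibble::tibble(E_solid = x$E_solid, C = x$C, n = x$n,
                 fit_r2 = x$fit_r2, n_points = nrow(x$calibration))
}

#' Plot a calibrated porosity law
#'
#' Calibration points overlaid on the fitted power-law curve.
#'
#' @param object A `porosity_law`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.porosity_law <- function(object, ...) {
  grid <- tibble::tibble(porosity = seq(0, 0.9, length.out = 200))
  grid$E_eff_GPa <- effective_modulus(object, grid$porosity)
  ggplot2::ggplot(object$calibration,
                  ggplot2::aes(x = .data$porosity, y = .data$E_eff_GPa)) +
    ggplot2::geom_line(data = grid, colour = "steelblue") +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "porosity (fraction)",
                  y = "effective modulus (GPa)",
                  title = sprintf("E_eff = %.2f E_s (1-p)^%.2f", object$C,
                                  object$n)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
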