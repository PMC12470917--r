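#' Uncertainty specification for the scatter nodes
#'
#' The factorised input-uncertainty graph: three independent root nodes
#' feeding every mechanical output — cortical-bone modulus scale (default
#' ±20%), bite-force scale (±30%), and build-porosity offset (±5 percentage
#' points) — plus the per-output Gaussian residual noise of the surrogate.
#' "±x" is read as a uniform factor/offset over `[1-x, 1+x]` (or
#' `[-x, +x]`); with `family = "normal"` the same ±x is a 95% interval
#' (sd = x/1.96).
#'
#' @param bone_modulus_pm Half-width of the bone-modulus scale scatter.
#' @param bite_force_pm Half-width of the bite-force scale scatter.
#' @param porosity_pm Half-width of the additive porosity offset.
#' @param family `"uniform"` (default) or `"normal"`.
#' @return An object of class `uncertainty_spec`.
#' @export
uncertainty_spec <- function(bone_modulus_pm = 0.20, bite_force_pm = 0.30,
                             porosity_pm = 0.05,
                             family = c("uniform", "normal")) {
  family <- match.arg(family)
  stopifnot(bone_modulus_pm >= 0, bite_force_pm >= 0, porosity_pm >= 0)
  structure(
    list(nodes = list(
      bone_modulus_scale = list(centre = 1, pm = bone_modulus_pm),
      bite_force_scale = list(centre = 1, pm = bite_force_pm),
      porosity_offset = list(centre = 0, pm = porosity_pm)),
      family = family),
    class = "uncertainty_spec"
  )
}

#' Draw a joint sample table from the uncertainty spec
#'
#' Forward sampling of the factorised joint distribution (all scatter nodes
#' are roots, so the product of the marginals is the joint); reproducible
#' under the seed.
#'
#' @param spec An [uncertainty_spec()].
#' @param n Number of samples.
#' @param seed Integer seed.
#' @return A tibble with columns `bone_modulus_scale`, `bite_force_scale`,
#'   `porosity_offset`.
#' @export
sample_joint <- function(spec, n = 10000, seed = 1) {
  stopifnot(inherits(spec, "uncertainty_spec"), n >= 1)
  set.seed(seed)
  draw <- function(node) {
    if (node$pm == 0) return(rep(node$centre, n))
    if (spec$family == "uniform") {
      stats::runif(n, node$centre - node$pm, node$centre + node$pm)
    } else {
      stats::rnorm(n, node$centre, node$pm / 1.96)
    }
  }
  tibble::as_tibble(lapply(spec$nodes, draw))
}

#' Exceedance thresholds for the reliability checks
#'
#' Allowable stress defaults to 0.9 of the Ti-6Al-4V proof strength
#' (0.9 x 880 = 792 MPa); the displacement limit is 1 mm; the risk cap for
#' design acceptance is 3%.
#'
#' @param sigma_allow Allowable plate stress, MPa.
#' @param sigma_y Proof strength used for the 0.9 sigma_y check, MPa.
#' @param disp_limit Displacement limit, mm.
#' @param risk_cap Acceptable exceedance probability.
#' @return A list of class `risk_thresholds`.
#' @export
risk_thresholds <- function(sigma_allow = 0.9 * 880, sigma_y = 880,
                            disp_limit = 1, risk_cap = 0.03) {
  structure(list(sigma_allow = sigma_allow, sigma_y = sigma_y,
                 disp_limit = disp_limit, risk_cap = risk_cap),
            class = "risk_thresholds")
}

#' Empirical exceedance probability with binomial standard error
#'
#' @param values Numeric sample of a response.
#' @param threshold Limit value.
#' @return List with `p_hat` and `se` (`sqrt(p(1-p)/n)`).
#' @export
exceedance_probability <- function(values, threshold) {
  n <- length(values)
  if (n < 1) stop("need at least one value")
  p <- mean(values > threshold)
  list(p_hat = p, se = sqrt(p * (1 - p) / n))
}

# map a perturbed porosity back to the equivalent strut diameter
porosity_to_d <- function(p, a, cell) {
  p <- pmin(0.98, pmax(1e-3, p))
  a * sqrt((1 - p) / cell$density_coefficient)
}

#' Propagate input scatter through the surrogate to a risk report
#'
#' For each Monte-Carlo sample the design's load is scaled by the bite-force
#' factor, the lattice porosity is offset and mapped back to an equivalent
#' strut diameter (the surrogate's porosity carrier), and the bone-modulus
#' multiplier is fed to the surrogate's sixth input when the fit has one;
#' the three targets are predicted, per-output Gaussian residual noise is
#' added, and exceedance fractions against the thresholds are reported with
#' binomial standard errors.
#'
#' @param design One-row tibble/list with `d`, `a`, `t_lat`, `t_plate`, `P`.
#' @param samples Tibble from [sample_joint()] (or `n`/`seed` to draw here).
#' @param fit A `surrogate_fit`.
#' @param residual A `residual_model` (optional: no noise when NULL).
#' @param thresholds A [risk_thresholds()].
#' @param cell The [lattice_cell()] of the design space.
#' @param n,seed Used only when `samples` is NULL.
#' @param uspec Uncertainty spec used when drawing here.
#' @return An object of class `risk_report`.
#' @export
propagate_risk <- function(design, samples = NULL, fit, residual = NULL,
                           thresholds = risk_thresholds(),
                           cell = lattice_cell(), n = 10000, seed = 1,
                           uspec = uncertainty_spec()) {
  if (is.null(samples)) samples <- sample_joint(uspec, n = n, seed = seed)
  design <- tibble::as_tibble(design)[1, ]
  m <- nrow(samples)
  p0 <- struts_to_porosity(design$d, design$a, cell)$p
  p_pert <- p0 + samples$porosity_offset
  X <- tibble::tibble(
    d = porosity_to_d(p_pert, design$a, cell),
    a = rep(design$a, m),
    t_lat = rep(design$t_lat, m),
    t_plate = rep(design$t_plate, m),
    P = design$P * samples$bite_force_scale
  )
  if ("bone_scale" %in% fit$inputs) {
    X$bone_scale <- samples$bone_modulus_scale
  }
  pred <- predict_surrogate(fit, X)
  n_extrap <- attr(pred, "extrapolated")
  if (!is.null(residual)) {
    for (tg in fit$targets) {
      pred[[tg]] <- pred[[tg]] + stats::rnorm(m, 0, residual$sigma[[tg]])
    }
  }
  pr1 <- exceedance_probability(pred$sigma_vm_max, thresholds$sigma_allow)
  pr2 <- exceedance_probability(pred$sigma_vm_max, 0.9 * thresholds$sigma_y)
  pr3 <- exceedance_probability(pred$delta_max, thresholds$disp_limit)
  structure(
    list(n_samples = m, seed = seed,
         Pr_stress_allow = pr1$p_hat, se_stress_allow = pr1$se,
         Pr_yield90 = pr2$p_hat, se_yield90 = pr2$se,
         Pr_disp = pr3$p_hat, se_disp = pr3$se,
         thresholds = thresholds, n_extrapolated = n_extrap,
         design = design),
    class = "risk_report"
  )
}

#' @exportS3Method base::print
print.risk_report <- function(x, ...) {
  cat(sprintf(
    "<risk_report> n = %d: Pr(stress>%g MPa) = %.4f, Pr(stress>0.9 sy) = %.4f, Pr(disp>%g mm) = %.4f\n",
    x$n_samples, x$thresholds$sigma_allow, x$Pr_stress_allow,
    x$thresholds$disp_limit, x$Pr_disp))
  invisible(x)
}

#' @rdname propagate_risk
#' @param x A `risk_report`.
#' @param ... Unused.
#' @export
tidy.risk_report <- function(x, ...) {
  tibble::tibble(
    criterion = c("stress_allow", "yield90", "disp"),
    threshold = c(x$thresholds$sigma_allow, 0.9 * x$thresholds$sigma_y,
                  x$thresholds$disp_limit),
    probability = c(x$Pr_stress_allow, x$Pr_yield90, x$Pr_disp),
    se = c(x$se_stress_allow, x$se_yield90, x$se_disp),
    n = x$n_samples
  )
}

#' Maximum risk across criteria
#'
#' @param report A `risk_report`.
#' @return Largest exceedance probability over the three criteria.
#' @export
max_risk <- function(report) {
  max(report$Pr_stress_allow, report$Pr_yield90, report$Pr_disp)
}

#' Spot-check the surrogate against the FE chain under scatter
#'
#' Reruns the full FE chain at `k` sampled perturbations of a design and
#' reports the maximum relative discrepancy per output between surrogate and
#' FE predictions.
#'
#' @param design One-row design tibble.
#' @param k Number of FE re-solves (desk scale).
#' @param fit A `surrogate_fit`.
#' @param spec Template [construct_spec()] used for the FE chain.
#' @param law Porosity law.
#' @param uspec Uncertainty spec.
#' @param seed Sampling seed.
#' @return A tibble with columns `target`, `max_rel_discrepancy`; empty for
#'   `k = 0`.
#' @export
verify_against_fem <- function(design, k = 3, fit, spec = construct_spec(),
                               law = NULL, uspec = uncertainty_spec(),
                               seed = 1) {
  targets <- fit$targets
  if (k == 0) {
    return(tibble::tibble(target = character(0),
                          max_rel_discrepancy = numeric(0)))
  }
  design <- tibble::as_tibble(design)[1, ]
  samples <- sample_joint(uspec, n = k, seed = seed)
  worst <- stats::setNames(numeric(length(targets)), targets)
  cell <- spec$cell
  p0 <- struts_to_porosity(design$d, design$a, cell)$p
  for (s in seq_len(k)) {
    sp <- apply_design(spec, design)
    res <- solve_construct(sp, P = design$P * samples$bite_force_scale[s],
                           law = law,
                           bone_scale = samples$bone_modulus_scale[s],
                           porosity_offset = samples$porosity_offset[s])
    fe <- c(sigma_vm_max = res$sigma_vm_max_plate,
            delta_max = res$delta_max,
            sigma_screw_max = res$sigma_screw_max)
    X <- tibble::tibble(
      d = porosity_to_d(p0 + samples$porosity_offset[s], design$a, cell),
      a = design$a, t_lat = design$t_lat, t_plate = design$t_plate,
      P = design$P * samples$bite_force_scale[s])
    if ("bone_scale" %in% fit$inputs) {
      X$bone_scale <- samples$bone_modulus_scale[s]
    }
    pred <- predict_surrogate(fit, X)
    for (tg in targets) {
      worst[tg] <- max(worst[tg], abs(pred[[tg]] - fe[[tg]]) / abs(fe[[tg]]))
    }
  }
  tibble::tibble(target = targets, max_rel_discrepancy = unname(worst))
}

#' Plot a risk report
#'
#' Exceedance probabilities per criterion with 3-SE error bars and the
#' acceptance cap.
#'
#' @param object A `risk_report`.
#' @param cap Risk cap to draw (default the 3% acceptance cap).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.risk_report <- function(object, cap = 0.03, ...) {
  td <- tidy(object)
  ggplot2::ggplot(td, ggplot2::aes(x = .data$criterion,
                                   y = .data$probability)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = pmax(0, .data$probability -
                                                      3 * .data$se),
                                        ymax = .data$probability +
                                          3 * .data$se), width = 0.2) +
    ggplot2::geom_hline(yintercept = cap, linetype = 2, colour = "firebrick") +
    ggplot2::labs(x = NULL, y = "exceedance probability") +
    ggplot2::theme_minimal()
}
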