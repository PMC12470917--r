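# (linear surrogate fixture lives in helper-fixtures.R)

test_that("joint sampling honours the factorised node spec", {
  spec0 <- uncertainty_spec(0, 0, 0)
  s <- sample_joint(spec0, n = 50, seed = 1)
  expect_true(all(s$bone_modulus_scale == 1))
  expect_true(all(s$porosity_offset == 0))

  spec <- uncertainty_spec()
  s1 <- sample_joint(spec, n = 5000, seed = 42)
  s2 <- sample_joint(spec, n = 5000, seed = 42)
  expect_identical(s1, s2)
  # +-20% uniform scale has mean 1 within 3 standard errors
  se <- (0.4 / sqrt(12)) / sqrt(5000)
  expect_lt(abs(mean(s1$bone_modulus_scale) - 1), 3 * se)
  expect_true(all(s1$bite_force_scale >= 0.7 & s1$bite_force_scale <= 1.3))
  expect_error(sample_joint(spec, n = 0), "n >= 1")
})

test_that("exceedance probability follows the binomial arithmetic", {
  vals <- c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10)
  out <- exceedance_probability(vals, 7)
  expect_equal(out$p_hat, 0.3)
  expect_equal(out$se, sqrt(0.3 * 0.7 / 10))
  expect_equal(exceedance_probability(vals, 100)$p_hat, 0)
  expect_equal(exceedance_probability(vals, -1)$p_hat, 1)
  # monotone in the threshold
  expect_gte(exceedance_probability(vals, 2)$p_hat,
             exceedance_probability(vals, 5)$p_hat)
  expect_error(exceedance_probability(numeric(0), 1), "at least one")
})

test_that("Monte-Carlo exceedance matches the closed-form normal tail", {
  fit <- linear_fit()
  # only bite-force scatter, normal family: sigma_vm ~ N(600, (600*0.3/1.96)^2)
  uspec <- uncertainty_spec(bone_modulus_pm = 0, bite_force_pm = 0.3,
                            porosity_pm = 0, family = "normal")
  th <- risk_thresholds(sigma_allow = 700, sigma_y = 1000, disp_limit = 1)
  rep <- propagate_risk(canonical_design(), fit = fit, thresholds = th,
                        n = 10000, seed = 3, uspec = uspec)
  sd_s <- 600 * 0.3 / 1.96
  p_exact <- stats::pnorm(700, 600, sd_s, lower.tail = FALSE)
  expect_lt(abs(rep$Pr_stress_allow - p_exact),
            3 * sqrt(p_exact * (1 - p_exact) / 10000))
  # delta_max ~ N(1, .); threshold at the mean -> one half by symmetry
  expect_lt(abs(rep$Pr_disp - 0.5), 3 * rep$se_disp + 1e-3)
  # with Gaussian residual noise the variances add
  resid <- structure(list(sigma = c(sigma_vm_max = 50, delta_max = 1e-9,
                                    sigma_screw_max = 1e-9)),
                     class = "residual_model")
  rep2 <- propagate_risk(canonical_design(), fit = fit, residual = resid,
                         thresholds = th, n = 10000, seed = 4, uspec = uspec)
  p_exact2 <- stats::pnorm(700, 600, sqrt(sd_s^2 + 50^2), lower.tail = FALSE)
  expect_lt(abs(rep2$Pr_stress_allow - p_exact2),
            3 * sqrt(p_exact2 * (1 - p_exact2) / 10000))
})

test_that("zero scatter reduces the report to deterministic indicators", {
  fit <- linear_fit()
  uspec <- uncertainty_spec(0, 0, 0)
  th_lo <- risk_thresholds(sigma_allow = 500, sigma_y = 500, disp_limit = 0.5)
  th_hi <- risk_thresholds(sigma_allow = 700, sigma_y = 1000, disp_limit = 2)
  rep_lo <- propagate_risk(canonical_design(), fit = fit, thresholds = th_lo,
                           n = 500, seed = 1, uspec = uspec)
  rep_hi <- propagate_risk(canonical_design(), fit = fit, thresholds = th_hi,
                           n = 500, seed = 1, uspec = uspec)
  expect_equal(c(rep_lo$Pr_stress_allow, rep_lo$Pr_yield90, rep_lo$Pr_disp),
               c(1, 1, 1))
  expect_equal(c(rep_hi$Pr_stress_allow, rep_hi$Pr_yield90, rep_hi$Pr_disp),
               c(0, 0, 0))
  expect_equal(max_risk(rep_hi), 0)
})

test_that("Monte-Carlo standard error shrinks like 1/sqrt(n)", {
  fit <- linear_fit()
  uspec <- uncertainty_spec(0, 0.3, 0)
  th <- risk_thresholds(sigma_allow = 650, sigma_y = 1000, disp_limit = 10)
  r1 <- propagate_risk(canonical_design(), fit = fit, thresholds = th,
                       n = 10000, seed = 5, uspec = uspec)
  r4 <- propagate_risk(canonical_design(), fit = fit, thresholds = th,
                       n = 40000, seed = 6, uspec = uspec)
  expect_lt(abs(r4$se_stress_allow / r1$se_stress_allow - 0.5), 0.2 * 0.5)
})

test_that("porosity perturbations invert exactly through the strut map", {
  cell <- lattice_cell()
  p0 <- struts_to_porosity(0.7, 3, cell)$p
  d_back <- latticeplate:::porosity_to_d(p0, 3, cell)
  expect_equal(d_back, 0.7, tolerance = 1e-12)
  # an offset moves the equivalent diameter the right way
  d_softer <- latticeplate:::porosity_to_d(p0 + 0.05, 3, cell)
  expect_lt(d_softer, 0.7)
})

test_that("tidied risk reports expose the three criteria", {
  fit <- linear_fit()
  rep <- propagate_risk(canonical_design(), fit = fit, n = 200, seed = 1,
                        uspec = uncertainty_spec(0, 0, 0))
  td <- tidy(rep)
  expect_identical(td$criterion, c("stress_allow", "yield90", "disp"))
  expect_true(all(td$probability >= 0 & td$probability <= 1))
  expect_equal(td$se, sqrt(td$probability * (1 - td$probability) / 200))
})

test_that("FE spot-check machinery handles the empty case", {
  fit <- linear_fit()
  out <- verify_against_fem(canonical_design(), k = 0, fit = fit)
  expect_identical(nrow(out), 0L)
})
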