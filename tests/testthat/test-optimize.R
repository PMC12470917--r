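test_that("Pareto dominance is sound on enumerated fixtures", {
  expect_false(dominates(c(1, 1), c(1, 1)))
  expect_true(dominates(c(1, 1), c(2, 2)))
  expect_false(dominates(c(1, 2), c(2, 1)))
  # maximised objectives are sign-normalised
  expect_true(dominates(c(1, 1, 5), c(2, 2, 4),
                        sense = c("min", "min", "max")))
  # transitivity over an enumerated set of 4-vectors
  set.seed(1)
  vecs <- lapply(1:8, function(i) sample(1:3, 4, replace = TRUE))
  for (a in vecs) for (b in vecs) for (c in vecs) {
    if (dominates(a, b) && dominates(b, c)) {
      expect_true(dominates(a, c))
    }
  }
})

test_that("brute-force Pareto front handles degenerate inputs", {
  pts <- tibble::tibble(id = 1)
  expect_identical(nrow(pareto_front_bruteforce(pts, cbind(1, 2))), 1L)
  pts3 <- tibble::tibble(id = 1:3)
  objs <- rbind(c(1, 1), c(1, 1), c(1, 1))
  expect_identical(nrow(pareto_front_bruteforce(pts3, objs)), 3L)
  objs2 <- rbind(c(1, 1), c(2, 2), c(0.5, 3))
  expect_identical(pareto_front_bruteforce(pts3, objs2)$id, c(1L, 3L))
})

test_that("the GA solves a single-objective degenerate case", {
  cfg <- ga_config(pop_size = 20, generations = 25, seed = 3)
  evaluate_fn <- function(df) {
    df$f <- (df$x - 0.3)^2
    df
  }
  out <- run_ga(cfg, space = list(x = c(0, 1)), evaluate_fn,
                risk_fn = NULL, minimise = "f", maximise = character(0),
                geometry_cap = NULL)
  expect_true(attr(out, "feasible"))
  expect_lt(abs(out$x[which.min(out$f)] - 0.3), 0.02)
})

test_that("the GA archive matches the brute-force front on a convex toy", {
  cfg <- ga_config(pop_size = 24, generations = 25, seed = 7)
  evaluate_fn <- function(df) {
    df$f1 <- df$x
    df$f2 <- 1 - df$x
    df
  }
  out <- run_ga(cfg, space = list(x = c(0, 1)), evaluate_fn, risk_fn = NULL,
                minimise = c("f1", "f2"), maximise = character(0),
                geometry_cap = NULL)
  expect_gt(nrow(out), 5)                 # archive spans the front
  expect_gt(diff(range(out$x)), 0.5)
  # no archive member is dominated by any point of a fine grid enumeration
  grid <- seq(0, 1, by = 1e-2)
  for (r in seq_len(nrow(out))) {
    dominated <- any(grid < out$f1[r] - 1e-12 &
                       (1 - grid) < out$f2[r] - 1e-12)
    expect_false(dominated)
  }
  # the archive itself is mutually non-dominated
  audit <- pareto_front_bruteforce(out, out[, c("f1", "f2")])
  expect_identical(nrow(audit), nrow(out))
})

test_that("an always-infeasible constraint yields an explicit empty result", {
  cfg <- ga_config(pop_size = 8, generations = 3, seed = 1, risk_cap = 0.03)
  evaluate_fn <- function(df) {
    df$f <- df$x
    df
  }
  out <- run_ga(cfg, space = list(x = c(0, 1)), evaluate_fn,
                risk_fn = function(design) 1, minimise = "f",
                maximise = character(0), geometry_cap = NULL)
  expect_false(attr(out, "feasible"))
  expect_identical(nrow(out), 0L)
})

test_that("GA runs are bit-reproducible under a fixed seed", {
  cfg <- ga_config(pop_size = 12, generations = 8, seed = 11)
  evaluate_fn <- function(df) {
    df$f1 <- df$x^2
    df$f2 <- (df$x - 1)^2
    df
  }
  o1 <- run_ga(cfg, space = list(x = c(0, 1)), evaluate_fn, NULL,
               minimise = c("f1", "f2"), maximise = character(0),
               geometry_cap = NULL)
  o2 <- run_ga(cfg, space = list(x = c(0, 1)), evaluate_fn, NULL,
               minimise = c("f1", "f2"), maximise = character(0),
               geometry_cap = NULL)
  expect_identical(as.data.frame(o1), as.data.frame(o2))
})

test_that("implant mass follows the density bookkeeping", {
  # rho * V arithmetic: a 10 mm cube of dense alloy weighs 4.43 g
  expect_equal(ti6al4v_card()$rho * 10^3 / 1000, 4.43)
  spec <- tiny_spec()
  evaluator <- function(df) {
    tibble::tibble(sigma_vm_max = rep(40, nrow(df)),
                   delta_max = 0.05, sigma_screw_max = 20)
  }
  des <- tibble::tibble(d = c(0.7, 1e-4), a = 3, t_lat = 2.5, t_plate = 1,
                        P = 600)
  obj <- design_objectives(des, evaluator, spec = spec)
  L <- 2 * spec$bone_block_length + spec$defect_span
  W <- spec$section_width
  mass_hand <- 4.43 * (2 * 1 * W * L + (1 - obj$p[1]) * 2.5 * W * L) / 1000
  expect_equal(obj$mass[1], mass_hand, tolerance = 1e-12)
  # p -> 1 drives the lattice-region mass to zero (plates remain)
  expect_equal(obj$mass[2], 4.43 * 2 * W * L / 1000, tolerance = 1e-6)
  # the solid counterpart outweighs any porous variant of the same envelope
  mass_solid <- 4.43 * (2 + 2.5) * W * L / 1000
  expect_true(all(obj$mass < mass_solid))
  expect_equal(obj$fatigue_margin, 340 / obj$sigma_vm_max)
})

test_that("efficiency index normalises to [0, 1] with the expected ranks", {
  spec <- tiny_spec()
  set.seed(2)
  ev <- tibble::tibble(
    d = runif(12, 0.4, 1.15), a = 3, t_lat = runif(12, 1.5, 4.5),
    t_plate = 1, P = 600)
  ev$p <- struts_to_porosity(ev$d, ev$a)$p
  ev$mass <- 4.43 * (2 + (1 - ev$p) * ev$t_lat) * 10 * 80 / 1000
  ev$delta_max <- runif(12, 0.02, 0.3)
  out <- efficiency_index(ev, spec = spec)
  expect_equal(max(out$efficiency), 1)
  expect_equal(min(out$efficiency), 0)
  expect_true(all(out$efficiency >= 0 & out$efficiency <= 1))
  binned <- attr(out, "binned")
  expect_true(all(c("bin", "mean_efficiency", "n") %in% names(binned)))
  # weights (1, 0) rank purely by mass saving
  out_mass <- efficiency_index(ev, weights = c(1, 0), spec = spec)
  expect_identical(order(out_mass$efficiency), order(out_mass$mass_saving))
  expect_error(efficiency_index(ev[1, ]), "at least 2")
})

test_that("trend regression matches closed-form least squares", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(trend_regression(x, 2 * x + 1),
               tibble::tibble(slope = 2, intercept = 1, r2 = 1, p_value = 0),
               tolerance = 1e-10)
  flat <- trend_regression(x, rep(3, 5))
  expect_equal(flat$slope, 0)
  expect_equal(flat$r2, 0)
  # 5-point fixture against the textbook normal equations
  y <- c(2.1, 3.9, 6.2, 7.8, 10.1)
  out <- trend_regression(x, y)
  sxx <- sum((x - mean(x))^2)
  slope_hand <- sum((x - mean(x)) * (y - mean(y))) / sxx
  intercept_hand <- mean(y) - slope_hand * mean(x)
  r2_hand <- slope_hand^2 * sxx / sum((y - mean(y))^2)
  tstat <- slope_hand / sqrt((sum((y - intercept_hand - slope_hand * x)^2) /
                                3) / sxx)
  expect_equal(out$slope, slope_hand, tolerance = 1e-10)
  expect_equal(out$intercept, intercept_hand, tolerance = 1e-10)
  expect_equal(out$r2, r2_hand, tolerance = 1e-10)
  expect_equal(out$p_value, 2 * stats::pt(abs(tstat), 3, lower.tail = FALSE),
               tolerance = 1e-10)
  expect_error(trend_regression(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_error(trend_regression(1:2, 1:2), "at least 3")
})

test_that("construct compliance converts to a sensible effective modulus", {
  spec <- tiny_spec()
  res <- solve_construct(spec, P = 600)
  E_c <- construct_effective_modulus(res$delta_max, 600, spec)
  expect_gt(E_c, 1)       # stiffer than trabecular bone
  expect_lt(E_c, 110)     # softer than the dense alloy
  # doubling the deflection halves the equivalent modulus
  expect_equal(construct_effective_modulus(0.2, 600, spec),
               construct_effective_modulus(0.1, 600, spec) / 2)
})
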