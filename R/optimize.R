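#' Objective vector for a plate design
#'
#' Mass (g, minimised) of the implant stack — two solid face plates plus the
#' lattice core at relative density `1 - p` over the construct envelope;
#' peak plate von Mises stress (MPa, minimised) from the supplied evaluator;
#' and fatigue margin (maximised) as the HIPped-alloy endurance limit,
#' 340 MPa, over the peak stress.
#'
#' @param designs Tibble with columns `d`, `a`, `t_lat`, `t_plate`, `P`.
#' @param evaluator Function `designs -> tibble(sigma_vm_max, delta_max,
#'   sigma_screw_max)`, e.g. a wrapped surrogate or the FE chain.
#' @param spec Construct template (envelope dimensions).
#' @param ti Titanium card (density).
#' @param fatigue_limit Endurance limit, MPa.
#' @return The input tibble with `p`, `mass`, `sigma_vm_max`, `delta_max`,
#'   `fatigue_margin` appended.
#' @export
design_objectives <- function(designs, evaluator, spec = construct_spec(),
                              ti = ti6al4v_card(), fatigue_limit = 340) {
  designs <- tibble::as_tibble(designs)
  L <- 2 * spec$bone_block_length + spec$defect_span
  W <- spec$section_width
  p <- struts_to_porosity(designs$d, designs$a, spec$cell)$p
  vol_plate <- 2 * designs$t_plate * W * L      # mm^3
  vol_lat <- designs$t_lat * W * L
  mass <- ti$rho * (vol_plate + (1 - p) * vol_lat) / 1000   # g
  pred <- evaluator(designs)
  designs$p <- p
  designs$mass <- mass
  designs$sigma_vm_max <- pred$sigma_vm_max
  designs$delta_max <- pred$delta_max
  designs$fatigue_margin <- fatigue_limit / pred$sigma_vm_max
  designs
}

#' Pareto dominance between objective vectors
#'
#' `a` dominates `b` iff it is no worse in every objective and strictly
#' better in at least one, after sign-normalising maximised objectives.
#'
#' @param a,b Numeric objective vectors.
#' @param sense Character vector `"min"`/`"max"` per objective.
#' @return Logical flag.
#' @export
dominates <- function(a, b, sense = rep("min", length(a))) {
  sgn <- ifelse(sense == "max", -1, 1)
  a <- a * sgn; b <- b * sgn
  all(a <= b) && any(a < b)
}

# nondominated mask for a matrix of minimised objectives
nondominated_mask <- function(Fm) {
  n <- nrow(Fm)
  keep <- rep(TRUE, n)
  for (i in seq_len(n)) {
    if (!keep[i]) next
    for (j in seq_len(n)) {
      if (i == j) next
      if (all(Fm[j, ] <= Fm[i, ]) && any(Fm[j, ] < Fm[i, ])) {
        keep[i] <- FALSE
        break
      }
    }
  }
  keep
}

#' Exact Pareto front by pairwise comparison
#'
#' Brute-force non-dominated subset of an enumerable point list; serves as
#' the oracle the genetic search is audited against.
#'
#' @param points Tibble of designs.
#' @param objectives Matrix/data frame of objective values (rows match
#'   `points`).
#' @param sense `"min"`/`"max"` per objective column.
#' @return The non-dominated rows of `points`.
#' @export
pareto_front_bruteforce <- function(points, objectives,
                                    sense = rep("min", ncol(objectives))) {
  Fm <- as.matrix(objectives)
  Fm <- sweep(Fm, 2, ifelse(sense == "max", -1, 1), "*")
  tibble::as_tibble(points)[nondominated_mask(Fm), , drop = FALSE]
}

# constraint-dominated fast non-dominated sorting (NSGA-II)
cd_sort <- function(Fm, cv) {
  n <- nrow(Fm)
  dom <- function(i, j) {
    if (cv[i] < cv[j]) return(TRUE)
    if (cv[i] > cv[j]) return(FALSE)
    all(Fm[i, ] <= Fm[j, ]) && any(Fm[i, ] < Fm[j, ])
  }
  S <- vector("list", n)
  ncount <- integer(n)
  rank <- integer(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      if (dom(i, j)) S[[i]] <- c(S[[i]], j)
      else if (dom(j, i)) ncount[i] <- ncount[i] + 1
    }
  }
  front <- which(ncount == 0)
  r <- 1
  while (length(front) > 0) {
    rank[front] <- r
    nxt <- integer(0)
    for (i in front) {
      for (j in S[[i]]) {
        ncount[j] <- ncount[j] - 1
        if (ncount[j] == 0) nxt <- c(nxt, j)
      }
    }
    front <- nxt
    r <- r + 1
  }
  rank
}

crowding_distance <- function(Fm) {
  n <- nrow(Fm)
  if (n <= 2) return(rep(Inf, n))
  dist <- numeric(n)
  for (k in seq_len(ncol(Fm))) {
    o <- order(Fm[, k])
    rng <- Fm[o[n], k] - Fm[o[1], k]
    dist[o[c(1, n)]] <- Inf
    if (rng > 0) {
      dist[o[2:(n - 1)]] <- dist[o[2:(n - 1)]] +
        (Fm[o[3:n], k] - Fm[o[1:(n - 2)], k]) / rng
    }
  }
  dist
}

sbx_crossover <- function(p1, p2, lower, upper, eta = 15, pc = 0.9) {
  c1 <- p1; c2 <- p2
  if (stats::runif(1) < pc) {
    for (k in seq_along(p1)) {
      if (stats::runif(1) < 0.5 && abs(p1[k] - p2[k]) > 1e-12) {
        u <- stats::runif(1)
        beta <- if (u <= 0.5) (2 * u)^(1 / (eta + 1)) else
          (1 / (2 * (1 - u)))^(1 / (eta + 1))
        c1[k] <- 0.5 * ((1 + beta) * p1[k] + (1 - beta) * p2[k])
        c2[k] <- 0.5 * ((1 - beta) * p1[k] + (1 + beta) * p2[k])
      }
    }
  }
  list(pmin(pmax(c1, lower), upper), pmin(pmax(c2, lower), upper))
}

poly_mutation <- function(x, lower, upper, eta = 20, pm = NULL) {
  if (is.null(pm)) pm <- 1 / length(x)
  for (k in seq_along(x)) {
    if (stats::runif(1) < pm) {
      u <- stats::runif(1)
      delta <- if (u < 0.5) (2 * u)^(1 / (eta + 1)) - 1 else
        1 - (2 * (1 - u))^(1 / (eta + 1))
      x[k] <- x[k] + delta * (upper[k] - lower[k])
    }
  }
  pmin(pmax(x, lower), upper)
}

#' Genetic-algorithm configuration
#'
#' @param pop_size Even population size >= 4.
#' @param generations Number of generations.
#' @param p_crossover Simulated-binary crossover probability.
#' @param p_mutation Per-variable polynomial-mutation probability (default
#'   1/n_var).
#' @param risk_cap Probabilistic constraint: maximum acceptable exceedance
#'   probability (default 3%).
#' @param risk_samples Monte-Carlo sample count used inside the search loop.
#' @param seed Integer seed.
#' @return A list of class `ga_config`.
#' @export
ga_config <- function(pop_size = 40, generations = 30, p_crossover = 0.9,
                      p_mutation = NULL, risk_cap = 0.03,
                      risk_samples = 4000, seed = 2025) {
  stopifnot(pop_size >= 4, pop_size %% 2 == 0,
            p_crossover >= 0, p_crossover <= 1)
  structure(list(pop_size = pop_size, generations = generations,
                 p_crossover = p_crossover, p_mutation = p_mutation,
                 risk_cap = risk_cap, risk_samples = risk_samples,
                 seed = seed),
            class = "ga_config")
}

#' Risk-constrained multi-objective genetic search
#'
#' NSGA-II-style search (binary tournament on constraint-dominated rank and
#' crowding, simulated-binary crossover, polynomial mutation) over a
#' continuous design space. Candidates whose risk exceeds the cap, or whose
#' geometry violates the strut-slenderness cap, carry a constraint violation
#' and are dominated by every feasible candidate. All feasible evaluated
#' candidates feed an external archive; the returned Pareto set is the
#' non-dominated subset of that archive, so a larger generation budget can
#' only grow it.
#'
#' @param config A [ga_config()].
#' @param space Named list of `c(min, max)` bounds for the design variables.
#' @param evaluate_fn Function `tibble of designs -> tibble of objectives`
#'   containing at least the columns named in `minimise`/`maximise`.
#' @param risk_fn Function `one-row design -> max exceedance probability`,
#'   or NULL for unconstrained search.
#' @param minimise,maximise Objective column names by orientation.
#' @param geometry_cap Optional `d/a` feasibility cap (NULL disables).
#' @return An object of class `pareto_set`: tibble of non-dominated,
#'   risk-feasible designs with their objectives and risk; attributes
#'   `generation_log`, `config`, `feasible` (FALSE when no feasible design
#'   was ever found — the tibble is then empty rather than an error).
#' @export
run_ga <- function(config, space, evaluate_fn, risk_fn = NULL,
                   minimise = c("mass", "sigma_vm_max"),
                   maximise = "fatigue_margin",
                   geometry_cap = 0.5) {
  lower <- vapply(space, `[`, numeric(1), 1)
  upper <- vapply(space, `[`, numeric(1), 2)
  if (any(upper <= lower)) stop("invalid space bounds")
  nv <- length(space)
  vars <- names(space)
  set.seed(config$seed)
  pop <- matrix(stats::runif(config$pop_size * nv, lower, upper),
                ncol = nv, byrow = TRUE)
  colnames(pop) <- vars

  eval_pop <- function(P) {
    df <- tibble::as_tibble(as.data.frame(P))
    ev <- evaluate_fn(df)
    risk <- if (is.null(risk_fn)) rep(0, nrow(df)) else
      vapply(seq_len(nrow(df)),
             function(r) risk_fn(ev[r, , drop = FALSE]), numeric(1))
    cv <- pmax(0, risk - config$risk_cap)
    if (!is.null(geometry_cap) && all(c("d", "a") %in% vars)) {
      cv <- cv + pmax(0, df$d / df$a - geometry_cap)
    }
    ev$risk <- risk
    ev$cv <- cv
    ev
  }

  obj_matrix <- function(ev) {
    Fm <- as.matrix(ev[, c(minimise, maximise), drop = FALSE])
    if (length(maximise) > 0) {
      Fm[, maximise] <- -Fm[, maximise, drop = FALSE]
    }
    Fm
  }

  ev <- eval_pop(pop)
  archive <- ev[ev$cv == 0, , drop = FALSE]
  obj1 <- minimise[1]
  log <- tibble::tibble(generation = 0L, n_feasible = sum(ev$cv == 0),
                        best_obj = suppressWarnings(
                          min(ev[[obj1]][ev$cv == 0])))
  for (gen in seq_len(config$generations)) {
    Fm <- obj_matrix(ev)
    rank <- cd_sort(Fm, ev$cv)
    crowd <- numeric(nrow(Fm))
    for (r in unique(rank)) {
      idx <- which(rank == r)
      crowd[idx] <- crowding_distance(Fm[idx, , drop = FALSE])
    }
    tournament <- function() {
      i <- sample.int(nrow(pop), 2)
      if (rank[i[1]] < rank[i[2]]) i[1]
      else if (rank[i[2]] < rank[i[1]]) i[2]
      else if (crowd[i[1]] >= crowd[i[2]]) i[1] else i[2]
    }
    children <- matrix(0, config$pop_size, nv)
    for (c2 in seq(1, config$pop_size, by = 2)) {
      pr <- sbx_crossover(pop[tournament(), ], pop[tournament(), ],
                          lower, upper, pc = config$p_crossover)
      children[c2, ] <- poly_mutation(pr[[1]], lower, upper,
                                      pm = config$p_mutation)
      children[c2 + 1, ] <- poly_mutation(pr[[2]], lower, upper,
                                          pm = config$p_mutation)
    }
    colnames(children) <- vars
    ev_c <- eval_pop(children)
    archive <- dplyr::bind_rows(archive, ev_c[ev_c$cv == 0, , drop = FALSE])

    both <- rbind(pop, children)
    ev_both <- dplyr::bind_rows(ev, ev_c)
    Fb <- obj_matrix(ev_both)
    rb <- cd_sort(Fb, ev_both$cv)
    sel <- integer(0)
    for (r in sort(unique(rb))) {
      idx <- which(rb == r)
      if (length(sel) + length(idx) <= config$pop_size) {
        sel <- c(sel, idx)
      } else {
        cd <- crowding_distance(Fb[idx, , drop = FALSE])
        sel <- c(sel, idx[order(cd, decreasing = TRUE)][
          seq_len(config$pop_size - length(sel))])
        break
      }
    }
    pop <- both[sel, , drop = FALSE]
    ev <- ev_both[sel, , drop = FALSE]
    log <- dplyr::bind_rows(log, tibble::tibble(
      generation = gen, n_feasible = sum(ev$cv == 0),
      best_obj = suppressWarnings(min(ev[[obj1]][ev$cv == 0]))))
  }

  if (nrow(archive) == 0) {
    out <- structure(tibble::tibble(), feasible = FALSE,
                     generation_log = log, config = config,
                     class = c("pareto_set", class(tibble::tibble())))
    return(out)
  }
  archive <- dplyr::distinct(archive)
  keep <- nondominated_mask(obj_matrix(archive))
  structure(archive[keep, , drop = FALSE],
            feasible = TRUE, generation_log = log, config = config,
            class = c("pareto_set", class(tibble::tibble())))
}

#' Plot a Pareto set in the mass-stress plane
#'
#' @param object A `pareto_set`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pareto_set <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$mass,
                                       y = .data$sigma_vm_max,
                                       colour = .data$p)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "implant mass (g)",
                  y = "peak plate von Mises stress (MPa)",
                  colour = "porosity") +
    ggplot2::theme_minimal()
}

#' Effective construct modulus from the load-point compliance
#'
#' Converts the solved midspan deflection into an equivalent homogeneous
#' beam modulus via the fixed-fixed centre-loaded beam formula
#' `E = P L^3 / (192 delta I)` with `I = W H^3 / 12` of the full envelope
#' cross-section. Used by the efficiency index as the stiffness-matching
#' proxy.
#'
#' @param delta_max Peak deflection, mm.
#' @param P Load, N.
#' @param spec Construct template (envelope dimensions).
#' @return Effective modulus, GPa.
#' @export
construct_effective_modulus <- function(delta_max, P, spec = construct_spec()) {
  L <- 2 * spec$bone_block_length + spec$defect_span
  I <- spec$section_width * spec$section_height^3 / 12
  (P * L^3 / (192 * delta_max * I)) / 1000
}

#' Optimisation-efficiency index
#'
#' Weighted, min-max-normalised combination of (i) mass saving relative to
#' each design's fully solid counterpart (`p = 0` in the lattice region) and
#' (ii) stiffness matching to cortical bone, `-|E_construct - E_bone|`. The
#' best design in the evaluated set scores exactly 1 and the worst 0 by
#' construction of the normalisation.
#'
#' @param evaluated Tibble with columns `p`, `mass`, `t_lat`, `t_plate`,
#'   `delta_max`, `P` (as produced by [design_objectives()]).
#' @param weights `c(w_mass, w_stiffness)`, normalised to sum 1.
#' @param spec Construct template.
#' @param E_bone Target modulus, GPa.
#' @param ti Titanium card.
#' @return The input tibble with `mass_saving`, `E_construct`, `efficiency`
#'   columns; attribute `binned` holds the porosity-decade summary table.
#' @export
efficiency_index <- function(evaluated, weights = c(0.5, 0.5),
                             spec = construct_spec(), E_bone = 13,
                             ti = ti6al4v_card()) {
  evaluated <- tibble::as_tibble(evaluated)
  if (nrow(evaluated) < 2) stop("need at least 2 evaluated designs")
  weights <- weights / sum(weights)
  L <- 2 * spec$bone_block_length + spec$defect_span
  W <- spec$section_width
  mass_solid <- ti$rho * (2 * evaluated$t_plate + evaluated$t_lat) * W * L /
    1000
  evaluated$mass_saving <- (mass_solid - evaluated$mass) / mass_solid
  evaluated$E_construct <- construct_effective_modulus(evaluated$delta_max,
                                                       evaluated$P, spec)
  minmax <- function(x) {
    rng <- diff(range(x))
    if (rng <= 0) {
      warning("degenerate normalisation range: scores set to 0.5")
      return(rep(0.5, length(x)))
    }
    (x - min(x)) / rng
  }
  n_mass <- minmax(evaluated$mass_saving)
  n_stiff <- minmax(-abs(evaluated$E_construct - E_bone))
  # final min-max pass pins the set's best design at exactly 1, worst at 0
  evaluated$efficiency <- minmax(weights[1] * n_mass + weights[2] * n_stiff)
  bins <- cut(evaluated$p, breaks = seq(0, 1, by = 0.1),
              include.lowest = TRUE)
  binned <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(bin = bins,
                                   efficiency = evaluated$efficiency),
                    .data$bin),
    mean_efficiency = mean(.data$efficiency), n = dplyr::n(),
    .groups = "drop")
  attr(evaluated, "binned") <- binned
  evaluated
}

#' Ordinary-least-squares trend regression
#'
#' Slope, intercept, R-squared and the two-tailed p value of the slope's t
#' statistic for a response-versus-porosity (or any x-y) trend.
#'
#' @param x,y Numeric vectors (>= 3 points; x not constant).
#' @return One-row tibble: `slope`, `intercept`, `r2`, `p_value`.
#' @export
trend_regression <- function(x, y) {
  if (length(x) < 3) stop("need at least 3 points")
  if (stats::sd(x) == 0) stop("x must not be constant")
  if (stats::sd(y) == 0) {
    # flat response: no trend, no explained variance
    return(tibble::tibble(slope = 0, intercept = y[1], r2 = 0, p_value = 1))
  }
  fit <- stats::lm(y ~ x)
  sm <- suppressWarnings(summary(fit))  # exact fits are legitimate here
  p <- if (sm$sigma == 0) 0 else stats::coef(sm)["x", "Pr(>|t|)"]
  tibble::tibble(
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    r2 = sm$r.squared,
    p_value = unname(p)
  )
}
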