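#' Occlusal load case
#'
#' A resultant force of magnitude `P` applied as uniform pressure over the
#' named node-set patch, along a unit direction (default occlusal
#' compression, -z). Nodal forces are consistent with the geometric patch:
#' each top face carries the fraction of `P` given by its overlap with the
#' patch interval, so the nodal forces always sum to exactly `P * direction`.
#'
#' @param P Bite-force magnitude, N (300 N average mastication, 600 N
#'   maximum clench are the two canonical cases).
#' @param direction Unit 3-vector of the load direction.
#' @param patch Node-set name carrying the load.
#' @return An object of class `load_case`.
#' @export
load_case <- function(P = 600, direction = c(0, 0, -1),
                      patch = "load_patch") {
  if (!is.finite(P) || P < 0) stop("P must be >= 0")
  nrm <- sqrt(sum(direction^2))
  if (abs(nrm - 1) > 1e-8) stop("direction must have unit norm")
  structure(list(P = P, direction = direction, patch = patch),
            class = "load_case")
}

# --- hex8 element kernel (axis-aligned box, 2x2x2 Gauss) ------------------

hex8_signs <- cbind(
  xi   = c(-1,  1,  1, -1, -1,  1,  1, -1),
  eta  = c(-1, -1,  1,  1, -1, -1,  1,  1),
  zeta = c(-1, -1, -1, -1,  1,  1,  1,  1)
)

isotropic_D <- function(E_mpa, nu) {
  c1 <- E_mpa / ((1 + nu) * (1 - 2 * nu))
  D <- matrix(0, 6, 6)
  D[1:3, 1:3] <- c1 * nu
  diag(D)[1:3] <- c1 * (1 - nu)
  diag(D)[4:6] <- c1 * (1 - 2 * nu) / 2
  D
}

# strain-displacement matrix at natural coords for a box element
hex8_B <- function(xi, eta, zeta, hx, hy, hz) {
  s <- hex8_signs
  dNdxi   <- s[, 1] * (1 + s[, 2] * eta) * (1 + s[, 3] * zeta) / 8
  dNdeta  <- s[, 2] * (1 + s[, 1] * xi)  * (1 + s[, 3] * zeta) / 8
  dNdzeta <- s[, 3] * (1 + s[, 1] * xi)  * (1 + s[, 2] * eta)  / 8
  dNdx <- dNdxi * 2 / hx
  dNdy <- dNdeta * 2 / hy
  dNdz <- dNdzeta * 2 / hz
  B <- matrix(0, 6, 24)
  ix <- seq(1, 24, by = 3)
  B[1, ix]     <- dNdx
  B[2, ix + 1] <- dNdy
  B[3, ix + 2] <- dNdz
  B[4, ix]     <- dNdy; B[4, ix + 1] <- dNdx
  B[5, ix + 1] <- dNdz; B[5, ix + 2] <- dNdy
  B[6, ix]     <- dNdz; B[6, ix + 2] <- dNdx
  B
}

gauss2 <- 1 / sqrt(3)
hex8_gp <- as.matrix(expand.grid(xi = c(-gauss2, gauss2),
                                 eta = c(-gauss2, gauss2),
                                 zeta = c(-gauss2, gauss2)))

#' Stiffness matrix of one axis-aligned hex8 box element
#'
#' Full 2x2x2 Gauss integration of `B' D B` on a box of edge lengths
#' `(hx, hy, hz)` mm with modulus `E_mpa` (MPa) and Poisson ratio `nu`.
#' Exposed for verification against independent quadrature oracles.
#'
#' @param hx,hy,hz Element edge lengths, mm.
#' @param E_mpa Young's modulus, MPa.
#' @param nu Poisson ratio.
#' @return A 24 x 24 symmetric matrix (N/mm).
#' @export
hex8_stiffness <- function(hx, hy, hz, E_mpa, nu) {
  D <- isotropic_D(E_mpa, nu)
  detJ <- hx * hy * hz / 8
  ke <- matrix(0, 24, 24)
  for (g in seq_len(nrow(hex8_gp))) {
    B <- hex8_B(hex8_gp[g, 1], hex8_gp[g, 2], hex8_gp[g, 3], hx, hy, hz)
    ke <- ke + crossprod(B, D %*% B) * detJ
  }
  (ke + t(ke)) / 2
}

# --- material maps --------------------------------------------------------

#' Region-to-material map for a construct
#'
#' Maps the four mesh regions to material cards. The lattice region gets a
#' homogenised card whose modulus comes from [effective_modulus()] at the
#' porosity implied by the spec's strut diameter and cell size; plate and
#' screw regions are dense Ti-6Al-4V; bone (blocks and graft) is cortical
#' bone, optionally scaled by `bone_scale` for uncertainty propagation.
#'
#' @param spec A [construct_spec()].
#' @param law A [calibrate_porosity_law()] fit; default is the built-in
#'   coupon calibration.
#' @param bone_scale Multiplier on the cortical-bone modulus.
#' @param ti Dense titanium card.
#' @param bone Cortical-bone card.
#' @return Named list of `material_card`s (`bone`, `plate`, `lattice`,
#'   `screw`) with attribute `porosity`.
#' @export
region_material_map <- function(spec, law = NULL, bone_scale = 1,
                                ti = ti6al4v_card(),
                                bone = cortical_bone_card()) {
  if (is.null(law)) law <- calibrate_porosity_law(lattice_coupon_table(),
                                                  E_solid = ti$E)
  sp <- struts_to_porosity(spec$d, spec$a, spec$cell)
  p <- sp$p
  E_lat <- effective_modulus(law, p)
  bone_scaled <- material_card(bone$name, E = bone$E * bone_scale,
                               nu = bone$nu, rho = bone$rho)
  lat <- material_card("homogenised lattice", E = E_lat, nu = ti$nu,
                       rho = ti$rho * (1 - p))
  mm <- list(bone = bone_scaled, plate = ti, lattice = lat, screw = ti)
  attr(mm, "porosity") <- p
  attr(mm, "feasible") <- sp$feasible
  mm
}

# --- assembly -------------------------------------------------------------

#' Assemble the global stiffness operator
#'
#' Builds the sparse symmetric stiffness matrix K (N/mm) of the static
#' equilibrium system `K u = F` from per-region isotropic materials on a
#' structured box mesh. Elements are grouped by identical (edge lengths,
#' E, nu) so each distinct element stiffness is integrated once.
#'
#' @param mesh A `construct_mesh`.
#' @param material_map Named list of `material_card`s covering every region
#'   present in the mesh (see [region_material_map()]).
#' @return An object of class `fe_stiffness`: fields `K` (sparse,
#'   3n x 3n), `mesh`, `material_map`, `elem_E_mpa`, `elem_nu`, `groups`.
#' @export
assemble_stiffness <- function(mesh, material_map) {
  regions <- levels(mesh$region)[unique(as.integer(mesh$region))]
  missing <- setdiff(regions, names(material_map))
  if (length(missing) > 0) {
    stop("assembly error: no material mapped for region(s): ",
         paste(missing, collapse = ", "))
  }
  if (any(mesh$elem_dims <= 0)) {
    bad <- which(apply(mesh$elem_dims <= 0, 1, any))[1]
    stop("assembly error: degenerate element ", bad, " (non-positive edge)")
  }
  E_mpa <- vapply(material_map, function(m) m$E * 1000, numeric(1))
  nu <- vapply(material_map, function(m) m$nu, numeric(1))
  elem_E <- E_mpa[as.character(mesh$region)]
  elem_nu <- nu[as.character(mesh$region)]

  key <- paste(signif(mesh$elem_dims[, 1], 12), signif(mesh$elem_dims[, 2], 12),
               signif(mesh$elem_dims[, 3], 12), signif(elem_E, 12),
               signif(elem_nu, 12))
  groups <- split(seq_along(key), key)

  edof <- build_edof(mesh$elems)

  r_index <- rep(1:24, times = 24)
  c_index <- rep(1:24, each = 24)
  ii <- vector("list", length(groups))
  jj <- vector("list", length(groups))
  vv <- vector("list", length(groups))
  for (g in seq_along(groups)) {
    idx <- groups[[g]]
    e1 <- idx[1]
    ke <- hex8_stiffness(mesh$elem_dims[e1, 1], mesh$elem_dims[e1, 2],
                         mesh$elem_dims[e1, 3], elem_E[e1], elem_nu[e1])
    ii[[g]] <- as.vector(edof[idx, r_index, drop = FALSE])
    jj[[g]] <- as.vector(edof[idx, c_index, drop = FALSE])
    vv[[g]] <- rep(as.vector(ke), each = length(idx))
  }
  ndof <- 3L * nrow(mesh$nodes)
  K <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(vv),
                            dims = c(ndof, ndof))
  K <- Matrix::forceSymmetric((K + Matrix::t(K)) / 2)
  structure(
    list(K = K, mesh = mesh, material_map = material_map,
         elem_E_mpa = elem_E, elem_nu = elem_nu, edof = edof,
         groups = groups),
    class = "fe_stiffness"
  )
}

# consistent nodal load vector for a load case
build_load_vector <- function(mesh, load) {
  if (!load$patch %in% names(mesh$node_sets)) {
    stop("unknown load patch node set: ", load$patch)
  }
  ndof <- 3L * nrow(mesh$nodes)
  F <- numeric(ndof)
  if (load$P == 0) return(F)
  g <- mesh$grid
  x1 <- mesh$load_patch_bounds[1]; x2 <- mesh$load_patch_bounds[2]
  area <- (x2 - x1) * mesh$spec$section_width
  top <- mesh$elem_index[, "k"] == g$nz
  idx <- which(top)
  xlo <- g$xb[mesh$elem_index[idx, "i"]]
  xhi <- g$xb[mesh$elem_index[idx, "i"] + 1]
  ov <- pmax(0, pmin(xhi, x2) - pmax(xlo, x1))
  w <- ov * mesh$elem_dims[idx, 2] / area
  keep <- w > 0
  idx <- idx[keep]; w <- w[keep]
  for (t in seq_along(idx)) {
    face_nodes <- mesh$elems[idx[t], 5:8]
    f <- load$P * w[t] / 4
    for (nd in face_nodes) {
      F[3 * nd - 2:0] <- F[3 * nd - 2:0] + f * load$direction
    }
  }
  F
}

#' Solve the constrained static problem
#'
#' Eliminates the fixed node set's degrees of freedom and solves the reduced
#' symmetric positive-definite system by sparse Cholesky factorisation.
#'
#' @param stiffness An `fe_stiffness` from [assemble_stiffness()].
#' @param load A [load_case()].
#' @param fixed_set Name of the fully constrained node set.
#' @return An object of class `fe_result`: nodal displacement matrix `u`
#'   (mm), per-element von Mises stresses `sigma_vm` (MPa), target summaries
#'   `sigma_vm_max_plate`, `delta_max`, `sigma_screw_max`, `strain_energy`
#'   (N mm), `external_work`, and a `converged` flag.
#' @export
solve_static <- function(stiffness, load, fixed_set = "fixed_end") {
  mesh <- stiffness$mesh
  if (!fixed_set %in% names(mesh$node_sets)) {
    stop("unknown fixed node set: ", fixed_set)
  }
  fixed_nodes <- mesh$node_sets[[fixed_set]]
  if (length(fixed_nodes) == 0) stop("fixed set is empty")
  patch <- mesh$node_sets[[load$patch]]
  if (length(patch) == 0) stop("load patch is empty")
  ndof <- 3L * nrow(mesh$nodes)
  fixed_dofs <- as.vector(rbind(3 * fixed_nodes - 2, 3 * fixed_nodes - 1,
                                3 * fixed_nodes))
  free <- setdiff(seq_len(ndof), fixed_dofs)
  F <- build_load_vector(mesh, load)

  u <- numeric(ndof)
  converged <- TRUE
  if (load$P > 0) {
    Kff <- stiffness$K[free, free, drop = FALSE]
    Ff <- F[free]
    uf <- tryCatch(as.vector(Matrix::solve(Kff, Ff)),
                   error = function(e) NULL)
    # a nearly singular reduced system (rigid modes not removed) can pass
    # the factorisation on round-off; the residual check catches it
    if (is.null(uf) || any(!is.finite(uf)) ||
        sqrt(sum((as.vector(Kff %*% uf) - Ff)^2)) >
          1e-6 * sqrt(sum(Ff^2))) {
      converged <- FALSE
      uf <- rep(NA_real_, length(free))
    }
    u[free] <- uf
  }

  U <- matrix(u, ncol = 3, byrow = TRUE)
  sigma_vm <- if (converged) {
    recover_von_mises(u, mesh, stiffness)
  } else rep(NA_real_, nrow(mesh$elems))
  strain_energy <- if (converged) 0.5 * sum(F * u) else NA_real_

  res <- structure(
    list(u = U, u_flat = u, F = F, sigma_vm = sigma_vm,
         strain_energy = strain_energy, external_work = strain_energy,
         converged = converged, load = load, mesh = mesh),
    class = "fe_result"
  )
  s <- summarize_targets(res, mesh)
  res$sigma_vm_max_plate <- s$sigma_vm_max_plate
  res$delta_max <- s$delta_max
  res$sigma_screw_max <- s$sigma_screw_max
  res
}

#' @exportS3Method base::print
print.fe_result <- function(x, ...) {
  cat(sprintf(
    "<fe_result> P = %g N: sigma_vm_max_plate = %.4g MPa, delta_max = %.4g mm, sigma_screw_max = %.4g MPa (converged: %s)\n",
    x$load$P, x$sigma_vm_max_plate, x$delta_max, x$sigma_screw_max,
    x$converged))
  invisible(x)
}

#' Recover per-element von Mises stress
#'
#' Evaluates the constitutive stress `sigma = D B u` at the 2x2x2 Gauss
#' points of every element and volume-averages the von Mises equivalent per
#' element.
#'
#' @param u Flat displacement vector (3n) or an `fe_result`.
#' @param mesh The `construct_mesh`.
#' @param stiffness The `fe_stiffness` used for the solve (carries moduli).
#' @return Numeric vector of element von Mises stresses, MPa.
#' @export
recover_von_mises <- function(u, mesh, stiffness) {
  if (inherits(u, "fe_result")) u <- u$u_flat
  ne <- nrow(mesh$elems)
  vm <- numeric(ne)
  edof <- stiffness$edof
  for (g in seq_along(stiffness$groups)) {
    idx <- stiffness$groups[[g]]
    e1 <- idx[1]
    hx <- mesh$elem_dims[e1, 1]; hy <- mesh$elem_dims[e1, 2]
    hz <- mesh$elem_dims[e1, 3]
    D <- isotropic_D(stiffness$elem_E_mpa[e1], stiffness$elem_nu[e1])
    Ue <- matrix(u[edof[idx, , drop = FALSE]], nrow = length(idx))
    acc <- numeric(length(idx))
    for (q in seq_len(nrow(hex8_gp))) {
      DB <- D %*% hex8_B(hex8_gp[q, 1], hex8_gp[q, 2], hex8_gp[q, 3],
                         hx, hy, hz)
      S <- Ue %*% t(DB)   # n_elem x 6 stress components
      acc <- acc + sqrt(pmax(0,
        0.5 * ((S[, 1] - S[, 2])^2 + (S[, 2] - S[, 3])^2 +
                 (S[, 3] - S[, 1])^2) +
          3 * (S[, 4]^2 + S[, 5]^2 + S[, 6]^2)))
    }
    vm[idx] <- acc / nrow(hex8_gp)
  }
  vm
}

#' Summarise an FE result into the three surrogate targets
#'
#' Peak thickness-averaged plate von Mises stress, peak nodal displacement
#' magnitude, and peak screw-region von Mises stress. Plate stresses are
#' arithmetically averaged over the column of plate elements sharing an
#' (x, y) footprint before the maximum is taken, suppressing spurious
#' surface singularities.
#'
#' @param result An `fe_result`.
#' @param mesh The `construct_mesh` (defaults to the result's own mesh).
#' @return A one-row tibble with `sigma_vm_max_plate`, `delta_max`,
#'   `sigma_screw_max`.
#' @export
summarize_targets <- function(result, mesh = result$mesh) {
  vm <- result$sigma_vm
  plate <- mesh$region == "plate"
  screw <- mesh$region == "screw"
  if (!any(plate)) stop("summary error: no plate elements in mesh")
  if (!any(screw)) stop("summary error: no screw elements in mesh")
  col_id <- paste(mesh$elem_index[plate, "i"], mesh$elem_index[plate, "j"])
  col_mean <- tapply(vm[plate], col_id, mean)
  disp <- sqrt(rowSums(result$u^2))
  tibble::tibble(
    sigma_vm_max_plate = max(col_mean),
    delta_max = max(disp),
    sigma_screw_max = max(vm[screw])
  )
}

#' One-call FE solve of a construct design
#'
#' Convenience chain mesh -> materials -> assembly -> solve used by the DOE
#' sweep and verification loops.
#'
#' @param spec A [construct_spec()].
#' @param P Load magnitude, N.
#' @param law Porosity law (default: built-in coupon calibration).
#' @param bone_scale Multiplier on the bone modulus.
#' @param porosity_offset Additive perturbation of the lattice porosity
#'   before the effective-modulus evaluation (build scatter).
#' @return An `fe_result`.
#' @export
solve_construct <- function(spec, P = 600, law = NULL, bone_scale = 1,
                            porosity_offset = 0) {
  mm <- region_material_map(spec, law = law, bone_scale = bone_scale)
  if (porosity_offset != 0) {
    if (is.null(law)) law <- calibrate_porosity_law(lattice_coupon_table(),
                                                    E_solid = 110)
    p <- min(0.98, max(0, attr(mm, "porosity") + porosity_offset))
    mm$lattice <- material_card("homogenised lattice",
                                E = effective_modulus(law, p),
                                nu = mm$plate$nu,
                                rho = mm$plate$rho * (1 - p))
    attr(mm, "porosity") <- p
  }
  mesh <- build_construct_mesh(spec)
  ks <- assemble_stiffness(mesh, mm)
  solve_static(ks, load_case(P = P))
}

#' Mesh-convergence study
#'
#' Re-solves the construct over a ladder of refinement factors and reports
#' the successive relative change in the peak thickness-averaged plate
#' stress, mirroring the refine-by-20%, accept-below-3% convergence check.
#'
#' @param spec A [construct_spec()].
#' @param load A [load_case()].
#' @param factors Refinement factors (>= 2 values).
#' @param law Porosity law (default built-in).
#' @return A tibble with columns `factor`, `element_size`, `n_elements`,
#'   `sigma_vm_max_plate`, `delta_max`, `rel_change_stress_pct`.
#' @export
convergence_study <- function(spec, load = load_case(600),
                              factors = c(1.0, 1.2), law = NULL) {
  if (length(factors) < 2) stop("need at least 2 refinement factors")
  rows <- purrr::map(factors, function(f) {
    mesh <- refine_mesh(spec, f)
    mm <- region_material_map(spec, law = law)
    ks <- assemble_stiffness(mesh, mm)
    res <- solve_static(ks, load)
    if (!res$converged) stop("solver failed at refinement factor ", f)
    tibble::tibble(factor = f, element_size = mesh$element_size,
                   n_elements = nrow(mesh$elems),
                   sigma_vm_max_plate = res$sigma_vm_max_plate,
                   delta_max = res$delta_max)
  })
  out <- dplyr::bind_rows(rows)
  out$rel_change_stress_pct <- c(NA_real_,
    100 * abs(diff(out$sigma_vm_max_plate)) /
      utils::head(out$sigma_vm_max_plate, -1))
  out
}

#' Export an FE result to legacy VTK
#'
#' Writes the mesh with displacement vectors and element von Mises stress.
#'
#' @param result An `fe_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_result_vtk <- function(result, path) {
  write_mesh_vtk(result$mesh, path,
                 cell_data = list(von_mises_mpa = result$sigma_vm),
                 point_data = list(displacement_mm = result$u))
}

# --- fast re-assembly across designs --------------------------------------

build_edof <- function(elems) {
  ne <- nrow(elems)
  edof <- matrix(0L, ne, 24)
  for (m in 1:8) {
    edof[, 3 * m - 2] <- 3L * elems[, m] - 2L
    edof[, 3 * m - 1] <- 3L * elems[, m] - 1L
    edof[, 3 * m]     <- 3L * elems[, m]
  }
  edof
}

#' Unit-modulus stiffness decomposition by region
#'
#' Each element stiffness is linear in its Young's modulus, so the global
#' matrix decomposes as `K = sum_r E_r * K_r` with `K_r` assembled once per
#' mesh at unit modulus (region Poisson ratios are design-independent).
#' [assemble_from_parts()] then rebuilds `K` for any modulus assignment in
#' milliseconds — the workhorse of the design-of-experiments sweep, where
#' hundreds of designs share a handful of meshes.
#'
#' @param mesh A `construct_mesh`.
#' @param material_map Region material cards (only the Poisson ratios are
#'   consumed here).
#' @return An opaque parts object for [assemble_from_parts()].
#' @export
region_stiffness_parts <- function(mesh, material_map) {
  regions <- intersect(levels(mesh$region), unique(as.character(mesh$region)))
  missing <- setdiff(regions, names(material_map))
  if (length(missing) > 0) {
    stop("assembly error: no material mapped for region(s): ",
         paste(missing, collapse = ", "))
  }
  edof <- build_edof(mesh$elems)
  ndof <- 3L * nrow(mesh$nodes)
  r_index <- rep(1:24, times = 24)
  c_index <- rep(1:24, each = 24)
  parts <- list()
  for (r in regions) {
    nu_r <- material_map[[r]]$nu
    idx_r <- which(mesh$region == r)
    key <- paste(signif(mesh$elem_dims[idx_r, 1], 12),
                 signif(mesh$elem_dims[idx_r, 2], 12),
                 signif(mesh$elem_dims[idx_r, 3], 12))
    ii <- jj <- vv <- list()
    for (kk in unique(key)) {
      idx <- idx_r[key == kk]
      e1 <- idx[1]
      ke <- hex8_stiffness(mesh$elem_dims[e1, 1], mesh$elem_dims[e1, 2],
                           mesh$elem_dims[e1, 3], 1, nu_r)
      ii[[kk]] <- as.vector(edof[idx, r_index, drop = FALSE])
      jj[[kk]] <- as.vector(edof[idx, c_index, drop = FALSE])
      vv[[kk]] <- rep(as.vector(ke), each = length(idx))
    }
    parts[[r]] <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj),
                                       x = unlist(vv), dims = c(ndof, ndof))
  }
  structure(list(parts = parts, edof = edof, mesh = mesh,
                 nu = vapply(material_map, function(m) m$nu, numeric(1))),
            class = "fe_stiffness_parts")
}

#' @rdname region_stiffness_parts
#' @param pp Parts object from [region_stiffness_parts()].
#' @return `assemble_from_parts()` returns an `fe_stiffness` identical (to
#'   round-off) to [assemble_stiffness()] on the same inputs.
#' @export
assemble_from_parts <- function(pp, material_map) {
  mesh <- pp$mesh
  E_mpa <- vapply(material_map, function(m) m$E * 1000, numeric(1))
  K <- NULL
  for (r in names(pp$parts)) {
    Kr <- E_mpa[[r]] * pp$parts[[r]]
    K <- if (is.null(K)) Kr else K + Kr
  }
  K <- Matrix::forceSymmetric(K)
  nu <- vapply(material_map, function(m) m$nu, numeric(1))
  elem_E <- E_mpa[as.character(mesh$region)]
  elem_nu <- nu[as.character(mesh$region)]
  key <- paste(signif(mesh$elem_dims[, 1], 12), signif(mesh$elem_dims[, 2], 12),
               signif(mesh$elem_dims[, 3], 12), signif(elem_E, 12),
               signif(elem_nu, 12))
  structure(
    list(K = K, mesh = mesh, material_map = material_map,
         elem_E_mpa = elem_E, elem_nu = elem_nu, edof = pp$edof,
         groups = split(seq_along(key), key)),
    class = "fe_stiffness"
  )
}
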