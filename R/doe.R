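#' Canonical design-variable levels
#'
#' The full-factorial grid over four geometric factors and two bite-load
#' levels: strut diameter d in {0.40, 0.55, 0.70, 0.85, 1.00, 1.15} mm,
#' unit-cell size a in {2.0, 2.5, 3.0, 3.5, 4.0} mm, lattice-core thickness
#' t_lat in {1.5, 2.5, 3.5, 4.5} mm, face-plate thickness t_plate in
#' {1.0, 1.5} mm, occlusal load P in {300, 600} N — 6 x 5 x 4 x 2 x 2 = 480
#' design points.
#'
#' @return Named list of level vectors.
#' @export
design_levels <- function() {
  list(
    d = c(0.40, 0.55, 0.70, 0.85, 1.00, 1.15),
    a = c(2.0, 2.5, 3.0, 3.5, 4.0),
    t_lat = c(1.5, 2.5, 3.5, 4.5),
    t_plate = c(1.0, 1.5),
    P = c(300, 600)
  )
}

add_derived_porosity <- function(points, cell = lattice_cell()) {
  sp <- struts_to_porosity(points$d, points$a, cell)
  points$p <- sp$p
  points$feasible <- sp$feasible
  points
}

#' Full-factorial design-point set
#'
#' Cartesian product of the per-variable level lists in deterministic
#' lexicographic order (first variable varying fastest). Derived porosity
#' `p` and the geometric feasibility flag are appended when both `d` and `a`
#' are among the variables.
#'
#' @param levels Named list of level vectors; defaults to [design_levels()].
#' @param cell [lattice_cell()] for the porosity map.
#' @return A tibble of design points.
#' @examples
#' nrow(full_factorial())  # 480
#' @export
full_factorial <- function(levels = design_levels(), cell = lattice_cell()) {
  if (length(levels) == 0 || any(lengths(levels) < 1)) {
    stop("every variable needs at least one level")
  }
  pts <- tibble::as_tibble(expand.grid(levels, KEEP.OUT.ATTRS = FALSE))
  if (all(c("d", "a") %in% names(pts))) {
    pts <- add_derived_porosity(pts, cell)
  }
  pts
}

#' Latin-hypercube design-point set
#'
#' Maximin-free stratified sampling: each variable's marginal places exactly
#' one sample in each of `n` equal-probability strata of its range
#' (delegated to `lhs::randomLHS`), reproducibly under a seed.
#'
#' @param n Number of points.
#' @param bounds Named list of `c(min, max)` ranges per variable.
#' @param seed Integer seed.
#' @param cell [lattice_cell()] for the porosity map.
#' @return A tibble of design points.
#' @export
latin_hypercube <- function(n,
                            bounds = list(d = c(0.40, 1.15),
                                          a = c(2.0, 4.0),
                                          t_lat = c(1.5, 4.5),
                                          t_plate = c(1.0, 1.5),
                                          P = c(300, 600)),
                            seed = 1, cell = lattice_cell()) {
  if (n < 1) stop("n must be >= 1")
  rng <- vapply(bounds, function(b) diff(range(b)), numeric(1))
  if (any(rng <= 0)) stop("degenerate bounds: every range must have width")
  set.seed(seed)
  U <- lhs::randomLHS(n, length(bounds))
  pts <- purrr::imap(bounds, function(b, nm) {
    b[1] + U[, match(nm, names(bounds))] * (b[2] - b[1])
  })
  pts <- tibble::as_tibble(pts)
  if (all(c("d", "a") %in% names(pts))) {
    pts <- add_derived_porosity(pts, cell)
  }
  pts
}

apply_design <- function(spec, row) {
  for (nm in intersect(c("d", "a", "t_lat", "t_plate"), names(row))) {
    spec[[nm]] <- row[[nm]]
  }
  validate_construct_spec(spec)
  spec
}

#' Run the FE sweep over a set of design points
#'
#' Solves the full FE chain once per design point on the converged mesh
#' settings of the template spec. Points sharing a geometry (and bone-modulus
#' multiplier) reuse one stiffness factorisation across load levels. Rows
#' whose geometry is infeasible (d/a above the cell cap) or whose
#' spec is unbuildable are recorded with `converged = FALSE` rather than
#' aborting the sweep.
#'
#' @param points Tibble of design points (columns `d`, `a`, `t_lat`,
#'   `t_plate`, `P`, optional `bone_scale`).
#' @param spec Template [construct_spec()] supplying geometry not in the
#'   design variables (envelope, screws, mesh divisions).
#' @param law Porosity law; default built-in coupon calibration.
#' @param progress Print a progress line every 50 geometries.
#' @return An `fe_dataset` tibble: the design columns plus `p`,
#'   `sigma_vm_max`, `delta_max`, `sigma_screw_max`, `converged`, `feasible`,
#'   with provenance attributes (`generator`, `mesh_divisions`, `version`).
#' @export
run_sweep <- function(points, spec = construct_spec(), law = NULL,
                      progress = FALSE) {
  if (is.null(law)) law <- calibrate_porosity_law(lattice_coupon_table(),
                                                  E_solid = 110)
  points <- tibble::as_tibble(points)
  if (!"bone_scale" %in% names(points)) points$bone_scale <- 1
  points <- add_derived_porosity(points, spec$cell)
  geom_cols <- intersect(c("d", "a", "t_lat", "t_plate", "bone_scale"),
                         names(points))
  key <- do.call(paste, points[geom_cols])
  # the mesh depends only on the layer thicknesses; materials are linear in
  # each region modulus, so unit-modulus parts are cached per distinct mesh
  mesh_cols <- intersect(c("t_lat", "t_plate"), names(points))
  mesh_key <- do.call(paste, points[mesh_cols])
  parts_cache <- list()
  out <- vector("list", nrow(points))
  n_geom <- 0
  for (kk in unique(key)) {
    idx <- which(key == kk)
    row1 <- points[idx[1], ]
    n_geom <- n_geom + 1
    if (progress && n_geom %% 50 == 0) {
      message("sweep geometry ", n_geom)
    }
    build <- tryCatch({
      sp <- apply_design(spec, row1)
      mm <- region_material_map(sp, law = law,
                                bone_scale = row1$bone_scale)
      mk <- mesh_key[idx[1]]
      if (is.null(parts_cache[[mk]])) {
        parts_cache[[mk]] <- region_stiffness_parts(build_construct_mesh(sp),
                                                    mm)
      }
      assemble_from_parts(parts_cache[[mk]], mm)
    }, error = function(e) NULL)
    for (r in idx) {
      row <- points[r, ]
      res <- if (is.null(build) || !row$feasible) NULL else {
        tryCatch(solve_static(build, load_case(P = row$P)),
                 error = function(e) NULL)
      }
      ok <- !is.null(res) && isTRUE(res$converged)
      out[[r]] <- tibble::tibble(
        sigma_vm_max = if (ok) res$sigma_vm_max_plate else NA_real_,
        delta_max = if (ok) res$delta_max else NA_real_,
        sigma_screw_max = if (ok) res$sigma_screw_max else NA_real_,
        converged = ok
      )
    }
  }
  ds <- dplyr::bind_cols(points, dplyr::bind_rows(out))
  new_fe_dataset(ds, generator = "run_sweep",
                 mesh_divisions = spec$mesh_divisions)
}

new_fe_dataset <- function(df, generator = "unknown", seed = NA,
                           mesh_divisions = NULL) {
  structure(
    tibble::as_tibble(df),
    generator = generator, seed = seed, mesh_divisions = mesh_divisions,
    version = as.character(utils::packageVersion("latticeplate")),
    class = c("fe_dataset", class(tibble::tibble())))
}

#' Quality-control filter for an FE dataset
#'
#' Drops rows that failed to converge or whose geometry is infeasible
#' (strut slenderness above the cell cap), recording the exclusion reason
#' per dropped row in the `excluded` attribute.
#'
#' @param rows An `fe_dataset` (or tibble with `converged`/`feasible`
#'   columns).
#' @return The retained rows as an `fe_dataset`; `attr(x, "excluded")` holds
#'   a tibble of dropped rows with a `reason` column.
#' @export
qc_filter <- function(rows) {
  rows <- tibble::as_tibble(rows)
  feas <- if ("feasible" %in% names(rows)) rows$feasible else TRUE
  conv <- if ("converged" %in% names(rows)) rows$converged else TRUE
  reason <- dplyr::case_when(
    !feas ~ "infeasible",
    !conv ~ "non-converged",
    .default = NA_character_
  )
  excluded <- rows[!is.na(reason), ]
  excluded$reason <- reason[!is.na(reason)]
  kept <- rows[is.na(reason), ]
  out <- new_fe_dataset(kept, generator = attr(rows, "generator") %||% "qc",
                        mesh_divisions = attr(rows, "mesh_divisions"))
  attr(out, "excluded") <- excluded
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read/write an FE dataset as CSV with a JSON provenance sidecar
#'
#' Schema: one header row,
#' `d,a,t_lat,t_plate,P,p,sigma_vm_max,delta_max,sigma_screw_max,converged`
#' (plus `bone_scale` and `feasible` when present). Provenance (generator,
#' seed, mesh settings, package version) goes to `<path>.json`.
#'
#' @param dataset An `fe_dataset`.
#' @param path CSV path.
#' @return The writer returns `path` invisibly; the reader an `fe_dataset`.
#' @export
write_fe_dataset <- function(dataset, path) {
  utils::write.csv(dataset, path, row.names = FALSE, quote = FALSE)
  prov <- list(generator = attr(dataset, "generator"),
               seed = attr(dataset, "seed"),
               mesh_divisions = attr(dataset, "mesh_divisions"),
               version = attr(dataset, "version"),
               n_rows = nrow(dataset))
  jsonlite::write_json(prov, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_fe_dataset
#' @export
read_fe_dataset <- function(path) {
  df <- tibble::as_tibble(utils::read.csv(path))
  prov_path <- paste0(path, ".json")
  prov <- if (file.exists(prov_path)) {
    jsonlite::read_json(prov_path, simplifyVector = TRUE)
  } else list()
  new_fe_dataset(df, generator = prov$generator %||% "file",
                 seed = prov$seed %||% NA,
                 mesh_divisions = prov$mesh_divisions)
}
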