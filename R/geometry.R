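#' Parametric synthetic bone-plate-lattice construct
#'
#' Defines the desk-scale surrogate of a plated segmental defect: two
#' cortical-bone end blocks bridged by a grafted span, with an implant stack
#' running along the full top surface — solid face plates sandwiching a
#' homogenised lattice core — and discrete screw columns tying the stack to
#' the bone blocks. Coordinates are right-handed, x along the span, z through
#' the thickness, origin at one fixed end; all lengths in mm.
#'
#' @param bone_block_length Length of each bone end block, mm.
#' @param defect_span Length of the bridged defect, mm.
#' @param section_width Cross-section width (y), mm.
#' @param section_height Cross-section height (z), mm.
#' @param t_plate Solid face-plate thickness, mm (two plate layers).
#' @param t_lat Lattice-core thickness, mm.
#' @param d Strut diameter of the lattice cell, mm.
#' @param a Lattice unit-cell size, mm.
#' @param screw_positions Axial (x) positions of screw columns, mm; must lie
#'   inside the bone blocks. Each position yields one screw column per
#'   central y-row (two rows for the default width), eight screws in all for
#'   the default four positions.
#' @param load_patch_width Axial extent of the occlusal load patch centred
#'   over the defect midspan, mm.
#' @param mesh_divisions Named list of per-segment element counts:
#'   `nx_bone`, `nx_span`, `ny`, `nz_lower`, `nz_plate`, `nz_lat`.
#' @param cell A [lattice_cell()] used to derive the core porosity.
#'
#' @return An object of class `construct_spec`.
#' @export
construct_spec <- function(bone_block_length = 25,
                           defect_span = 30,
                           section_width = 10,
                           section_height = 12,
                           t_plate = 1.0,
                           t_lat = 2.5,
                           d = 0.70,
                           a = 3.0,
                           screw_positions = NULL,
                           load_patch_width = 8,
                           mesh_divisions = list(nx_bone = 8, nx_span = 12,
                                                 ny = 5, nz_lower = 4,
                                                 nz_plate = 2, nz_lat = 3),
                           cell = lattice_cell()) {
  L <- 2 * bone_block_length + defect_span
  if (is.null(screw_positions)) {
    screw_positions <- c(0.4 * bone_block_length, 0.7 * bone_block_length,
                         L - 0.7 * bone_block_length,
                         L - 0.4 * bone_block_length)
  }
  spec <- structure(
    list(bone_block_length = bone_block_length, defect_span = defect_span,
         section_width = section_width, section_height = section_height,
         t_plate = t_plate, t_lat = t_lat, d = d, a = a,
         screw_positions = screw_positions,
         load_patch_width = load_patch_width,
         mesh_divisions = mesh_divisions, cell = cell),
    class = "construct_spec"
  )
  validate_construct_spec(spec)
  spec
}

validate_construct_spec <- function(spec) {
  with(spec, {
    if (defect_span <= 0) stop("construct build error: defect_span must be > 0")
    if (bone_block_length <= 0) {
      stop("construct build error: bone_block_length must be > 0")
    }
    if (t_plate <= 0 || t_lat <= 0) {
      stop("construct build error: plate and lattice thicknesses must be > 0")
    }
    if (2 * t_plate + t_lat >= section_height) {
      stop("construct build error: plate/lattice stack (2*t_plate + t_lat) ",
           "exceeds section_height, no room for the bone substrate")
    }
    L <- 2 * bone_block_length + defect_span
    in_blocks <- (spec$screw_positions > 0 &
                    spec$screw_positions < bone_block_length) |
      (spec$screw_positions > L - bone_block_length & spec$screw_positions < L)
    if (!all(in_blocks)) {
      stop("construct build error: screw_positions must lie inside the ",
           "bone blocks")
    }
    md <- spec$mesh_divisions
    need <- c("nx_bone", "nx_span", "ny", "nz_lower", "nz_plate", "nz_lat")
    if (!all(need %in% names(md))) {
      stop("mesh_divisions needs: ", paste(need, collapse = ", "))
    }
    if (any(unlist(md[need]) < 1)) {
      stop("construct build error: all mesh divisions must be >= 1")
    }
    if (spec$load_patch_width <= 0 || spec$load_patch_width > defect_span) {
      stop("construct build error: load_patch_width must lie in ",
           "(0, defect_span]")
    }
    invisible(TRUE)
  })
}

#' @exportS3Method base::print
print.construct_spec <- function(x, ...) {
  L <- 2 * x$bone_block_length + x$defect_span
  cat(sprintf(
    "<construct_spec> %g x %g x %g mm, span %g mm, t_plate %g, t_lat %g, d %g, a %g, %d screw columns\n",
    L, x$section_width, x$section_height, x$defect_span,
    x$t_plate, x$t_lat, x$d, x$a, length(x$screw_positions)))
  invisible(x)
}

# segment breakpoints: seq subdivided into n equal elements
seg_breaks <- function(from, to, n) seq(from, to, length.out = n + 1)

#' Build the structured hexahedral mesh of a construct
#'
#' Generates a conforming grid of 8-node trilinear hexahedra on the construct
#' prism. Grid lines are placed on every material interface (bone/graft to
#' plate, plate to lattice), so each element carries exactly one region label:
#' `bone` (end blocks and grafted span substrate), `plate` (both solid face
#' plates), `lattice` (homogenised core), or `screw` (vertical tie columns at
#' the screw positions). Node sets: `fixed_end` (both outer x faces),
#' `load_patch` (top-face nodes under the occlusal patch).
#'
#' @param spec A [construct_spec()].
#' @return An object of class `construct_mesh` with fields `nodes` (n x 3),
#'   `elems` (ne x 8 connectivity), `region` (factor), `elem_dims` (ne x 3
#'   box edge lengths), `node_sets`, `grid`, `element_size`, `spec`.
#' @export
build_construct_mesh <- function(spec) {
  validate_construct_spec(spec)
  md <- spec$mesh_divisions
  Lb <- spec$bone_block_length; S <- spec$defect_span
  W <- spec$section_width; H <- spec$section_height
  L <- 2 * Lb + S
  H_low <- H - 2 * spec$t_plate - spec$t_lat

  xb <- c(seg_breaks(0, Lb, md$nx_bone),
          seg_breaks(Lb, Lb + S, md$nx_span)[-1],
          seg_breaks(Lb + S, L, md$nx_bone)[-1])
  yb <- seg_breaks(0, W, md$ny)
  z1 <- H_low; z2 <- H_low + spec$t_plate; z3 <- z2 + spec$t_lat
  zb <- c(seg_breaks(0, z1, md$nz_lower),
          seg_breaks(z1, z2, md$nz_plate)[-1],
          seg_breaks(z2, z3, md$nz_lat)[-1],
          seg_breaks(z3, H, md$nz_plate)[-1])

  nx <- length(xb) - 1; ny <- length(yb) - 1; nz <- length(zb) - 1
  nnx <- nx + 1; nny <- ny + 1; nnz <- nz + 1

  nodes <- as.matrix(expand.grid(x = xb, y = yb, z = zb,
                                 KEEP.OUT.ATTRS = FALSE))
  dimnames(nodes) <- NULL
  nid <- function(i, j, k) i + (j - 1) * nnx + (k - 1) * nnx * nny

  eg <- expand.grid(i = seq_len(nx), j = seq_len(ny), k = seq_len(nz),
                    KEEP.OUT.ATTRS = FALSE)
  i <- eg$i; j <- eg$j; k <- eg$k
  elems <- cbind(nid(i, j, k),     nid(i + 1, j, k),
                 nid(i + 1, j + 1, k), nid(i, j + 1, k),
                 nid(i, j, k + 1), nid(i + 1, j, k + 1),
                 nid(i + 1, j + 1, k + 1), nid(i, j + 1, k + 1))

  hx <- diff(xb)[i]; hy <- diff(yb)[j]; hz <- diff(zb)[k]
  xc <- (xb[i] + xb[i + 1]) / 2
  zc <- (zb[k] + zb[k + 1]) / 2

  # z-layer -> region; grid lines sit on every interface so centres decide
  region <- ifelse(zc < z1, "bone",
                   ifelse(zc < z2, "plate",
                          ifelse(zc < z3, "lattice", "plate")))

  # screw tie columns: nearest x element column, two central y rows, full z
  iy_mid <- sort(unique(pmax(1, pmin(ny, c(floor((ny + 1) / 2),
                                           ceiling((ny + 1) / 2))))))
  xcu <- (xb[-length(xb)] + xb[-1]) / 2
  for (sx in spec$screw_positions) {
    ix <- which.min(abs(xcu - sx))
    region[i == ix & j %in% iy_mid] <- "screw"
  }
  region <- factor(region, levels = c("bone", "plate", "lattice", "screw"))

  fixed_end <- which(nodes[, 1] == 0 | nodes[, 1] == L)
  xmid <- L / 2; wpatch <- spec$load_patch_width
  eps <- 1e-9 * L
  top <- nodes[, 3] == H
  # nodes of any top face overlapping the geometric patch interval
  x1 <- xmid - wpatch / 2; x2 <- xmid + wpatch / 2
  face_overlap <- which(pmin(xb[-1], x2) - pmax(xb[-length(xb)], x1) > eps)
  patch_nodes <- which(top & nodes[, 1] >= xb[min(face_overlap)] - eps &
                         nodes[, 1] <= xb[max(face_overlap) + 1] + eps)

  structure(
    list(nodes = nodes, elems = elems, region = region,
         elem_dims = cbind(hx, hy, hz),
         elem_index = cbind(i = i, j = j, k = k),
         node_sets = list(fixed_end = fixed_end, load_patch = patch_nodes),
         grid = list(xb = xb, yb = yb, zb = zb, nx = nx, ny = ny, nz = nz),
         element_size = mean(c(diff(xb), diff(yb), diff(zb))),
         load_patch_bounds = c(x1, x2),
         spec = spec),
    class = "construct_mesh"
  )
}

#' @exportS3Method base::print
print.construct_mesh <- function(x, ...) {
  cat(sprintf(
    "<construct_mesh> %d nodes, %d hex8 elements (mean edge %.3g mm)\n",
    nrow(x$nodes), nrow(x$elems), x$element_size))
  print(table(x$region))
  invisible(x)
}

#' Refine a construct mesh
#'
#' Scales every per-segment division count by `factor` (rounded up) and
#' rebuilds the mesh; regions, node sets and the load patch keep their
#' geometric definitions.
#'
#' @param spec A [construct_spec()].
#' @param factor Refinement factor >= 1.
#' @return A `construct_mesh`.
#' @export
refine_mesh <- function(spec, factor = 1.2) {
  if (!is.finite(factor) || factor < 1) stop("refinement factor must be >= 1")
  md <- lapply(spec$mesh_divisions, function(n) as.integer(ceiling(n * factor)))
  spec$mesh_divisions <- md
  build_construct_mesh(spec)
}

#' Total area of the load patch
#'
#' Geometric area of the occlusal pressure patch (axial extent times section
#' width); independent of mesh refinement by construction.
#'
#' @param mesh A `construct_mesh`.
#' @return Area in mm^2.
#' @export
load_patch_area <- function(mesh) {
  diff(mesh$load_patch_bounds) * mesh$spec$section_width
}

#' Per-region volumes of a construct mesh
#'
#' @param mesh A `construct_mesh`.
#' @return A tibble with columns `region`, `volume_mm3`.
#' @export
region_volumes <- function(mesh) {
  v <- mesh$elem_dims[, 1] * mesh$elem_dims[, 2] * mesh$elem_dims[, 3]
  out <- tapply(v, mesh$region, sum, default = 0)
  tibble::tibble(region = names(out), volume_mm3 = as.numeric(out))
}

#' Export a mesh (and optional fields) to legacy ASCII VTK
#'
#' Writes an unstructured-grid VTK file with region labels as cell data and
#' node sets as 0/1 point masks, for inspection in ParaView-class viewers.
#'
#' @param mesh A `construct_mesh`.
#' @param path Output file path.
#' @param cell_data Optional named list of per-element numeric vectors.
#' @param point_data Optional named list of per-node numeric vectors (or
#'   n x 3 matrices written as vectors).
#' @return `path`, invisibly.
#' @export
write_mesh_vtk <- function(mesh, path, cell_data = NULL, point_data = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  n <- nrow(mesh$nodes); ne <- nrow(mesh$elems)
  writeLines(c("# vtk DataFile Version 3.0",
               "latticeplate construct mesh", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", n)), con)
  utils::write.table(format(mesh$nodes, scientific = FALSE), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  writeLines(sprintf("CELLS %d %d", ne, ne * 9), con)
  utils::write.table(cbind(8, mesh$elems - 1), con, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  writeLines(sprintf("CELL_TYPES %d", ne), con)
  writeLines(as.character(rep(12L, ne)), con)

  writeLines(sprintf("CELL_DATA %d", ne), con)
  writeLines(c("SCALARS region int 1", "LOOKUP_TABLE default"), con)
  writeLines(as.character(as.integer(mesh$region)), con)
  for (nm in names(cell_data)) {
    writeLines(c(sprintf("SCALARS %s double 1", nm),
                 "LOOKUP_TABLE default"), con)
    writeLines(format(cell_data[[nm]], scientific = TRUE), con)
  }

  writeLines(sprintf("POINT_DATA %d", n), con)
  for (set in names(mesh$node_sets)) {
    mask <- integer(n); mask[mesh$node_sets[[set]]] <- 1L
    writeLines(c(sprintf("SCALARS %s int 1", set), "LOOKUP_TABLE default"),
               con)
    writeLines(as.character(mask), con)
  }
  for (nm in names(point_data)) {
    v <- point_data[[nm]]
    if (is.matrix(v)) {
      writeLines(sprintf("VECTORS %s double", nm), con)
      utils::write.table(format(v, scientific = TRUE), con,
                         row.names = FALSE, col.names = FALSE, quote = FALSE)
    } else {
      writeLines(c(sprintf("SCALARS %s double 1", nm),
                   "LOOKUP_TABLE default"), con)
      writeLines(format(v, scientific = TRUE), con)
    }
  }
  invisible(path)
}
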