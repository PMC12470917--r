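# independent element oracle: 4-point Gauss-Legendre quadrature with shape
# gradients obtained by numerical differentiation of the trilinear shape
# functions (entirely separate code path from the production kernel)
oracle_hex8 <- function(hx, hy, hz, E, nu) {
  shape <- function(xi, eta, zeta) {
    sx <- c(-1, 1, 1, -1, -1, 1, 1, -1)
    sy <- c(-1, -1, 1, 1, -1, -1, 1, 1)
    sz <- c(-1, -1, -1, -1, 1, 1, 1, 1)
    (1 + sx * xi) * (1 + sy * eta) * (1 + sz * zeta) / 8
  }
  num_grad <- function(xi, eta, zeta, h = 1e-6) {
    cbind((shape(xi + h, eta, zeta) - shape(xi - h, eta, zeta)) / (2 * h),
          (shape(xi, eta + h, zeta) - shape(xi, eta - h, zeta)) / (2 * h),
          (shape(xi, eta, zeta + h) - shape(xi, eta, zeta - h)) / (2 * h))
  }
  lam <- E * nu / ((1 + nu) * (1 - 2 * nu))
  mu <- E / (2 * (1 + nu))
  D <- diag(c(rep(2 * mu, 3), rep(mu, 3)))
  D[1:3, 1:3] <- D[1:3, 1:3] + lam
  gl <- pracma::gaussLegendre(4, -1, 1)
  ke <- matrix(0, 24, 24)
  for (qi in 1:4) for (qj in 1:4) for (qk in 1:4) {
    g <- num_grad(gl$x[qi], gl$x[qj], gl$x[qk])
    g <- sweep(g, 2, c(hx, hy, hz) / 2, "/")
    B <- matrix(0, 6, 24)
    for (nn in 1:8) {
      cdof <- 3 * (nn - 1)
      B[1, cdof + 1] <- g[nn, 1]
      B[2, cdof + 2] <- g[nn, 2]
      B[3, cdof + 3] <- g[nn, 3]
      B[4, cdof + 1] <- g[nn, 2]; B[4, cdof + 2] <- g[nn, 1]
      B[5, cdof + 2] <- g[nn, 3]; B[5, cdof + 3] <- g[nn, 2]
      B[6, cdof + 1] <- g[nn, 3]; B[6, cdof + 3] <- g[nn, 1]
    }
    w <- gl$w[qi] * gl$w[qj] * gl$w[qk] * hx * hy * hz / 8
    ke <- ke + t(B) %*% D %*% B * w
  }
  ke
}

test_that("element stiffness matches an independent quadrature oracle", {
  ke <- hex8_stiffness(2, 1, 1.5, 2000, 0.3)
  ko <- oracle_hex8(2, 1, 1.5, 2000, 0.3)
  expect_lt(max(abs(ke - ko)) / max(abs(ko)), 1e-6)
  ke1 <- hex8_stiffness(1, 1, 1, 1000, 0.25)
  ko1 <- oracle_hex8(1, 1, 1, 1000, 0.25)
  expect_lt(max(abs(ke1 - ko1)) / max(abs(ko1)), 1e-6)
})

test_that("stiffness is symmetric with rigid-body modes in its nullspace", {
  mesh <- build_construct_mesh(tiny_spec())
  ks <- assemble_stiffness(mesh, region_material_map(tiny_spec()))
  K <- ks$K
  expect_lt(max(abs(K - Matrix::t(K))), 1e-8 * max(abs(K)))
  n <- nrow(mesh$nodes)
  modes <- list(
    rep(c(1, 0, 0), n), rep(c(0, 1, 0), n), rep(c(0, 0, 1), n),
    as.vector(t(cbind(-mesh$nodes[, 2], mesh$nodes[, 1], 0))),   # rot z
    as.vector(t(cbind(0, -mesh$nodes[, 3], mesh$nodes[, 2]))),   # rot x
    as.vector(t(cbind(mesh$nodes[, 3], 0, -mesh$nodes[, 1])))    # rot y
  )
  for (m in modes) {
    expect_lt(max(abs(K %*% m)), 1e-8 * max(abs(K)))
  }
  expect_error(assemble_stiffness(mesh, list(plate = ti6al4v_card())),
               "no material mapped")
})

test_that("uniaxial patch test: constant stress and PL/EA end displacement", {
  # single material, nu = 0, uniform traction: exact at any mesh density
  for (nz in c(3, 7)) {
    mesh <- box_mesh(3, 2, nz, Lx = 4, Ly = 2, Lz = 10)
    ks <- assemble_stiffness(mesh, uniform_material_map(E = 100))
    res <- solve_static(ks, load_case(P = 1000))
    A <- 4 * 2
    expect_equal(max(res$sigma_vm), 1000 / A, tolerance = 1e-9)
    expect_equal(min(res$sigma_vm), 1000 / A, tolerance = 1e-9)
    expect_equal(res$delta_max, 1000 * 10 / (100e3 * A), tolerance = 1e-6)
    expect_equal(res$sigma_vm_max_plate, 1000 / A, tolerance = 1e-9)
    # energy consistency on the same solve
    expect_equal(res$strain_energy, 0.5 * sum(res$F * res$u_flat),
                 tolerance = 1e-9)
  }
})

test_that("zero load gives the zero solution", {
  mesh <- box_mesh(2, 2, 2, 2, 2, 2)
  ks <- assemble_stiffness(mesh, uniform_material_map())
  res <- solve_static(ks, load_case(P = 0))
  expect_true(all(res$u == 0))
  expect_true(all(res$sigma_vm == 0))
  expect_equal(res$delta_max, 0)
})

test_that("solution is linear and superposable in the load", {
  spec <- tiny_spec()
  ks <- assemble_stiffness(build_construct_mesh(spec),
                           region_material_map(spec))
  r1 <- solve_static(ks, load_case(P = 300))
  r2 <- solve_static(ks, load_case(P = 600))
  r3 <- solve_static(ks, load_case(P = 900))
  expect_equal(r2$u, 2 * r1$u, tolerance = 1e-12)
  expect_equal(r2$sigma_vm, 2 * r1$sigma_vm, tolerance = 1e-12)
  expect_equal(r3$u_flat, r1$u_flat + r2$u_flat, tolerance = 1e-8)
  # external work equals stored strain energy
  expect_equal(r2$strain_energy, 0.5 * sum(r2$F * r2$u_flat),
               tolerance = 1e-9)
})

test_that("hydrostatic deformation has zero von Mises stress", {
  mesh <- box_mesh(2, 2, 2, 2, 2, 2)
  ks <- assemble_stiffness(mesh, uniform_material_map(E = 50, nu = 0.3))
  u <- as.vector(t(mesh$nodes)) * 1e-3   # u = eps * (x, y, z)
  vm <- recover_von_mises(u, mesh, ks)
  expect_lt(max(vm), 1e-10 * 50e3)
})

test_that("tip-loaded cantilever recovers the Euler-Bernoulli fibre stress", {
  Lx <- 32; Ly <- 2; Lz <- 4
  mesh <- box_mesh(64, 2, 20, Lx, Ly, Lz, fixed = "xmin",
                   patch_x = c(Lx - 1, Lx))
  ks <- assemble_stiffness(mesh, uniform_material_map(E = 100))
  res <- solve_static(ks, load_case(P = 100))
  arm <- (Lx - 0.5)                     # load centroid to the fixed face
  I <- Ly * Lz^3 / 12
  sigma_ref <- 100 * arm * (Lz / 2) / I
  expect_equal(max(res$sigma_vm), sigma_ref, tolerance = 0.05)
})

test_that("increasing lattice porosity never stiffens the construct", {
  spec_stiff <- tiny_spec(d = 1.0, a = 2.5)
  spec_soft <- tiny_spec(d = 0.4, a = 2.5)
  r_stiff <- solve_construct(spec_stiff, P = 600)
  r_soft <- solve_construct(spec_soft, P = 600)
  expect_gt(r_soft$delta_max, r_stiff$delta_max)
})

test_that("screw summary is invariant under relabelling non-screw elements", {
  spec <- tiny_spec()
  res <- solve_construct(spec, P = 600)
  mesh2 <- res$mesh
  bone_idx <- which(mesh2$region == "bone")
  mesh2$region[bone_idx[1:5]] <- "lattice"
  expect_equal(summarize_targets(res, mesh2)$sigma_screw_max,
               res$sigma_screw_max)
  # delta_max dominates the displacement of any node subset
  sub <- sqrt(rowSums(res$u[res$mesh$node_sets$load_patch, ]^2))
  expect_gte(res$delta_max, max(sub))
})

test_that("under-constrained systems flag non-convergence instead of lying", {
  mesh <- box_mesh(2, 2, 2, 2, 2, 2)
  mesh$node_sets$fixed_end <- mesh$node_sets$fixed_end[1]  # rigid modes left
  ks <- assemble_stiffness(mesh, uniform_material_map())
  res <- solve_static(ks, load_case(P = 10))
  expect_false(res$converged)
})

test_that("convergence study reports stable rows and patch-level stability", {
  spec <- tiny_spec()
  tab <- convergence_study(spec, load_case(600), factors = c(1, 1))
  expect_equal(tab$sigma_vm_max_plate[1], tab$sigma_vm_max_plate[2])
  expect_equal(tab$delta_max[1], tab$delta_max[2])
  expect_error(convergence_study(spec, load_case(600), factors = 1),
               "at least 2")
})

test_that("region-decomposed assembly reproduces the direct assembly", {
  spec <- tiny_spec()
  mesh <- build_construct_mesh(spec)
  mm <- region_material_map(spec)
  k1 <- assemble_stiffness(mesh, mm)
  pp <- region_stiffness_parts(mesh, mm)
  k2 <- assemble_from_parts(pp, mm)
  expect_lt(max(abs(k1$K - k2$K)), 1e-9 * max(abs(k1$K)))
  r1 <- solve_static(k1, load_case(600))
  r2 <- solve_static(k2, load_case(600))
  expect_equal(r1$sigma_vm_max_plate, r2$sigma_vm_max_plate,
               tolerance = 1e-10)
  expect_equal(r1$delta_max, r2$delta_max, tolerance = 1e-10)
  # re-weighting the lattice part tracks a softer design
  mm_soft <- mm
  mm_soft$lattice <- material_card("soft", E = mm$lattice$E / 4, nu = 0.33,
                                   rho = 1)
  k3 <- assemble_from_parts(pp, mm_soft)
  expect_gt(solve_static(k3, load_case(600))$delta_max, r2$delta_max)
})
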