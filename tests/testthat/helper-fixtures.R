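# shared fixtures: coarse construct for fast FE tests, plain box meshes with
# bar/cantilever boundary conditions for closed-form verification

tiny_spec <- function(...) {
  construct_spec(mesh_divisions = list(nx_bone = 3, nx_span = 5, ny = 2,
                                       nz_lower = 2, nz_plate = 1,
                                       nz_lat = 1), ...)
}

table2_law <- function() {
  calibrate_porosity_law(lattice_coupon_table(), E_solid = 110)
}

# structured box mesh with z-axis loading semantics compatible with
# solve_static: fixed bottom face, load over the (optionally restricted)
# top face
box_mesh <- function(nx, ny, nz, Lx, Ly, Lz,
                     fixed = c("zmin", "xmin"),
                     patch_x = c(0, Lx)) {
  fixed <- match.arg(fixed)
  xb <- seq(0, Lx, length.out = nx + 1)
  yb <- seq(0, Ly, length.out = ny + 1)
  zb <- seq(0, Lz, length.out = nz + 1)
  nnx <- nx + 1; nny <- ny + 1
  nodes <- as.matrix(expand.grid(x = xb, y = yb, z = zb,
                                 KEEP.OUT.ATTRS = FALSE))
  dimnames(nodes) <- NULL
  nid <- function(i, j, k) i + (j - 1) * nnx + (k - 1) * nnx * nny
  eg <- expand.grid(i = seq_len(nx), j = seq_len(ny), k = seq_len(nz),
                    KEEP.OUT.ATTRS = FALSE)
  i <- eg$i; j <- eg$j; k <- eg$k
  elems <- cbind(nid(i, j, k), nid(i + 1, j, k), nid(i + 1, j + 1, k),
                 nid(i, j + 1, k), nid(i, j, k + 1), nid(i + 1, j, k + 1),
                 nid(i + 1, j + 1, k + 1), nid(i, j + 1, k + 1))
  region <- factor(rep("plate", nrow(elems)),
                   levels = c("bone", "plate", "lattice", "screw"))
  region[1] <- "screw"  # label only; tests map screw to the same card
  fixed_nodes <- if (fixed == "zmin") which(nodes[, 3] == 0) else
    which(nodes[, 1] == 0)
  top <- which(nodes[, 3] == Lz & nodes[, 1] >= patch_x[1] - 1e-9 &
                 nodes[, 1] <= patch_x[2] + 1e-9)
  structure(
    list(nodes = nodes, elems = elems, region = region,
         elem_dims = cbind(diff(xb)[i], diff(yb)[j], diff(zb)[k]),
         elem_index = cbind(i = i, j = j, k = k),
         node_sets = list(fixed_end = fixed_nodes, load_patch = top),
         grid = list(xb = xb, yb = yb, zb = zb, nx = nx, ny = ny, nz = nz),
         element_size = mean(c(diff(xb), diff(yb), diff(zb))),
         load_patch_bounds = patch_x,
         spec = list(section_width = Ly)),
    class = "construct_mesh"
  )
}

uniform_material_map <- function(E = 100, nu = 1e-9) {
  # nu ~ 0 keeps axial states exactly uniaxial while satisfying the card
  if (nu == 0) nu <- 1e-9
  card <- material_card("test solid", E = E, nu = nu, rho = 1)
  list(bone = card, plate = card, lattice = card, screw = card)
}

# tiny linear-regression dataset for surrogate toys
linear_toy <- function(n = 200, seed = 1, noise = 0) {
  set.seed(seed)
  df <- tibble::tibble(x = stats::runif(n, -1, 1),
                       z = stats::runif(n, -1, 1))
  df$y <- 2 * df$x + 0.5 * df$z + stats::rnorm(n, 0, noise)
  df
}

toy_splits <- function(df, frac = c(0.7, 0.15, 0.15)) {
  n <- nrow(df)
  n1 <- round(frac[1] * n); n2 <- round(frac[2] * n)
  list(train = df[seq_len(n1), ],
       val = df[n1 + seq_len(n2), ],
       test = df[(n1 + n2 + 1):n, ])
}

fast_config <- function(...) {
  train_config(max_epochs = 400, patience = 60, ...)
}

# thin wrappers over package internals used by the unit tests
net_forward_test <- function(net, X) {
  latticeplate:::net_forward(net, X)$A[[length(net$W) + 1]]
}

net_gradient_test <- function(net, X, Y, config) {
  latticeplate:::net_backward(net, X, Y, config)
}

# exactly linear surrogate: sigma_vm_max = P, delta_max = P / 600,
# sigma_screw_max = 0.1 * P, built from a ReLU pair (P+, P-)
linear_fit <- function() {
  net <- surrogate_net(5, hidden = 2, n_outputs = 3, dropout = 0,
                       weight_decay = 0, seed = 1)
  net$W[[1]] <- matrix(0, 5, 2)
  net$W[[1]][5, ] <- c(1, -1)
  net$b[[1]] <- c(0, 0)
  net$W[[2]] <- rbind(c(1, 1 / 600, 0.1), -c(1, 1 / 600, 0.1))
  net$b[[2]] <- c(0, 0, 0)
  net$dropout_layers <- integer(0)
  ident <- function(k) structure(list(mean = rep(0, k), sd = rep(1, k)),
                                 class = "standardizer")
  structure(
    list(net = net, x_std = ident(5), y_std = ident(3),
         inputs = c("d", "a", "t_lat", "t_plate", "P"),
         targets = c("sigma_vm_max", "delta_max", "sigma_screw_max"),
         history = NULL, best_epoch = 1, config = NULL,
         train_ranges = list(d = c(-1e6, 1e6), a = c(-1e6, 1e6),
                             t_lat = c(-1e6, 1e6), t_plate = c(-1e6, 1e6),
                             P = c(-1e6, 1e6))),
    class = "surrogate_fit")
}

canonical_design <- function(P = 600) {
  tibble::tibble(d = 0.7, a = 3, t_lat = 2.5, t_plate = 1, P = P)
}

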