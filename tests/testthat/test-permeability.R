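## helper: random rotation matrix via QR of a Gaussian matrix
random_rotation <- function() {
  qr_d <- qr(matrix(rnorm(9), 3, 3))
  Q <- qr.Q(qr_d)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

rotate_network <- function(net, Rm) {
  P <- as.matrix(net$nodes[, c("x", "y", "z")]) %*% t(Rm)
  net$nodes$x <- P[, 1]; net$nodes$y <- P[, 2]; net$nodes$z <- P[, 3]
  net
}

test_that("porosity-scaled isotropic tensors are exact multiples of I", {
  K <- k_isotropic(c(0, 0.02, 0.5))
  expect_equal(K[1, ], c(xx = 0, yy = 0, zz = 0, xy = 0, xz = 0, yz = 0))
  expect_equal(unname(K[2, 1:3]), rep(0.02, 3))
  ev <- eigen(sym6_to_mat(K[3, ]), symmetric = TRUE)$values
  expect_equal(ev, rep(0.5, 3))
  expect_error(k_isotropic(-0.1), "non-negative")
})

test_that("HvC tensor reproduces the single-vessel hand value", {
  nodes <- data.frame(id = 0:1, x = c(0, 0.5), y = 0, z = 0, radius = 0.001)
  edges <- data.frame(id = 0L, node_a = 0L, node_b = 1L)
  net <- vascular_network(nodes, edges, root_id = 0L)
  net$vessels$compartment <- 1L
  K <- k_hvc(c(0, 0, 0), 0.6, 1, net, delta_x0 = 1, mu = 0.0035,
             vol_rve = 1)
  ## d = 0.002 mm, l = 0.5 mm, dx = (0.5, 0, 0):
  ## K11 = pi / (128 * 0.0035) * 0.002^4 * 0.25 / 0.5
  hand <- pi / (128 * 0.0035) * (0.002^4 * 0.25 / 0.5)
  expect_equal(K[1, 1], hand, tolerance = 1e-12)
  expect_equal(K[1, 1], 5.610e-11, tolerance = 1e-4)
  expect_true(all(abs(K[-1]) < 1e-25))
})

test_that("HvC tensor is diagonal-equal for three orthogonal identical vessels", {
  nodes <- data.frame(id = 0:5,
                      x = c(-0.2, 0.2, 0, 0, 0, 0),
                      y = c(0, 0, -0.2, 0.2, 0, 0),
                      z = c(0.01, 0.01, 0.01, 0.01, -0.19, 0.21),
                      radius = 0.002)
  edges <- data.frame(id = 0:2, node_a = c(0L, 2L, 4L), node_b = c(1L, 3L, 5L))
  net <- vascular_network(nodes, edges, root_id = NA_integer_,
                          validate = FALSE)
  net$vessels$compartment <- 1L
  K <- k_hvc(c(0, 0, 0.01), 0.5, 1, net, vol_rve = 1)
  expect_equal(K[1, 1], K[2, 2], tolerance = 1e-10)
  expect_equal(K[2, 2], K[3, 3], tolerance = 1e-10)
  expect_lt(max(abs(K[upper.tri(K)])), 1e-12 * K[1, 1])
})

test_that("HvC and PCA tensors are rotation-equivariant", {
  net <- assign_fluxes(random_tree(25, seed = 6))
  net$vessels$compartment <- 1L
  x <- c(0, 0, 0); R <- 2
  K_h <- k_hvc(x, R, 1, net, vol_rve = 1)
  K_p <- k_pca(x, R, 1, net)
  set.seed(21)
  for (rep in 1:5) {
    Rm <- random_rotation()
    net_r <- rotate_network(net, Rm)
    K_h_r <- k_hvc(as.numeric(Rm %*% x), R, 1, net_r, vol_rve = 1)
    K_p_r <- k_pca(as.numeric(Rm %*% x), R, 1, net_r)
    expect_equal(K_h_r, Rm %*% K_h %*% t(Rm), tolerance = 1e-8)
    expect_equal(K_p_r, Rm %*% K_p %*% t(Rm), tolerance = 1e-8)
  }
})

test_that("PCA handles collinear and oblique single-direction cases", {
  ## all vessels parallel to e1: all conductance along e1, ~0 transverse
  nodes <- data.frame(id = 0:3, x = c(0, 0.4, 0, 0.4),
                      y = c(0, 0, 0.1, 0.1), z = 0, radius = 0.002)
  edges <- data.frame(id = 0:1, node_a = c(0L, 2L), node_b = c(1L, 3L))
  net <- vascular_network(nodes, edges, root_id = NA_integer_,
                          validate = FALSE)
  net$vessels$compartment <- 1L
  K <- k_pca(c(0.2, 0.05, 0), 1, 1, net)
  Cp <- sum(poiseuille_conductance(net$vessels$radius, net$vessels$length))
  expect_equal(K[1, 1], Cp, tolerance = 1e-10)
  expect_lt(max(abs(K[-1])), 1e-10 * Cp)

  ## single vessel at 45 degrees in the e1-e2 plane: trace = conductance,
  ## equal split over the two in-plane directions
  nodes <- data.frame(id = 0:1, x = c(0, 0.3), y = c(0, 0.3), z = 0,
                      radius = 0.002)
  edges <- data.frame(id = 0L, node_a = 0L, node_b = 1L)
  net1 <- vascular_network(nodes, edges, root_id = NA_integer_,
                           validate = FALSE)
  net1$vessels$compartment <- 1L
  K1 <- k_pca(c(0.15, 0.15, 0), 1, 1, net1)
  C1 <- poiseuille_conductance(net1$vessels$radius, net1$vessels$length)
  expect_equal(sum(diag(K1)), C1, tolerance = 1e-12)
  expect_equal(K1[1, 1], K1[2, 2], tolerance = 1e-12)
})

test_that("PCA trace equals the summed conductances on random vessel sets", {
  set.seed(17)
  for (rep in 1:100) {
    nv <- sample(2:12, 1)
    u <- matrix(rnorm(3 * nv), ncol = 3)
    u <- u / sqrt(rowSums(u^2))
    Cp <- runif(nv, 1e-11, 1e-8)
    K <- darcypar:::k_pca_core(u, Cp)
    expect_lt(abs(sum(diag(K)) - sum(Cp)) / sum(Cp), 1e-10)
    expect_true(min(eigen(K, symmetric = TRUE)$values) > -1e-12 * sum(Cp))
  }
})

test_that("adding a vessel can only increase the HvC and PCA traces", {
  net <- assign_fluxes(random_tree(20, seed = 13))
  net$vessels$compartment <- 1L
  idx <- build_spatial_index(net)
  x <- c(0, 0, 0)
  hits <- vessels_in_rve(x, 2, net, 1, idx)
  terms <- darcypar:::hvc_vessel_terms(net)
  tr_all <- sum(colSums(terms[hits$row, 1:3] * hits$fraction))
  tr_less <- sum(colSums(terms[hits$row[-1], 1:3] * hits$fraction[-1]))
  expect_gt(tr_all, tr_less)
})

test_that("eigenvalue flooring preserves symmetry and perturbs minimally", {
  K <- diag(c(2, 1, 0.5))
  expect_equal(regularize_spd(K), K)
  u <- c(1, 2, 3) / sqrt(14)
  K1 <- 5 * (u %o% u)                       # rank one
  K1r <- regularize_spd(K1)
  ev <- eigen(K1r, symmetric = TRUE)$values
  expect_equal(ev[1], 5, tolerance = 1e-9)
  expect_true(all(ev[2:3] >= 1e-6 * 5 * (1 - 1e-9)))
  expect_lt(norm(K1r - K1, "2"), 1e-6 * 5 * (1 + 1e-9))
  expect_error(regularize_spd(matrix(1:9, 3, 3)), "symmetric")
})

test_that("field parameterisation dispatches, fills and regularises", {
  net <- generate_volume_filling_tree(7, seed = 2)
  h <- compute_zeta(net)
  net <- set_compartments(net, partition_by_zeta(net, h,
                                                 optimise_partition(net, h,
                                                   proportion_targets(net, h))))
  fl <- solve_network_flow(net, tree_boundary_conditions(net))
  mesh <- build_grid(n = 6)
  rf <- rve_fields(net, fl, mesh$points, 0.4)
  iso <- parameterise_field(mesh, 0.4, 2, "iso", net, fl, rve = rf,
                            quiet = TRUE)
  jc <- match("2", colnames(rf$phi))
  nz <- rf$phi[, jc] > 0
  expect_equal(iso$K[nz, 1], rf$phi[nz, jc])
  for (m in c("iso", "hvc", "pca")) {
    tf <- parameterise_field(mesh, 0.4, 2, m, net, fl, rve = rf,
                             quiet = TRUE)
    expect_false(anyNA(tf$K))
    mineig <- vapply(seq_len(nrow(tf$K)), function(r)
      min(eigen(sym6_to_mat(tf$K[r, ]), symmetric = TRUE)$values),
      numeric(1))
    expect_true(all(mineig > 0))
  }
  ## a compartment with no vessels has no coverage at any radius
  expect_error(parameterise_field(mesh, 0.05, 99, "hvc", net, fl,
                                  quiet = TRUE), "radius too small")
})

test_that("uniform isotropic fixtures give spatially stable hvc/pca fields", {
  ## evaluate on an interior box so every RVE sees bulk lattice
  net <- generate_isotropic_lattice(n_per_axis = 9, seed = 4, jitter = 0.05)
  mesh <- build_grid(cbind(c(0.21, 0.46), c(0.21, 0.46), c(0.21, 0.46)),
                     n = 4)
  fl <- solve_network_flow(
    net, stats::setNames(c(2000, 1000),
                         c(face_nodes(net, 1, "lower")[1],
                           face_nodes(net, 1, "upper")[1])),
    zero_flux = terminal_nodes(net))
  rf <- rve_fields(net, fl, mesh$points, 0.2,
                   domain = attr(net, "domain"))
  for (m in c("hvc", "pca")) {
    tf <- parameterise_field(mesh, 0.2, 1, m, net, fl, rve = rf,
                             quiet = TRUE)
    tr <- rowSums(tf$K[, 1:3])
    expect_lt(stats::sd(tr) / mean(tr), 0.2)
  }
})
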