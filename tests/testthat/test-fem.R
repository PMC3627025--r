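test_that("grid construction has the right counts and spacing", {
  m1 <- build_grid(n = 1)
  expect_equal(nrow(m1$points), 8L)
  expect_equal(nrow(darcypar:::element_nodes(m1)), 1L)
  m16 <- build_grid(cbind(c(-1, 1), c(-1, 1), c(-1, 1)), 16)
  expect_equal(unname(m16$h), rep(0.125, 3))
  expect_equal(nrow(m16$points), 17L^3)
  expect_equal(nrow(darcypar:::element_nodes(m16)), 16L^3)
})

test_that("unit-Laplacian element stiffness matches an independent quadrature oracle", {
  mesh <- build_grid(cbind(c(0, 1), c(0, 1), c(0, 1)), 1)
  m <- nrow(mesh$points)
  asm <- assemble_darcy(mesh, K = cbind(rep(1, m), 1, 1, 0, 0, 0))
  Ke <- as.matrix(asm$A_stiff)

  ## oracle: midpoint-rule integration of grad(N_a) . grad(N_b) on the unit
  ## cube with independently coded trilinear shape gradients
  corners <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  gradN <- function(p, a) {
    cx <- corners[a, ]
    g <- numeric(3)
    for (d in 1:3) {
      others <- setdiff(1:3, d)
      term <- prod(ifelse(cx[others] == 1, p[others], 1 - p[others]))
      g[d] <- ifelse(cx[d] == 1, 1, -1) * term
    }
    g
  }
  ## Simpson rule per axis: exact for the (at most quadratic per axis)
  ## gradient products
  nodes1 <- c(0, 0.5, 1); w1 <- c(1, 4, 1) / 6
  pts <- as.matrix(expand.grid(nodes1, nodes1, nodes1))
  wts <- apply(as.matrix(expand.grid(w1, w1, w1)), 1, prod)
  oracle <- matrix(0, 8, 8)
  for (a in 1:8) for (b in 1:8) {
    vals <- vapply(seq_len(nrow(pts)), function(i)
      sum(gradN(pts[i, ], a) * gradN(pts[i, ], b)), numeric(1))
    oracle[a, b] <- sum(wts * vals)
  }
  ## map oracle corner order (x fastest in expand.grid) to mesh node order
  ord <- order(corners[, 3], corners[, 2], corners[, 1])
  expect_equal(Ke, oracle[ord, ord], tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("assembled systems are symmetric, PD, and linear in the K scale", {
  mesh <- build_grid(n = 4)
  m <- nrow(mesh$points)
  K <- cbind(rep(2, m), 1, 1.5, 0.1, 0, 0.2)
  asm <- assemble_darcy(mesh, K = K, coeff = rep(1, m))
  A <- asm$A_stiff + asm$A_mass
  expect_lt(max(abs(A - Matrix::t(A))), 1e-14)
  set.seed(2)
  v <- rnorm(m)
  expect_gt(as.numeric(v %*% (A %*% v)), 0)
  asm2 <- assemble_darcy(mesh, K = 2 * K)
  expect_lt(max(abs(asm2$A_stiff - 2 * asm$A_stiff)), 1e-12)
})

test_that("a constant equilibrium is reproduced exactly", {
  mesh <- build_grid(n = 6)
  m <- nrow(mesh$points)
  K <- cbind(rep(1, m), 1, 1, 0, 0, 0)
  prob <- darcy_problem(K, beta = list(a = rep(1, m), b = rep(2, m)),
                        pbar = list(a = rep(9000, m), b = rep(9000, m)),
                        vol_rve = 1)
  sol <- solve_darcy(prob, mesh)
  expect_equal(sol$p, rep(9000, m), tolerance = 1e-10)
  expect_lt(max(abs(sol$w)), 1e-6)
  mb <- mass_balance_report(sol, prob, mesh)
  expect_lt(abs(mb$exchange), 1e-6)
  expect_lt(abs(mb$total), 1e-6)
})

test_that("manufactured cosine solution converges at second order", {
  errs <- vapply(c(8, 16), function(n) {
    mesh <- build_grid(n = n)
    m <- nrow(mesh$points)
    K <- cbind(rep(1, m), 1, 1, 0, 0, 0)
    pbar1 <- (1 + pi^2) * cos(pi * mesh$points[, 1])
    prob <- darcy_problem(K, beta = list("1,2" = rep(1, m)),
                          pbar = list("1,2" = pbar1), vol_rve = 1)
    sol <- solve_darcy(prob, mesh)
    expect_lt(sol$residual, 1e-10)
    sqrt(mean((sol$p - cos(pi * mesh$points[, 1]))^2))
  }, numeric(1))
  expect_gt(errs[1] / errs[2], 3.4)
  expect_lt(errs[1] / errs[2], 4.7)
})

test_that("solution obeys the imposed-field bounds and shift equivariance", {
  set.seed(5)
  mesh <- build_grid(n = 5)
  m <- nrow(mesh$points)
  for (rep in 1:3) {
    K <- k_isotropic(runif(m, 0.01, 0.05))
    b1 <- runif(m, 0, 2); b2 <- runif(m, 0, 2)
    p1 <- runif(m, 9000, 13000); p3 <- runif(m, 7000, 9000)
    prob <- darcy_problem(K, beta = list(a = b1, b = b2),
                          pbar = list(a = p1, b = p3), vol_rve = 1)
    sol <- solve_darcy(prob, mesh)
    rng <- range(c(p1, p3))
    expect_true(all(sol$p >= rng[1] - 1e-6) && all(sol$p <= rng[2] + 1e-6))
    prob2 <- darcy_problem(K, beta = list(a = b1, b = b2),
                           pbar = list(a = p1 + 700, b = p3 + 700),
                           vol_rve = 1)
    sol2 <- solve_darcy(prob2, mesh)
    expect_equal(sol2$p - sol$p, rep(700, m), tolerance = 1e-8)
  }
})

test_that("deliberately inconsistent load coefficients break the balance", {
  ## negative control: load assembled with a perturbed (asymmetric-like)
  ## coupling field must violate the aggregate balance
  mesh <- build_grid(n = 4)
  m <- nrow(mesh$points)
  K <- cbind(rep(1, m), 1, 1, 0, 0, 0)
  beta <- rep(1, m)
  pbar1 <- 9000 + 1000 * mesh$points[, 1]
  prob <- darcy_problem(K, beta = list(a = beta), pbar = list(a = pbar1),
                        vol_rve = 1)
  good <- solve_darcy(prob, mesh)
  expect_lt(abs(mass_balance_report(good, prob, mesh)$total), 1e-6)

  cache <- good$cache
  bad_cache <- cache
  bad_cache$b <- assemble_darcy(mesh, load = 1.3 * beta * pbar1)$b
  bad <- solve_darcy(prob, mesh, cache = bad_cache)
  ## balance computed against the consistent load detects the inconsistency
  bad$cache$b <- cache$b
  expect_gt(abs(mass_balance_report(bad, prob, mesh)$total), 1)
})

test_that("pure-Neumann problems without coupling are rejected", {
  mesh <- build_grid(n = 3)
  m <- nrow(mesh$points)
  K <- cbind(rep(1, m), 1, 1, 0, 0, 0)
  expect_error(darcy_problem(K), "singular|supply")
  prob0 <- darcy_problem(K, beta = list(a = rep(0, m)),
                         pbar = list(a = rep(0, m)), vol_rve = 1)
  expect_error(solve_darcy(prob0, mesh), "singular")
})

test_that("Dirichlet faces and trilinear interpolation work together", {
  mesh <- build_grid(cbind(c(0, 1), c(0, 1), c(0, 1)), 6)
  m <- nrow(mesh$points)
  K <- cbind(rep(1, m), 1, 1, 0, 0, 0)
  lo <- mesh_face_nodes(mesh, 1, "lower")
  hi <- mesh_face_nodes(mesh, 1, "upper")
  prob <- darcy_problem(K, dirichlet = list(nodes = c(lo, hi),
                                            values = rep(c(2000, 1000),
                                                         c(length(lo),
                                                           length(hi)))))
  sol <- solve_darcy(prob, mesh)
  ## uniform K, two-face Dirichlet: exact linear profile in x
  expect_equal(sol$p, 2000 - 1000 * mesh$points[, 1], tolerance = 1e-8)
  q <- matrix(runif(9, 0.1, 0.9), 3)
  expect_equal(grid_interpolate(mesh, sol$p, q), 2000 - 1000 * q[, 1],
               tolerance = 1e-8)
})
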