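test_that("spatial index queries agree with a brute-force scan", {
  net <- generate_volume_filling_tree(6, seed = 6)
  idx <- build_spatial_index(net)
  set.seed(3)
  for (q in 1:20) {
    x <- runif(3, -0.8, 0.8)
    R <- runif(1, 0.05, 0.6)
    hits <- vessels_in_rve(x, R, net, index = idx)
    ## brute force: per-vessel scalar geometry, straight from the tables
    brute <- vapply(seq_len(nrow(net$vessels)), function(v) {
      a <- idx$A[v, ]; b <- idx$B[v, ]
      f <- function(t) sqrt(sum((a + t * (b - a) - x)^2)) - R
      ts <- seq(0, 1, length.out = 201)
      mean(vapply(ts, function(t) f(t) < 0, logical(1)))
    }, numeric(1))
    expect_setequal(hits$row, which(brute > 0))
    expect_equal(hits$fraction, brute[hits$row], tolerance = 0.02)
  }
  ## a ball covering the whole domain returns every vessel
  all_hits <- vessels_in_rve(c(0, 0, 0), 10, net, index = idx)
  expect_equal(sort(all_hits$row), seq_len(nrow(net$vessels)))
  expect_true(all(all_hits$fraction == 1))
})

test_that("segment-ball fractions match chord geometry", {
  ## vessel crossing the ball symmetrically through the centre:
  ## inside fraction = 2R / l for l > 2R
  nodes <- data.frame(id = 0:1, x = c(-2, 2), y = 0, z = 0, radius = 0.01)
  edges <- data.frame(id = 0L, node_a = 0L, node_b = 1L)
  net <- vascular_network(nodes, edges, root_id = 0L)
  hits <- vessels_in_rve(c(0, 0, 0), 0.5, net)
  expect_equal(hits$fraction, 2 * 0.5 / 4, tolerance = 1e-12)
  ## entirely outside: excluded
  expect_equal(nrow(vessels_in_rve(c(0, 3, 0), 0.5, net)), 0L)
})

test_that("averaged pressure is the volume-weighted vessel-pressure mean", {
  ## two vessels fully inside, volumes 1 and 3 mm^3, pressures 1000/2000 Pa
  r1 <- sqrt(1 / pi); r2 <- sqrt(3 / pi)     # volumes pi r^2 l with l = 1
  nodes <- data.frame(id = 0:3,
                      x = c(-0.5, 0.5, -0.5, 0.5),
                      y = c(-0.1, -0.1, 0.1, 0.1), z = 0,
                      radius = rep(c(r1, r2), each = 2))
  edges2 <- data.frame(id = 0:2, node_a = c(0L, 2L, 1L),
                       node_b = c(1L, 3L, 2L))
  net <- vascular_network(nodes, edges2, root_id = 0L, validate = FALSE)
  net$vessels$radius <- c(r1, r2, 1e-6)
  net$vessels$volume <- pi * net$vessels$radius^2 * net$vessels$length
  net$vessels$compartment <- c(1L, 1L, 2L)
  flow <- structure(list(
    pressure = stats::setNames(c(1000, 1000, 1500, 2500), 0:3),
    flux = stats::setNames(numeric(3), 0:2), mu = 0.0035,
    mass_residual = 0), class = "network_flow")
  ## vessel pressures: v0 = 1000, v1 = (1500+2500)/2 = 2000
  pb <- averaged_pressure(c(0, 0, 0), 5, 1, net, flow)
  expect_equal(pb, (1 * 1000 + 3 * 2000) / 4, tolerance = 1e-6)

  ## constant pressure field averages to itself
  flow$pressure[] <- 1234
  expect_equal(averaged_pressure(c(0, 0, 0), 5, 1, net, flow), 1234)

  ## empty RVE is flagged as missing
  expect_true(is.na(averaged_pressure(c(0, 0, 0), 5, 3, net, flow)))
})

test_that("averaged pressure is invariant under splitting a vessel in two", {
  net <- assign_fluxes(random_tree(30, seed = 10))
  term <- terminal_nodes(net)
  bc <- c(stats::setNames(13300, net$root_id),
          stats::setNames(rep(8000, length(term)), term))
  net$vessels$compartment <- 1L
  fl <- solve_network_flow(net, bc)
  x <- c(0, 0, 0); R <- 1.5
  p1 <- averaged_pressure(x, R, 1, net, fl)

  ## split vessel 1 at its midpoint into two collinear halves
  v <- net$vessels[1, ]
  mid_id <- max(net$nodes$id) + 1L
  ra <- match(v$node_a, net$nodes$id); rb <- match(v$node_b, net$nodes$id)
  mid <- (net$nodes[ra, c("x", "y", "z")] + net$nodes[rb, c("x", "y", "z")]) / 2
  nodes2 <- rbind(net$nodes,
                  data.frame(id = mid_id, mid, radius = v$radius))
  edges2 <- rbind(net$vessels[-1, c("id", "node_a", "node_b", "radius")],
                  data.frame(id = max(net$vessels$id) + 1:2,
                             node_a = c(v$node_a, mid_id),
                             node_b = c(mid_id, v$node_b),
                             radius = v$radius))
  net2 <- vascular_network(nodes2, edges2, root_id = net$root_id)
  net2$vessels$compartment <- 1L
  fl2 <- solve_network_flow(net2, bc)
  p2 <- averaged_pressure(x, R, 1, net2, fl2)
  expect_equal(p2, p1, tolerance = 1e-6)
})

test_that("porosity matches the hand example and is additive", {
  ## one vessel r = 0.01 mm, l = 0.5 mm inside a fully interior ball R = 0.5
  nodes <- data.frame(id = 0:1, x = c(-0.25, 0.25), y = 0, z = 0,
                      radius = 0.01)
  edges <- data.frame(id = 0L, node_a = 0L, node_b = 1L)
  dom <- cbind(c(-2, 2), c(-2, 2), c(-2, 2))
  net <- vascular_network(nodes, edges, root_id = 0L, domain = dom)
  net$vessels$compartment <- 1L
  phi <- porosity(c(0, 0, 0), 0.5, 1, net, domain = dom)
  expect_equal(phi, (pi * 1e-4 * 0.5) / (4 / 3 * pi * 0.125),
               tolerance = 1e-12)
  expect_equal(phi, 3.0e-4, tolerance = 1e-12)
  expect_equal(porosity(c(1.5, 1.5, 1.5), 0.2, 1, net, domain = dom), 0)

  ## additivity over compartments equals the all-vessel porosity, exactly
  net3 <- generate_volume_filling_tree(6, seed = 2)
  h <- compute_zeta(net3)
  net3 <- set_compartments(net3, partition_by_zeta(net3, h, c(1, 0.2, 0.02, 0)))
  fl <- solve_network_flow(net3, tree_boundary_conditions(net3))
  mesh <- build_grid(n = 4)
  rf <- rve_fields(net3, fl, mesh$points, 0.5)
  phi_all <- vapply(seq_len(nrow(mesh$points)), function(i)
    porosity(mesh$points[i, ], 0.5, NULL, net3,
             domain = attr(net3, "domain"), vol_rve = rf$vol_rve[i]),
    numeric(1))
  expect_equal(rf$phi_total, phi_all, tolerance = 1e-12)
  expect_equal(rowSums(rf$phi), rf$phi_total)
  expect_true(all(rf$phi_total < 1))
})

test_that("clipped RVE volumes match symmetry closed forms", {
  dom <- cbind(c(-1, 1), c(-1, 1), c(-1, 1))
  R <- 0.3
  full <- 4 / 3 * pi * R^3
  expect_equal(rve_volume_in_domain(c(0, 0, 0), R, dom), full)
  se <- full * sqrt(0.5 * 0.5 / 1e5)
  half <- rve_volume_in_domain(c(-1, 0, 0), R, dom)
  expect_lt(abs(half - full / 2), 3 * se)
  eighth <- rve_volume_in_domain(c(-1, -1, -1), R, dom)
  expect_lt(abs(eighth - full / 8), 3 * se)
})

test_that("inter-compartment flux reduces to conductance times pressure drop", {
  ## 3-vessel chain: compartments 1,1,2; the single connector is vessel 1
  ## (compartment 1 sharing node 2 with the compartment-2 vessel)
  nodes <- data.frame(id = 0:3, x = 0:3 / 10, y = 0, z = 0, radius = 0.002)
  edges <- data.frame(id = 0:2, node_a = 0:2, node_b = 1:3)
  net <- vascular_network(nodes, edges, root_id = 0L,
                          domain = cbind(c(-1, 1), c(-1, 1), c(-1, 1)))
  net$vessels$compartment <- c(1L, 1L, 2L)
  fl <- solve_network_flow(net, c("0" = 2000, "3" = 1000))
  x <- c(0.15, 0, 0)
  Q <- intercompartment_flux(x, 1, 2, 1, net, fl)
  conn <- connector_vessels(net, 2, 1)
  expect_equal(conn, 2L)
  C <- poiseuille_conductance(net$vessels$radius[2], net$vessels$length[2])
  dp <- fl$pressure[["1"]] - fl$pressure[["2"]]
  expect_equal(Q, C * dp, tolerance = 1e-12)

  ## no connectors in the RVE: zero
  expect_equal(intercompartment_flux(c(50, 50, 50), 0.01, 2, 1, net, fl), 0)
})

test_that("beta fields obey the defining cases and symmetry", {
  net <- generate_volume_filling_tree(7, seed = 3)
  h <- compute_zeta(net)
  Z <- optimise_partition(net, h, proportion_targets(net, h))
  net <- set_compartments(net, partition_by_zeta(net, h, Z))
  fl <- solve_network_flow(net, tree_boundary_conditions(net))
  mesh <- build_grid(n = 4)
  rf <- rve_fields(net, fl, mesh$points, 0.5,
                   pairs = list(c(2, 1), c(3, 2), c(3, 1)))
  for (nm in names(rf$beta)) {
    b <- rf$beta[[nm]]
    expect_true(all(b[!is.na(b)] >= 0))
  }
  ## the generator never connects compartments 1 and 3 directly
  expect_equal(length(connector_vessels(net, 3, 1)), 0L)
  expect_true(all(rf$beta[["3,1"]][!is.na(rf$beta[["3,1"]])] == 0))
  ## beta equals |Q| / |dpbar| wherever both averaged pressures exist
  ok <- !is.na(rf$pbar[, "1"]) & !is.na(rf$pbar[, "2"])
  dp <- rf$pbar[ok, "2"] - rf$pbar[ok, "1"]
  expect_equal(rf$beta[["2,1"]][ok],
               ifelse(dp == 0, 0, abs(rf$Q[["2,1"]][ok]) / abs(dp)))

  ## the grid-level wrapper agrees with the field set plus nearest fill
  mesh2 <- build_grid(n = 3)
  rfg <- rve_fields(net, fl, mesh2$points, 0.5, pairs = list(c(2, 1)))
  expect_equal(suppressWarnings(beta_field(mesh2, 0.5, 2, 1, net, fl)),
               suppressWarnings(fill_nearest(rfg$beta[["2,1"]],
                                             mesh2$points)))

  ## equal averaged pressures force beta to zero
  fl0 <- fl
  fl0$pressure[] <- 9000
  fl0$flux[] <- 0
  rf0 <- rve_fields(net, fl0, mesh$points, 0.5, pairs = list(c(2, 1)))
  b0 <- rf0$beta[["2,1"]]
  expect_true(all(b0[!is.na(b0)] == 0))
})
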