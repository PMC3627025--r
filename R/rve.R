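## Spherical representative-volume-element (RVE) averaging. Discrete vessel
## quantities (pressure, lumen volume, inter-compartment flux) are averaged
## over a ball of fixed radius centred at each query point, clipped to the
## tissue box. Vessels partially inside the ball contribute in proportion to
## the fraction of their centreline length inside it.

#' Spatial index over vessel segments
#'
#' Precomputes segment endpoints, midpoints and half-lengths so that
#' ball queries can prune candidates by the midpoint distance bound
#' `|mid - x| <= R + l/2` before exact segment-sphere intersection.
#'
#' @param net a `vascular_network`.
#' @return object of class `vessel_index`.
#' @export
build_spatial_index <- function(net) {
  ia <- match(net$vessels$node_a, net$nodes$id)
  ib <- match(net$vessels$node_b, net$nodes$id)
  A <- cbind(net$nodes$x[ia], net$nodes$y[ia], net$nodes$z[ia])
  B <- cbind(net$nodes$x[ib], net$nodes$y[ib], net$nodes$z[ib])
  structure(list(A = A, B = B, mid = (A + B) / 2,
                 len = net$vessels$length, half = net$vessels$length / 2,
                 compartment = net$vessels$compartment,
                 vessel_id = net$vessels$id),
            class = "vessel_index")
}

## fraction of each segment's centreline length inside ball(x, R);
## vectorised over segment rows
segment_ball_fraction <- function(A, B, len, x, R) {
  Ax <- sweep(A, 2, x)
  D <- B - A
  a <- len^2
  b <- 2 * rowSums(Ax * D)
  c0 <- rowSums(Ax^2) - R^2
  disc <- b^2 - 4 * a * c0
  frac <- numeric(nrow(A))
  pos <- disc > 0
  if (any(pos)) {
    sq <- sqrt(disc[pos])
    t1 <- (-b[pos] - sq) / (2 * a[pos])
    t2 <- (-b[pos] + sq) / (2 * a[pos])
    frac[pos] <- pmax(0, pmin(t2, 1) - pmax(t1, 0))
  }
  frac
}

#' Vessels intersecting an RVE
#'
#' Returns the vessels of a compartment that intersect the ball of radius
#' `radius` centred at `x`, with the fraction of each vessel's centreline
#' length inside the ball (exact segment-sphere intersection).
#'
#' @param x centre, length-3 numeric (mm).
#' @param radius RVE radius, mm.
#' @param net a `vascular_network`.
#' @param compartment integer compartment label, or `NULL` for all vessels.
#' @param index optional prebuilt [build_spatial_index()] result.
#' @return data.frame with columns `vessel` (id), `row` (vessel table row)
#'   and `fraction` in (0, 1].
#' @export
vessels_in_rve <- function(x, radius, net, compartment = NULL, index = NULL) {
  if (is.null(index)) index <- build_spatial_index(net)
  cand <- which(sqrt(colSums((t(index$mid) - x)^2)) <= radius + index$half)
  if (!is.null(compartment))
    cand <- cand[index$compartment[cand] %in% compartment]
  if (!length(cand))
    return(data.frame(vessel = integer(0), row = integer(0),
                      fraction = numeric(0)))
  frac <- segment_ball_fraction(index$A[cand, , drop = FALSE],
                                index$B[cand, , drop = FALSE],
                                index$len[cand], x, radius)
  keep <- frac > 0
  data.frame(vessel = index$vessel_id[cand[keep]], row = cand[keep],
             fraction = frac[keep])
}

## Sparse points x vessels matrix of inside-length fractions, built in
## chunks. Rows: query points; columns: vessel table rows.
rve_fraction_matrix <- function(net, points, radius, index = NULL,
                                chunk = 256L) {
  if (is.null(index)) index <- build_spatial_index(net)
  m <- nrow(points); V <- nrow(index$A)
  ti <- tj <- tx <- vector("list", ceiling(m / chunk))
  midT <- t(index$mid)
  bound <- radius + index$half
  for (ci in seq_len(ceiling(m / chunk))) {
    rows <- ((ci - 1L) * chunk + 1L):min(ci * chunk, m)
    P <- points[rows, , drop = FALSE]
    D2 <- outer(rowSums(P^2), rep(1, V)) + outer(rep(1, length(rows)),
                                                 colSums(midT^2)) -
      2 * P %*% midT
    hit <- which(D2 <= outer(rep(1, length(rows)), bound^2), arr.ind = TRUE)
    if (nrow(hit)) {
      pr <- hit[, 1]; vr <- hit[, 2]
      ## exact fractions for the candidate pairs
      xs <- P[pr, , drop = FALSE]
      A <- index$A[vr, , drop = FALSE]; B <- index$B[vr, , drop = FALSE]
      Ax <- A - xs; D <- B - A
      a <- index$len[vr]^2
      b <- 2 * rowSums(Ax * D)
      c0 <- rowSums(Ax^2) - radius^2
      disc <- b^2 - 4 * a * c0
      frac <- numeric(length(a))
      pos <- disc > 0
      sq <- sqrt(pmax(disc, 0))
      t1 <- (-b - sq) / (2 * a); t2 <- (-b + sq) / (2 * a)
      frac[pos] <- pmax(0, pmin(t2[pos], 1) - pmax(t1[pos], 0))
      keep <- frac > 0
      ti[[ci]] <- rows[pr[keep]]; tj[[ci]] <- vr[keep]; tx[[ci]] <- frac[keep]
    }
  }
  Matrix::sparseMatrix(i = unlist(ti), j = unlist(tj), x = unlist(tx),
                       dims = c(m, V))
}

#' Volume of an RVE clipped to the domain
#'
#' Volume of `ball(x, R)` intersected with the tissue box. Balls entirely
#' inside the box use the closed form `4/3 pi R^3`; clipped balls are
#' integrated by seeded Monte Carlo sampling within the ball. Results are
#' cached per clipping geometry (the per-axis distances to the nearest
#' face, capped at R), which makes regular-grid evaluation cheap.
#'
#' @param x centre (length-3) or an n x 3 matrix of centres, mm.
#' @param radius RVE radius, mm (must not exceed the half-width of the box).
#' @param domain 2 x 3 bounds matrix, mm.
#' @param n_samples Monte Carlo samples per distinct clipping geometry.
#' @param seed RNG seed for the Monte Carlo draws.
#' @return volume(s), mm^3.
#' @export
rve_volume_in_domain <- function(x, radius, domain, n_samples = 1e5,
                                 seed = 77L) {
  domain <- check_domain(domain)
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (any(2 * radius > (domain[2, ] - domain[1, ])))
    stop("RVE diameter exceeds the domain width")
  dlo <- sweep(x, 2, domain[1, ])
  dhi <- sweep(-x, 2, -domain[2, ])
  d <- pmin(pmin(dlo, dhi), radius)   # per-axis distance to nearest face
  full <- 4 / 3 * pi * radius^3
  out <- rep(full, nrow(x))
  clipped <- which(apply(d < radius, 1, any))
  if (length(clipped)) {
    key <- apply(d[clipped, , drop = FALSE], 1, function(v)
      paste(signif(sort(v), 10), collapse = "|"))
    uk <- unique(key)
    ball <- with_seed(seed, {
      u <- matrix(stats::rnorm(3 * n_samples), ncol = 3)
      u <- u / sqrt(rowSums(u^2))
      u * radius * stats::runif(n_samples)^(1 / 3)
    })
    vol_uk <- vapply(uk, function(k) {
      v <- as.numeric(strsplit(k, "|", fixed = TRUE)[[1]])
      inside <- ball[, 1] > -v[1] & ball[, 2] > -v[2] & ball[, 3] > -v[3]
      mean(inside) * full
    }, numeric(1))
    out[clipped] <- vol_uk[match(key, uk)]
  }
  if (nrow(x) == 1L) out[[1]] else out
}

#' RVE-averaged pressure
#'
#' Volume-weighted mean of the per-vessel average nodal pressures over the
#' compartment's vessels inside the RVE; each vessel's weight is its lumen
#' volume times its inside-length fraction. Returns `NA` when no vessel of
#' the compartment intersects the RVE (the caller should enlarge the
#' radius or fill from neighbours).
#'
#' @param x centre, mm.
#' @param radius RVE radius, mm.
#' @param compartment integer label.
#' @param net a `vascular_network`.
#' @param flow a `network_flow` from [solve_network_flow()].
#' @param index optional prebuilt spatial index.
#' @return pressure in Pa, or `NA`.
#' @export
averaged_pressure <- function(x, radius, compartment, net, flow,
                              index = NULL) {
  hits <- vessels_in_rve(x, radius, net, compartment, index)
  if (!nrow(hits)) return(NA_real_)
  Pv <- vessel_pressures(net, flow)[hits$row]
  w <- net$vessels$volume[hits$row] * hits$fraction
  sum(w * Pv) / sum(w)
}

## per-vessel average of the two endpoint nodal pressures
vessel_pressures <- function(net, flow) {
  pa <- flow$pressure[as.character(net$vessels$node_a)]
  pb <- flow$pressure[as.character(net$vessels$node_b)]
  unname((pa + pb) / 2)
}

#' RVE porosity
#'
#' Fraction of the (clipped) RVE volume occupied by the compartment's
#' vessel lumen. Zero for an empty RVE.
#'
#' @inheritParams averaged_pressure
#' @param domain 2 x 3 bounds matrix, mm.
#' @param vol_rve optional precomputed clipped RVE volume.
#' @return dimensionless porosity.
#' @export
porosity <- function(x, radius, compartment, net, domain = NULL,
                     index = NULL, vol_rve = NULL) {
  if (is.null(domain)) domain <- attr(net, "domain")
  if (is.null(vol_rve)) vol_rve <- rve_volume_in_domain(x, radius, domain)
  hits <- vessels_in_rve(x, radius, net, compartment, index)
  if (!nrow(hits)) return(0)
  sum(net$vessels$volume[hits$row] * hits$fraction) / vol_rve
}

#' Connector vessels between two compartments
#'
#' The set `c[i,k]` (with `i > k`): vessels of compartment `k` that share a
#' node with a compartment-`i` vessel. The inter-compartment flux is
#' carried by these vessels.
#'
#' @param net a `vascular_network` with compartments assigned.
#' @param i,k compartment labels with `i > k`.
#' @return vessel table row indices.
#' @export
connector_vessels <- function(net, i, k) {
  if (i <= k) stop("require i > k")
  vi <- net$vessels$compartment == i
  vk <- net$vessels$compartment == k
  nodes_i <- unique(c(net$vessels$node_a[vi], net$vessels$node_b[vi]))
  which(vk & (net$vessels$node_a %in% nodes_i |
                net$vessels$node_b %in% nodes_i))
}

#' Inter-compartment flux within an RVE
#'
#' Sum of the Poiseuille fluxes `C * dp` over the connector vessels inside
#' the RVE, each weighted by its inside-length fraction. `dp` is the signed
#' proximal-minus-distal pressure difference, so this equals the summed
#' vessel fluxes of the connectors.
#'
#' @inheritParams averaged_pressure
#' @param i,k compartment labels, `i > k`.
#' @return flux in mm^3/s (signed).
#' @export
intercompartment_flux <- function(x, radius, i, k, net, flow, index = NULL) {
  conn <- connector_vessels(net, i, k)
  if (!length(conn)) return(0)
  hits <- vessels_in_rve(x, radius, net, compartment = NULL, index = index)
  hits <- hits[hits$row %in% conn, , drop = FALSE]
  if (!nrow(hits)) return(0)
  q <- flow$flux[as.character(net$vessels$id[hits$row])]
  sum(hits$fraction * q)
}

#' All averaged discrete fields on a set of points
#'
#' Workhorse used by the fitting pipeline: computes, for every query point,
#' the clipped RVE volume, per-compartment averaged pressure and porosity,
#' total porosity, inter-compartment fluxes and the pressure-coupling
#' coefficients `beta = |Q| / |dpbar|` for the requested compartment pairs.
#' Points whose RVE contains no vessel of a compartment get `NA` pressure;
#' [fill_nearest()] completes such fields from the nearest valid point.
#'
#' @param net a `vascular_network` with compartments assigned.
#' @param flow a `network_flow`.
#' @param points n x 3 matrix of query points, mm.
#' @param radius RVE radius, mm.
#' @param domain 2 x 3 bounds matrix, mm (defaults to the network's domain).
#' @param compartments integer labels to average (default: all present).
#' @param pairs list of `c(i, k)` pairs (`i > k`) for flux/beta fields;
#'   default: all neighbouring pairs.
#' @param mc_samples,mc_seed Monte Carlo controls for clipped RVE volumes.
#' @return object of class `rve_fields`: list with `pbar` (matrix points x
#'   compartments), `phi` (matrix, plus `phi_total`), `Q` and `beta` (named
#'   lists per pair, symmetric in (i,k)), `vol_rve`, `W` (sparse
#'   fraction matrix) and bookkeeping.
#' @export
rve_fields <- function(net, flow, points, radius, domain = NULL,
                       compartments = NULL, pairs = NULL,
                       mc_samples = 1e5, mc_seed = 77L) {
  if (is.null(domain)) domain <- attr(net, "domain")
  if (is.null(domain)) stop("supply a domain")
  cpt <- net$vessels$compartment
  if (anyNA(cpt)) stop("assign compartments first")
  if (is.null(compartments)) compartments <- sort(unique(cpt))
  if (is.null(pairs) && length(compartments) > 1L)
    pairs <- lapply(seq_len(length(compartments) - 1L),
                    function(j) c(compartments[j + 1L], compartments[j]))
  index <- build_spatial_index(net)
  W <- rve_fraction_matrix(net, points, radius, index)
  vol_rve <- rve_volume_in_domain(points, radius, domain,
                                  n_samples = mc_samples, seed = mc_seed)
  Pv <- vessel_pressures(net, flow)
  vol_v <- net$vessels$volume
  m <- nrow(points)

  pbar <- matrix(NA_real_, m, length(compartments),
                 dimnames = list(NULL, compartments))
  phi <- matrix(0, m, length(compartments),
                dimnames = list(NULL, compartments))
  for (j in seq_along(compartments)) {
    cols <- which(cpt == compartments[j])
    Wi <- W[, cols, drop = FALSE]
    wv <- as.numeric(Wi %*% vol_v[cols])
    num <- as.numeric(Wi %*% (vol_v[cols] * Pv[cols]))
    pbar[, j] <- ifelse(wv > 0, num / wv, NA_real_)
    phi[, j] <- wv / vol_rve
  }
  Q <- list(); beta <- list()
  qv <- unname(flow$flux[as.character(net$vessels$id)])
  for (pr in pairs) {
    i <- pr[1]; k <- pr[2]
    nm <- paste(i, k, sep = ",")
    conn <- connector_vessels(net, i, k)
    Qik <- if (length(conn))
      as.numeric(W[, conn, drop = FALSE] %*% qv[conn]) else numeric(m)
    ji <- match(as.character(i), colnames(pbar))
    jk <- match(as.character(k), colnames(pbar))
    dp <- pbar[, ji] - pbar[, jk]
    b <- ifelse(is.na(dp), NA_real_, ifelse(dp == 0, 0, abs(Qik) / abs(dp)))
    Q[[nm]] <- Qik
    beta[[nm]] <- b
  }
  structure(list(points = points, radius = radius, domain = domain,
                 compartments = compartments, pairs = pairs,
                 pbar = pbar, phi = phi, phi_total = rowSums(phi),
                 Q = Q, beta = beta, vol_rve = vol_rve, W = W),
            class = "rve_fields")
}

#' Fill missing field values from the nearest valid point
#'
#' @param values numeric vector with `NA` gaps.
#' @param points n x 3 coordinates of the values.
#' @param quiet suppress the fill warning.
#' @return completed vector.
#' @export
fill_nearest <- function(values, points, quiet = FALSE) {
  miss <- which(is.na(values))
  if (!length(miss)) return(values)
  ok <- which(!is.na(values))
  if (!length(ok)) stop("no valid values to fill from: RVE radius too small")
  if (!quiet)
    warning(length(miss), " point(s) had an empty RVE; filled from nearest ",
            "valid neighbour", call. = FALSE)
  Pok <- points[ok, , drop = FALSE]
  for (ix in miss) {
    d2 <- colSums((t(Pok) - points[ix, ])^2)
    values[ix] <- values[ok[which.min(d2)]]
  }
  values
}

#' Beta coupling field on a grid
#'
#' Pointwise `beta[i,k] = |Q[i,k]| / |pbar_i - pbar_k|` (0 where the
#' averaged pressures coincide), symmetric in (i, k). Missing values
#' (empty RVEs) are filled from the nearest valid grid point.
#'
#' @param grid a `grid_mesh` (see [build_grid()]).
#' @param radius RVE radius, mm.
#' @param i,k compartment labels with `i > k`.
#' @param net a `vascular_network`.
#' @param flow a `network_flow`.
#' @param ... passed to [rve_fields()].
#' @return numeric vector of beta values (mm^3 Pa^-1 s^-1) at grid nodes.
#' @export
beta_field <- function(grid, radius, i, k, net, flow, ...) {
  rf <- rve_fields(net, flow, grid$points, radius,
                   compartments = c(k, i), pairs = list(c(i, k)), ...)
  b <- rf$beta[[paste(i, k, sep = ",")]]
  fill_nearest(b, grid$points)
}
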