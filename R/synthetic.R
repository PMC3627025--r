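## Seeded synthetic network generators: a bifurcating volume-filling tree on a
## box domain and near-parallel capillary lattices used as anisotropic test
## networks. All randomness is drawn under a locally restored RNG state so the
## generators are pure functions of their seed.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

default_domain <- function() {
  matrix(c(-1, 1, -1, 1, -1, 1), nrow = 2,
         dimnames = list(c("lower", "upper"), c("x", "y", "z")))
}

check_domain <- function(domain) {
  domain <- as.matrix(domain)
  if (!all(dim(domain) == c(2, 3)) || any(domain[2, ] <= domain[1, ]))
    stop("domain must be a 2 x 3 matrix with lower < upper bounds")
  domain
}

#' Generate a volume-filling bifurcating tree
#'
#' Builds a rooted binary tree whose terminal segments are spread through a
#' box domain by recursive alternating-axis bisection: each subdomain
#' receives one branch point at its centroid, perturbed by a seeded uniform
#' jitter, and is then split in half along the next coordinate axis. The
#' root node sits at the centre of the lower-x face. Terminal vessels are
#' assigned unit flux (mm^3/s), parent fluxes are the sums of their
#' daughters, and radii follow the flux-radius relation
#' `r = (q / alpha1)^(1 / alpha2) * alpha3`.
#'
#' @param levels bifurcation depth (>= 1); the tree has `2^levels` terminal
#'   nodes and `2^(levels+1) - 1` vessels.
#' @param domain 2 x 3 bounds matrix in mm (default `[-1, 1]^3`).
#' @param seed integer RNG seed; the generator is deterministic given the
#'   seed.
#' @param alpha numeric length-3 `(alpha1, alpha2, alpha3)`, defaults
#'   `c(1, 3, 0.001)`.
#' @param jitter branch-point perturbation as a fraction of the subdomain
#'   half-width, in `[0, 1)`.
#' @return a rooted `vascular_network` with fluxes, radii and volumes set.
#' @export
generate_volume_filling_tree <- function(levels, domain = default_domain(),
                                         seed = 1L, alpha = c(1, 3, 0.001),
                                         jitter = 0.3) {
  domain <- check_domain(domain)
  levels <- as.integer(levels)
  if (levels < 1L) stop("levels must be >= 1")
  if (alpha[2] == 0) stop("alpha2 must be non-zero")
  if (alpha[3] <= 0) stop("alpha3 must be positive")
  widths <- (domain[2, ] - domain[1, ]) / 2^ceiling(levels / 3)
  if (any(widths < 1e-12))
    stop("levels too large: subdomain size underflows")

  n_nodes <- 2^(levels + 1L)
  pos <- matrix(NA_real_, n_nodes, 3)
  parent <- rep(NA_integer_, n_nodes)
  root_pos <- c(domain[1, 1], mean(domain[, 2]), mean(domain[, 3]))
  pos[1, ] <- root_pos
  next_id <- 2L

  with_seed(seed, {
    ## depth-first so the RNG draw order is independent of vector growth
    recurse <- function(parent_idx, lo, hi, depth, axis) {
      centre <- (lo + hi) / 2
      half <- (hi - lo) / 2
      pt <- centre + stats::runif(3, -1, 1) * jitter * half
      idx <- next_id; next_id <<- next_id + 1L
      pos[idx, ] <<- pt
      parent[idx] <<- parent_idx
      if (depth < levels) {
        ax <- axis
        mid <- (lo[ax] + hi[ax]) / 2
        lo2 <- lo; lo2[ax] <- mid
        hi1 <- hi; hi1[ax] <- mid
        nxt <- ax %% 3L + 1L
        recurse(idx, lo, hi1, depth + 1L, nxt)
        recurse(idx, lo2, hi, depth + 1L, nxt)
      }
    }
    recurse(1L, domain[1, ], domain[2, ], 0L, 1L)
  })

  child_idx <- 2:n_nodes
  vessels <- data.frame(id = seq_along(child_idx) - 1L,
                        node_a = parent[child_idx] - 1L,
                        node_b = child_idx - 1L)
  nodes <- data.frame(id = seq_len(n_nodes) - 1L,
                      x = pos[, 1], y = pos[, 2], z = pos[, 3],
                      radius = 1)   # placeholder until radii assigned
  net <- vascular_network(nodes, vessels, root_id = 0L, domain = domain,
                          validate = FALSE)
  net <- assign_fluxes(net)
  net <- assign_radii(net, alpha = alpha)
  validate_network(net)
  net
}

#' Assign mass-conserving fluxes on a rooted tree
#'
#' Every terminal vessel carries a flow rate of 1 mm^3/s and each parent
#' carries the sum of its daughters, so a vessel's flux equals the number of
#' terminal nodes in its distal subtree.
#'
#' @param net a rooted tree `vascular_network`.
#' @return the network with the `flux` column filled (and vessels oriented
#'   proximal to distal).
#' @export
assign_fluxes <- function(net) {
  net <- orient_from_root(net)
  ord <- attr(net, "bfs_order")
  pe <- attr(net, "parent_edge")
  ia <- match(net$vessels$node_a, net$nodes$id)
  deg <- node_degree(net)
  leaves <- integer(nrow(net$nodes))
  root_row <- match(net$root_id, net$nodes$id)
  leaves[deg == 1L] <- 1L
  leaves[root_row] <- 0L
  flux <- numeric(nrow(net$vessels))
  for (v in rev(ord)) {
    e <- pe[v]
    if (is.na(e)) next
    flux[e] <- leaves[v]
    p <- ia[e]
    leaves[p] <- leaves[p] + leaves[v]
  }
  net$vessels$flux <- flux
  attr(net, "bfs_order") <- NULL
  attr(net, "parent_edge") <- NULL
  net
}

#' Radii from fluxes
#'
#' Implements the flux-radius relation `r = (q / alpha1)^(1 / alpha2) *
#' alpha3`. Applied to a network it also sets nodal radii: each node
#' inherits the radius of its proximal (parent) vessel, the root node that
#' of the root vessel.
#'
#' @param q vessel fluxes (mm^3/s, > 0) or a rooted `vascular_network` with
#'   fluxes assigned.
#' @param alpha numeric `(alpha1, alpha2, alpha3)`.
#' @return radii in mm, or the updated network.
#' @export
assign_radii <- function(q, alpha = c(1, 3, 0.001)) {
  if (inherits(q, "vascular_network")) {
    net <- q
    if (anyNA(net$vessels$flux)) stop("assign fluxes first")
    r <- assign_radii(net$vessels$flux, alpha)
    net$vessels$radius <- r
    net$vessels$volume <- pi * r^2 * net$vessels$length
    ib <- match(net$vessels$node_b, net$nodes$id)
    net$nodes$radius[ib] <- r
    root_row <- match(net$root_id, net$nodes$id)
    root_vessel <- which(net$vessels$node_a == net$root_id)[1]
    net$nodes$radius[root_row] <- r[root_vessel]
    return(net)
  }
  if (any(q <= 0)) stop("fluxes must be positive")
  (q / alpha[1])^(1 / alpha[2]) * alpha[3]
}

#' Generate an aligned capillary lattice
#'
#' Emulates the directional preference of imaged capillary beds: `n_fibres`
#' near-parallel chains run along one coordinate axis, with sparse
#' cross-links between neighbouring chains. Chain endpoints lie exactly on
#' the two domain faces normal to the fibre direction, so those faces expose
#' the terminal nodes used for pressure boundary conditions. The generator
#' always returns a connected network: if the sampled cross-links leave
#' components disconnected, deterministic extra links are added. Radii are
#' drawn from a truncated normal (defaults emulate a capillary bed with
#' radii 5.3 +/- 2.3 um).
#'
#' @param domain 2 x 3 bounds matrix, mm.
#' @param direction unit vector along a coordinate axis (only axis-aligned
#'   directions are supported).
#' @param n_fibres number of chains (laid out on a near-square transverse
#'   grid).
#' @param cross_link_fraction probability of a transverse link at each
#'   interior station between neighbouring chains.
#' @param radius_mean,radius_sd radius distribution, mm.
#' @param seed integer RNG seed.
#' @param n_segments segments per chain.
#' @param jitter transverse node perturbation as a fraction of fibre
#'   spacing.
#' @return a `vascular_network` (general graph, unrooted; all vessels
#'   labelled compartment 1).
#' @export
generate_aligned_lattice <- function(domain = cbind(c(0, 0.67), c(0, 0.67),
                                                    c(0, 0.67)),
                                     direction = c(1, 0, 0), n_fibres = 49L,
                                     cross_link_fraction = 0.12,
                                     radius_mean = 0.0053,
                                     radius_sd = 0.0023, seed = 1L,
                                     n_segments = 8L, jitter = 0.15) {
  domain <- check_domain(domain)
  axis <- which(abs(abs(direction) - 1) < 1e-9)
  if (length(axis) != 1L || sum(abs(direction)) > 1 + 1e-9)
    stop("direction must be an axis-aligned unit vector")
  n_fibres <- as.integer(n_fibres)
  n_segments <- as.integer(n_segments)
  if (n_fibres < 1L) stop("n_fibres must be >= 1")
  tax <- setdiff(1:3, axis)

  n1 <- ceiling(sqrt(n_fibres))
  n2 <- ceiling(n_fibres / n1)
  g1 <- seq(domain[1, tax[1]], domain[2, tax[1]], length.out = n1 + 2L)[-c(1, n1 + 2L)]
  g2 <- seq(domain[1, tax[2]], domain[2, tax[2]], length.out = n2 + 2L)[-c(1, n2 + 2L)]
  fibre_pos <- expand.grid(u = g1, v = g2)[seq_len(n_fibres), , drop = FALSE]
  fibre_cell <- expand.grid(iu = seq_len(n1), iv = seq_len(n2))[seq_len(n_fibres), ]
  sp1 <- if (n1 > 1) diff(g1[1:2]) else (domain[2, tax[1]] - domain[1, tax[1]]) / 2
  sp2 <- if (n2 > 1) diff(g2[1:2]) else (domain[2, tax[2]] - domain[1, tax[2]]) / 2
  ax_seq <- seq(domain[1, axis], domain[2, axis], length.out = n_segments + 1L)

  with_seed(seed, {
    npf <- n_segments + 1L
    n_nodes <- n_fibres * npf
    pos <- matrix(NA_real_, n_nodes, 3)
    for (f in seq_len(n_fibres)) {
      rows <- (f - 1L) * npf + seq_len(npf)
      ju <- stats::runif(npf, -1, 1) * jitter * sp1
      jv <- stats::runif(npf, -1, 1) * jitter * sp2
      ju[c(1, npf)] <- ju[c(1, npf)] / 4   # keep endpoints near the face axis
      jv[c(1, npf)] <- jv[c(1, npf)] / 4
      pos[rows, axis] <- ax_seq
      pos[rows, tax[1]] <- fibre_pos$u[f] + ju
      pos[rows, tax[2]] <- fibre_pos$v[f] + jv
    }
    ea <- integer(0); eb <- integer(0)
    for (f in seq_len(n_fibres)) {
      rows <- (f - 1L) * npf + seq_len(npf)
      ea <- c(ea, rows[-npf]); eb <- c(eb, rows[-1L])
    }
    ## neighbouring fibre pairs on the transverse grid
    pair_a <- integer(0); pair_b <- integer(0)
    for (f in seq_len(n_fibres)) {
      for (g in seq_len(n_fibres)) {
        if (g <= f) next
        du <- abs(fibre_cell$iu[f] - fibre_cell$iu[g])
        dv <- abs(fibre_cell$iv[f] - fibre_cell$iv[g])
        if (du + dv == 1L) { pair_a <- c(pair_a, f); pair_b <- c(pair_b, g) }
      }
    }
    for (p in seq_along(pair_a)) {
      for (s in 2:n_segments) {
        if (stats::runif(1) < cross_link_fraction) {
          ea <- c(ea, (pair_a[p] - 1L) * npf + s)
          eb <- c(eb, (pair_b[p] - 1L) * npf + s)
        }
      }
    }
    ## enforce connectivity with deterministic re-links
    comp <- lattice_components(n_nodes, ea, eb)
    for (p in seq_along(pair_a)) {
      a <- (pair_a[p] - 1L) * npf + 2L
      b <- (pair_b[p] - 1L) * npf + 2L
      if (comp[a] != comp[b]) {
        ea <- c(ea, a); eb <- c(eb, b)
        comp[comp == comp[b]] <- comp[a]
      }
    }
    nodes <- data.frame(id = seq_len(n_nodes) - 1L,
                        x = pos[, 1], y = pos[, 2], z = pos[, 3],
                        radius = pmax(stats::rnorm(n_nodes, radius_mean,
                                                   radius_sd),
                                      radius_mean / 5))
    vessels <- data.frame(id = seq_along(ea) - 1L,
                          node_a = ea - 1L, node_b = eb - 1L,
                          compartment = 1L)
    vascular_network(nodes, vessels, root_id = NA_integer_, domain = domain)
  })
}

## connected-component labels via union-find
lattice_components <- function(n, ea, eb) {
  ea <- as.integer(ea); eb <- as.integer(eb)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (e in seq_along(ea)) {
    ra <- find(ea[e]); rb <- find(eb[e])
    if (ra != rb) parent[rb] <- ra
  }
  vapply(seq_len(n), find, integer(1))
}

#' Generate an isotropic lattice (negative control)
#'
#' A full three-dimensional grid lattice with vessels along all three axes:
#' the isotropic counterpart of [generate_aligned_lattice()], used to check
#' that direction-aware permeability methods fall back to the isotropic
#' answer when the network has no preferred direction.
#'
#' @param domain 2 x 3 bounds matrix, mm.
#' @param n_per_axis lattice nodes per axis.
#' @param radius_mean,radius_sd radius distribution, mm.
#' @param seed integer RNG seed.
#' @param jitter node perturbation as a fraction of lattice spacing.
#' @return a `vascular_network`.
#' @export
generate_isotropic_lattice <- function(domain = cbind(c(0, 0.67), c(0, 0.67),
                                                      c(0, 0.67)),
                                       n_per_axis = 8L, radius_mean = 0.0053,
                                       radius_sd = 0.0023, seed = 1L,
                                       jitter = 0.15) {
  domain <- check_domain(domain)
  n <- as.integer(n_per_axis)
  gx <- seq(domain[1, 1], domain[2, 1], length.out = n)
  gy <- seq(domain[1, 2], domain[2, 2], length.out = n)
  gz <- seq(domain[1, 3], domain[2, 3], length.out = n)
  sp <- c(diff(gx[1:2]), diff(gy[1:2]), diff(gz[1:2]))
  idx <- function(i, j, k) (k - 1L) * n * n + (j - 1L) * n + i
  with_seed(seed, {
    grid <- expand.grid(i = seq_len(n), j = seq_len(n), k = seq_len(n))
    pos <- cbind(gx[grid$i], gy[grid$j], gz[grid$k])
    jit <- matrix(stats::runif(length(pos), -1, 1), ncol = 3) * jitter *
      rep(sp, each = nrow(pos))
    on_face <- cbind(grid$i %in% c(1L, n), grid$j %in% c(1L, n),
                     grid$k %in% c(1L, n))
    jit[on_face] <- 0   # keep face nodes on their faces
    pos <- pos + jit
    ea <- integer(0); eb <- integer(0)
    for (k in seq_len(n)) for (j in seq_len(n)) for (i in seq_len(n)) {
      if (i < n) { ea <- c(ea, idx(i, j, k)); eb <- c(eb, idx(i + 1L, j, k)) }
      if (j < n) { ea <- c(ea, idx(i, j, k)); eb <- c(eb, idx(i, j + 1L, k)) }
      if (k < n) { ea <- c(ea, idx(i, j, k)); eb <- c(eb, idx(i, j, k + 1L)) }
    }
    nodes <- data.frame(id = seq_len(nrow(pos)) - 1L,
                        x = pos[, 1], y = pos[, 2], z = pos[, 3],
                        radius = pmax(stats::rnorm(nrow(pos), radius_mean,
                                                   radius_sd),
                                      radius_mean / 5))
    vessels <- data.frame(id = seq_along(ea) - 1L,
                          node_a = ea - 1L, node_b = eb - 1L,
                          compartment = 1L)
    vascular_network(nodes, vessels, root_id = NA_integer_, domain = domain)
  })
}

#' Nodes lying on a domain face
#'
#' @param net a `vascular_network` with a `domain` attribute (or `domain`
#'   supplied).
#' @param axis 1, 2 or 3.
#' @param side `"lower"` or `"upper"`.
#' @param domain optional 2 x 3 bounds matrix.
#' @param tol distance tolerance in mm.
#' @return node ids on the face.
#' @export
face_nodes <- function(net, axis, side = c("lower", "upper"), domain = NULL,
                       tol = 1e-9) {
  side <- match.arg(side)
  if (is.null(domain)) domain <- attr(net, "domain")
  if (is.null(domain)) stop("network has no domain attribute")
  coord <- net$nodes[[c("x", "y", "z")[axis]]]
  target <- if (side == "lower") domain[1, axis] else domain[2, axis]
  net$nodes$id[abs(coord - target) < tol]
}

#' Monte Carlo volume of a region
#'
#' Estimates the volume of `region` (a predicate over points) within a
#' bounding box by uniform sampling.
#'
#' @param region function taking an n x 3 matrix of points and returning a
#'   logical vector (inside / outside).
#' @param box 2 x 3 bounds matrix.
#' @param n_samples number of samples (>= 1).
#' @param seed integer RNG seed.
#' @return list with `volume` (mm^3), `se` (standard error) and `n`.
#' @export
monte_carlo_volume <- function(region, box, n_samples = 1e5, seed = 1L) {
  box <- check_domain(box)
  stopifnot(n_samples >= 1)
  vol_box <- prod(box[2, ] - box[1, ])
  with_seed(seed, {
    pts <- cbind(stats::runif(n_samples, box[1, 1], box[2, 1]),
                 stats::runif(n_samples, box[1, 2], box[2, 2]),
                 stats::runif(n_samples, box[1, 3], box[2, 3]))
    hit <- as.logical(region(pts))
    p <- mean(hit)
    list(volume = p * vol_box,
         se = sqrt(p * (1 - p) / n_samples) * vol_box,
         n = n_samples)
  })
}
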