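## Trilinear hexahedral finite elements on a regular grid. The solved
## compartment obeys  -div(K grad p) + (sum_k beta_k) p = sum_k beta_k pbar_k
## with natural zero-flux boundaries (or Dirichlet faces), where the beta
## coefficients are per unit volume (s^-1 Pa^-1 scale): RVE-averaged beta
## values (mm^3 Pa^-1 s^-1) are divided by the clipped RVE volume before
## entering the weak form.

#' Build a regular hexahedral grid mesh
#'
#' @param box 2 x 3 bounds matrix, mm.
#' @param n elements per axis (scalar or length 3); the mesh has
#'   `(n+1)^3` nodes and `n^3` trilinear hexahedral elements.
#' @return object of class `grid_mesh`: list with `box`, `n`, `dims`
#'   (nodes per axis), `h` (spacing), and `points` (nodes in x-fastest
#'   order).
#' @export
build_grid <- function(box = default_domain(), n = 16L) {
  box <- check_domain(box)
  n <- as.integer(rep(n, length.out = 3))
  if (any(n < 1L)) stop("n must be >= 1")
  dims <- n + 1L
  gx <- seq(box[1, 1], box[2, 1], length.out = dims[1])
  gy <- seq(box[1, 2], box[2, 2], length.out = dims[2])
  gz <- seq(box[1, 3], box[2, 3], length.out = dims[3])
  pts <- cbind(rep(gx, times = dims[2] * dims[3]),
               rep(rep(gy, each = dims[1]), times = dims[3]),
               rep(gz, each = dims[1] * dims[2]))
  structure(list(box = box, n = n, dims = dims,
                 h = (box[2, ] - box[1, ]) / n, points = pts),
            class = "grid_mesh")
}

#' @export
print.grid_mesh <- function(x, ...) {
  cat("<grid_mesh> ", paste(x$n, collapse = " x "), " elements, ",
      nrow(x$points), " nodes, spacing ",
      paste(signif(x$h, 4), collapse = " x "), " mm\n", sep = "")
  invisible(x)
}

## element-node index matrix (n_elem x 8), x-fastest node ordering
element_nodes <- function(mesh) {
  d <- mesh$dims
  ex <- seq_len(mesh$n[1]); ey <- seq_len(mesh$n[2]); ez <- seq_len(mesh$n[3])
  base <- outer(ex, (ey - 1L) * d[1], `+`)
  base <- outer(as.vector(base), (ez - 1L) * d[1] * d[2], `+`)
  base <- as.vector(base)                       # node at (i, j, k) corner
  off <- c(0L, 1L, d[1], d[1] + 1L, d[1] * d[2], d[1] * d[2] + 1L,
           d[1] * d[2] + d[1], d[1] * d[2] + d[1] + 1L)
  outer(base, off, `+`)
}

## trilinear shape functions and reference gradients at the 2x2x2 Gauss
## points (and at the element centre); corner order matches element_nodes
hex_shape <- function(xi) {
  signs <- as.matrix(expand.grid(sx = c(-1, 1), sy = c(-1, 1),
                                 sz = c(-1, 1)))
  N <- (1 + signs[, 1] * xi[1]) * (1 + signs[, 2] * xi[2]) *
    (1 + signs[, 3] * xi[3]) / 8
  dN <- cbind(signs[, 1] * (1 + signs[, 2] * xi[2]) * (1 + signs[, 3] * xi[3]),
              signs[, 2] * (1 + signs[, 1] * xi[1]) * (1 + signs[, 3] * xi[3]),
              signs[, 3] * (1 + signs[, 1] * xi[1]) * (1 + signs[, 2] * xi[2])) / 8
  list(N = N, dN = dN)
}

gauss_points <- function() {
  g <- 1 / sqrt(3)
  as.matrix(expand.grid(x = c(-g, g), y = c(-g, g), z = c(-g, g)))
}

#' Assemble the Darcy finite-element system
#'
#' Builds, over the trilinear hexahedral mesh with full 2x2x2 Gauss
#' quadrature, any of: the stiffness matrix `int grad(v) . K grad(p)` for a
#' nodal tensor field `K`; the mass-like matrix `int v * c * p` for a nodal
#' coefficient field `c`; and the load vector `int v * f` for a nodal field
#' `f`. Nodal fields are interpolated trilinearly to the quadrature points.
#'
#' @param mesh a `grid_mesh`.
#' @param K m x 6 symmetric tensor field at mesh nodes (or `NULL`).
#' @param coeff nodal coefficient field for the mass-like matrix (or
#'   `NULL`).
#' @param load nodal field for the load vector (or `NULL`).
#' @return list with any of `A_stiff`, `A_mass` (sparse symmetric) and `b`.
#' @export
assemble_darcy <- function(mesh, K = NULL, coeff = NULL, load = NULL) {
  E <- element_nodes(mesh)
  ne <- nrow(E)
  h <- mesh$h
  detJ <- prod(h) / 8
  gp <- gauss_points()
  out <- list()
  want_stiff <- !is.null(K)
  want_mass <- !is.null(coeff)
  want_load <- !is.null(load)

  if (want_stiff) { si <- sj <- sx <- vector("list", 8 * 36) ; sc <- 0L }
  if (want_mass) { mi <- mj <- mx <- vector("list", 8 * 36) ; mc <- 0L }
  if (want_load) b <- numeric(nrow(mesh$points))

  for (g in seq_len(8)) {
    sh <- hex_shape(gp[g, ])
    Ng <- sh$N
    dNdx <- sweep(sh$dN, 2, 2 / h, `*`)   # physical gradients, 8 x 3
    if (want_stiff) {
      Kg <- matrix(0, ne, 6)
      for (a in 1:8) Kg <- Kg + Ng[a] * K[E[, a], , drop = FALSE]
    }
    if (want_mass) {
      cg <- numeric(ne)
      for (a in 1:8) cg <- cg + Ng[a] * coeff[E[, a]]
    }
    if (want_load) {
      fg <- numeric(ne)
      for (a in 1:8) fg <- fg + Ng[a] * load[E[, a]]
      for (a in 1:8) {
        vals <- detJ * fg * Ng[a]
        agg <- rowsum(vals, E[, a])
        rows <- as.integer(rownames(agg))
        b[rows] <- b[rows] + agg[, 1]
      }
    }
    for (a in 1:8) for (bb in a:8) {
      if (want_stiff) {
        val <- detJ * (
          dNdx[a, 1] * dNdx[bb, 1] * Kg[, 1] +
          dNdx[a, 2] * dNdx[bb, 2] * Kg[, 2] +
          dNdx[a, 3] * dNdx[bb, 3] * Kg[, 3] +
          (dNdx[a, 1] * dNdx[bb, 2] + dNdx[a, 2] * dNdx[bb, 1]) * Kg[, 4] +
          (dNdx[a, 1] * dNdx[bb, 3] + dNdx[a, 3] * dNdx[bb, 1]) * Kg[, 5] +
          (dNdx[a, 2] * dNdx[bb, 3] + dNdx[a, 3] * dNdx[bb, 2]) * Kg[, 6])
        sc <- sc + 1L
        si[[sc]] <- E[, a]; sj[[sc]] <- E[, bb]; sx[[sc]] <- val
        if (bb > a) {
          sc <- sc + 1L
          si[[sc]] <- E[, bb]; sj[[sc]] <- E[, a]; sx[[sc]] <- val
        }
      }
      if (want_mass) {
        val <- detJ * cg * Ng[a] * Ng[bb]
        mc <- mc + 1L
        mi[[mc]] <- E[, a]; mj[[mc]] <- E[, bb]; mx[[mc]] <- val
        if (bb > a) {
          mc <- mc + 1L
          mi[[mc]] <- E[, bb]; mj[[mc]] <- E[, a]; mx[[mc]] <- val
        }
      }
    }
  }
  nn <- nrow(mesh$points)
  if (want_stiff)
    out$A_stiff <- Matrix::sparseMatrix(i = unlist(si[seq_len(sc)]),
                                        j = unlist(sj[seq_len(sc)]),
                                        x = unlist(sx[seq_len(sc)]),
                                        dims = c(nn, nn))
  if (want_mass)
    out$A_mass <- Matrix::sparseMatrix(i = unlist(mi[seq_len(mc)]),
                                       j = unlist(mj[seq_len(mc)]),
                                       x = unlist(mx[seq_len(mc)]),
                                       dims = c(nn, nn))
  if (want_load) out$b <- b
  out
}

#' Define a Darcy problem for the solved compartment
#'
#' Encodes the test protocol: one compartment is solved for pressure while
#' the neighbouring compartments enter as Dirichlet-imposed nodal pressure
#' fields through the coupling terms. Coupling coefficients are per unit
#' volume: pass RVE-averaged beta fields together with `vol_rve` and they
#' are divided through, or pass `vol_rve = 1` for coefficients already per
#' volume.
#'
#' @param K an m x 6 tensor field matrix or a `tensor_field`.
#' @param beta named list of nodal coupling fields (mm^3 Pa^-1 s^-1), e.g.
#'   `list("2,1" = ..., "3,2" = ...)`; may be empty for a pure-Dirichlet
#'   single-compartment problem.
#' @param pbar named list of imposed nodal pressure fields (Pa) aligned
#'   with `beta` (the other compartment of each pair).
#' @param vol_rve nodal clipped RVE volumes (mm^3) used to convert beta to
#'   per-volume form; scalar 1 keeps beta as given.
#' @param dirichlet optional list `list(nodes = indices, values = Pa)` of
#'   mesh-node Dirichlet conditions (used by the single-compartment face
#'   protocol); elsewhere boundaries are natural zero-flux.
#' @return object of class `darcy_problem`.
#' @export
darcy_problem <- function(K, beta = list(), pbar = list(), vol_rve = 1,
                          dirichlet = NULL) {
  if (inherits(K, "tensor_field")) K <- K$K * K$scale
  if (length(beta) != length(pbar))
    stop("beta and pbar must pair up")
  if (length(beta)) {
    for (nm in names(beta)) {
      if (any(beta[[nm]] < 0, na.rm = TRUE)) stop("beta must be >= 0")
      beta[[nm]] <- beta[[nm]] / vol_rve
    }
  }
  if (!length(beta) && is.null(dirichlet))
    stop("pure-Neumann problem with no coupling is singular: ",
         "supply beta fields or Dirichlet conditions")
  structure(list(K = K, beta = beta, pbar = pbar, dirichlet = dirichlet),
            class = "darcy_problem")
}

#' Solve the Darcy problem on a mesh
#'
#' Assembles (or reuses) the stiffness, coupling-mass and load pieces and
#' solves the sparse symmetric positive-definite system by direct
#' factorisation. The Darcy velocity `w = -K grad p` is evaluated at
#' element centres.
#'
#' @param problem a `darcy_problem`.
#' @param mesh a `grid_mesh`.
#' @param scale scalar multiplier applied to the permeability field.
#' @param cache optional precomputed assembly (list with `A_stiff`,
#'   `A_mass`, `b`) from a previous call with the same fields.
#' @return object of class `darcy_solution`: list with `p` (nodal Pa), `w`
#'   (element-centre velocities), `residual` (relative linear-solver
#'   residual), `scale` and the assembly `cache`.
#' @export
solve_darcy <- function(problem, mesh, scale = 1, cache = NULL) {
  if (is.null(cache)) cache <- darcy_assembly(problem, mesh)
  A <- scale * cache$A_stiff
  if (!is.null(cache$A_mass)) A <- A + cache$A_mass
  b <- if (is.null(cache$b)) numeric(nrow(mesh$points)) else cache$b
  nn <- nrow(mesh$points)
  p <- numeric(nn)
  if (!is.null(problem$dirichlet)) {
    dn <- problem$dirichlet$nodes
    p[dn] <- rep(problem$dirichlet$values, length.out = length(dn))
    free <- setdiff(seq_len(nn), dn)
    rhs <- b[free] - as.numeric(A[free, dn, drop = FALSE] %*% p[dn])
    p[free] <- as.numeric(Matrix::solve(
      Matrix::forceSymmetric(A[free, free, drop = FALSE]), rhs))
    res <- norm_vec(as.numeric(A[free, , drop = FALSE] %*% p) - b[free])
    den <- max(norm_vec(b[free]), norm_vec(p), .Machine$double.eps)
  } else {
    if (is.null(cache$A_mass) || max(abs(cache$A_mass@x)) == 0)
      stop("singular pure-Neumann system: all coupling coefficients are zero")
    p <- as.numeric(Matrix::solve(Matrix::forceSymmetric(A), b))
    res <- norm_vec(as.numeric(A %*% p) - b)
    den <- max(norm_vec(b), .Machine$double.eps)
  }
  w <- darcy_velocity(problem$K * scale, p, mesh)
  structure(list(p = p, w = w, residual = res / den, scale = scale,
                 cache = cache), class = "darcy_solution")
}

norm_vec <- function(v) sqrt(sum(v^2))

darcy_assembly <- function(problem, mesh) {
  coeff <- NULL; load <- NULL
  if (length(problem$beta)) {
    coeff <- Reduce(`+`, problem$beta)
    load <- Reduce(`+`, Map(`*`, problem$beta, problem$pbar))
  }
  assemble_darcy(mesh, K = problem$K, coeff = coeff, load = load)
}

## element-centre Darcy velocity -K grad p
darcy_velocity <- function(K, p, mesh) {
  E <- element_nodes(mesh)
  sh <- hex_shape(c(0, 0, 0))
  dNdx <- sweep(sh$dN, 2, 2 / mesh$h, `*`)
  Pn <- matrix(p[E], nrow(E), 8)
  grad <- Pn %*% dNdx                    # n_elem x 3
  Kc <- matrix(0, nrow(E), 6)
  for (a in 1:8) Kc <- Kc + sh$N[a] * K[E[, a], , drop = FALSE]
  -cbind(Kc[, 1] * grad[, 1] + Kc[, 4] * grad[, 2] + Kc[, 5] * grad[, 3],
         Kc[, 4] * grad[, 1] + Kc[, 2] * grad[, 2] + Kc[, 6] * grad[, 3],
         Kc[, 5] * grad[, 1] + Kc[, 6] * grad[, 2] + Kc[, 3] * grad[, 3])
}

#' @export
print.darcy_solution <- function(x, ...) {
  cat("<darcy_solution> ", length(x$p), " nodal pressures, scale=",
      format(x$scale), "\n  pressure range [Pa]: ",
      paste(signif(range(x$p), 5), collapse = " - "),
      "\n  relative residual: ", format(x$residual), "\n", sep = "")
  invisible(x)
}

#' Global mass balance of a Darcy solution
#'
#' With zero-flux outer boundaries and symmetric coupling, the solved
#' compartment's net volumetric exchange with the imposed compartments
#' equals its boundary flux; both are reported. In the weak form with the
#' constant test function these cancel exactly, so `total` is at machine
#' precision for a converged solve.
#'
#' @param solution a `darcy_solution`.
#' @param problem the `darcy_problem` it solved.
#' @param mesh the `grid_mesh`.
#' @return list with `exchange` (mm^3/s, `int sum_k beta_k (p - pbar_k)`),
#'   `boundary_flux` (mm^3/s, from the stiffness form) and `total`.
#' @export
mass_balance_report <- function(solution, problem, mesh) {
  cache <- solution$cache
  exch <- if (!is.null(cache$A_mass))
    sum(cache$A_mass %*% solution$p) - sum(cache$b) else 0
  bflux <- sum((solution$scale * cache$A_stiff) %*% solution$p)
  list(exchange = exch, boundary_flux = bflux, total = exch + bflux)
}

#' Trilinear interpolation of a nodal grid field
#'
#' @param mesh a `grid_mesh`.
#' @param values nodal values (length `prod(mesh$dims)`).
#' @param points n x 3 query points inside the box.
#' @return interpolated values.
#' @export
grid_interpolate <- function(mesh, values, points) {
  if (is.null(dim(points))) points <- matrix(points, nrow = 1)
  d <- mesh$dims
  rel <- sweep(sweep(points, 2, mesh$box[1, ]), 2, mesh$h, `/`)
  ie <- pmin(pmax(floor(rel), 0), mesh$n - 1L)
  t3 <- rel - ie
  i0 <- ie[, 1] + 1L; j0 <- ie[, 2] + 1L; k0 <- ie[, 3] + 1L
  idx <- function(i, j, k) (k - 1L) * d[1] * d[2] + (j - 1L) * d[1] + i
  v <- numeric(nrow(points))
  for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
    wgt <- (if (dx == 1) t3[, 1] else 1 - t3[, 1]) *
      (if (dy == 1) t3[, 2] else 1 - t3[, 2]) *
      (if (dz == 1) t3[, 3] else 1 - t3[, 3])
    v <- v + wgt * values[idx(i0 + dx, j0 + dy, k0 + dz)]
  }
  v
}

#' Mesh nodes on a box face
#' @param mesh a `grid_mesh`.
#' @param axis 1, 2 or 3.
#' @param side `"lower"` or `"upper"`.
#' @return node indices (1-based, mesh ordering).
#' @export
mesh_face_nodes <- function(mesh, axis, side = c("lower", "upper")) {
  side <- match.arg(side)
  target <- if (side == "lower") mesh$box[1, axis] else mesh$box[2, axis]
  which(abs(mesh$points[, axis] - target) < 1e-9)
}
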