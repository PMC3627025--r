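## Permeability tensor parameterisation. Three methods produce symmetric
## positive-definite 3x3 tensor fields in mm^2 Pa^-1 s^-1 at grid nodes:
## (i) porosity-scaled isotropic, (ii) Huyghe-Van Campen chord sums, and
## (iii) projected PCA of conductance-scaled vessel directions.
##
## Tensor fields are stored compactly as an m x 6 matrix with columns
## (xx, yy, zz, xy, xz, yz).

SYM6 <- matrix(c(1L, 4L, 5L, 4L, 2L, 6L, 5L, 6L, 3L), 3, 3)

sym6_to_mat <- function(v) {
  matrix(v[SYM6], 3, 3)
}

mat_to_sym6 <- function(K) {
  c(K[1, 1], K[2, 2], K[3, 3], K[1, 2], K[1, 3], K[2, 3])
}

#' Porosity-scaled isotropic permeability
#'
#' `K(x) = phi(x) * I`: the identity tensor (unit mm^2 Pa^-1 s^-1) scaled by
#' the local porosity.
#'
#' @param phi porosity values at field points.
#' @return m x 6 symmetric-tensor matrix (columns xx, yy, zz, xy, xz, yz).
#' @export
k_isotropic <- function(phi) {
  if (any(phi < 0, na.rm = TRUE)) stop("porosity must be non-negative")
  m <- length(phi)
  cbind(xx = phi, yy = phi, zz = phi,
        xy = numeric(m), xz = numeric(m), yz = numeric(m))
}

#' Huyghe-Van Campen permeability at a point
#'
#' Entry-wise chord sum over the compartment's vessels inside the RVE:
#' `K_ij = pi / (128 vol_RVE dx0 mu) * sum_v d_v^4 dx_i dx_j / l_v`, where
#' `d_v` is the vessel diameter and `dx` the endpoint coordinate
#' differences. Vessels partially inside contribute in proportion to their
#' inside-length fraction. Returns `NA` entries when the RVE is empty.
#'
#' @param x centre, mm.
#' @param radius RVE radius, mm.
#' @param compartment integer label (or `NULL` for all vessels).
#' @param net a `vascular_network`.
#' @param delta_x0 hierarchic-parameter width of the compartment
#'   (dimensionless); rescaling of K downstream absorbs its magnitude.
#' @param mu dynamic viscosity, Pa s.
#' @param vol_rve clipped RVE volume (computed if omitted).
#' @param domain 2 x 3 bounds matrix, used when `vol_rve` is omitted.
#' @param index optional prebuilt spatial index.
#' @return symmetric 3 x 3 matrix, mm^2 Pa^-1 s^-1.
#' @export
k_hvc <- function(x, radius, compartment, net, delta_x0 = 1, mu = 0.0035,
                  vol_rve = NULL, domain = NULL, index = NULL) {
  if (is.null(vol_rve)) {
    if (is.null(domain)) domain <- attr(net, "domain")
    vol_rve <- rve_volume_in_domain(x, radius, domain)
  }
  hits <- vessels_in_rve(x, radius, net, compartment, index)
  if (!nrow(hits)) return(matrix(NA_real_, 3, 3))
  rows <- hits$row
  terms <- hvc_vessel_terms(net)[rows, , drop = FALSE]
  v6 <- colSums(terms * hits$fraction) * pi / (128 * vol_rve * delta_x0 * mu)
  sym6_to_mat(v6)
}

## per-vessel d^4 dx_i dx_j / l terms, m x 6
hvc_vessel_terms <- function(net) {
  ia <- match(net$vessels$node_a, net$nodes$id)
  ib <- match(net$vessels$node_b, net$nodes$id)
  dx <- cbind(net$nodes$x[ib] - net$nodes$x[ia],
              net$nodes$y[ib] - net$nodes$y[ia],
              net$nodes$z[ib] - net$nodes$z[ia])
  d4 <- (2 * net$vessels$radius)^4
  w <- d4 / net$vessels$length
  cbind(xx = w * dx[, 1]^2, yy = w * dx[, 2]^2, zz = w * dx[, 3]^2,
        xy = w * dx[, 1] * dx[, 2], xz = w * dx[, 1] * dx[, 3],
        yz = w * dx[, 2] * dx[, 3])
}

#' Projected-PCA permeability at a point
#'
#' Each vessel in the RVE contributes a datum: its unit direction (signed so
#' the vessel points away from the node nearest the RVE centre) scaled by
#' its Poiseuille conductance. The data set is made zero-mean by reflecting
#' every datum through the origin, its covariance (population normaliser)
#' is eigendecomposed, and each vessel's conductance is then distributed
#' over the eigenvector directions in proportion to the absolute
#' projections of its direction, normalised per vessel so the projected
#' lengths sum to the conductance. The permeability is the resulting
#' eigenbasis expansion; its trace equals the summed conductances by
#' construction. Vessels partially inside the RVE contribute their
#' conductance scaled by the inside-length fraction.
#'
#' @inheritParams k_hvc
#' @return symmetric 3 x 3 matrix, mm^2 Pa^-1 s^-1 (NA if the RVE is
#'   empty).
#' @export
k_pca <- function(x, radius, compartment, net, mu = 0.0035, index = NULL) {
  hits <- vessels_in_rve(x, radius, net, compartment, index)
  if (!nrow(hits)) return(matrix(NA_real_, 3, 3))
  if (is.null(index)) index <- build_spatial_index(net)
  rows <- hits$row
  Cp <- poiseuille_conductance(net$vessels$radius[rows],
                               net$vessels$length[rows], mu) * hits$fraction
  A <- index$A[rows, , drop = FALSE]; B <- index$B[rows, , drop = FALSE]
  u <- (B - A) / index$len[rows]
  ## anchor: node closest to x at the origin fixes the datum sign
  flip <- rowSums(sweep(A, 2, x)^2) > rowSums(sweep(B, 2, x)^2)
  u[flip, ] <- -u[flip, , drop = FALSE]
  k_pca_core(u, Cp)
}

## shared by the point-wise and field-wise paths; u: unit directions,
## Cp: (fraction-weighted) conductances
k_pca_core <- function(u, Cp) {
  d <- u * Cp
  covm <- crossprod(d) / nrow(d)   # reflected pairs share this covariance
  eg <- eigen((covm + t(covm)) / 2, symmetric = TRUE)
  E <- eg$vectors
  proj <- abs(u %*% E)             # |direction . e_m|
  sums <- rowSums(proj)
  sums[sums == 0] <- 1
  lam <- colSums(proj / sums * Cp)
  K <- E %*% diag(lam) %*% t(E)
  (K + t(K)) / 2
}

#' Floor the eigenvalues of a symmetric tensor
#'
#' Regularises a positive semi-definite tensor to strict positive
#' definiteness by raising eigenvalues below
#' `eps = 1e-6 * max(trace(K), tiny)` up to `eps`. Needed because the
#' chord-sum and PCA constructions are only PSD for degenerate (e.g.
#' collinear) vessel sets.
#'
#' @param K symmetric 3 x 3 matrix, or an m x 6 tensor-field matrix.
#' @param rel_floor relative eigenvalue floor (default 1e-6 of the trace).
#' @return regularised tensor(s), same shape as the input.
#' @export
regularize_spd <- function(K, rel_floor = 1e-6) {
  if (is.matrix(K) && ncol(K) == 6L && !(nrow(K) == 3L && ncol(K) == 3L)) {
    out <- K
    for (r in seq_len(nrow(K)))
      out[r, ] <- mat_to_sym6(regularize_spd(sym6_to_mat(K[r, ])))
    return(out)
  }
  if (!isTRUE(all.equal(K, t(K), tolerance = 1e-8)))
    stop("input tensor is not symmetric")
  eg <- eigen((K + t(K)) / 2, symmetric = TRUE)
  eps <- rel_floor * max(sum(diag(K)), .Machine$double.xmin)
  vals <- pmax(eg$values, eps)
  K2 <- eg$vectors %*% diag(vals) %*% t(eg$vectors)
  (K2 + t(K2)) / 2
}

#' Parameterise a permeability tensor field on a grid
#'
#' Dispatches over the three methods, evaluates the tensor at every grid
#' node, fills nodes with empty RVEs from their nearest valid neighbour,
#' and floors eigenvalues to keep the field strictly positive definite.
#'
#' @param grid a `grid_mesh`.
#' @param radius RVE radius, mm.
#' @param compartment integer label.
#' @param method one of `"iso"`, `"hvc"`, `"pca"`.
#' @param net a `vascular_network`.
#' @param flow a `network_flow` (unused by the tensor constructions but
#'   accepted for a uniform signature).
#' @param mu dynamic viscosity, Pa s.
#' @param delta_x0 hierarchic width for the HvC method; defaults to 1.
#' @param rve optional precomputed [rve_fields()] object (reused for the
#'   fraction matrix, porosities and RVE volumes).
#' @param quiet suppress empty-RVE fill warnings.
#' @return object of class `tensor_field`: list with `K` (m x 6), `points`,
#'   `method`, `scale` (applied multiplier, initially 1) and `n_filled`.
#' @export
parameterise_field <- function(grid, radius, compartment,
                               method = c("iso", "hvc", "pca"), net,
                               flow = NULL, mu = 0.0035, delta_x0 = 1,
                               rve = NULL, quiet = FALSE) {
  method <- match.arg(method)
  points <- grid$points
  if (is.null(rve)) {
    if (is.null(flow))
      flow <- structure(list(pressure = stats::setNames(
        numeric(nrow(net$nodes)), net$nodes$id),
        flux = stats::setNames(numeric(nrow(net$vessels)), net$vessels$id),
        mu = mu, mass_residual = 0), class = "network_flow")
    rve <- rve_fields(net, flow, points, radius,
                      compartments = compartment, pairs = list())
  }
  cols <- which(net$vessels$compartment == compartment)
  W <- rve$W[, cols, drop = FALSE]
  m <- nrow(points)
  if (method == "iso") {
    jc <- match(as.character(compartment), colnames(rve$phi))
    K <- k_isotropic(rve$phi[, jc])
    empty <- Matrix::rowSums(W) == 0
  } else if (method == "hvc") {
    terms <- hvc_vessel_terms(net)[cols, , drop = FALSE]
    K <- as.matrix(W %*% terms) * pi / (128 * rve$vol_rve * delta_x0 * mu)
    colnames(K) <- c("xx", "yy", "zz", "xy", "xz", "yz")
    empty <- Matrix::rowSums(W) == 0
    K[empty, ] <- NA_real_
  } else {
    index <- build_spatial_index(net)
    A <- index$A[cols, , drop = FALSE]; B <- index$B[cols, , drop = FALSE]
    len <- index$len[cols]
    Cp_all <- poiseuille_conductance(net$vessels$radius[cols],
                                     net$vessels$length[cols], mu)
    Wt <- methods::as(W, "TsparseMatrix")
    byrow <- split(data.frame(j = Wt@j + 1L, f = Wt@x), Wt@i + 1L)
    K <- matrix(NA_real_, m, 6,
                dimnames = list(NULL, c("xx", "yy", "zz", "xy", "xz", "yz")))
    for (nm in names(byrow)) {
      r <- as.integer(nm)
      hh <- byrow[[nm]]
      u <- (B[hh$j, , drop = FALSE] - A[hh$j, , drop = FALSE]) / len[hh$j]
      flip <- rowSums(sweep(A[hh$j, , drop = FALSE], 2, points[r, ])^2) >
        rowSums(sweep(B[hh$j, , drop = FALSE], 2, points[r, ])^2)
      u[flip, ] <- -u[flip, , drop = FALSE]
      K[r, ] <- mat_to_sym6(k_pca_core(u, Cp_all[hh$j] * hh$f))
    }
    empty <- is.na(K[, 1])
  }
  n_filled <- sum(empty)
  if (all(empty)) stop("no grid node has a non-empty RVE: radius too small")
  if (n_filled) {
    if (!quiet)
      warning(n_filled, " grid node(s) had an empty RVE for compartment ",
              compartment, "; tensors filled from nearest valid node",
              call. = FALSE)
    ok <- which(!empty)
    Pok <- points[ok, , drop = FALSE]
    for (r in which(empty)) {
      d2 <- colSums((t(Pok) - points[r, ])^2)
      K[r, ] <- K[ok[which.min(d2)], ]
    }
  }
  K <- regularize_spd(K)
  structure(list(K = K, points = points, method = method, scale = 1,
                 compartment = compartment, n_filled = n_filled),
            class = "tensor_field")
}

#' @export
print.tensor_field <- function(x, ...) {
  tr <- rowSums(x$K[, 1:3, drop = FALSE])
  cat("<tensor_field> method=", x$method, ", ", nrow(x$K), " nodes, scale=",
      format(x$scale), "\n  trace range [mm^2/Pa/s]: ",
      paste(signif(range(tr), 4), collapse = " - "), "\n", sep = "")
  invisible(x)
}
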