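#' Fit a continuum Darcy perfusion model to a discrete vascular network
#'
#' The central pipeline: solve Poiseuille flow on the network, partition the
#' vessels into compartments by hierarchic parameter, average pressure,
#' porosity and inter-compartment flux over spherical RVEs at the mesh
#' nodes, parameterise the permeability tensor field of the solved
#' compartment by the requested methods, rescale each field by the constant
#' minimising the rms error, solve the Darcy system and compare its
#' pressure with the averaged discrete pressure.
#'
#' Two protocols are supported, selected by the network:
#' \describe{
#'   \item{multi-compartment (rooted tree)}{compartment 2 is solved with
#'     zero-flux outer boundaries; compartments 1 and 3 enter as
#'     Dirichlet-imposed averaged-pressure fields through the coupling
#'     coefficients `beta`.}
#'   \item{single compartment (unrooted lattice)}{all vessels form one
#'     compartment; the Darcy problem carries Dirichlet pressures on two
#'     opposing faces and zero flux elsewhere, mirroring the discrete
#'     boundary conditions.}
#' }
#'
#' @param net a `vascular_network` (with a `domain` attribute, or supply
#'   `domain`).
#' @param flow optional precomputed `network_flow`; otherwise solved from
#'   `dirichlet`.
#' @param dirichlet named pressure vector for the discrete solve. Default
#'   for rooted trees: root at `root_pressure`, terminals at
#'   `terminal_pressure`. For lattices: the two faces normal to `bc_axis`
#'   at `face_pressures`, other terminals zero flux.
#' @param partition integer compartment labels per vessel (named by vessel
#'   id) or `NULL` to derive them.
#' @param Z partition vector; when `NULL` it is optimised for
#'   `target_radii`.
#' @param target_radii decreasing target mean radii (mm) per compartment;
#'   `NULL` derives them from the network with
#'   [derive_partition_targets()]. Networks spanning the full
#'   arteriole-to-capillary range would use explicit targets such as
#'   `c(0.030, 0.006, 0.003)`.
#' @param rve_radius RVE radius, mm.
#' @param grid_n Darcy mesh elements per axis.
#' @param domain 2 x 3 bounds matrix, mm.
#' @param methods subset of `c("iso", "hvc", "pca")`.
#' @param mu dynamic viscosity, Pa s.
#' @param delta_x0 hierarchic width for the HvC method; default: the zeta
#'   width of the solved compartment's partition interval (1 when unknown).
#' @param solve_compartment compartment solved by the Darcy model
#'   (multi-compartment protocol).
#' @param root_pressure,terminal_pressure default tree boundary pressures,
#'   Pa.
#' @param bc_axis,face_pressures lattice-protocol boundary conditions:
#'   axis index and `c(inlet, outlet)` pressures, Pa.
#' @param comparison_n number of vascular nodes for the Poiseuille-vs-
#'   averaged-pressure comparison.
#' @param comparison_seed seed for that node sample.
#' @param mc_samples,mc_seed Monte Carlo controls for clipped RVE volumes.
#' @param optimise_scale run the permeability-scale optimisation (ignored
#'   -- the solution is scale-invariant -- for the pure-Dirichlet
#'   single-compartment protocol).
#' @param quiet suppress empty-RVE fill warnings.
#' @return an object of class `perfusion_fit`; see
#'   [summary.perfusion_fit()], [coef.perfusion_fit()],
#'   [predict.perfusion_fit()], [residuals.perfusion_fit()].
#' @export
perfusion_fit <- function(net, flow = NULL, dirichlet = NULL,
                          partition = NULL, Z = NULL, target_radii = NULL,
                          rve_radius = 0.2667, grid_n = 16L, domain = NULL,
                          methods = c("iso", "hvc", "pca"), mu = 0.0035,
                          delta_x0 = NULL, solve_compartment = 2L,
                          root_pressure = 13300, terminal_pressure = 8000,
                          bc_axis = 1L, face_pressures = c(2000, 1000),
                          comparison_n = 1000L, comparison_seed = 1L,
                          mc_samples = 1e5, mc_seed = 77L,
                          optimise_scale = TRUE, quiet = TRUE) {
  methods <- match.arg(methods, several.ok = TRUE)
  if (is.null(domain)) domain <- attr(net, "domain")
  if (is.null(domain)) stop("supply a domain")
  rooted <- !is.na(net$root_id)

  hier <- NULL
  if (rooted) {
    if (is.null(partition)) {
      hier <- compute_zeta(net)
      if (is.null(Z)) {
        if (is.null(target_radii))
          target_radii <- derive_partition_targets(net, hier)
        Z <- optimise_partition(net, hier, target_radii)
      }
      partition <- partition_by_zeta(net, hier, Z)
    }
    net <- set_compartments(net, partition)
    cpt <- solve_compartment
    compartments <- sort(unique(net$vessels$compartment))
    if (!(cpt %in% compartments)) stop("solved compartment is empty")
    if (is.null(dirichlet))
      dirichlet <- tree_boundary_conditions(net, root_pressure,
                                            terminal_pressure)
    if (is.null(flow)) flow <- solve_network_flow(net, dirichlet, mu)
  } else {
    if (all(is.na(net$vessels$compartment)))
      net$vessels$compartment <- 1L
    cpt <- 1L
    compartments <- sort(unique(net$vessels$compartment))
    if (is.null(dirichlet)) {
      inlet <- face_nodes(net, bc_axis, "lower", domain)
      outlet <- face_nodes(net, bc_axis, "upper", domain)
      dirichlet <- stats::setNames(
        c(rep(face_pressures[1], length(inlet)),
          rep(face_pressures[2], length(outlet))), c(inlet, outlet))
    }
    if (is.null(flow)) {
      zf <- setdiff(terminal_nodes(net), as.integer(names(dirichlet)))
      flow <- solve_network_flow(net, dirichlet, mu, zero_flux = zf)
    }
  }

  mesh <- build_grid(domain, grid_n)
  pairs <- if (length(compartments) > 1L) {
    nb <- list()
    if ((cpt - 1L) %in% compartments) nb <- c(nb, list(c(cpt, cpt - 1L)))
    if ((cpt + 1L) %in% compartments) nb <- c(nb, list(c(cpt + 1L, cpt)))
    nb
  } else list()

  rve <- rve_fields(net, flow, mesh$points, rve_radius, domain,
                    compartments = compartments, pairs = pairs,
                    mc_samples = mc_samples, mc_seed = mc_seed)
  jc <- match(as.character(cpt), colnames(rve$pbar))
  fill <- function(v) fill_nearest(v, mesh$points, quiet = quiet)
  pbar_solved <- fill(rve$pbar[, jc])

  if (is.null(delta_x0))
    delta_x0 <- if (!is.null(Z)) Z[cpt] - Z[cpt + 1L] else 1

  ## Darcy problem pieces common to all methods
  if (length(pairs)) {
    beta <- lapply(rve$beta, fill)
    pbar_other <- lapply(pairs, function(pr) {
      other <- setdiff(pr, cpt)
      fill(rve$pbar[, match(as.character(other), colnames(rve$pbar))])
    })
    names(pbar_other) <- names(beta)
    problem_of <- function(K)
      darcy_problem(K, beta = beta, pbar = pbar_other,
                    vol_rve = rve$vol_rve)
    common <- {
      beta_pv <- Map(`/`, beta, list(rve$vol_rve))
      coeff <- Reduce(`+`, beta_pv)
      load <- Reduce(`+`, Map(`*`, beta_pv, pbar_other))
      assemble_darcy(mesh, coeff = coeff, load = load)
    }
    dirichlet_mesh <- NULL
  } else {
    beta <- list(); pbar_other <- list()
    lo <- mesh_face_nodes(mesh, bc_axis, "lower")
    hi <- mesh_face_nodes(mesh, bc_axis, "upper")
    dirichlet_mesh <- list(nodes = c(lo, hi),
                           values = rep(face_pressures, c(length(lo),
                                                          length(hi))))
    problem_of <- function(K)
      darcy_problem(K, dirichlet = dirichlet_mesh)
    common <- NULL
  }

  results <- list()
  for (mth in methods) {
    tf <- parameterise_field(mesh, rve_radius, cpt, mth, net, flow, mu,
                             delta_x0, rve = rve, quiet = quiet)
    prob <- problem_of(tf)
    stiff <- assemble_darcy(mesh, K = prob$K)
    cache <- c(stiff, common)
    if (length(pairs) && optimise_scale) {
      opt <- optimise_k_scale_cached(prob, mesh, pbar_solved, cache)
      tf$scale <- opt$scale
      sol <- solve_darcy(prob, mesh, scale = opt$scale, cache = cache)
      rms <- opt$rms
    } else {
      sol <- solve_darcy(prob, mesh, scale = 1, cache = cache)
      rms <- rms_error(pbar_solved, sol$p)
    }
    results[[mth]] <- list(tensor = tf, scale = tf$scale, rms = rms,
                           p = sol$p, psi = smoothness_psi(sol$p, mesh$dims),
                           residual = sol$residual,
                           stiff = stiff$A_stiff)
  }

  ## Poiseuille-vs-averaged comparison at sampled vascular nodes
  vrows <- which(net$vessels$compartment == cpt)
  node_ids <- unique(c(net$vessels$node_a[vrows], net$vessels$node_b[vrows]))
  take <- min(comparison_n, length(node_ids))
  sample_ids <- with_seed(comparison_seed,
                          sort(sample(node_ids, take)))
  nrows <- match(sample_ids, net$nodes$id)
  npts <- cbind(net$nodes$x[nrows], net$nodes$y[nrows], net$nodes$z[nrows])
  rve_nodes <- rve_fields(net, flow, npts, rve_radius, domain,
                          compartments = cpt, pairs = list(),
                          mc_samples = mc_samples, mc_seed = mc_seed)
  pbar_nodes <- fill_nearest(rve_nodes$pbar[, 1], npts, quiet = quiet)
  p_tilde <- unname(flow$pressure[as.character(sample_ids)])
  rms_poiseuille <- rms_error(pbar_nodes, p_tilde)

  structure(list(network = net, flow = flow, hier = hier, Z = Z,
                 labels = net$vessels$compartment, compartment = cpt,
                 mesh = mesh, rve = rve, rve_radius = rve_radius,
                 pbar = pbar_solved, beta = beta, pbar_imposed = pbar_other,
                 methods = results, mu = mu, delta_x0 = delta_x0,
                 dirichlet = dirichlet, dirichlet_mesh = dirichlet_mesh,
                 protocol = if (length(pairs)) "multi" else "single",
                 comparison = list(node_ids = sample_ids, points = npts,
                                   p_tilde = p_tilde, p_bar = pbar_nodes,
                                   rms = rms_poiseuille),
                 psi_pbar = smoothness_psi(pbar_solved, mesh$dims),
                 common_cache = common),
            class = "perfusion_fit")
}

## scale optimisation with a prebuilt assembly cache
optimise_k_scale_cached <- function(problem, mesh, p_bar, cache,
                                    log_range = 4, n_scan = 21L,
                                    tol = 1e-3) {
  rms_at <- function(ls) {
    sol <- solve_darcy(problem, mesh, scale = 10^ls, cache = cache)
    rms_error(p_bar, sol$p)
  }
  grid_ls <- seq(-log_range, log_range, length.out = n_scan)
  prof <- vapply(grid_ls, rms_at, numeric(1))
  i0 <- which.min(prof)
  opt <- stats::optimize(rms_at, c(grid_ls[max(1L, i0 - 1L)],
                                   grid_ls[min(n_scan, i0 + 1L)]),
                         tol = tol / log(10))
  if (opt$objective <= prof[i0])
    list(scale = 10^opt$minimum, rms = opt$objective)
  else list(scale = 10^grid_ls[i0], rms = prof[i0])
}

#' @export
print.perfusion_fit <- function(x, ...) {
  cat("<perfusion_fit> ", x$protocol, "-compartment protocol, RVE radius ",
      x$rve_radius, " mm, mesh ", paste(x$mesh$n, collapse = "x"), "\n",
      sep = "")
  tab <- do.call(rbind, lapply(names(x$methods), function(m)
    data.frame(method = m, scale = x$methods[[m]]$scale,
               rms = x$methods[[m]]$rms)))
  print(tab, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Summarise a perfusion fit
#'
#' @param object a `perfusion_fit`.
#' @param ... unused.
#' @return a `summary.perfusion_fit` with per-method rms, optimal scales,
#'   smoothness values and compartment statistics.
#' @export
summary.perfusion_fit <- function(object, ...) {
  cptstat <- stats::aggregate(
    radius ~ compartment, data = object$network$vessels,
    FUN = function(r) c(n = length(r), mean = mean(r)))
  tab <- do.call(rbind, lapply(names(object$methods), function(m)
    data.frame(method = m, scale = object$methods[[m]]$scale,
               rms = object$methods[[m]]$rms,
               psi = object$methods[[m]]$psi)))
  structure(list(methods = tab, compartments = cptstat,
                 psi_pbar = object$psi_pbar, Z = object$Z,
                 rms_poiseuille = object$comparison$rms,
                 rve_radius = object$rve_radius,
                 protocol = object$protocol), class = "summary.perfusion_fit")
}

#' @export
print.summary.perfusion_fit <- function(x, ...) {
  cat("Continuum perfusion fit (", x$protocol, "-compartment protocol)\n",
      "RVE radius: ", x$rve_radius, " mm\n", sep = "")
  if (!is.null(x$Z))
    cat("Partition vector Z: ", paste(signif(x$Z, 5), collapse = ", "),
        "\n", sep = "")
  cat("\nPer-method comparison with the averaged discrete pressure:\n")
  print(x$methods, row.names = FALSE, digits = 4)
  cat("\nUnsmoothness of averaged pressure field: ",
      format(signif(x$psi_pbar, 4)), "\n", sep = "")
  cat("rms between nodal Poiseuille and averaged pressure: ",
      format(signif(x$rms_poiseuille, 4)), "\n", sep = "")
  invisible(x)
}

#' @export
coef.perfusion_fit <- function(object, ...) {
  vapply(object$methods, function(m) m$scale, numeric(1))
}

#' Fitted Darcy pressures at mesh nodes
#' @param object a `perfusion_fit`.
#' @param ... unused.
#' @return matrix (mesh nodes x methods) of pressures, Pa.
#' @export
fitted.perfusion_fit <- function(object, ...) {
  vapply(object$methods, function(m) m$p,
         numeric(nrow(object$mesh$points)))
}

#' Normalised residuals of the Darcy pressure fields
#'
#' Differences between the Darcy and averaged discrete pressure at the mesh
#' nodes after the shared min-max normalisation used by the rms metric.
#'
#' @param object a `perfusion_fit`.
#' @param ... unused.
#' @return matrix (mesh nodes x methods).
#' @export
residuals.perfusion_fit <- function(object, ...) {
  rng <- range(object$pbar)
  vapply(object$methods,
         function(m) (m$p - object$pbar) / diff(rng),
         numeric(nrow(object$mesh$points)))
}

#' Predict the Darcy pressure at new points
#'
#' Trilinear interpolation of the fitted nodal pressure field.
#'
#' @param object a `perfusion_fit`.
#' @param newdata n x 3 matrix of points, mm.
#' @param method which permeability method's solution to evaluate.
#' @param ... unused.
#' @return pressures, Pa.
#' @export
predict.perfusion_fit <- function(object, newdata,
                                  method = names(object$methods)[1], ...) {
  grid_interpolate(object$mesh, object$methods[[method]]$p,
                   as.matrix(newdata))
}

#' Plot a perfusion fit
#'
#' Mid-depth slice images of the averaged discrete pressure and the fitted
#' Darcy pressure.
#'
#' @param x a `perfusion_fit`.
#' @param method which method's Darcy field to show.
#' @param slice_axis axis normal to the slice (default 3).
#' @param ... unused.
#' @export
plot.perfusion_fit <- function(x, method = names(x$methods)[1],
                               slice_axis = 3L, ...) {
  d <- x$mesh$dims
  mid <- ceiling(d[slice_axis] / 2)
  arr_b <- array(x$pbar, d)
  arr_p <- array(x$methods[[method]]$p, d)
  take <- function(a) switch(slice_axis, a[mid, , ], a[, mid, ], a[, , mid])
  oldpar <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(oldpar))
  graphics::image(take(arr_b), main = "averaged discrete pressure",
                  useRaster = TRUE)
  graphics::image(take(arr_p), main = paste("Darcy pressure,", method),
                  useRaster = TRUE)
  invisible(x)
}

#' Re-solve a fit under new discrete boundary conditions with frozen
#' parameters
#'
#' Re-solves the Poiseuille flow under new terminal pressures, re-averages
#' the discrete pressure fields, and re-solves the Darcy problem keeping
#' the permeability fields, their optimal scales and the coupling
#' coefficients exactly as fitted. Used to test that the parameterisation
#' is independent of the boundary conditions it was derived with.
#'
#' @param fit a multi-compartment `perfusion_fit`.
#' @param dirichlet new named pressure vector for the discrete model.
#' @return list with `rms` per method, the new `flow` and comparison
#'   fields.
#' @export
refit_bc <- function(fit, dirichlet) {
  if (fit$protocol != "multi") stop("refit_bc applies to the multi-compartment protocol")
  net <- fit$network
  flow <- solve_network_flow(net, dirichlet, fit$mu)
  mesh <- fit$mesh
  rve <- fit$rve
  Pv <- vessel_pressures(net, flow)
  vol_v <- net$vessels$volume
  cptv <- net$vessels$compartment
  pbar_of <- function(cpt) {
    cols <- which(cptv == cpt)
    Wi <- rve$W[, cols, drop = FALSE]
    wv <- as.numeric(Wi %*% vol_v[cols])
    v <- ifelse(wv > 0, as.numeric(Wi %*% (vol_v[cols] * Pv[cols])) / wv,
                NA_real_)
    fill_nearest(v, mesh$points, quiet = TRUE)
  }
  pbar_solved <- pbar_of(fit$compartment)
  pbar_other <- lapply(names(fit$pbar_imposed), function(nm) {
    pr <- as.integer(strsplit(nm, ",")[[1]])
    pbar_of(setdiff(pr, fit$compartment))
  })
  names(pbar_other) <- names(fit$pbar_imposed)
  beta_pv <- Map(`/`, fit$beta, list(rve$vol_rve))   # frozen beta
  load <- Reduce(`+`, Map(`*`, beta_pv, pbar_other))
  bvec <- assemble_darcy(mesh, load = load)$b
  rms <- vapply(names(fit$methods), function(m) {
    mm <- fit$methods[[m]]
    prob <- darcy_problem(mm$tensor$K, beta = fit$beta,
                          pbar = pbar_other, vol_rve = rve$vol_rve)
    cache <- list(A_stiff = mm$stiff, A_mass = fit$common_cache$A_mass,
                  b = bvec)
    sol <- solve_darcy(prob, mesh, scale = mm$scale, cache = cache)
    rms_error(pbar_solved, sol$p)
  }, numeric(1))
  list(rms = rms, flow = flow, pbar = pbar_solved, pbar_imposed = pbar_other)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
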