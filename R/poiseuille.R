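## Discrete network haemodynamics: Poiseuille conductances, junction mass
## conservation, and the sparse nodal pressure solve.

#' Poiseuille conductance of a vessel
#'
#' `C = pi r^4 / (8 mu l)` (equivalently `pi d^4 / (128 mu l)`), in
#' mm^3 Pa^-1 s^-1, so that vessel flux is `Q = C * dp`.
#'
#' @param r vessel radius, mm.
#' @param l vessel length, mm.
#' @param mu dynamic viscosity, Pa s (blood default 0.0035).
#' @return conductance(s), mm^3 Pa^-1 s^-1.
#' @export
poiseuille_conductance <- function(r, l, mu = 0.0035) {
  if (any(r <= 0) || any(l <= 0) || any(mu <= 0))
    stop("r, l and mu must be positive")
  pi * r^4 / (8 * mu * l)
}

#' Incidence matrix over internal nodes
#'
#' Sparse matrix with one row per internal (junction) node and one column
#' per vessel; entries are +1 for a vessel incoming to the node, -1 for an
#' outgoing vessel, 0 otherwise. Mass conservation at junctions reads
#' `L %*% Q = 0`.
#'
#' @param net a `vascular_network` with flow orientation `node_a -> node_b`.
#' @return a `dgCMatrix` with dimnames (internal node ids, vessel ids).
#' @export
build_incidence <- function(net) {
  deg <- node_degree(net)
  internal <- which(deg > 1L)
  if (!is.na(net$root_id))   # the inlet is a boundary node whatever its degree
    internal <- setdiff(internal, match(net$root_id, net$nodes$id))
  ia <- match(net$vessels$node_a, net$nodes$id)
  ib <- match(net$vessels$node_b, net$nodes$id)
  rows_in <- match(ib, internal)    # incoming: node is the distal endpoint
  rows_out <- match(ia, internal)
  keep_in <- !is.na(rows_in); keep_out <- !is.na(rows_out)
  L <- Matrix::sparseMatrix(
    i = c(rows_in[keep_in], rows_out[keep_out]),
    j = c(which(keep_in), which(keep_out)),
    x = c(rep(1, sum(keep_in)), rep(-1, sum(keep_out))),
    dims = c(length(internal), nrow(net$vessels)),
    dimnames = list(as.character(net$nodes$id[internal]),
                    as.character(net$vessels$id)))
  L
}

#' Solve Poiseuille flow on a network
#'
#' Substitutes the per-vessel Poiseuille law into junction mass conservation
#' and solves the resulting symmetric positive-definite weighted graph
#' Laplacian for the nodal pressures, with Dirichlet pressures eliminated.
#' Terminal nodes without a Dirichlet value are treated as natural zero-flux
#' boundaries (free unknowns).
#'
#' @param net a `vascular_network`.
#' @param dirichlet named numeric vector of pressures in Pa; names are node
#'   ids. At least one value is required and every terminal node must be
#'   either listed here or in `zero_flux`.
#' @param mu dynamic viscosity, Pa s.
#' @param zero_flux node ids of terminals intentionally left as no-flow
#'   boundaries.
#' @return object of class `network_flow`: list with `pressure` (Pa, named
#'   by node id), `flux` (mm^3/s, named by vessel id, positive in the
#'   `node_a -> node_b` direction), `mu`, and `mass_residual` (max junction
#'   imbalance relative to the max flux magnitude).
#' @export
solve_network_flow <- function(net, dirichlet, mu = 0.0035,
                               zero_flux = integer(0)) {
  if (length(dirichlet) == 0L) stop("at least one Dirichlet node is required")
  dnodes <- as.integer(names(dirichlet))
  if (anyNA(match(dnodes, net$nodes$id)))
    stop("Dirichlet names must be node ids")
  term <- terminal_nodes(net)
  unhandled <- setdiff(term, c(dnodes, as.integer(zero_flux)))
  if (length(unhandled))
    stop("terminal node(s) without a pressure or zero-flux condition: ",
         paste(utils::head(unhandled, 5), collapse = ", "))

  n <- nrow(net$nodes)
  ia <- match(net$vessels$node_a, net$nodes$id)
  ib <- match(net$vessels$node_b, net$nodes$id)
  C <- poiseuille_conductance(net$vessels$radius, net$vessels$length, mu)
  A <- Matrix::sparseMatrix(i = c(ia, ib, ia, ib), j = c(ia, ib, ib, ia),
                            x = c(C, C, -C, -C), dims = c(n, n))
  drows <- match(dnodes, net$nodes$id)
  free <- setdiff(seq_len(n), drows)

  ## every free node must be reachable from a Dirichlet node
  comp <- graph_components(net)
  if (!all(comp[free] %in% comp[drows]))
    stop("disconnected component without any Dirichlet node")

  p <- numeric(n)
  p[drows] <- as.numeric(dirichlet)
  if (length(free)) {
    Aff <- A[free, free, drop = FALSE]
    rhs <- -A[free, drows, drop = FALSE] %*% p[drows]
    p[free] <- as.numeric(Matrix::solve(Matrix::forceSymmetric(Aff), rhs))
  }
  q <- C * (p[ia] - p[ib])

  deg <- node_degree(net)
  imbalance <- numeric(n)
  agg_in <- tapply(q, ib, sum); agg_out <- tapply(q, ia, sum)
  imbalance[as.integer(names(agg_in))] <-
    imbalance[as.integer(names(agg_in))] + agg_in
  imbalance[as.integer(names(agg_out))] <-
    imbalance[as.integer(names(agg_out))] - agg_out
  internal_free <- intersect(which(deg > 1L), free)
  res <- if (length(internal_free) && max(abs(q)) > 0)
    max(abs(imbalance[internal_free])) / max(abs(q)) else 0

  structure(list(pressure = stats::setNames(p, net$nodes$id),
                 flux = stats::setNames(q, net$vessels$id),
                 mu = mu, mass_residual = res),
            class = "network_flow")
}

#' @export
print.network_flow <- function(x, ...) {
  cat("<network_flow> ", length(x$pressure), " nodal pressures, ",
      length(x$flux), " vessel fluxes\n", sep = "")
  cat("  pressure range [Pa]: ",
      paste(signif(range(x$pressure), 5), collapse = " - "), "\n", sep = "")
  cat("  junction mass residual (rel.): ", format(x$mass_residual), "\n",
      sep = "")
  invisible(x)
}

#' Standard tree boundary conditions
#'
#' Root node at the inlet pressure, all terminal nodes at the outlet
#' pressure; individual terminals can be overridden (used for the
#' boundary-condition robustness sweep, which raises the outlets inside a
#' subregion).
#'
#' @param net a rooted `vascular_network`.
#' @param root_pressure inlet pressure, Pa (default 13.3 kPa).
#' @param terminal_pressure outlet pressure, Pa (default 8 kPa).
#' @param override named numeric vector (node id -> Pa) replacing selected
#'   terminal pressures.
#' @return named pressure vector suitable for [solve_network_flow()].
#' @export
tree_boundary_conditions <- function(net, root_pressure = 13300,
                                     terminal_pressure = 8000,
                                     override = NULL) {
  term <- terminal_nodes(net)
  bc <- stats::setNames(c(root_pressure, rep(terminal_pressure,
                                             length(term))),
                        c(net$root_id, term))
  if (!is.null(override)) bc[names(override)] <- override
  bc
}
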