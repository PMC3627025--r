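#' Vascular network objects
#'
#' A `vascular_network` couples a node table (positions in mm, nodal radii in
#' mm) with a vessel table (directed segments `node_a -> node_b`, lengths,
#' radii, fluxes and compartment labels). Synthetic networks are rooted trees;
#' file-supplied networks may be general connected graphs, in which case
#' `root_id` may be `NA`.
#'
#' @param nodes data.frame with columns `id`, `x`, `y`, `z`, `radius`.
#' @param vessels data.frame with columns `id`, `node_a`, `node_b` and
#'   optionally `radius` (mm), `flux` (mm^3/s), `compartment` (integer).
#'   Vessel orientation is flow-wise: `node_a` proximal, `node_b` distal.
#' @param root_id id of the root (inlet) node, or `NA` for unrooted graphs.
#' @param domain optional 2 x 3 matrix (rows: lower, upper bounds in mm) of
#'   the tissue box the network occupies; kept as an attribute.
#' @param validate check invariants (positive radii, resolvable ids,
#'   connectivity).
#' @return object of class `vascular_network`.
#' @export
vascular_network <- function(nodes, vessels, root_id = NA_integer_,
                             domain = NULL, validate = TRUE) {
  nodes <- as.data.frame(nodes)
  vessels <- as.data.frame(vessels)
  req_n <- c("id", "x", "y", "z", "radius")
  if (!all(req_n %in% names(nodes)))
    stop("nodes table must have columns: ", paste(req_n, collapse = ", "))
  req_v <- c("id", "node_a", "node_b")
  if (!all(req_v %in% names(vessels)))
    stop("vessels table must have columns: ", paste(req_v, collapse = ", "))
  nodes$id <- as.integer(nodes$id)
  vessels$id <- as.integer(vessels$id)

  ia <- match(vessels$node_a, nodes$id)
  ib <- match(vessels$node_b, nodes$id)
  if (anyNA(ia) || anyNA(ib)) {
    bad <- unique(c(vessels$node_a[is.na(ia)], vessels$node_b[is.na(ib)]))
    stop("vessel table references missing node id(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  dx <- nodes$x[ib] - nodes$x[ia]
  dy <- nodes$y[ib] - nodes$y[ia]
  dz <- nodes$z[ib] - nodes$z[ia]
  vessels$length <- sqrt(dx^2 + dy^2 + dz^2)
  if (is.null(vessels$radius))
    vessels$radius <- (nodes$radius[ia] + nodes$radius[ib]) / 2
  if (is.null(vessels$flux)) vessels$flux <- NA_real_
  if (is.null(vessels$compartment)) vessels$compartment <- NA_integer_
  vessels$compartment <- as.integer(vessels$compartment)
  vessels$volume <- pi * vessels$radius^2 * vessels$length

  net <- structure(
    list(nodes = nodes, vessels = vessels,
         root_id = if (is.na(root_id)) NA_integer_ else as.integer(root_id)),
    class = "vascular_network")
  if (!is.null(domain)) attr(net, "domain") <- domain

  if (validate) validate_network(net)
  net
}

validate_network <- function(net) {
  nodes <- net$nodes; vessels <- net$vessels
  if (anyDuplicated(nodes$id)) stop("duplicate node ids")
  if (nrow(vessels) && anyDuplicated(vessels$id)) stop("duplicate vessel ids")
  if (!all(is.finite(as.matrix(nodes[, c("x", "y", "z")]))))
    stop("non-finite node positions")
  if (any(!is.finite(nodes$radius)) || any(nodes$radius <= 0))
    stop("nodal radii must be positive and finite")
  if (nrow(vessels)) {
    if (any(vessels$length <= 0)) stop("zero-length vessel(s) present")
    if (any(vessels$radius <= 0)) stop("vessel radii must be positive")
    comp <- graph_components(net)
    if (max(comp) > 1L) stop("network is disconnected")
  }
  if (!is.na(net$root_id) && !(net$root_id %in% nodes$id))
    stop("root_id is not a node id")
  invisible(net)
}

## connected components by label propagation over the node-vessel graph
graph_components <- function(net) {
  n <- nrow(net$nodes)
  ia <- match(net$vessels$node_a, net$nodes$id)
  ib <- match(net$vessels$node_b, net$nodes$id)
  comp <- rep(NA_integer_, n)
  adj <- adjacency_list(n, ia, ib)
  cid <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cid <- cid + 1L
    queue <- s; comp[s] <- cid
    while (length(queue)) {
      v <- queue[[1L]]; queue <- queue[-1L]
      for (e in adj[[v]]) {
        other <- if (ia[e] == v) ib[e] else ia[e]
        if (is.na(comp[other])) { comp[other] <- cid; queue <- c(queue, other) }
      }
    }
  }
  comp
}

adjacency_list <- function(n_nodes, ia, ib) {
  adj <- vector("list", n_nodes)
  es <- c(seq_along(ia), seq_along(ib))
  vs <- c(ia, ib)
  sp <- split(es, vs)
  adj[as.integer(names(sp))] <- sp
  adj
}

#' Node degrees and kinds
#'
#' @param net a `vascular_network`.
#' @return integer degree vector / character kind vector aligned with the
#'   node table (`root`, `terminal`, `internal`).
#' @export
node_degree <- function(net) {
  ia <- match(net$vessels$node_a, net$nodes$id)
  ib <- match(net$vessels$node_b, net$nodes$id)
  tabulate(c(ia, ib), nbins = nrow(net$nodes))
}

#' @rdname node_degree
#' @export
node_kind <- function(net) {
  deg <- node_degree(net)
  kind <- ifelse(deg == 1L, "terminal", "internal")
  if (!is.na(net$root_id)) kind[match(net$root_id, net$nodes$id)] <- "root"
  kind
}

#' Terminal node ids (degree-one nodes, excluding the root)
#' @param net a `vascular_network`.
#' @export
terminal_nodes <- function(net) {
  net$nodes$id[node_kind(net) == "terminal"]
}

is_tree <- function(net) {
  nrow(net$vessels) == nrow(net$nodes) - 1L
}

#' @export
print.vascular_network <- function(x, ...) {
  cat("<vascular_network> ", nrow(x$nodes), " nodes, ", nrow(x$vessels),
      " vessels", if (is_tree(x)) " (tree)" else "", "\n", sep = "")
  cat("  radius range [mm]: ",
      paste(signif(range(x$vessels$radius), 4), collapse = " - "), "\n",
      sep = "")
  if (!is.na(x$root_id)) cat("  root node id: ", x$root_id, "\n", sep = "")
  ncpt <- x$vessels$compartment
  if (!all(is.na(ncpt)))
    cat("  compartments: ", paste(sort(unique(ncpt)), collapse = ", "),
        "\n", sep = "")
  invisible(x)
}

## Orient a rooted tree flow-wise (node_a proximal). Returns the network with
## vessels possibly flipped, plus parent/child structure as attributes.
## Errors on cycles or if no root is set.
orient_from_root <- function(net) {
  if (is.na(net$root_id)) stop("network has no root node")
  if (!is_tree(net))
    stop("unsupported topology: network contains cycles (|vessels| != |nodes| - 1); ",
         "looped networks are out of scope")
  n <- nrow(net$nodes)
  ia <- match(net$vessels$node_a, net$nodes$id)
  ib <- match(net$vessels$node_b, net$nodes$id)
  adj <- adjacency_list(n, ia, ib)
  root <- match(net$root_id, net$nodes$id)
  seen <- logical(n)
  order_nodes <- integer(0)
  parent_edge <- rep(NA_integer_, n)   # vessel row leading into each node
  queue <- root; seen[root] <- TRUE
  flip <- logical(nrow(net$vessels))
  while (length(queue)) {
    v <- queue[[1L]]; queue <- queue[-1L]
    order_nodes <- c(order_nodes, v)
    for (e in adj[[v]]) {
      other <- if (ia[e] == v) ib[e] else ia[e]
      if (seen[other]) {
        if (!identical(e, parent_edge[v]))
          stop("unsupported topology: cycle detected")
        next
      }
      seen[other] <- TRUE
      parent_edge[other] <- e
      if (ib[e] == v) flip[e] <- TRUE   # stored distal->proximal; flip
      queue <- c(queue, other)
    }
  }
  if (!all(seen)) stop("network is disconnected")
  if (any(flip)) {
    tmp <- net$vessels$node_a[flip]
    net$vessels$node_a[flip] <- net$vessels$node_b[flip]
    net$vessels$node_b[flip] <- tmp
    net$vessels$flux[flip] <- -net$vessels$flux[flip]
  }
  attr(net, "bfs_order") <- order_nodes
  attr(net, "parent_edge") <- parent_edge
  net
}

#' Read / write a vascular network as node and edge tables
#'
#' Networks are stored as two comma-separated tables with one-line headers:
#' `nodes.csv` (`id,x,y,z,radius`) and `edges.csv`
#' (`id,node_a,node_b[,radius,flux,compartment]`). Ids are 0-based integers;
#' all lengths are in mm, fluxes in mm^3/s.
#'
#' @param path directory holding (or to hold) `nodes.csv` and `edges.csv`.
#' @param root_id optional root node id. On read, when omitted and the
#'   network is a tree, the degree-one node attached to the widest vessel is
#'   taken as the inlet.
#' @return `read_network` returns a `vascular_network`; `write_network`
#'   returns the path invisibly.
#' @export
read_network <- function(path, root_id = NULL) {
  nf <- file.path(path, "nodes.csv")
  ef <- file.path(path, "edges.csv")
  if (!file.exists(nf) || !file.exists(ef))
    stop("expected ", nf, " and ", ef)
  nodes <- utils::read.csv(nf)
  edges <- utils::read.csv(ef)
  if (is.null(root_id)) {
    root_id <- NA_integer_
    if (nrow(edges) == nrow(nodes) - 1L && nrow(edges) > 0L) {
      deg <- tabulate(match(c(edges$node_a, edges$node_b), nodes$id),
                      nbins = nrow(nodes))
      term <- which(deg == 1L)
      if (length(term)) {
        r_in <- vapply(term, function(i) {
          id <- nodes$id[i]
          e <- edges$node_a == id | edges$node_b == id
          if (!is.null(edges$radius)) max(edges$radius[e]) else nodes$radius[i]
        }, numeric(1))
        root_id <- nodes$id[term[which.max(r_in)]]
      }
    }
  }
  vascular_network(nodes, edges, root_id = root_id)
}

#' @param net a `vascular_network` to write.
#' @rdname read_network
#' @export
write_network <- function(net, path) {
  if (nrow(net$vessels) == 0L) stop("refusing to write a network with no vessels")
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  nn <- net$nodes[, c("id", "x", "y", "z", "radius")]
  ee <- net$vessels[, c("id", "node_a", "node_b", "radius", "flux",
                        "compartment")]
  fmt <- function(df) {
    for (j in seq_along(df))
      if (is.double(df[[j]])) df[[j]] <- formatC(df[[j]], digits = 17,
                                                 format = "g")
    df
  }
  utils::write.csv(fmt(nn), file.path(path, "nodes.csv"), row.names = FALSE,
                   quote = FALSE)
  utils::write.csv(fmt(ee), file.path(path, "edges.csv"), row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Hierarchic parameter field
#'
#' The hierarchic parameter zeta orders a rooted tree from inlet to
#' periphery: zeta at a node is the summed length of all vessels distal to
#' that node divided by the total vessel length of the network, so the root
#' has zeta = 1 and every distal terminal has zeta = 0. The per-vessel value
#' is the arithmetic mean of its two endpoint values and is what the
#' compartment partition operates on.
#'
#' @param net a rooted `vascular_network` that is a tree (acyclic). Looped
#'   networks are rejected.
#' @return object of class `hierarchic_field`: list with `zeta_node` (named
#'   by node id) and `zeta_vessel` (named by vessel id).
#' @export
compute_zeta <- function(net) {
  net <- orient_from_root(net)
  ord <- attr(net, "bfs_order")
  pe <- attr(net, "parent_edge")
  ia <- match(net$vessels$node_a, net$nodes$id)
  ib <- match(net$vessels$node_b, net$nodes$id)
  len <- net$vessels$length
  total <- sum(len)
  distal <- numeric(nrow(net$nodes))
  for (v in rev(ord)) {
    e <- pe[v]
    if (!is.na(e)) {
      p <- ia[e]
      distal[p] <- distal[p] + distal[v] + len[e]
    }
  }
  zn <- distal / total
  zv <- (zn[ia] + zn[ib]) / 2
  structure(list(zeta_node = stats::setNames(zn, net$nodes$id),
                 zeta_vessel = stats::setNames(zv, net$vessels$id)),
            class = "hierarchic_field")
}

#' Partition vessels into compartments by hierarchic parameter
#'
#' Given a strictly decreasing partition vector `Z` with `Z[1] = 1` and
#' `Z[N+1] = 0`, compartment `i` collects the vessels whose mean zeta lies in
#' `[Z[i+1], Z[i])`; a vessel with mean zeta exactly 1 goes to compartment 1.
#' Compartment 1 is therefore the most proximal (largest vessels).
#'
#' @param net a `vascular_network`.
#' @param hier a `hierarchic_field` from [compute_zeta()].
#' @param Z numeric partition vector of length N+1, strictly decreasing from
#'   1 to 0.
#' @return integer compartment labels (1..N) named by vessel id.
#' @export
partition_by_zeta <- function(net, hier, Z) {
  check_partition_vector(Z)
  zv <- hier$zeta_vessel[as.character(net$vessels$id)]
  N <- length(Z) - 1L
  if (N == 1L) {
    comp <- rep(1L, length(zv))
  } else {
    interior <- Z[2:N]
    comp <- 1L + as.integer(colSums(outer(interior, zv, `>`)))
  }
  stats::setNames(comp, net$vessels$id)
}

check_partition_vector <- function(Z) {
  if (length(Z) < 2L || any(diff(Z) >= 0))
    stop("Z must be strictly decreasing")
  if (abs(Z[1] - 1) > 1e-12 || abs(Z[length(Z)]) > 1e-12)
    stop("Z must run from 1 to 0")
  invisible(Z)
}

#' Store compartment labels on the vessel table
#' @param net a `vascular_network`.
#' @param labels integer labels named by vessel id (as returned by
#'   [partition_by_zeta()]), or an unnamed vector in vessel-table order.
#' @export
set_compartments <- function(net, labels) {
  if (!is.null(names(labels)))
    labels <- labels[as.character(net$vessels$id)]
  net$vessels$compartment <- as.integer(labels)
  net
}

#' Derive partition targets from compartment proportions
#'
#' For networks whose radii do not span the full arteriole-to-capillary
#' range (e.g. generated test trees), sensible target mean radii for
#' [optimise_partition()] can be derived from the network itself: vessels
#' are ordered proximal-to-distal by mean zeta, split into groups of the
#' given proportions, and each group's mean radius becomes the target.
#' The default proportions (4 / 46 / 50 %) mirror the compartment sizes
#' typical of a three-compartment arterial partition.
#'
#' @param net a `vascular_network`.
#' @param hier a `hierarchic_field`.
#' @param proportions fractions per compartment, summing to 1, proximal
#'   first.
#' @return strictly decreasing target radii, mm.
#' @export
derive_partition_targets <- function(net, hier,
                                     proportions = c(0.04, 0.46, 0.50)) {
  stopifnot(abs(sum(proportions) - 1) < 1e-9)
  zv <- hier$zeta_vessel[as.character(net$vessels$id)]
  o <- order(zv, decreasing = TRUE)
  n <- length(o)
  cuts <- c(0, round(cumsum(proportions) * n))
  cuts[length(cuts)] <- n
  g <- cut(seq_len(n), cuts)
  targets <- as.numeric(tapply(net$vessels$radius[o], g, mean))
  if (any(diff(targets) >= 0))
    stop("derived targets are not strictly decreasing; ",
         "supply explicit targets")
  targets
}

#' Optimise the partition vector for target mean radii
#'
#' Searches interior entries of the partition vector Z so that the mean
#' vessel radius of each compartment is as close as possible (root mean
#' square) to the requested targets. The search is a deterministic coarse
#' grid over candidate thresholds (the observed per-vessel zeta values)
#' followed by coordinate-wise refinement over the full candidate set; ties
#' resolve toward larger Z entries.
#'
#' @param net a `vascular_network`.
#' @param hier a `hierarchic_field`.
#' @param target_mean_radii strictly decreasing target mean radii (mm), one
#'   per compartment.
#' @param coarse number of candidate quantiles per coordinate in the coarse
#'   pass.
#' @return partition vector Z (length N+1).
#' @export
optimise_partition <- function(net, hier, target_mean_radii, coarse = 40L) {
  targets <- as.numeric(target_mean_radii)
  N <- length(targets)
  if (N >= 2L && any(diff(targets) >= 0))
    stop("target radii must be strictly decreasing")
  if (N == 1L) return(c(1, 0))
  zv <- hier$zeta_vessel[as.character(net$vessels$id)]
  rv <- net$vessels$radius
  if (length(unique(zv)) < N)
    stop("infeasible partition: fewer distinct zeta values than compartments")
  cand <- sort(unique(zv), decreasing = TRUE)
  cand <- cand[cand > 0 & cand < 1]

  ## prefix sums over vessels sorted by decreasing zeta: compartments are
  ## contiguous runs, so interval mean radii come from cumulative sums
  o <- order(zv, decreasing = TRUE)
  zs <- zv[o]
  cr <- cumsum(rv[o]); cn <- seq_along(o)
  ## number of vessels with zeta >= t  (threshold t includes its own vessel)
  n_ge <- function(t) findInterval(-t, -zs)
  cost_of <- function(th) {        # th: decreasing interior thresholds
    cuts <- c(0L, vapply(th, n_ge, integer(1)), length(o))
    if (any(diff(cuts) <= 0L)) return(Inf)
    sr <- diff(c(0, cr[cuts[-1L]]))
    nr <- diff(cuts)
    means <- sr / nr
    sqrt(mean((means - targets)^2))
  }

  pick <- function(v, k) v[unique(pmax(1L, round(seq(1, length(v),
                                                     length.out = k))))]
  coarse_cand <- pick(cand, min(coarse, length(cand)))
  ## coarse pass: exhaustive over ordered combinations of coarse candidates
  best <- NULL; best_cost <- Inf
  combos <- utils::combn(seq_along(coarse_cand), N - 1L)
  for (j in seq_len(ncol(combos))) {
    th <- coarse_cand[combos[, j]]       # already decreasing
    cst <- cost_of(th)
    if (cst < best_cost) { best_cost <- cst; best <- th }
  }
  ## coordinate-wise refinement over the full candidate set (descending order
  ## with strict improvement keeps the largest-threshold tie-break)
  repeat {
    improved <- FALSE
    for (i in seq_len(N - 1L)) {
      lo <- if (i < N - 1L) best[i + 1L] else 0
      hi <- if (i > 1L) best[i - 1L] else 1
      for (t in cand[cand > lo & cand < hi]) {
        th <- best; th[i] <- t
        cst <- cost_of(th)
        if (cst < best_cost - 1e-15) {
          best_cost <- cst; best <- th; improved <- TRUE
        }
      }
    }
    if (!improved) break
  }
  c(1, best, 0)
}
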