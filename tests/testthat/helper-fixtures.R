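## Small fixture networks built in code.

## straight two-node network: one vessel of given length along x
single_vessel <- function(l = 1, r = 0.001) {
  nodes <- data.frame(id = 0:1, x = c(0, l), y = 0, z = 0, radius = r)
  edges <- data.frame(id = 0L, node_a = 0L, node_b = 1L)
  vascular_network(nodes, edges, root_id = 0L,
                   domain = cbind(c(-l, 2 * l), c(-l, l), c(-l, l)))
}

## symmetric Y: root -> junction, junction -> two terminals, all length L
y_network <- function(L = 1, r = 0.001) {
  s <- L / sqrt(2)
  nodes <- data.frame(id = 0:3,
                      x = c(0, L, L + s, L + s),
                      y = c(0, 0, s, -s),
                      z = 0, radius = r)
  edges <- data.frame(id = 0:2, node_a = c(0L, 1L, 1L),
                      node_b = c(1L, 2L, 3L))
  vascular_network(nodes, edges, root_id = 0L,
                   domain = cbind(c(-1, 3), c(-2, 2), c(-1, 1)))
}

## random rooted tree with given node count: each new node attaches to a
## uniformly chosen existing node, at a random position
random_tree <- function(n_nodes, seed = 1, box = 1) {
  set.seed(seed)
  pos <- matrix(runif(3, -box, box), 1, 3)
  parent <- NA_integer_
  for (i in 2:n_nodes) {
    p <- sample.int(i - 1L, 1L)
    parent <- c(parent, p)
    pos <- rbind(pos, pos[p, ] + runif(3, -box / 4, box / 4))
  }
  nodes <- data.frame(id = seq_len(n_nodes) - 1L, x = pos[, 1], y = pos[, 2],
                      z = pos[, 3],
                      radius = runif(n_nodes, 0.001, 0.01))
  edges <- data.frame(id = seq_len(n_nodes - 1L) - 1L,
                      node_a = parent[-1L] - 1L,
                      node_b = seq(2L, n_nodes) - 1L)
  vascular_network(nodes, edges, root_id = 0L,
                   domain = cbind(c(-2 * box, 2 * box), c(-2 * box, 2 * box),
                                  c(-2 * box, 2 * box)))
}

## independent depth-first oracle for the hierarchic parameter
zeta_oracle <- function(net) {
  ia <- match(net$vessels$node_a, net$nodes$id)
  ib <- match(net$vessels$node_b, net$nodes$id)
  children <- split(seq_len(nrow(net$vessels)), ia)
  total <- sum(net$vessels$length)
  subtree <- function(node_row) {
    es <- children[[as.character(node_row)]]
    if (is.null(es)) return(0)
    sum(vapply(es, function(e) net$vessels$length[e] + subtree(ib[e]),
               numeric(1)))
  }
  zn <- vapply(seq_len(nrow(net$nodes)), subtree, numeric(1)) / total
  list(zeta_node = setNames(zn, net$nodes$id),
       zeta_vessel = setNames((zn[ia] + zn[ib]) / 2, net$vessels$id))
}

## tree-appropriate partition targets (package helper, aliased for tests)
proportion_targets <- function(net, hier) derive_partition_targets(net, hier)
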