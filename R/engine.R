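# Internal likelihood engine shared by the sampler and the closed-form
# helpers: a postorder, strictly bifurcating representation of the tree
# together with the bookkeeping needed for clade rate scalars.

vr_engine <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  validate_tree(tree)
  if (!ape::is.binary.phylo(tree)) tree <- ape::multi2di(tree, random = FALSE)
  tree <- stats::reorder(tree, "postorder")
  n <- length(tree$tip.label)
  E <- nrow(tree$edge)
  root <- n + 1L
  edge <- tree$edge
  storage.mode(edge) <- "integer"

  # edges in the subtree of each node, including the node's stem edge
  # (postorder: a node's stem is visited after everything beneath it)
  below <- vector("list", n + tree$Nnode)
  eid <- integer(n + tree$Nnode)            # stem edge index per node
  for (e in seq_len(E)) {
    u <- edge[e, 1L]; v <- edge[e, 2L]
    below[[v]] <- c(below[[v]], e)
    below[[u]] <- c(below[[u]], below[[v]])
    eid[v] <- e
  }
  internal <- (n + 1L):(n + tree$Nnode)
  clade_nodes <- setdiff(internal, root)

  # tip x edge path incidence: P[i, e] = 1 iff edge e lies on root -> tip i
  parent <- integer(n + tree$Nnode)
  parent[edge[, 2L]] <- edge[, 1L]
  P <- matrix(0, n, E)
  for (i in seq_len(n)) {
    v <- i
    while (v != root) { P[i, eid[v]] <- 1; v <- parent[v] }
  }

  list(tree = tree, n = n, E = E, edge = edge, elen = tree$edge.length,
       root = root, below = below, eid = eid, clade_nodes = clade_nodes,
       path = P)
}

# whitened representation of data matrix M (rows in engine tip order)
engine_whiten <- function(eng, M, lambda = 1, scalars = NULL,
                          ridge = NULL) {
  len <- if (is.null(scalars)) eng$elen else eng$elen * scalars
  if (is.null(ridge)) {
    H <- sum(len) / eng$n            # rough mean depth scale
    ridge <- 1e-10 * max(H, .Machine$double.eps)
  }
  .whiten_bm(eng$edge, len, lambda, eng$n, as.matrix(M), ridge)
}

# covariance matrix from an engine and per-edge scaled lengths
engine_cov <- function(eng, lambda = 1, scalars = NULL) {
  w <- if (is.null(scalars)) eng$elen else eng$elen * scalars
  V <- eng$path %*% (w * t(eng$path))
  if (lambda != 1) {
    d <- diag(V)
    V <- lambda * V
    diag(V) <- d
  }
  dimnames(V) <- list(eng$tree$tip.label, eng$tree$tip.label)
  V
}

# per-edge effective scalar implied by a placement list
effective_scalars <- function(eng, placements) {
  s <- rep(1, eng$E)
  for (pl in placements) {
    idx <- if (pl$type == "branch") pl$target else eng$below[[pl$target]]
    s[idx] <- s[idx] * pl$r
  }
  s
}
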