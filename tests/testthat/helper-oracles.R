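# Brute-force oracles written with plain matrix algebra, deliberately
# independent of the package's pruning code path.

oracle_gls <- function(y, X, V) {
  X <- as.matrix(X)
  Vi <- solve(V)
  XtVi <- t(X) %*% Vi
  b <- solve(XtVi %*% X, XtVi %*% y)
  r <- y - X %*% b
  s2 <- drop(t(r) %*% Vi %*% r) / length(y)
  ld <- as.numeric(determinant(V, logarithm = TRUE)$modulus)
  list(coefficients = drop(b), sigma2 = s2,
       logLik = -0.5 * length(y) * log(2 * pi * s2) - 0.5 * ld -
         0.5 * length(y))
}

# joint ML ancestral states: minimise sum over edges of
# (x_child - x_parent)^2 / length, a weighted-Laplacian linear system
oracle_anc <- function(tree, x) {
  tree <- stats::reorder(tree, "postorder")
  n <- length(tree$tip.label)
  m <- tree$Nnode
  A <- matrix(0, m, m)
  bvec <- numeric(m)
  for (e in seq_len(nrow(tree$edge))) {
    u <- tree$edge[e, 1] - n
    v <- tree$edge[e, 2]
    w <- 1 / tree$edge.length[e]
    A[u, u] <- A[u, u] + w
    if (v <= n) {
      bvec[u] <- bvec[u] + w * x[v]
    } else {
      vv <- v - n
      A[u, vv] <- A[u, vv] - w
      A[vv, u] <- A[vv, u] - w
      A[vv, vv] <- A[vv, vv] + w
    }
  }
  stats::setNames(drop(solve(A, bvec)), (n + 1):(n + m))
}

# closed-form log marginal likelihood of the conjugate normal-mean model
# y ~ N(alpha 1, s0 I), alpha ~ N(0, tau^2)
oracle_conjugate_logml <- function(y, s0, tau) {
  n <- length(y)
  V <- diag(s0, n) + tau^2
  ch <- chol(V)
  w <- backsolve(ch, y, transpose = TRUE)
  -0.5 * n * log(2 * pi) - sum(log(diag(ch))) - 0.5 * sum(w^2)
}

# random tree with strictly positive branch lengths
rtree_pos <- function(n) {
  tr <- ape::rtree(n)
  tr$edge.length <- tr$edge.length + 0.1
  tr
}

# star phylogeny (identity covariance with unit branch lengths)
star_tree <- function(n) {
  tr <- ape::stree(n, "star")
  tr$edge.length <- rep(1, n)
  tr$tip.label <- sprintf("sp%03d", seq_len(n))
  tr
}

# minimal dataset wrapper for a response vector on a tree
ds_simple <- function(tree, y, lat = NULL) {
  trait_dataset(
    data.frame(species = tree$tip.label, response = as.numeric(y)),
    data.frame(species = tree$tip.label,
               latitude = if (is.null(lat)) rep(0, length(y)) else lat))
}
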