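# Closed-form Brownian-motion machinery: phylogenetic covariance with
# Pagel's lambda and rate scalars, GLS estimation, independent contrasts,
# ancestral states, R^2, VIFs and effect-size conversion.

#' Phylogenetic covariance matrix under Brownian motion
#'
#' `V[i, j]` is the shared root-to-MRCA path length of tips i and j on the
#' (optionally rate-scaled) tree, multiplied by Pagel's lambda off the
#' diagonal; `V[i, i]` is the scaled root-to-tip length. Branch b
#' contributes `length(b) * scalar(b)` to every path through it.
#'
#' @param tree a rooted [ape::phylo] with branch lengths (Myr).
#' @param lambda Pagel's lambda in `[0, 1]`; scales off-diagonals only.
#' @param scalars optional positive per-edge multipliers, one per row of
#'   `tree$edge` (default 1 everywhere).
#' @return an n x n covariance matrix with tip labels as dimnames and
#'   attributes `lambda` and `scalars`.
#' @export
phylo_covariance <- function(tree, lambda = 1, scalars = NULL) {
  stopifnot(inherits(tree, "phylo"))
  validate_tree(tree)
  if (!is.numeric(lambda) || length(lambda) != 1 || lambda < 0 || lambda > 1)
    stop("lambda must be a single value in [0, 1]")
  if (!is.null(scalars)) {
    if (length(scalars) != nrow(tree$edge))
      stop("scalars must have one entry per edge")
    if (any(!is.finite(scalars)) || any(scalars <= 0))
      stop("scalars must be positive")
  }
  tree2 <- tree
  if (!is.null(scalars)) tree2$edge.length <- tree2$edge.length * scalars
  n <- length(tree2$tip.label)
  depth <- node_depths(tree2)
  M <- ape::mrca(tree2)
  V <- matrix(depth[M], n, n, dimnames = list(tree2$tip.label, tree2$tip.label))
  diag(V) <- depth[seq_len(n)]
  if (lambda != 1) {
    d <- diag(V)
    V <- lambda * V
    diag(V) <- d
  }
  attr(V, "lambda") <- lambda
  attr(V, "scalars") <- scalars
  V
}

node_depths <- function(tree) {
  tree <- stats::reorder(tree, "postorder")
  ntot <- length(tree$tip.label) + tree$Nnode
  depth <- numeric(ntot)
  for (e in rev(seq_len(nrow(tree$edge))))
    depth[tree$edge[e, 2L]] <- depth[tree$edge[e, 1L]] + tree$edge.length[e]
  depth
}

chol_or_ridge <- function(V) {
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) {
    r <- 1e-10 * mean(diag(V))
    warning("singular phylogenetic covariance; adding ridge ",
            format(r, digits = 3), " to the diagonal")
    ch <- chol(V + diag(r, nrow(V)))
  }
  ch
}

#' Phylogenetic generalised least squares fit
#'
#' Closed-form GLS: `b = (X' V^-1 X)^-1 X' V^-1 y`, with the residual rate
#' `sigma2 = r' V^-1 r / n` (trait variance per Myr) and the multivariate
#' normal log density of `y` evaluated at these values. A singular `V` is
#' ridge-regularised with a logged warning.
#'
#' @param y numeric response vector (log10 scale in the intended use).
#' @param X design matrix (include an intercept column explicitly; see
#'   [design_matrix()]).
#' @param V phylogenetic covariance, e.g. from [phylo_covariance()].
#' @return list with `coefficients`, `sigma2`, `logLik`, `fitted`,
#'   `residuals`, of class `gls_fit`.
#' @export
gls_fit <- function(y, X, V) {
  X <- as.matrix(X)
  n <- length(y)
  stopifnot(nrow(X) == n, nrow(V) == n, ncol(V) == n)
  ch <- chol_or_ridge(V)
  Wy <- backsolve(ch, y, transpose = TRUE)
  WX <- backsolve(ch, X, transpose = TRUE)
  qx <- qr(WX)
  if (qx$rank < ncol(WX)) {
    bad <- colnames(X)[qx$pivot[seq(qx$rank + 1L, ncol(WX))]]
    stop("rank-deficient design; offending columns: ",
         paste(bad, collapse = ", "))
  }
  b <- qr.coef(qx, Wy)
  rw <- Wy - WX %*% b
  sigma2 <- sum(rw^2) / n
  logdet <- 2 * sum(log(diag(ch)))
  logLik <- if (sigma2 > 0)
    -0.5 * n * log(2 * pi * sigma2) - 0.5 * logdet - 0.5 * n else Inf
  fit <- drop(X %*% b)
  structure(list(coefficients = setNames(drop(b), colnames(X)),
                 sigma2 = sigma2, logLik = logLik, fitted = fit,
                 residuals = y - fit, n = n),
            class = "gls_fit")
}

#' @export
print.gls_fit <- function(x, ...) {
  cat("Phylogenetic GLS fit (n =", x$n, ")\n")
  print(round(x$coefficients, 6))
  cat("sigma2 =", format(x$sigma2, digits = 6),
      " logLik =", format(x$logLik, digits = 8), "\n")
  invisible(x)
}

#' Phylogenetic independent contrasts
#'
#' Standardised contrasts by Felsenstein pruning on a (possibly
#' deterministically resolved) bifurcating tree. The through-origin
#' regression of response contrasts on predictor contrasts equals the GLS
#' slope with lambda = 1.
#'
#' @param tree a rooted [ape::phylo].
#' @param x named numeric vector of tip values.
#' @return numeric vector of `n - 1` standardised contrasts with
#'   attributes `root_estimate`, `root_variance` and `logdet`.
#' @export
independent_contrasts <- function(tree, x) {
  eng <- vr_engine(tree)
  x <- align_tip_values(x, eng$tree$tip.label)
  wh <- engine_whiten(eng, matrix(x, ncol = 1), lambda = 1)
  out <- wh$W[seq_len(eng$n - 1L), 1L]
  attr(out, "root_estimate") <- wh$root[1L]
  attr(out, "root_variance") <- wh$root_var
  attr(out, "logdet") <- wh$logdet
  out
}

align_tip_values <- function(x, tips) {
  if (is.null(names(x))) {
    if (length(x) != length(tips)) stop("tip values do not match tree tips")
    return(as.numeric(x))
  }
  names(x) <- normalize_taxa(names(x))
  miss <- setdiff(tips, names(x))
  if (length(miss)) stop("missing tip values for: ", paste(miss, collapse = ", "))
  as.numeric(x[tips])
}

#' Maximum-likelihood ancestral states under Brownian motion
#'
#' For every internal node, the ML (equivalently GLS/BLUP) state; the root
#' state is the GLS phylogenetic mean `(1' V^-1 1)^-1 1' V^-1 x`.
#'
#' @param tree a rooted [ape::phylo].
#' @param x named numeric vector with one value per tip (multi-occurrence
#'   species must be reduced beforehand).
#' @return numeric vector of states named by internal node number.
#' @export
ancestral_states <- function(tree, x) {
  stopifnot(inherits(tree, "phylo"))
  n <- length(tree$tip.label)
  x <- align_tip_values(x, tree$tip.label)
  depth <- node_depths(tree)
  Mfull <- ape::mrca(tree, full = TRUE)
  ids <- (n + 1L):(n + tree$Nnode)
  Vtt <- matrix(depth[Mfull[seq_len(n), seq_len(n)]], n, n)
  diag(Vtt) <- depth[seq_len(n)]
  Cat <- matrix(depth[Mfull[ids, seq_len(n), drop = FALSE]],
                length(ids), n)
  ch <- chol_or_ridge(Vtt)
  iv1 <- backsolve(ch, backsolve(ch, rep(1, n), transpose = TRUE))
  mu <- sum(iv1 * x) / sum(iv1)
  ivr <- backsolve(ch, backsolve(ch, x - mu, transpose = TRUE))
  setNames(mu + drop(Cat %*% ivr), ids)
}

#' Coefficient of determination for a (possibly sampled) PGLS fit
#'
#' `R^2 = 1 - SSE/SST` on data whitened by the inverse Cholesky factor of
#' `V`, with SST taken about the GLS phylogenetic mean. Evaluated at
#' arbitrary (for instance posterior-sampled, hence non-optimal)
#' coefficients, so it may be negative.
#'
#' @param y response vector.
#' @param X design matrix.
#' @param V phylogenetic covariance.
#' @param coefficients coefficient vector at which to evaluate the fit.
#' @return a single numeric value; `NA` (with a warning) if the whitened
#'   response is constant so that SST is zero.
#' @export
r_squared <- function(y, X, V, coefficients) {
  X <- as.matrix(X)
  ch <- chol_or_ridge(V)
  Wy <- backsolve(ch, y, transpose = TRUE)
  W1 <- backsolve(ch, rep(1, length(y)), transpose = TRUE)
  mu <- sum(W1 * Wy) / sum(W1^2)
  sst <- sum((Wy - mu * W1)^2)
  if (sst < 1e-12 * max(1, sum(Wy^2))) {
    warning("whitened response is constant; R^2 undefined")
    return(NA_real_)
  }
  WX <- backsolve(ch, X, transpose = TRUE)
  sse <- sum((Wy - WX %*% coefficients)^2)
  1 - sse / sst
}

#' Variance inflation factors under a phylogenetic covariance
#'
#' `VIF_j = 1 / (1 - R^2_j)` where `R^2_j` comes from GLS-regressing
#' column j on all remaining columns (data whitened by `V`). Values above
#' 10 conventionally flag problematic multicollinearity. A perfectly
#' collinear column yields `Inf`.
#'
#' @param X design matrix; a column named `"(Intercept)"` (or constant
#'   column) is used as the regression intercept and gets no VIF itself.
#' @param V covariance matrix; identity if `NULL`.
#' @return named numeric vector of VIFs for the non-intercept columns.
#' @export
vif <- function(X, V = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (is.null(V)) V <- diag(n)
  ch <- chol_or_ridge(V)
  WX <- backsolve(ch, X, transpose = TRUE)
  colnames(WX) <- colnames(X)
  isint <- apply(X, 2, function(col) all(col == col[1]))
  if (!any(isint)) {
    WX <- cbind(`(Intercept)` = backsolve(ch, rep(1, n), transpose = TRUE), WX)
    isint <- c(TRUE, isint)
  }
  targets <- which(!isint)
  if (length(targets) < 2L) stop("need at least two non-intercept columns")
  out <- vapply(targets, function(j) {
    yj <- WX[, j]
    Xo <- WX[, -j, drop = FALSE]
    b <- qr.coef(qr(Xo), yj)
    b[is.na(b)] <- 0
    res <- yj - Xo %*% b
    wint <- WX[, which(isint)[1L]]
    muj <- sum(wint * yj) / sum(wint^2)
    sst <- sum((yj - muj * wint)^2)
    if (sst <= 0) return(Inf)
    r2 <- 1 - sum(res^2) / sst
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, 0)
  setNames(out, colnames(WX)[targets])
}

#' Percent change in the response per unit change of a predictor
#'
#' For a slope `beta` on a log10 response scale, a `delta`-unit change in
#' the predictor multiplies the expected response by `10^(beta * delta)`;
#' this returns the corresponding relative change in percent,
#' `(10^(beta * delta) - 1) * 100`. Report rounded to one decimal place
#' by convention.
#'
#' @param beta slope on the log10 response scale.
#' @param delta predictor change (default +1 unit; use -1 for a one-unit
#'   decrease).
#' @return percent change in the expected (back-transformed) response.
#' @export
percent_change_per_unit <- function(beta, delta = 1) {
  stopifnot(is.finite(beta))
  (10^(beta * delta) - 1) * 100
}
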