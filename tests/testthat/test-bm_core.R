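# Closed-form Brownian-motion machinery against hand values and
# brute-force oracles.

test_that("phylogenetic covariance reads off shared path lengths", {
  tr2 <- ape::read.tree(text = "(A:1,B:1);")
  expect_equal(unname(phylo_covariance(tr2)[1:2, 1:2]), diag(2))

  tr3 <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  V <- phylo_covariance(tr3)[c("A", "B", "C"), c("A", "B", "C")]
  expect_equal(unname(V), matrix(c(2, 1, 0, 1, 2, 0, 0, 0, 2), 3))

  Vl <- phylo_covariance(tr3, lambda = 0.5)[c("A", "B", "C"), c("A", "B", "C")]
  expect_equal(diag(Vl), diag(V))            # diagonal untouched
  expect_equal(Vl["A", "B"], 0.5)            # off-diagonals halved

  expect_error(phylo_covariance(tr3, lambda = 1.2), "lambda")
  expect_error(phylo_covariance(tr3, scalars = rep(-1, 4)), "positive")
})

test_that("covariance is symmetric PSD for random trees, lambda, scalars", {
  set.seed(7)
  for (rep in 1:12) {
    tr <- rtree_pos(sample(4:10, 1))
    lam <- runif(1)
    sc <- exp(rnorm(nrow(tr$edge), 0, 1))
    V <- phylo_covariance(tr, lam, sc)
    expect_equal(V, t(V), tolerance = 1e-12, ignore_attr = TRUE)
    expect_true(min(eigen(V, symmetric = TRUE)$values) > -1e-10)
    # cross-check the lambda/scalar construction against ape::vcv
    tr2 <- tr; tr2$edge.length <- tr2$edge.length * sc
    Va <- ape::vcv(tr2)[rownames(V), colnames(V)]
    d <- diag(Va); Va <- lam * Va; diag(Va) <- d
    expect_equal(unclass(V), Va, tolerance = 1e-10, ignore_attr = TRUE)
  }
})

test_that("GLS reduces to OLS on a star tree and is exact without noise", {
  set.seed(11)
  tr <- star_tree(20)
  x <- rnorm(20)
  y <- 1 + 2 * x + rnorm(20)
  X <- cbind(`(Intercept)` = 1, x = x)
  f <- gls_fit(y, X, phylo_covariance(tr))
  ols <- lm(y ~ x)
  expect_equal(unname(f$coefficients), unname(coef(ols)), tolerance = 1e-10)

  tr <- rtree_pos(8)
  X <- cbind(`(Intercept)` = 1, x = rnorm(8))
  b <- c(0.7, -1.3)
  f <- gls_fit(drop(X %*% b), X, phylo_covariance(tr))
  expect_equal(unname(f$coefficients), b, tolerance = 1e-9)
  expect_equal(f$sigma2, 0, tolerance = 1e-12)
})

test_that("GLS matches a brute-force matrix oracle on random trees", {
  set.seed(13)
  for (rep in 1:20) {
    n <- sample(4:10, 1)
    tr <- rtree_pos(n)
    V <- phylo_covariance(tr, lambda = runif(1))
    X <- cbind(`(Intercept)` = 1, x = rnorm(n), z = rnorm(n))
    y <- rnorm(n, sd = 2)
    f <- gls_fit(y, X, V)
    o <- oracle_gls(y, X, V)
    expect_equal(unname(f$coefficients), unname(o$coefficients),
                 tolerance = 1e-8)
    expect_equal(f$sigma2, o$sigma2, tolerance = 1e-8)
    expect_equal(f$logLik, o$logLik, tolerance = 1e-8)
  }
})

test_that("rank-deficient designs are reported with the offending column", {
  tr <- rtree_pos(6)
  X <- cbind(`(Intercept)` = 1, x = rnorm(6))
  X <- cbind(X, dup = X[, "x"])
  expect_error(gls_fit(rnorm(6), X, phylo_covariance(tr)), "dup")
})

test_that("independent contrasts match the textbook formula and ape::pic", {
  tr <- ape::read.tree(text = "(A:1,B:1);")
  expect_equal(abs(unclass(independent_contrasts(tr, c(A = 0, B = 2)))[1]),
               2 / sqrt(2))
  expect_equal(unclass(independent_contrasts(tr, c(A = 5, B = 5)))[1], 0)

  set.seed(17)
  for (rep in 1:10) {
    tr <- rtree_pos(sample(5:12, 1))
    x <- setNames(rnorm(length(tr$tip.label)), tr$tip.label)
    ours <- sort(abs(as.numeric(
      independent_contrasts(tr, x)[seq_len(length(tr$tip.label) - 1)])))
    theirs <- sort(abs(unname(ape::pic(x[tr$tip.label], tr))))
    expect_equal(ours, theirs, tolerance = 1e-8)
  }
})

test_that("through-origin PIC slope equals the lambda = 1 GLS slope", {
  set.seed(19)
  for (rep in 1:10) {
    n <- sample(6:12, 1)
    tr <- rtree_pos(n)
    x <- setNames(rnorm(n), tr$tip.label)
    y <- setNames(2 + 0.8 * x + rnorm(n), tr$tip.label)
    cx <- independent_contrasts(tr, x)[seq_len(n - 1)]
    cy <- independent_contrasts(tr, y)[seq_len(n - 1)]
    pic_slope <- sum(cx * cy) / sum(cx^2)
    V <- phylo_covariance(tr)
    f <- gls_fit(y[rownames(V)], cbind(1, x[rownames(V)]), V)
    expect_equal(pic_slope, unname(f$coefficients[2]), tolerance = 1e-8)
  }
})

test_that("ancestral states: symmetry, constancy, and the joint-GLS oracle", {
  tr <- ape::read.tree(text = "(A:1,B:1);")
  expect_equal(unname(ancestral_states(tr, c(A = 1, B = 3))), 2)

  tr <- rtree_pos(6)
  a <- ancestral_states(tr, setNames(rep(4.2, 6), tr$tip.label))
  expect_equal(unname(a), rep(4.2, tr$Nnode), tolerance = 1e-9)

  set.seed(23)
  for (rep in 1:10) {
    n <- sample(4:8, 1)
    tr <- rtree_pos(n)
    x <- setNames(rnorm(n, sd = 2), tr$tip.label)
    ours <- ancestral_states(tr, x)
    brute <- oracle_anc(tr, x[tr$tip.label])
    expect_equal(unname(ours[names(brute)]), unname(brute),
                 tolerance = 1e-8)
    if (requireNamespace("phytools", quietly = TRUE)) {
      fa <- phytools::fastAnc(tr, x)
      expect_equal(unname(ours[names(fa)]), unname(as.numeric(fa)),
                   tolerance = 1e-6)
    }
  }
})

test_that("the root state is invariant to re-rooting along a zero-length
           basal edge", {
  # the two trees place the root on either side of a zero-length basal
  # edge; every tip covariance is identical, so the root state must be too
  t1 <- ape::read.tree(text = "(((A:1,B:1):1,C:2):0,D:3);")
  t2 <- ape::read.tree(text = "((A:1,B:1):1,C:2,D:3);")
  set.seed(37)
  x <- setNames(rnorm(4), c("A", "B", "C", "D"))
  r1 <- ancestral_states(t1, x)[1]
  r2 <- ancestral_states(t2, x)[1]
  expect_equal(unname(r1), unname(r2), tolerance = 1e-8)
})

test_that("R^2 is 1 for a perfect fit and 0 at a zero slope on centred data", {
  set.seed(29)
  tr <- rtree_pos(10)
  V <- phylo_covariance(tr)
  X <- cbind(`(Intercept)` = 1, x = rnorm(10))
  b <- c(0.5, 1.5)
  y <- drop(X %*% b)
  expect_equal(r_squared(y, X, V, b), 1)

  y2 <- rnorm(10)
  mu <- oracle_gls(y2, matrix(1, 10), V)$coefficients
  expect_equal(r_squared(y2, X, V, c(mu, 0)), 0, tolerance = 1e-10)
  expect_warning(r2 <- r_squared(rep(3, 10), X, V, c(3, 0)), "undefined")
  expect_true(is.na(r2))
})

test_that("VIFs: orthogonal columns, exact collinearity, rho = 0.9, rescale", {
  set.seed(31)
  n <- 40
  z1 <- rnorm(n); z2 <- rnorm(n)
  z2 <- residuals(lm(z2 ~ z1))                       # empirically orthogonal
  X <- cbind(`(Intercept)` = 1, a = z1, b = z2)
  v <- vif(X)
  expect_equal(unname(v), c(1, 1), tolerance = 1e-8)

  Xd <- cbind(X, dup = z1)
  expect_true(is.infinite(vif(Xd)["a"]))

  # construct exact sample correlation 0.9
  u1 <- scale(z1); u2 <- scale(residuals(lm(rnorm(n) ~ z1)))
  x2 <- 0.9 * u1 + sqrt(1 - 0.81) * u2
  Xr <- cbind(`(Intercept)` = 1, a = drop(u1), b = drop(x2))
  expect_equal(unname(vif(Xr)), rep(1 / (1 - 0.81), 2), tolerance = 1e-6)

  Xs <- Xr; Xs[, "b"] <- 1000 * Xs[, "b"]
  expect_equal(vif(Xs), vif(Xr), tolerance = 1e-8)
})

test_that("percent change per unit is exact arithmetic and composes", {
  expect_equal(percent_change_per_unit(0), 0)
  for (b in c(-0.0036, 0.0097, 0.3)) {
    p <- percent_change_per_unit(b)
    q <- percent_change_per_unit(-b)
    expect_equal((1 + p / 100) * (1 + q / 100), 1, tolerance = 1e-12)
    expect_equal(percent_change_per_unit(b, delta = -1), q)
  }
})
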