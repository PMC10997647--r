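# The generators: reproducibility, Brownian scaling laws, control
# calibration, temperature gradients and the fixture registry.

test_that("generation is bit-reproducible from the seed", {
  s1 <- simulate_dataset(simulation_spec("regression", n_tips = 20, seed = 7))
  s2 <- simulate_dataset(simulation_spec("regression", n_tips = 20, seed = 7))
  expect_identical(s1$dataset, s2$dataset)
  expect_identical(ape::write.tree(s1$tree), ape::write.tree(s2$tree))

  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  p1 <- make_fixture("ursid8", d1); p2 <- make_fixture("ursid8", d2)
  expect_identical(readLines(p1["traits"]), readLines(p2["traits"]))
  expect_identical(readLines(p1["tree"]), readLines(p2["tree"]))
})

test_that("Brownian tip variance scales linearly with tree height", {
  tr1 <- ape::read.tree(text = "(A:1,B:1);")
  tr4 <- ape::read.tree(text = "(A:4,B:4);")
  set.seed(71)
  v1 <- var(replicate(1500, vrpgls:::sim_bm_tips(tr1, sig2 = 1)[1, 1]))
  v4 <- var(replicate(1500, vrpgls:::sim_bm_tips(tr4, sig2 = 1)[1, 1]))
  expect_equal(v1, 1, tolerance = 0.12)
  expect_equal(v4 / v1, 4, tolerance = 0.2)
})

test_that("independent evolution leaves contrast correlations near zero", {
  sim <- simulate_dataset(simulation_spec("independent-bm", n_tips = 2500,
                                          seed = 73))
  tv <- sim$truth$traits
  p1 <- ape::pic(tv[sim$tree$tip.label, 1], sim$tree)
  p2 <- ape::pic(tv[sim$tree$tip.label, 2], sim$tree)
  expect_lt(abs(cor(p1, p2)), 0.05)
})

test_that("correlated evolution recovers the generating correlation", {
  S <- matrix(c(1, 0.8, 0.8, 1), 2)
  sim <- simulate_dataset(simulation_spec("correlated-bm", n_tips = 500,
                                          seed = 79, params = list(Sigma = S)))
  tv <- sim$truth$traits
  p1 <- ape::pic(tv[sim$tree$tip.label, 1], sim$tree)
  p2 <- ape::pic(tv[sim$tree$tip.label, 2], sim$tree)
  expect_lt(abs(cor(p1, p2) - 0.8), 0.1)
  expect_error(simulation_spec("correlated-bm", seed = 1,
                               params = list(Sigma = matrix(c(1, 2, 2, 1), 2))),
               "definite")
})

test_that("the strong-effect small-clade generator is recovered by GLS", {
  beta_hat <- r2_hat <- numeric(50)
  for (i in 1:50) {
    sim <- simulate_dataset(simulation_spec("bergmann", n_tips = 8,
                                            seed = 500 + i, root_height = 20,
                                            occurrence = list(p_multi = 0)))
    V <- phylo_covariance(sim$tree)
    X <- cbind(`(Intercept)` = 1,
               abslat = abs(sim$truth$lat[rownames(V)]))
    y <- sim$truth$response[rownames(V)]
    f <- gls_fit(y, X, V)
    beta_hat[i] <- f$coefficients["abslat"]
    r2_hat[i] <- r_squared(y, X, V, f$coefficients)
  }
  # mean estimate across seeds within its simulation CI around the truth
  se <- sd(beta_hat) / sqrt(50)
  expect_lt(abs(mean(beta_hat) - 0.0097), 3 * se)
  expect_equal(mean(r2_hat), 0.75, tolerance = 0.1)
})

test_that("regression residuals carry the stated covariance sigma2 V(lambda)", {
  tr <- ape::read.tree(text = "((A:50,B:50):50,C:100);")
  lam <- 0.7; s2 <- 2
  R <- matrix(0, 800, 3)
  for (i in 1:800) {
    sim <- simulate_dataset(simulation_spec(
      "regression", tree = tr, seed = 2000 + i,
      params = list(alpha = 1, beta = 0.01, sigma2 = s2, lambda = lam),
      occurrence = list(p_multi = 0)))
    res <- sim$truth$response - 1 - 0.01 * abs(sim$truth$lat)
    R[i, ] <- res[c("A", "B", "C")]
  }
  emp <- cov(R)
  theo <- s2 * phylo_covariance(tr, lambda = lam)[c("A", "B", "C"),
                                                  c("A", "B", "C")]
  expect_lt(norm(emp - theo, "F") / norm(theo, "F"), 0.15)
})

test_that("temperature gradients are anchored, monotone, and ordered", {
  t0 <- temperature_from_latitude(0, gradient_spec("triassic"))
  expect_equal(t0$mat, 30)
  lats <- seq(0, 90, by = 5)
  for (p in c("triassic", "jurassic", "cretaceous", "modern")) {
    tt <- temperature_from_latitude(lats, gradient_spec(p))
    expect_true(all(diff(tt$mat) <= 0))          # MAT(10) >= MAT(60)
    expect_true(all(tt$cmmt <= tt$mat + 1e-12))
  }
  expect_error(temperature_from_latitude(100), "latitude")
})

test_that("fixtures exist, parse, and honour their schemas", {
  d <- withr::local_tempdir()
  p <- make_fixture("ursid8", d)
  tr <- read_tree(p["tree"])
  ds <- read_traits(p["traits"], tree = tr)
  expect_equal(nrow(ds$species), 8)
  expect_length(multi_occurrence(ds), 0)

  p2 <- make_fixture("dino_small", d)
  tr2 <- read_tree(p2["tree"])
  ds2 <- read_traits(p2["traits"], trait_schema(period = "period",
                                                clade = "clade"),
                     tree = tr2)
  expect_equal(nrow(ds2$species), 40)
  expect_gt(length(multi_occurrence(ds2)), 0)
  al <- align_traits(ds2, tr2)
  expect_equal(al$tree$tip.label, al$dataset$species$species)

  expect_error(make_fixture("nope", d), "unknown fixture")
})

test_that("occurrence records are linked and jittered around the truth", {
  sim <- simulate_dataset(simulation_spec("regression", n_tips = 60, seed = 90,
                                          occurrence = list(p_multi = 1)))
  occ <- sim$dataset$occurrences
  # record temperatures must be consistent with record latitudes
  tt <- temperature_from_latitude(occ$latitude, gradient_spec("triassic"))
  expect_equal(occ$mat, tt$mat, tolerance = 1e-9)
  # jitter is centred on the species' generating latitude
  spread <- tapply(occ$latitude, occ$species, sd)
  expect_lt(median(spread, na.rm = TRUE), 6)
})
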