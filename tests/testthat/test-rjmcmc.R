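# The Bayesian sampler: reproducibility, summaries, analytic reductions
# and the prior-recovery (detailed balance) check for the reversible-jump
# scalar moves.

test_that("p_mcmc counts sign crossings relative to the median", {
  expect_equal(p_mcmc(c(1, 2, 3)), 0)
  expect_equal(p_mcmc(c(-1, 2, 3, 4)), 0.25)
  expect_equal(p_mcmc(c(-2, -1, 1, 2)), 0.5)   # median exactly zero
  set.seed(5)
  x <- rnorm(20000)
  expect_lt(abs(p_mcmc(x) - 0.5), 0.02)
})

test_that("posterior quantile arithmetic matches hand values", {
  x <- 1:100
  expect_equal(unname(quantile(x, c(0.025, 0.975))), c(3.475, 97.525))
  expect_equal(median(x), 50.5)
})

test_that("the same seed and configuration give a bit-identical stream", {
  sim <- simulate_dataset(simulation_spec("regression", n_tips = 24, seed = 2))
  ctl <- chain_control(iterations = 3000, burnin = 500, thin = 10)
  spc <- model_spec("abslat", variable_rates = TRUE)
  c1 <- run_chain(sim$dataset, sim$tree, spc, ctl, seed = 77)
  c2 <- run_chain(sim$dataset, sim$tree, spc, ctl, seed = 77)
  expect_identical(c1$samples, c2$samples)
  c3 <- run_chain(sim$dataset, sim$tree, spc, ctl, seed = 78)
  expect_false(identical(c1$samples$logL, c3$samples$logL))
})

test_that("increasing thinning retains a subset of the same iterations", {
  sim <- simulate_dataset(simulation_spec("regression", n_tips = 16, seed = 4))
  spc <- model_spec("abslat")
  c1 <- run_chain(sim$dataset, sim$tree, spc,
                  chain_control(iterations = 4000, burnin = 1000, thin = 10),
                  seed = 5)
  c2 <- run_chain(sim$dataset, sim$tree, spc,
                  chain_control(iterations = 4000, burnin = 1000, thin = 20),
                  seed = 5)
  l1 <- c1$samples$logL
  expect_equal(c2$samples$logL, l1[seq(2, length(l1), by = 2)])
})

test_that("summaries collapse for a constant sample stream", {
  sim <- simulate_dataset(simulation_spec("regression", n_tips = 8, seed = 6))
  spc <- model_spec("abslat")
  ctl <- chain_control(iterations = 300, burnin = 100, thin = 20,
                       move_weights = c(coef = 1, sigma2 = 0, lambda = 0,
                                        rj = 0, occurrence = 0),
                       fix = list(sigma2 = 0.01, lambda = 1,
                                  coef = c(`(Intercept)` = 2, abslat = 0.01)))
  expect_error(run_chain(sim$dataset, sim$tree, spc, ctl, seed = 1),
               "no free parameters")
  ctl$fix$coef <- c(abslat = 0.01)
  ch <- run_chain(sim$dataset, sim$tree, spc, ctl, seed = 1)
  s <- posterior_summary(ch)
  expect_equal(s$parameters["sigma2", "2.5%"],
               s$parameters["sigma2", "97.5%"])  # CI collapses to a point
})

test_that("with sigma2, slope and lambda fixed on a star tree the intercept
           posterior matches the conjugate normal posterior", {
  n <- 40; s0 <- 0.8; tau <- 10
  tr <- star_tree(n)
  set.seed(33)
  y <- rnorm(n, 1.5, sqrt(s0))
  ds <- ds_simple(tr, y)
  ctl <- chain_control(iterations = 30000, burnin = 5000, thin = 50,
                       fix = list(sigma2 = s0, lambda = 1),
                       priors = list(beta_sd = tau))
  ch <- run_chain(ds, tr, model_spec("none"), ctl, seed = 12)
  a <- ch$samples$coefficients[, 1]
  vstar <- 1 / (n / s0 + 1 / tau^2)
  mstar <- vstar * sum(y) / s0
  ks <- suppressWarnings(stats::ks.test(a, "pnorm", mstar, sqrt(vstar)))
  expect_gt(ks$p.value, 0.01)
  expect_equal(mean(a), mstar, tolerance = 0.05)
})

test_that("with the likelihood tempered away the number of scalar placements
           follows its truncated Poisson(1) prior", {
  sim <- simulate_dataset(simulation_spec("regression", n_tips = 16, seed = 8,
                                          occurrence = list(p_multi = 0)))
  spc <- model_spec("none", variable_rates = TRUE)
  ctl <- chain_control(iterations = 60000, burnin = 5000, thin = 100,
                       move_weights = c(coef = 0.2, sigma2 = 0.2,
                                        lambda = 0.1, rj = 0.5,
                                        occurrence = 0))
  ch <- run_chain(sim$dataset, sim$tree, spc, ctl, seed = 21, power = 0)
  k <- ch$samples$n_scalars
  obs <- c(sum(k == 0), sum(k == 1), sum(k == 2), sum(k >= 3))
  pr <- c(dpois(0:2, 1), 1 - ppois(2, 1))
  chi <- suppressWarnings(stats::chisq.test(obs, p = pr))
  expect_gt(chi$p.value, 0.01)
})

test_that("effective per-branch scalars always stay inside their bounds", {
  sim <- simulate_dataset(simulation_spec("variable-rates", n_tips = 24,
                                          seed = 9,
                                          occurrence = list(p_multi = 0),
                                          params = list(mult = 50)))
  spc <- model_spec("none", variable_rates = TRUE)
  ch <- run_chain(sim$dataset, sim$tree, spc,
                  chain_control(iterations = 8000, burnin = 1000, thin = 20),
                  seed = 10)
  S <- ch$samples$scalars
  expect_true(all(S >= 1e-3 - 1e-12 & S <= 1e3 + 1e-9))
})

test_that("occurrence reassignment explores the linked records", {
  sim <- simulate_dataset(simulation_spec("regression", n_tips = 30,
                                          seed = 14,
                                          occurrence = list(p_multi = 0.8)))
  spc <- model_spec("abslat")
  ch <- run_chain(sim$dataset, sim$tree, spc,
                  chain_control(iterations = 6000, burnin = 1000, thin = 10),
                  seed = 15)
  A <- ch$samples$assignment
  expect_false(is.null(A))
  # most multi-occurrence species should visit more than one record
  visited <- apply(A, 2, function(z) length(unique(z)))
  expect_gt(mean(visited > 1), 0.7)
})

test_that("traces are written with one row per retained sample", {
  sim <- simulate_dataset(simulation_spec("regression", n_tips = 8, seed = 16))
  ch <- run_chain(sim$dataset, sim$tree, model_spec("abslat"),
                  chain_control(iterations = 1000, burnin = 500, thin = 50),
                  seed = 17)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_trace(ch, f)
  tab <- read.delim(f)
  expect_equal(nrow(tab), length(ch$samples$logL))
  expect_true(all(c("iteration", "logL", "sigma2", "lambda") %in% names(tab)))
})
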