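# The Bayesian engine: Metropolis-Hastings / reversible-jump sampling of
# (coefficients, sigma2, lambda, rate-scalar placements, occurrence
# assignments) under the variable-rates PGLS model.
#
# Priors (proper, vague, scale-free; fixed here because the model ladder
# compares marginal likelihoods): coefficients ~ Normal(0, beta_sd^2);
# log(sigma2) ~ Normal(log_sigma2_mean, log_sigma2_sd^2); lambda ~
# Uniform(0, 1); number of scalar placements ~ Poisson(k_mean) truncated
# at 2n - 2; each placement targets a branch or a clade uniformly and
# draws log r uniformly on log(scalar_range); occurrence assignments are
# uniform over each species' linked records.

#' Sampler configuration
#'
#' @param iterations total MCMC iterations.
#' @param burnin iterations discarded before sampling begins; proposal
#'   adaptation is frozen at the end of burn-in.
#' @param thin sampling interval; iterations `burnin + thin, burnin +
#'   2*thin, ...` are recorded.
#' @param preset `"mesozoic"` (12.5M iterations, 2.5M burn-in, thin 1000)
#'   or `"extant"` (150M / 100M / 1000), overriding the three arguments
#'   above; `NULL` keeps them.
#' @param move_weights named weights for the move types `coef`, `sigma2`,
#'   `lambda`, `rj`, `occurrence`; weights of unavailable moves are zeroed
#'   automatically.
#' @param scales initial random-walk scales (coefficients, log sigma2,
#'   lambda); adapted during burn-in towards 20--40 percent acceptance.
#' @param priors list overriding any of `beta_sd`, `log_sigma2_mean`,
#'   `log_sigma2_sd`, `k_mean`, `scalar_range`, `modify_sd`.
#' @param fix optional list: `sigma2` and/or `lambda` fixed values, and/or
#'   `coef`, a named vector of coefficients to hold fixed (used by
#'   reduction tests and oracles).
#' @param adapt logical; adapt proposal scales during burn-in.
#' @return list of class `chain_control`.
#' @export
chain_control <- function(iterations = 20000, burnin = 5000, thin = 20,
                          preset = NULL,
                          move_weights = c(coef = 0.35, sigma2 = 0.15,
                                           lambda = 0.1, rj = 0.25,
                                           occurrence = 0.15),
                          scales = list(coef = 0.1, sigma2 = 0.6,
                                        lambda = 0.15),
                          priors = list(), fix = list(), adapt = TRUE) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("mesozoic", "extant"))
    if (preset == "mesozoic") {
      iterations <- 12.5e6; burnin <- 2.5e6; thin <- 1000
    } else {
      iterations <- 150e6; burnin <- 100e6; thin <- 1000
    }
  }
  pr <- list(beta_sd = 10, log_sigma2_mean = 0, log_sigma2_sd = 2,
             k_mean = 1, scalar_range = c(1e-3, 1e3), modify_sd = 0.3)
  pr[names(priors)] <- priors
  stopifnot(iterations > burnin, thin >= 1)
  structure(list(iterations = as.integer(iterations),
                 burnin = as.integer(burnin), thin = as.integer(thin),
                 move_weights = move_weights, scales = scales,
                 priors = pr, fix = fix, adapt = adapt),
            class = "chain_control")
}

#' Run the variable-rates PGLS sampler
#'
#' Metropolis-Hastings over regression coefficients (per-coefficient
#' Gaussian random walks with burn-in adaptation), the residual rate
#' sigma2 (log-scale walk), Pagel's lambda (reflected walk on `[0, 1]`),
#' reversible-jump moves that add, delete or modify branch/clade rate
#' scalar placements (the effective scalar of a branch is the product of
#' the placements covering it, kept inside `scalar_range` by rejection),
#' and occurrence reassignment: one multi-occurrence species at a time is
#' proposed a uniformly random linked record, latitude and temperatures
#' jointly, and accepted by likelihood ratio. The same seed and
#' configuration reproduce the sample stream bit-for-bit.
#'
#' @param dataset a `trait_dataset`.
#' @param tree a rooted [ape::phylo]; aligned to the dataset internally.
#' @param spec a [model_spec()]; `variable_rates = TRUE` enables the
#'   reversible-jump moves.
#' @param control a [chain_control()].
#' @param seed integer seed (mandatory).
#' @param power likelihood tempering exponent in `[0, 1]` used by
#'   stepping-stone estimation; 1 samples the posterior, 0 the prior.
#' @param init_state optional state list (as stored in `final_state` of a
#'   previous chain) to start from.
#' @return an object of class `pgls_chain`: recorded samples, acceptance
#'   rates, the prepared tree and inputs.
#' @export
run_chain <- function(dataset, tree, spec, control = chain_control(), seed,
                      power = 1, init_state = NULL) {
  if (missing(seed)) stop("a seed is mandatory")
  stopifnot(inherits(spec, "model_spec"), inherits(control, "chain_control"))
  al <- align_traits(dataset, tree)
  ds <- al$dataset
  eng <- vr_engine(al$tree)
  ord <- match(eng$tree$tip.label, ds$species$species)
  y <- ds$species$response[ord]
  recs <- design_records(ds, spec)[ord]
  k_rec <- vapply(recs, nrow, 0L)
  multi <- which(k_rec > 1L)
  p <- ncol(recs[[1L]])
  coefnames <- colnames(recs[[1L]])
  n <- eng$n
  E <- eng$E
  pr <- control$priors
  lsr <- log(pr$scalar_range)
  lwidth <- lsr[2L] - lsr[1L]
  kmax <- 2L * n - 2L
  nclade <- length(eng$clade_nodes)

  fix <- control$fix
  fixed_coef <- rep(FALSE, p)
  if (!is.null(fix$coef)) {
    j <- match(names(fix$coef), coefnames)
    if (anyNA(j)) stop("unknown fixed coefficient name")
    fixed_coef[j] <- TRUE
  }
  free_coef <- which(!fixed_coef)

  set.seed(as.integer(seed))

  # ---- initial state -------------------------------------------------
  if (is.null(init_state)) {
    assign <- rep(1L, n)
    lambda <- fix$lambda %||% 0.5
    plac <- list()
    X <- t(vapply(seq_len(n), function(i) recs[[i]][1L, ], numeric(p)))
    if (p == 1L) X <- matrix(X, ncol = 1L, dimnames = list(NULL, coefnames))
    wh <- engine_whiten(eng, cbind(y, X), lambda)
    b <- tryCatch({
      f <- lm.fit(wh$W[, -1L, drop = FALSE], wh$W[, 1L])
      cf <- f$coefficients; cf[is.na(cf)] <- 0; cf
    }, error = function(e) rep(0, p))
    if (!is.null(fix$coef)) b[match(names(fix$coef), coefnames)] <- fix$coef
    rw <- wh$W[, 1L] - wh$W[, -1L, drop = FALSE] %*% b
    ls2 <- if (!is.null(fix$sigma2)) log(fix$sigma2) else
      log(max(mean(rw^2), 1e-8))
  } else {
    assign <- init_state$assign
    lambda <- init_state$lambda
    plac <- init_state$plac
    b <- init_state$b
    ls2 <- init_state$ls2
    X <- t(vapply(seq_len(n), function(i) recs[[i]][assign[i], ], numeric(p)))
    if (p == 1L) X <- matrix(X, ncol = 1L, dimnames = list(NULL, coefnames))
  }
  scal <- effective_scalars(eng, plac)
  wh <- engine_whiten(eng, cbind(y, X), lambda,
                      if (length(plac)) scal else NULL)
  if (wh$n_ridge > 0)
    warning("singular covariance at chain start; ridge applied")
  Wy <- wh$W[, 1L]; WX <- wh$W[, -1L, drop = FALSE]; logdet <- wh$logdet

  const <- -0.5 * n * log(2 * pi)
  ll_of <- function(Wy, WX, logdet, b, ls2) {
    r <- Wy - WX %*% b
    const - 0.5 * n * ls2 - 0.5 * logdet - 0.5 * sum(r * r) / exp(ls2)
  }
  ll <- ll_of(Wy, WX, logdet, b, ls2)
  if (!is.finite(ll))
    stop("non-finite likelihood at initial state; check the data")

  # ---- move availability --------------------------------------------
  w <- control$move_weights[c("coef", "sigma2", "lambda", "rj", "occurrence")]
  w[is.na(w)] <- 0
  if (length(free_coef) == 0L) w["coef"] <- 0
  if (!is.null(fix$sigma2)) w["sigma2"] <- 0
  if (!is.null(fix$lambda)) w["lambda"] <- 0
  if (!spec$variable_rates) w["rj"] <- 0
  if (length(multi) == 0L) w["occurrence"] <- 0
  if (sum(w) <= 0) stop("no free parameters to sample")
  cw <- cumsum(w / sum(w))

  sc_coef <- rep(control$scales$coef, p)
  sc_s2 <- control$scales$sigma2
  sc_lam <- control$scales$lambda
  acc <- att <- c(coef = 0, sigma2 = 0, lambda = 0, rj = 0, occurrence = 0)
  # adaptation batches
  ab_n <- ab_a <- numeric(p); as_n <- as_a <- al_n <- al_a <- 0

  nsamp <- (control$iterations - control$burnin) %/% control$thin
  S_b <- matrix(NA_real_, nsamp, p, dimnames = list(NULL, coefnames))
  S_s2 <- S_lam <- S_ll <- S_k <- numeric(nsamp)
  S_scal <- if (spec$variable_rates) matrix(NA_real_, nsamp, E) else NULL
  S_asn <- if (length(multi)) matrix(NA_integer_, nsamp, length(multi),
                                     dimnames = list(NULL, eng$tree$tip.label[multi]))
           else NULL
  isamp <- 0L

  adapting <- isTRUE(control$adapt)
  burnin <- control$burnin; thin <- control$thin

  for (it in seq_len(control$iterations)) {
    mv <- findInterval(runif(1), cw) + 1L
    if (mv == 1L) {                      # coefficient random walk
      att[1L] <- att[1L] + 1
      j <- if (length(free_coef) == 1L) free_coef else sample(free_coef, 1L)
      bj <- b[j]
      b2 <- b; b2[j] <- bj + rnorm(1, 0, sc_coef[j])
      ll2 <- ll_of(Wy, WX, logdet, b2, ls2)
      dpost <- power * (ll2 - ll) +
        dnorm(b2[j], 0, pr$beta_sd, log = TRUE) -
        dnorm(bj, 0, pr$beta_sd, log = TRUE)
      ok <- is.finite(dpost) && log(runif(1)) < dpost
      if (ok) { b <- b2; ll <- ll2; acc[1L] <- acc[1L] + 1 }
      if (adapting && it <= burnin) {
        ab_n[j] <- ab_n[j] + 1; ab_a[j] <- ab_a[j] + ok
        if (ab_n[j] >= 50) {
          sc_coef[j] <- min(1e3, max(1e-8,
            sc_coef[j] * exp(ab_a[j] / ab_n[j] - 0.3)))
          ab_n[j] <- ab_a[j] <- 0
        }
      }
    } else if (mv == 2L) {               # log-sigma2 walk
      att[2L] <- att[2L] + 1
      ls2p <- ls2 + rnorm(1, 0, sc_s2)
      ll2 <- ll_of(Wy, WX, logdet, b, ls2p)
      dpost <- power * (ll2 - ll) +
        dnorm(ls2p, pr$log_sigma2_mean, pr$log_sigma2_sd, log = TRUE) -
        dnorm(ls2, pr$log_sigma2_mean, pr$log_sigma2_sd, log = TRUE)
      ok <- is.finite(dpost) && log(runif(1)) < dpost
      if (ok) { ls2 <- ls2p; ll <- ll2; acc[2L] <- acc[2L] + 1 }
      if (adapting && it <= burnin) {
        as_n <- as_n + 1; as_a <- as_a + ok
        if (as_n >= 50) {
          sc_s2 <- min(10, max(1e-4, sc_s2 * exp(as_a / as_n - 0.3)))
          as_n <- as_a <- 0
        }
      }
    } else if (mv == 3L) {               # lambda reflected walk
      att[3L] <- att[3L] + 1
      lamp <- reflect01(lambda + rnorm(1, 0, sc_lam))
      wh2 <- engine_whiten(eng, cbind(y, X), lamp,
                           if (length(plac)) scal else NULL)
      ll2 <- ll_of(wh2$W[, 1L], wh2$W[, -1L, drop = FALSE], wh2$logdet,
                   b, ls2)
      dpost <- power * (ll2 - ll)
      ok <- is.finite(dpost) && log(runif(1)) < dpost
      if (ok) {
        lambda <- lamp; ll <- ll2
        Wy <- wh2$W[, 1L]; WX <- wh2$W[, -1L, drop = FALSE]
        logdet <- wh2$logdet
        acc[3L] <- acc[3L] + 1
      }
      if (adapting && it <= burnin) {
        al_n <- al_n + 1; al_a <- al_a + ok
        if (al_n >= 50) {
          sc_lam <- min(1, max(1e-4, sc_lam * exp(al_a / al_n - 0.3)))
          al_n <- al_a <- 0
        }
      }
    } else if (mv == 4L) {               # reversible-jump scalar moves
      att[4L] <- att[4L] + 1
      k <- length(plac)
      kind <- sample.int(4L, 1L)          # add-branch, add-clade, delete, modify
      plac2 <- NULL; lprop <- -Inf
      # set-based birth/death: with a Poisson(mean 1) prior on the number
      # of placements and marks proposed from their prior, the proposal
      # densities of the mark cancel and the Green ratio reduces to
      # (1/2)/(k+1) for a birth and 2k for a death (the 1/2 is the prior
      # probability of the placement's type)
      if (kind == 1L && k < kmax) {
        tgt <- sample.int(E, 1L)
        r <- exp(runif(1, lsr[1L], lsr[2L]))
        plac2 <- c(plac, list(list(type = "branch", target = tgt, r = r)))
        lprop <- log(0.5) - log(k + 1)
      } else if (kind == 2L && k < kmax && nclade > 0L) {
        tgt <- eng$clade_nodes[sample.int(nclade, 1L)]
        r <- exp(runif(1, lsr[1L], lsr[2L]))
        plac2 <- c(plac, list(list(type = "clade", target = tgt, r = r)))
        lprop <- log(0.5) - log(k + 1)
      } else if (kind == 3L && k > 0L) {
        i <- sample.int(k, 1L)
        plac2 <- plac[-i]
        lprop <- log(2) + log(k)
      } else if (kind == 4L && k > 0L) {
        i <- sample.int(k, 1L)
        pl <- plac[[i]]
        r2 <- pl$r * exp(rnorm(1, 0, pr$modify_sd))
        if (log(r2) >= lsr[1L] && log(r2) <= lsr[2L]) {
          pl$r <- r2
          plac2 <- plac; plac2[[i]] <- pl
          lprop <- 0
        }
      }
      if (!is.null(plac2)) {
        scal2 <- effective_scalars(eng, plac2)
        if (all(scal2 >= pr$scalar_range[1L] & scal2 <= pr$scalar_range[2L])) {
          wh2 <- engine_whiten(eng, cbind(y, X), lambda,
                               if (length(plac2)) scal2 else NULL)
          ll2 <- ll_of(wh2$W[, 1L], wh2$W[, -1L, drop = FALSE], wh2$logdet,
                       b, ls2)
          dpost <- power * (ll2 - ll) + lprop
          if (is.finite(dpost) && log(runif(1)) < dpost) {
            plac <- plac2; scal <- scal2; ll <- ll2
            Wy <- wh2$W[, 1L]; WX <- wh2$W[, -1L, drop = FALSE]
            logdet <- wh2$logdet
            acc[4L] <- acc[4L] + 1
          }
        }
      }
    } else {                             # occurrence reassignment
      att[5L] <- att[5L] + 1
      i <- if (length(multi) == 1L) multi else sample(multi, 1L)
      jnew <- sample.int(k_rec[i], 1L)
      if (jnew != assign[i]) {
        X2 <- X
        X2[i, ] <- recs[[i]][jnew, ]
        wh2 <- engine_whiten(eng, cbind(y, X2), lambda,
                             if (length(plac)) scal else NULL)
        ll2 <- ll_of(wh2$W[, 1L], wh2$W[, -1L, drop = FALSE], wh2$logdet,
                     b, ls2)
        dpost <- power * (ll2 - ll)
        if (is.finite(dpost) && log(runif(1)) < dpost) {
          assign[i] <- jnew; X <- X2; ll <- ll2
          Wy <- wh2$W[, 1L]; WX <- wh2$W[, -1L, drop = FALSE]
          logdet <- wh2$logdet
          acc[5L] <- acc[5L] + 1
        }
      } else acc[5L] <- acc[5L] + 1       # proposing the current record
    }

    if (it == burnin) adapting <- FALSE   # freeze adaptation after burn-in

    if (it > burnin && (it - burnin) %% thin == 0L) {
      isamp <- isamp + 1L
      S_b[isamp, ] <- b
      S_s2[isamp] <- exp(ls2)
      S_lam[isamp] <- lambda
      S_ll[isamp] <- ll
      S_k[isamp] <- length(plac)
      if (!is.null(S_scal)) S_scal[isamp, ] <- scal
      if (!is.null(S_asn)) S_asn[isamp, ] <- assign[multi]
    }
  }

  structure(list(
    samples = list(coefficients = S_b, sigma2 = S_s2, lambda = S_lam,
                   logL = S_ll, n_scalars = S_k, scalars = S_scal,
                   assignment = S_asn),
    coef_names = coefnames,
    accept = ifelse(att > 0, acc / att, NA),
    attempts = att,
    control = control, spec = spec, seed = seed, power = power,
    tree = eng$tree, engine = eng,
    data = list(y = y, recs = recs, species = eng$tree$tip.label,
                multi = multi),
    final_state = list(b = b, ls2 = ls2, lambda = lambda, plac = plac,
                       assign = assign)),
    class = "pgls_chain")
}

#' @export
print.pgls_chain <- function(x, ...) {
  cat("pgls_chain:", x$spec$label, "--", length(x$samples$logL),
      "samples,", x$control$iterations, "iterations (seed", x$seed, ")\n")
  cat("acceptance:",
      paste(names(x$accept), round(x$accept, 2), collapse = ", "), "\n")
  invisible(x)
}

#' Proportion of slope samples crossing zero
#'
#' The fraction of posterior samples whose sign is opposite to (or zero
#' relative to) the sign of the posterior median; 0.5 when the median is
#' exactly zero. Small values indicate a slope consistently on one side
#' of zero.
#'
#' @param beta_samples numeric vector of posterior slope samples.
#' @return a value in `[0, 1]`.
#' @export
p_mcmc <- function(beta_samples) {
  stopifnot(length(beta_samples) >= 1)
  med <- median(beta_samples)
  if (med == 0) return(0.5)
  if (med > 0) mean(beta_samples <= 0) else mean(beta_samples >= 0)
}

# effective sample size by initial positive autocorrelation truncation
ess <- function(x) {
  nx <- length(x)
  if (nx < 10 || sd(x) == 0) return(nx)
  ac <- acf(x, lag.max = min(nx - 1L, 200L), plot = FALSE)$acf[-1L]
  s <- 0; k <- 1L
  while (k <= length(ac) && ac[k] > 0.05) { s <- s + ac[k]; k <- k + 1L }
  nx / (1 + 2 * s)
}

#' Summarise a posterior sample
#'
#' Per-parameter medians and equal-tailed 95 percent credible intervals,
#' `p_MCMC` for every non-intercept coefficient, the median per-sample
#' `R^2` (recomputed at each sample's coefficients, lambda, scalars and
#' occurrence assignment, so it may be negative), the plug-in
#' `r_squared_at_median` evaluated at the posterior medians, the
#' across-sample mean effective scalar per branch, acceptance rates and
#' effective sample sizes.
#'
#' @param chain a `pgls_chain` with at least two samples.
#' @param probs credible-interval probabilities.
#' @return an object of class `pgls_summary`.
#' @export
posterior_summary <- function(chain, probs = c(0.025, 0.975)) {
  stopifnot(inherits(chain, "pgls_chain"))
  S <- chain$samples
  m <- length(S$logL)
  if (m < 2) stop("need at least two samples")
  qs <- function(v) c(median = median(v), quantile(v, probs))
  pars <- rbind(t(apply(S$coefficients, 2, qs)),
                sigma2 = qs(S$sigma2), lambda = qs(S$lambda))
  slopes <- setdiff(chain$coef_names, "(Intercept)")
  pm <- vapply(slopes, function(nm) p_mcmc(S$coefficients[, nm]), 0)
  r2 <- vapply(seq_len(m), function(i) {
    V <- engine_cov(chain$engine, S$lambda[i],
                    if (!is.null(S$scalars)) S$scalars[i, ] else NULL)
    X <- sample_design(chain, i)
    suppressWarnings(r_squared(chain$data$y, X, V, S$coefficients[i, ]))
  }, 0)
  essv <- c(apply(S$coefficients, 2, ess), sigma2 = ess(S$sigma2),
            lambda = ess(S$lambda), logL = ess(S$logL))
  # plug-in fit quality at the posterior medians (the per-sample median
  # above is systematically lower at small n because sampled coefficients
  # are not optimal)
  bmed <- apply(S$coefficients, 2, median)
  scmed <- if (!is.null(S$scalars)) apply(S$scalars, 2, median) else NULL
  Vmed <- engine_cov(chain$engine, median(S$lambda), scmed)
  modal_assign <- if (!is.null(S$assignment))
    apply(S$assignment, 2, function(z) as.integer(names(which.max(table(z)))))
  else NULL
  imode <- 1L
  Xmed <- sample_design(chain, imode)
  if (!is.null(modal_assign)) {
    asn <- rep(1L, length(chain$data$recs))
    asn[chain$data$multi] <- modal_assign
    Xmed <- t(vapply(seq_along(chain$data$recs), function(s)
      chain$data$recs[[s]][asn[s], ], numeric(ncol(Xmed))))
  }
  r2_plug <- suppressWarnings(r_squared(chain$data$y, Xmed, Vmed, bmed))
  structure(list(parameters = pars, p_mcmc = pm,
                 r_squared = c(median = median(r2, na.rm = TRUE),
                               quantile(r2, probs, na.rm = TRUE)),
                 r_squared_at_median = r2_plug,
                 mean_scalars = if (!is.null(S$scalars)) colMeans(S$scalars)
                                else rep(1, chain$engine$E),
                 accept = chain$accept, ess = essv, n_samples = m),
            class = "pgls_summary")
}

# design matrix at the assignment stored with sample i
sample_design <- function(chain, i) {
  recs <- chain$data$recs
  n <- length(recs)
  asn <- rep(1L, n)
  if (!is.null(chain$samples$assignment))
    asn[chain$data$multi] <- chain$samples$assignment[i, ]
  X <- t(vapply(seq_len(n), function(s) recs[[s]][asn[s], ],
                numeric(ncol(recs[[1L]]))))
  if (ncol(recs[[1L]]) == 1L)
    X <- matrix(X, ncol = 1L, dimnames = list(NULL, chain$coef_names))
  X
}

#' @export
print.pgls_summary <- function(x, digits = 4, ...) {
  cat("Posterior summary (", x$n_samples, " samples)\n", sep = "")
  print(round(x$parameters, digits))
  if (length(x$p_mcmc)) {
    cat("p_MCMC:\n"); print(round(x$p_mcmc, digits))
  }
  cat("R^2 (median and CI):\n"); print(round(x$r_squared, digits))
  cat("acceptance: ",
      paste(names(x$accept), round(x$accept, 2), collapse = ", "), "\n")
  invisible(x)
}

#' Write a tab-separated chain trace
#'
#' One row per retained sample: iteration index, log-likelihood,
#' coefficients, sigma2, lambda and the number of scalar placements.
#'
#' @param chain a `pgls_chain`.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_trace <- function(chain, path) {
  S <- chain$samples
  it <- chain$control$burnin + seq_along(S$logL) * chain$control$thin
  df <- data.frame(iteration = it, logL = S$logL,
                   S$coefficients, sigma2 = S$sigma2, lambda = S$lambda,
                   n_scalars = S$n_scalars, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
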