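# Seeded generators for every statistical structure the analyses assume:
# Brownian trait evolution on a tree, correlated bivariate Brownian
# evolution (positive control), independent evolution (negative control),
# clade-specific rate multipliers, a Bergmann-type latitude -> size
# dependence, and multi-occurrence tip records with linked temperatures.

#' Random time-calibrated tree
#'
#' A pure-birth (Yule) tree with unit birth rate, rescaled to a stated
#' root height -- simple, standard, and irrelevant to the estimators under
#' test beyond supplying a realistic topology.
#'
#' @param n number of tips (>= 2).
#' @param root_height root-to-tip height in Myr.
#' @param seed optional seed.
#' @return an ultrametric [ape::phylo] with tips `sp001, sp002, ...`.
#' @export
sim_tree <- function(n, root_height = 100, seed = NULL) {
  stopifnot(n >= 2)
  if (!is.null(seed)) set.seed(as.integer(seed))
  tr <- ape::rphylo(n, birth = 1, death = 0)
  tr$edge.length <- tr$edge.length *
    root_height / max(node_depths(tr)[seq_len(n)])
  tr$tip.label <- sprintf("sp%03d", seq_len(n))
  tr
}

# Brownian motion along the tree; increments per edge, optionally
# multivariate (chol of Sigma) and with per-edge rate scalars.
# Returns tip values (and all node values as an attribute).
sim_bm_tips <- function(tree, sig2 = 1, x0 = 0, scalars = NULL,
                        Sigma = NULL) {
  tree <- stats::reorder(tree, "postorder")
  n <- length(tree$tip.label)
  ntot <- n + tree$Nnode
  q <- if (is.null(Sigma)) length(sig2) else ncol(Sigma)
  ch <- if (!is.null(Sigma)) chol(Sigma) else NULL
  vals <- matrix(0, ntot, q)
  vals[n + 1L, ] <- x0
  len <- tree$edge.length
  if (!is.null(scalars)) len <- len * scalars
  for (e in rev(seq_len(nrow(tree$edge)))) {       # parents before children
    u <- tree$edge[e, 1L]; v <- tree$edge[e, 2L]
    z <- rnorm(q)
    inc <- if (is.null(ch)) sqrt(sig2 * len[e]) * z
           else sqrt(len[e]) * drop(z %*% ch)
    vals[v, ] <- vals[u, ] + inc
  }
  tips <- vals[seq_len(n), , drop = FALSE]
  rownames(tips) <- tree$tip.label
  attr(tips, "nodes") <- vals[(n + 1L):ntot, , drop = FALSE]
  tips
}

#' Latitudinal temperature gradient presets
#'
#' Deterministic monotone profiles anchored on Mesozoic global-climate
#' reconstructions: equatorial mean annual temperatures near 30 C
#' throughout, with cooler poles and a seasonality (MAT minus CMMT)
#' offset that grows towards the poles. The `modern` preset has a steeper
#' gradient for extant-like data.
#'
#' @param preset `"triassic"`, `"jurassic"`, `"cretaceous"` or
#'   `"modern"`.
#' @param t_eq,t_pole,seasonality optional overrides: equatorial MAT,
#'   polar MAT, and the polar MAT-CMMT offset, all in degrees C.
#' @return list of class `gradient_spec`.
#' @export
gradient_spec <- function(preset = c("triassic", "jurassic", "cretaceous",
                                     "modern"),
                          t_eq = NULL, t_pole = NULL, seasonality = NULL) {
  preset <- match.arg(preset)
  def <- switch(preset,
                triassic = c(30, 6.5, 12),
                jurassic = c(30, 7, 18),
                cretaceous = c(30, 8, 25),
                modern = c(27, -12, 22))
  structure(list(preset = preset, t_eq = t_eq %||% def[1],
                 t_pole = t_pole %||% def[2],
                 seasonality = seasonality %||% def[3]),
            class = "gradient_spec")
}

#' Local temperatures from latitude
#'
#' MAT decreases linearly in absolute latitude from `t_eq` at the equator
#' to `t_pole` at the poles; CMMT sits below MAT by a seasonality offset
#' growing with absolute latitude, so CMMT <= MAT everywhere. Optional
#' Gaussian noise is added to both (the same draw, keeping the pair
#' coherent).
#'
#' @param lat latitude(s), degrees, `|lat| <= 90`.
#' @param gradient a [gradient_spec()].
#' @param noise_sd standard deviation of added local noise (degrees C).
#' @return data.frame with columns `mat` and `cmmt`.
#' @export
temperature_from_latitude <- function(lat, gradient = gradient_spec(),
                                      noise_sd = 0) {
  if (any(abs(lat) > 90)) stop("latitude outside [-90, 90]")
  f <- abs(lat) / 90
  mat <- gradient$t_eq - (gradient$t_eq - gradient$t_pole) * f
  cmmt <- mat - gradient$seasonality * f
  if (noise_sd > 0) {
    eps <- rnorm(length(lat), 0, noise_sd)
    mat <- mat + eps
    cmmt <- cmmt + eps
  }
  data.frame(mat = mat, cmmt = cmmt)
}

#' Specify a synthetic dataset
#'
#' Generating models: `"independent-bm"` (two uncorrelated Brownian
#' traits; the negative control), `"correlated-bm"` (bivariate Brownian
#' motion with rate matrix Sigma; the positive control),
#' `"regression"` / `"bergmann"` (latitude evolves by Brownian motion and
#' the response is `alpha + beta * |lat|` plus Brownian noise with rate
#' `sigma2` and signal `lambda`; the bergmann preset carries the
#' strong-effect, small-clade parameterisation), and `"variable-rates"`
#' (Brownian response with one clade's branches multiplied by `mult`).
#'
#' @param model generating model (above).
#' @param n_tips number of tips for the random tree (ignored if `tree`
#'   given).
#' @param tree optional tree to simulate on.
#' @param params named list overriding model parameter defaults; see
#'   Details in the package vignette.
#' @param occurrence list with `p_multi` (fraction of species with
#'   multiple linked records; default 0.35, the multi-locality fraction
#'   typical of Mesozoic dinosaur datasets), `extra_mean` (Poisson mean
#'   of extra records beyond the second) and `jitter_sd` (latitude
#'   jitter, degrees; default 2).
#' @param gradient a [gradient_spec()] used to derive record
#'   temperatures from (jittered) record latitudes.
#' @param root_height tree height in Myr for generated trees.
#' @param seed mandatory integer seed; generation is bit-reproducible.
#' @return list of class `simulation_spec`.
#' @export
simulation_spec <- function(model = c("independent-bm", "correlated-bm",
                                      "regression", "bergmann",
                                      "variable-rates"),
                            n_tips = 128, tree = NULL, params = list(),
                            occurrence = list(), gradient = gradient_spec(),
                            root_height = 100, seed) {
  if (missing(seed)) stop("a seed is mandatory")
  model <- match.arg(model)
  par <- switch(model,
    "independent-bm" = list(sig2 = c(1, 1), x0 = c(0, 0)),
    "correlated-bm" = list(Sigma = matrix(c(1, 0.8, 0.8, 1), 2),
                           x0 = c(0, 0)),
    "regression" = list(alpha = 2, beta = 0.01, sigma2 = 0.01, lambda = 1,
                        lat_sig2 = NULL, target_r2 = NULL),
    "bergmann" = list(alpha = 4.2, beta = 0.0097, sigma2 = NULL, lambda = 1,
                      lat_sig2 = NULL, target_r2 = 0.75),
    "variable-rates" = list(sig2 = 1, mult = 10, clade_node = NULL,
                            clade_frac = 0.25))
  par[names(params)] <- params
  occ <- list(p_multi = 0.35, extra_mean = 1, jitter_sd = 2)
  occ[names(occurrence)] <- occurrence
  if (model == "correlated-bm") {
    S <- par$Sigma
    if (!isTRUE(all.equal(S, t(S))) || any(eigen(S, TRUE)$values < -1e-12))
      stop("Sigma must be symmetric positive semi-definite")
  }
  structure(list(model = model, n_tips = n_tips, tree = tree, params = par,
                 occurrence = occ, gradient = gradient,
                 root_height = root_height, seed = as.integer(seed)),
            class = "simulation_spec")
}

# residual-rate calibration: choose sigma2 so the expected whitened R^2
# of the generating regression equals target_r2 (noise is iid after
# whitening, SSE ~ sigma2 * chisq(n-2), SST ~ signal + sigma2 * chisq(n-1))
calibrate_sigma2 <- function(tree, xabs, beta, target_r2) {
  n <- length(xabs)
  V <- phylo_covariance(tree)
  ch <- chol(V)
  Wx <- backsolve(ch, xabs, transpose = TRUE)
  W1 <- backsolve(ch, rep(1, n), transpose = TRUE)
  mu <- sum(W1 * Wx) / sum(W1^2)
  signal <- beta^2 * sum((Wx - mu * W1)^2)
  denom <- (n - 2) - (1 - target_r2) * (n - 1)
  if (denom <= 0) stop("target R^2 unattainable at this sample size")
  signal * (1 - target_r2) / denom
}

#' Simulate a phylogeny plus trait dataset with known truth
#'
#' Draws tip data under the model in `spec`, wraps them as a
#' [trait_dataset()] with linked multi-occurrence records (record
#' latitudes jittered around the species' generating latitude, record
#' temperatures re-derived from the jittered latitude so each record is
#' internally consistent), and returns the full generating truth for
#' recovery tests.
#'
#' @param spec a [simulation_spec()].
#' @return list with `tree`, `dataset` and `truth` (generating
#'   parameters, per-tip generating values, per-edge scalars where
#'   relevant).
#' @export
simulate_dataset <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  set.seed(spec$seed)
  tree <- spec$tree %||% {
    tr <- ape::rphylo(spec$n_tips, birth = 1, death = 0)
    tr$edge.length <- tr$edge.length *
      spec$root_height / max(node_depths(tr)[seq_len(spec$n_tips)])
    tr$tip.label <- sprintf("sp%03d", seq_len(spec$n_tips))
    tr
  }
  n <- length(tree$tip.label)
  par <- spec$params
  truth <- list(model = spec$model, params = par, seed = spec$seed)

  if (spec$model %in% c("independent-bm", "correlated-bm")) {
    tips <- if (spec$model == "independent-bm")
      sim_bm_tips(tree, sig2 = par$sig2, x0 = par$x0)
    else sim_bm_tips(tree, x0 = par$x0, Sigma = par$Sigma)
    y <- tips[, 1L]
    lat <- pmax(-90, pmin(90, tips[, 2L]))
    truth$traits <- tips
  } else if (spec$model == "variable-rates") {
    eng <- vr_engine(tree)
    node <- par$clade_node %||% pick_clade(eng, par$clade_frac)
    scal <- rep(1, eng$E)
    scal[eng$below[[node]]] <- par$mult
    tipsy <- sim_bm_tips(eng$tree, sig2 = par$sig2, scalars = scal)
    lat <- pmax(-90, pmin(90, drop(sim_bm_tips(eng$tree, sig2 = 1))))
    tree <- eng$tree
    y <- drop(tipsy)
    truth$clade_node <- node
    truth$scalars <- scal
    truth$fast_tips <- clade_tips(eng, node)
  } else {                                    # regression / bergmann
    lat_sig2 <- par$lat_sig2 %||% (35^2 / spec$root_height)
    lat <- pmax(-90, pmin(90, drop(sim_bm_tips(tree, sig2 = lat_sig2,
                                               x0 = 0))))
    sigma2 <- par$sigma2
    if (is.null(sigma2)) {
      if (is.null(par$target_r2)) stop("give sigma2 or target_r2")
      sigma2 <- calibrate_sigma2(tree, abs(lat), par$beta, par$target_r2)
    }
    eps <- if (par$lambda == 1) {
      drop(sim_bm_tips(tree, sig2 = sigma2))
    } else {
      V <- phylo_covariance(tree, lambda = par$lambda)
      drop(rnorm(n) %*% chol(sigma2 * V))
    }
    y <- par$alpha + par$beta * abs(lat) + eps[tree$tip.label]
    truth$sigma2 <- sigma2
    truth$beta <- par$beta
    truth$alpha <- par$alpha
    truth$lambda <- par$lambda
  }
  truth$lat <- setNames(as.numeric(lat), tree$tip.label)
  truth$response <- setNames(as.numeric(y), tree$tip.label)

  # clade covariate from the two root subtrees
  eng0 <- vr_engine(tree)
  rootkids <- eng0$edge[eng0$edge[, 1L] == eng0$root, 2L]
  cladeA <- if (rootkids[1L] <= n) tree$tip.label[rootkids[1L]] else
    clade_tips(eng0, rootkids[1L])
  clade <- ifelse(tree$tip.label %in% cladeA, "CladeA", "CladeB")

  occp <- spec$occurrence
  k <- 1L + as.integer(runif(n) < occp$p_multi) *
    (1L + rpois(n, occp$extra_mean))
  age_sp <- runif(n, 70, 240)
  species <- data.frame(species = tree$tip.label,
                        response = as.numeric(y),
                        period = period_from_age(age_sp),
                        clade = clade, age = age_sp)
  occs <- do.call(rbind, lapply(seq_len(n), function(i) {
    lj <- pmax(-90, pmin(90, lat[i] +
      c(0, rnorm(k[i] - 1L, 0, occp$jitter_sd))))
    tt <- temperature_from_latitude(lj, spec$gradient)
    data.frame(species = tree$tip.label[i], latitude = lj,
               mat = tt$mat, cmmt = tt$cmmt,
               age = pmax(66, pmin(251.9,
                 age_sp[i] + c(0, rnorm(k[i] - 1L, 0, 2)))))
  }))
  list(tree = tree, dataset = trait_dataset(species, occs), truth = truth)
}

# internal: tips under a node; node with tip count nearest frac * n
clade_tips <- function(eng, node) {
  e <- eng$below[[node]]
  ch <- eng$edge[e, 2L]
  eng$tree$tip.label[ch[ch <= eng$n]]
}

pick_clade <- function(eng, frac) {
  counts <- vapply(eng$clade_nodes, function(u) length(clade_tips(eng, u)), 0)
  target <- frac * eng$n
  ok <- which(counts >= 2)
  eng$clade_nodes[ok[which.min(abs(counts[ok] - target))]]
}

#' Write a named fixture to disk
#'
#' Deterministic end-to-end fixtures consumable by the I/O layer:
#' `ursid8` (8-tip bear-like clade with a strong latitude--size effect,
#' synthetic stand-in for the classic within-Ursidae pattern),
#' `dino_small` (40 species, multi-occurrence records, Mesozoic-style
#' covariates), `control_pos` / `control_neg` (250-tip correlated /
#' independent bivariate Brownian controls), and `biastable_toy` (a tiny
#' occurrence/formation table with known counts).
#'
#' @param name fixture name (above).
#' @param dir output directory (created if needed).
#' @return named character vector of written file paths, invisibly.
#' @export
make_fixture <- function(name, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c()
  wr <- function(df, file) {
    p <- file.path(dir, file)
    write.csv(df, p, row.names = FALSE, quote = FALSE)
    p
  }
  if (name == "ursid8") {
    set.seed(101)
    tree <- sim_tree(8, root_height = 20)
    lat <- c(5, -10, 15, 28, 33, 47, 55, 75)
    sigma2 <- calibrate_sigma2(tree, abs(lat), 0.0097, 0.75)
    y <- 4.2 + 0.0097 * abs(lat) + drop(sim_bm_tips(tree, sig2 = sigma2))
    tt <- temperature_from_latitude(lat, gradient_spec("modern"))
    df <- data.frame(species = tree$tip.label, response = y, latitude = lat,
                     mat = tt$mat, cmmt = tt$cmmt)
    tp <- file.path(dir, "ursid8.nwk")
    ape::write.tree(tree, tp)
    paths <- c(tree = tp, traits = wr(df, "ursid8_traits.csv"))
  } else if (name == "dino_small") {
    sim <- simulate_dataset(simulation_spec("regression", n_tips = 40,
                                            seed = 202))
    tp <- file.path(dir, "dino_small.nwk")
    ape::write.tree(sim$tree, tp)
    sp <- sim$dataset$species
    occ <- sim$dataset$occurrences
    long <- data.frame(species = occ$species,
                       response = sp$response[match(occ$species, sp$species)],
                       latitude = occ$latitude, mat = occ$mat,
                       cmmt = occ$cmmt, age = occ$age,
                       period = sp$period[match(occ$species, sp$species)],
                       clade = sp$clade[match(occ$species, sp$species)])
    paths <- c(tree = tp, traits = wr(long, "dino_small_traits.csv"))
  } else if (name %in% c("control_pos", "control_neg")) {
    sim <- if (name == "control_pos")
      simulate_dataset(simulation_spec("correlated-bm", n_tips = 250,
                                       seed = 303))
    else simulate_dataset(simulation_spec("independent-bm", n_tips = 250,
                                          seed = 404))
    tp <- file.path(dir, paste0(name, ".nwk"))
    ape::write.tree(sim$tree, tp)
    df <- data.frame(species = names(sim$truth$response),
                     response = sim$truth$response,
                     latitude = sim$truth$lat)
    paths <- c(tree = tp, traits = wr(df, paste0(name, "_traits.csv")))
  } else if (name == "biastable_toy") {
    df <- data.frame(
      taxon = paste0("tax", 1:10),
      formation = c("FmA", "FmA", "FmA", "FmB", "FmC", "FmC", "FmD", "FmE",
                    "FmF", "FmG"),
      period = c(rep("Cretaceous", 4), rep("Jurassic", 3),
                 rep("Triassic", 3)),
      palaeolat = c(75, 78, 82, 76, 12, 15, -35, 5, -88, 41),
      age = c(70, 72, 71, 80, 150, 152, 160, 210, 220, 230),
      identifiable = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, TRUE, TRUE,
                       FALSE, TRUE),
      body_fossil = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, TRUE,
                      TRUE, TRUE))
    paths <- c(occurrences = wr(df, "biastable_toy.csv"))
  } else stop("unknown fixture: ", name)
  invisible(paths)
}
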