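# Regression model specifications and design-matrix construction.
#
# Dummy coding is fixed: northern hemisphere, Triassic and Ornithischia
# are baselines coded 0 (when present among the levels); k-level factors
# use k - 1 indicators. The absolute-value transform of latitude happens
# here, at design-matrix time, never at read time.

#' Specify a PGLS regression model
#'
#' @param predictor focal predictor: `"abslat"` (absolute latitude,
#'   degrees), `"mat"` or `"cmmt"` (degrees C), or `"none"` for an
#'   intercept-only model (used by univariate variable-rates runs).
#' @param hemisphere,period,clade include dummy-coded indicators.
#' @param interactions include interactions of every requested indicator
#'   with the focal predictor.
#' @param tip_age include species tip age in Ma (Cope's-rule covariate).
#' @param formation_count,occurrence_count include the sampling-bias
#'   covariates attached by [attach_covariates()].
#' @param variable_rates allow reversible-jump branch/clade rate scalars
#'   in the Bayesian fit.
#' @param label optional model label used in reports.
#' @return an object of class `model_spec`.
#' @export
model_spec <- function(predictor = c("abslat", "mat", "cmmt", "none"),
                       hemisphere = FALSE, period = FALSE, clade = FALSE,
                       interactions = FALSE, tip_age = FALSE,
                       formation_count = FALSE, occurrence_count = FALSE,
                       variable_rates = FALSE, label = NULL) {
  predictor <- match.arg(predictor)
  if (interactions && !(hemisphere || period || clade))
    stop("interactions require at least one indicator variable")
  if (interactions && predictor == "none")
    stop("interactions require a focal predictor")
  structure(list(predictor = predictor, hemisphere = hemisphere,
                 period = period, clade = clade, interactions = interactions,
                 tip_age = tip_age, formation_count = formation_count,
                 occurrence_count = occurrence_count,
                 variable_rates = variable_rates,
                 label = label %||% spec_label(predictor, hemisphere, period,
                                               clade, interactions, tip_age,
                                               formation_count,
                                               occurrence_count,
                                               variable_rates)),
            class = "model_spec")
}

spec_label <- function(predictor, hemisphere, period, clade, interactions,
                       tip_age, formation_count, occurrence_count,
                       variable_rates) {
  parts <- c(predictor,
             if (hemisphere) "hemisphere", if (period) "period",
             if (clade) "clade", if (interactions) "interactions",
             if (tip_age) "age", if (formation_count) "formations",
             if (occurrence_count) "occurrences")
  paste0(paste(parts, collapse = "+"),
         if (variable_rates) " [VR]" else " [hom]")
}

#' @export
print.model_spec <- function(x, ...) {
  cat("model_spec:", x$label, "\n")
  invisible(x)
}

# factor metadata shared by every record of a dataset, so dummies are
# coded identically whichever occurrence is active
design_meta <- function(dataset, spec) {
  sp <- dataset$species
  meta <- list()
  if (spec$period) {
    if (all(is.na(sp$period))) stop("model needs a period column")
    lev <- unique(as.character(sp$period[!is.na(sp$period)]))
    base <- if ("Triassic" %in% lev) "Triassic" else sort(lev)[1]
    meta$period_levels <- c(base, sort(setdiff(lev, base)))
  }
  if (spec$clade) {
    if (all(is.na(sp$clade))) stop("model needs a clade column")
    lev <- unique(as.character(sp$clade[!is.na(sp$clade)]))
    base <- if ("Ornithischia" %in% lev) "Ornithischia" else sort(lev)[1]
    meta$clade_levels <- c(base, sort(setdiff(lev, base)))
  }
  if (spec$tip_age && all(is.na(sp$age)))
    stop("model needs tip ages (age column)")
  if (spec$formation_count && all(is.na(sp$formation_count)))
    stop("model needs formation counts; see attach_covariates()")
  if (spec$occurrence_count && all(is.na(sp$occurrence_count)))
    stop("model needs occurrence counts; see attach_covariates()")
  meta
}

# one design row from record-level fields (lat, mat, cmmt, south) and
# species-level fields
design_row_frame <- function(df, spec, meta) {
  n <- nrow(df)
  out <- list(`(Intercept)` = rep(1, n))
  focal <- NULL
  if (spec$predictor != "none") {
    focal <- switch(spec$predictor,
                    abslat = abs(df$latitude),
                    mat = df$mat,
                    cmmt = df$cmmt)
    if (any(!is.finite(focal)))
      stop("missing values in focal predictor '", spec$predictor, "'")
    out[[spec$predictor]] <- focal
  }
  dummies <- list()
  if (spec$hemisphere) dummies$hemisphereS <- as.numeric(df$latitude < 0)
  if (spec$period)
    for (lv in meta$period_levels[-1])
      dummies[[paste0("period", lv)]] <- as.numeric(df$period == lv)
  if (spec$clade)
    for (lv in meta$clade_levels[-1])
      dummies[[paste0("clade", lv)]] <- as.numeric(df$clade == lv)
  out <- c(out, dummies)
  if (spec$interactions)
    for (nm in names(dummies))
      out[[paste0(spec$predictor, ":", nm)]] <- focal * dummies[[nm]]
  if (spec$tip_age) out$age <- df$age
  if (spec$formation_count) out$formation_count <- df$formation_count
  if (spec$occurrence_count) out$occurrence_count <- df$occurrence_count
  X <- do.call(cbind, out)
  rownames(X) <- NULL
  X
}

# per-species list of k_i x p design matrices, one row per occurrence
design_records <- function(dataset, spec) {
  meta <- design_meta(dataset, spec)
  sp <- dataset$species
  occ <- dataset$occurrences
  idx <- match(occ$species, sp$species)
  df <- data.frame(latitude = occ$latitude, mat = occ$mat, cmmt = occ$cmmt,
                   period = sp$period[idx], clade = sp$clade[idx],
                   age = sp$age[idx],
                   formation_count = sp$formation_count[idx],
                   occurrence_count = sp$occurrence_count[idx])
  X <- design_row_frame(df, spec, meta)
  lapply(seq_len(nrow(sp)), function(i)
    X[idx == i, , drop = FALSE])
}

#' Build a design matrix from a trait dataset
#'
#' Multi-occurrence species are reduced deterministically: continuous
#' record-level fields are averaged after transformation (so `abslat` is
#' the mean of per-record absolute latitudes) and the hemisphere indicator
#' takes the majority hemisphere (ties resolve to the northern baseline).
#' The stochastic treatment of occurrence records lives in [run_chain()].
#'
#' @param dataset a `trait_dataset`.
#' @param spec a [model_spec()].
#' @param assignment optional integer vector (one entry per species)
#'   choosing a single occurrence record for each species instead of the
#'   mean reduction.
#' @return numeric design matrix with one row per species, in dataset
#'   species order.
#' @export
design_matrix <- function(dataset, spec, assignment = NULL) {
  meta <- design_meta(dataset, spec)
  sp <- dataset$species
  occ <- dataset$occurrences
  if (!is.null(assignment)) {
    stopifnot(length(assignment) == nrow(sp))
    pick <- unlist(lapply(seq_len(nrow(sp)), function(i) {
      w <- which(occ$species == sp$species[i])
      w[assignment[i]]
    }))
    o <- occ[pick, , drop = FALSE]
    df <- data.frame(latitude = o$latitude, mat = o$mat, cmmt = o$cmmt,
                     period = sp$period, clade = sp$clade, age = sp$age,
                     formation_count = sp$formation_count,
                     occurrence_count = sp$occurrence_count)
    X <- design_row_frame(df, spec, meta)
    rownames(X) <- sp$species
    return(X)
  }
  Xrec <- design_records(dataset, spec)
  X <- t(vapply(Xrec, function(m) {
    cm <- colMeans(m)
    s <- grep("^hemisphereS$", colnames(m))
    if (length(s)) cm[s] <- as.numeric(mean(m[, s]) > 0.5)
    cm
  }, numeric(ncol(Xrec[[1]]))))
  colnames(X) <- colnames(Xrec[[1]])
  rownames(X) <- sp$species
  X
}

#' The model ladder used for model selection
#'
#' An ordered list of regression specifications of increasing complexity:
#' focal predictor only; plus hemisphere; plus geologic period; plus
#' clade; plus indicator-by-predictor interactions; plus tip age (Cope's
#' rule); plus formation count; plus occurrence count -- each in
#' homogeneous-rate and variable-rates variants. The mammaliaform preset
#' omits the period and clade models (only a hemisphere difference is
#' testable at that sample size) and keeps the age and bias-covariate
#' models.
#'
#' @param dataset a `trait_dataset`; requested specs are checked against
#'   its available columns.
#' @param preset `"dinosaur"` (full ladder) or `"mammaliaform"`.
#' @param predictor focal predictor passed to every spec.
#' @return named list of [model_spec()] objects.
#' @export
model_ladder <- function(dataset, preset = c("dinosaur", "mammaliaform"),
                         predictor = "abslat") {
  preset <- match.arg(preset)
  base <- list(
    m1 = list(),
    m2 = list(hemisphere = TRUE),
    m3 = list(period = TRUE),
    m4 = list(clade = TRUE),
    m5 = list(hemisphere = TRUE, period = TRUE, clade = TRUE,
              interactions = TRUE),
    m6 = list(tip_age = TRUE),
    m7 = list(formation_count = TRUE),
    m8 = list(occurrence_count = TRUE))
  if (preset == "mammaliaform") base <- base[c("m1", "m2", "m6", "m7", "m8")]
  out <- list()
  for (nm in names(base)) {
    for (vr in c(FALSE, TRUE)) {
      args <- c(list(predictor = predictor, variable_rates = vr), base[[nm]])
      sp <- do.call(model_spec, args)
      design_meta(dataset, sp)   # validates required columns
      out[[paste0(nm, if (vr) "_vr" else "_hom")]] <- sp
    }
  }
  out
}
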