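# Geographic- and time-specific fossil sampling metric: tetrapod
# formation and occurrence counts per 20-degree latitudinal zone per
# Mesozoic period, attached to taxa by their average age and
# palaeolatitude.

MESOZOIC_PERIODS <- c("Triassic", "Jurassic", "Cretaceous")

# ICS numeric bounds (Ma), configurable through the `bounds` arguments
MESOZOIC_BOUNDS <- c(Triassic_old = 251.9, Jurassic_old = 201.4,
                     Cretaceous_old = 145.0, Cretaceous_young = 66.0)

#' Latitudinal zone index
#'
#' Nine contiguous 20-degree zones partition `[-90, 90]`; zone 0 is the
#' southernmost. Bins are half-open `[-90 + 20k, -70 + 20k)` with the top
#' bin closed, so +90 maps to zone 8.
#'
#' @param palaeolat palaeolatitude(s) in degrees, in `[-90, 90]`.
#' @return integer zone indices in `0:8`.
#' @export
assign_zone <- function(palaeolat) {
  if (any(!is.finite(palaeolat)) || any(palaeolat < -90 | palaeolat > 90))
    stop("palaeolatitude outside [-90, 90]")
  pmin(floor((palaeolat + 90) / 20), 8L)
}

#' Geologic period from a numeric age
#'
#' @param age age(s) in Ma.
#' @param bounds named numeric period bounds (Ma), defaulting to the ICS
#'   values Triassic 251.9--201.4, Jurassic 201.4--145.0, Cretaceous
#'   145.0--66.0.
#' @return character vector of period names, `NA` outside the Mesozoic.
#' @export
period_from_age <- function(age, bounds = MESOZOIC_BOUNDS) {
  out <- rep(NA_character_, length(age))
  out[age <= bounds["Triassic_old"] & age > bounds["Jurassic_old"]] <- "Triassic"
  out[age <= bounds["Jurassic_old"] & age > bounds["Cretaceous_old"]] <- "Jurassic"
  out[age <= bounds["Cretaceous_old"] & age >= bounds["Cretaceous_young"]] <- "Cretaceous"
  out
}

#' Build the sampling-bias count table
#'
#' From an occurrence table (one row per fossil occurrence), counts per
#' (zone, period) cell the number of unique fossil-bearing formations and
#' the number of terrestrial tetrapod occurrences, after removing
#' taxonomically unidentifiable fossils and those not based on body
#' fossils. Period labels take precedence over numeric ages when both are
#' present.
#'
#' @param occurrences data.frame with columns `formation`, `palaeolat`,
#'   and `period` and/or `age`; optional logical columns `identifiable`
#'   and `body_fossil` (missing columns default to `TRUE`).
#' @param bounds period bounds for [period_from_age()].
#' @return list of class `bias_table`: 9 x 3 integer matrices
#'   `formations` and `occurrences` (rows zones 0--8, columns the three
#'   periods) plus the number of retained occurrence rows.
#' @export
build_counts <- function(occurrences, bounds = MESOZOIC_BOUNDS) {
  df <- as.data.frame(occurrences)
  need <- c("formation", "palaeolat")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (is.null(df$identifiable)) df$identifiable <- rep(TRUE, nrow(df))
  if (is.null(df$body_fossil)) df$body_fossil <- rep(TRUE, nrow(df))
  if (!is.null(df$period)) {
    per <- as.character(df$period)
    if (!is.null(df$age)) {
      fill <- is.na(per) | per == ""
      per[fill] <- period_from_age(df$age[fill], bounds)
    }
  } else {
    if (is.null(df$age)) stop("need a period or age column")
    per <- period_from_age(df$age, bounds)
  }
  bad <- !is.na(per) & per != "" & !(per %in% MESOZOIC_PERIODS)
  if (any(bad)) stop("unknown period label: ",
                     paste(unique(per[bad]), collapse = ", "))
  empty <- matrix(0L, 9, 3, dimnames = list(paste0("zone", 0:8),
                                            MESOZOIC_PERIODS))
  if (nrow(df) == 0L)
    return(structure(list(formations = empty, occurrences = empty,
                          retained = 0L), class = "bias_table"))
  keep <- df$identifiable & df$body_fossil & !is.na(per) &
    per %in% MESOZOIC_PERIODS
  df <- df[keep, , drop = FALSE]
  per <- per[keep]
  zone <- assign_zone(df$palaeolat)
  fm <- occ <- empty
  for (cell in split(seq_len(nrow(df)),
                     list(zone = factor(zone, 0:8),
                          period = factor(per, MESOZOIC_PERIODS)),
                     drop = TRUE)) {
    z <- zone[cell[1]] + 1L
    p <- per[cell[1]]
    fm[z, p] <- length(unique(df$formation[cell]))
    occ[z, p] <- length(cell)
  }
  structure(list(formations = fm, occurrences = occ,
                 retained = nrow(df)), class = "bias_table")
}

#' @export
print.bias_table <- function(x, ...) {
  cat("bias_table:", x$retained, "retained occurrences\n")
  cat("formations:\n"); print(x$formations)
  cat("occurrences:\n"); print(x$occurrences)
  invisible(x)
}

#' Attach sampling-bias covariates to a trait dataset
#'
#' Each species receives the formation and occurrence counts of the
#' (zone, period) cell containing its mean signed palaeolatitude and mean
#' age across its occurrence records (the species' own period label, when
#' present, takes precedence over the age-derived period). The operation
#' is idempotent: counts are recomputed, not accumulated.
#'
#' @param dataset a `trait_dataset` whose occurrences carry latitudes and
#'   (unless period labels are present) ages.
#' @param table a `bias_table` from [build_counts()].
#' @param bounds period bounds for [period_from_age()].
#' @return the dataset with `formation_count` and `occurrence_count`
#'   filled in.
#' @export
attach_covariates <- function(dataset, table, bounds = MESOZOIC_BOUNDS) {
  stopifnot(inherits(dataset, "trait_dataset"), inherits(table, "bias_table"))
  sp <- dataset$species
  occ <- dataset$occurrences
  mlat <- vapply(sp$species, function(s)
    mean(occ$latitude[occ$species == s]), 0)
  mage <- vapply(sp$species, function(s) {
    a <- occ$age[occ$species == s]
    if (all(is.na(a))) NA_real_ else mean(a, na.rm = TRUE)
  }, 0)
  per <- as.character(sp$period)
  need_age <- is.na(per) | per == ""
  per[need_age] <- period_from_age(mage[need_age], bounds)
  bad <- is.na(per) | !(per %in% MESOZOIC_PERIODS)
  if (any(bad))
    stop("species with mean age outside the Mesozoic (or no period): ",
         paste(sp$species[bad], collapse = ", "))
  zone <- assign_zone(mlat)
  pc <- match(per, MESOZOIC_PERIODS)
  sp$formation_count <- table$formations[cbind(zone + 1L, pc)]
  sp$occurrence_count <- table$occurrences[cbind(zone + 1L, pc)]
  trait_dataset(sp, occ)
}
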