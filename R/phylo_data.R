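# Data model and I/O: trees, trait tables with linked occurrence records,
# and taxon alignment between the two.

#' Normalise taxon names
#'
#' Trims whitespace and unifies runs of spaces/underscores to a single
#' underscore. Matching between trees and tables is exact after this
#' normalisation; there is no fuzzy matching.
#'
#' @param x character vector of taxon names.
#' @return normalised character vector.
#' @export
normalize_taxa <- function(x) gsub("[ _]+", "_", trimws(as.character(x)))

#' Read a rooted, time-calibrated phylogeny
#'
#' Reads a single tree from a Newick or Nexus file and validates the
#' invariants required downstream: rooted, branch lengths present and
#' non-negative, tip labels unique. Polytomies are preserved as read; they
#' are resolved (deterministically, with zero-length branches) only inside
#' covariance and contrast computations.
#'
#' @param path path to the tree file.
#' @param format "auto" (default; sniffs a `#NEXUS` header), "newick" or
#'   "nexus".
#' @param index which tree to take when the file holds several; an error is
#'   raised if the file holds several trees and no index is given.
#' @return an [ape::phylo] object with normalised tip labels.
#' @export
read_tree <- function(path, format = c("auto", "newick", "nexus"), index = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("tree file not found: ", path)
  if (format == "auto") {
    first <- toupper(trimws(readLines(path, n = 1L, warn = FALSE)))
    format <- if (startsWith(first, "#NEXUS")) "nexus" else "newick"
  }
  tr <- tryCatch(
    suppressWarnings(
      if (format == "nexus") ape::read.nexus(path) else ape::read.tree(path)),
    error = function(e) stop("could not parse tree file '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  if (inherits(tr, "multiPhylo")) {
    if (is.null(index)) {
      if (length(tr) != 1L)
        stop("file contains ", length(tr), " trees; supply `index`")
      tr <- tr[[1L]]
    } else tr <- tr[[index]]
  }
  if (is.null(tr) || !inherits(tr, "phylo"))
    stop("could not parse tree file '", path, "'")
  if (!ape::is.rooted(tr) && !ape::is.binary(tr))
    stop("tree must be rooted")
  validate_tree(tr)
  tr$tip.label <- normalize_taxa(tr$tip.label)
  tr
}

# A basal multifurcation is accepted (ape encodes it identically to an
# unrooted tree); it is resolved with zero-length branches downstream,
# which leaves the covariance unchanged.
validate_tree <- function(tr) {
  if (is.null(tr$edge.length)) stop("tree must have branch lengths")
  if (any(tr$edge.length < 0)) stop("negative branch lengths in tree")
  if (anyDuplicated(normalize_taxa(tr$tip.label)))
    stop("duplicate tip labels after normalisation")
  invisible(tr)
}

#' Declare the column schema of a trait table
#'
#' Maps the logical fields of a trait dataset onto the column names of a
#' delimited file. `species`, `response` and `latitude` are required; the
#' rest are optional. A YAML file with the same keys may be passed to
#' [read_traits()] instead.
#'
#' @param species,response,latitude,mat,cmmt,period,clade,age,formation
#'   column names; set optional ones to `NULL` if absent.
#' @return a named list of class `trait_schema`.
#' @export
trait_schema <- function(species = "species", response = "response",
                         latitude = "latitude", mat = "mat", cmmt = "cmmt",
                         period = "period", clade = "clade", age = "age",
                         formation = "formation") {
  structure(list(species = species, response = response, latitude = latitude,
                 mat = mat, cmmt = cmmt, period = period, clade = clade,
                 age = age, formation = formation),
            class = "trait_schema")
}

read_schema <- function(path) {
  sc <- yaml::read_yaml(path)
  do.call(trait_schema, sc[intersect(names(sc), names(formals(trait_schema)))])
}

#' Construct a trait dataset
#'
#' A trait dataset holds one row per species (response on the log10 scale,
#' plus optional categorical covariates, tip age and sampling-bias counts)
#' and one or more linked occurrence records per species (signed
#' palaeolatitude in degrees, optional MAT/CMMT in degrees C, optional age
#' in Ma). Latitudes are stored signed; the absolute-value transform is
#' applied once, when a design matrix is built.
#'
#' @param species data.frame with columns `species`, `response` and
#'   optionally `period`, `clade`, `age`, `formation_count`,
#'   `occurrence_count`.
#' @param occurrences data.frame with columns `species`, `latitude` and
#'   optionally `mat`, `cmmt`, `age`; at least one row per species.
#' @return an object of class `trait_dataset`.
#' @export
trait_dataset <- function(species, occurrences) {
  species <- as.data.frame(species)
  occurrences <- as.data.frame(occurrences)
  stopifnot(all(c("species", "response") %in% names(species)),
            all(c("species", "latitude") %in% names(occurrences)))
  species$species <- normalize_taxa(species$species)
  occurrences$species <- normalize_taxa(occurrences$species)
  for (col in c("period", "clade", "age", "formation_count", "occurrence_count"))
    if (is.null(species[[col]])) species[[col]] <- NA
  for (col in c("mat", "cmmt", "age"))
    if (is.null(occurrences[[col]])) occurrences[[col]] <- NA_real_
  if (anyDuplicated(species$species)) stop("duplicate species rows")
  if (!all(is.finite(species$response))) stop("non-finite response values")
  if (!all(occurrences$species %in% species$species))
    stop("occurrence records for species missing from the species table")
  if (!all(species$species %in% occurrences$species))
    stop("species without any occurrence record: ",
         paste(setdiff(species$species, occurrences$species), collapse = ", "))
  lat <- occurrences$latitude
  if (any(!is.finite(lat)) || any(lat < -90 | lat > 90))
    stop("occurrence latitudes must lie in [-90, 90]")
  both <- is.finite(occurrences$mat) & is.finite(occurrences$cmmt)
  if (any(both & occurrences$mat < occurrences$cmmt))
    stop("MAT < CMMT in some occurrence records")
  structure(list(species = species, occurrences = occurrences),
            class = "trait_dataset")
}

#' @export
print.trait_dataset <- function(x, ...) {
  k <- table(x$occurrences$species)
  cat("trait_dataset:", nrow(x$species), "species,",
      nrow(x$occurrences), "occurrence records",
      sprintf("(%d species with multiple records)\n", sum(k > 1)))
  invisible(x)
}

n_species <- function(dataset) nrow(dataset$species)

#' Species carrying several linked occurrence records
#'
#' @param dataset a `trait_dataset`.
#' @return character vector of species names with more than one record.
#' @export
multi_occurrence <- function(dataset) {
  k <- table(dataset$occurrences$species)
  names(k)[k > 1]
}

#' Read a trait table with linked occurrence records
#'
#' Reads a delimited text file (comma or tab separated, sniffed from the
#' header) in which a species may appear on several rows, one per
#' occurrence; rows for the same species are collapsed into one species
#' entry holding multiple linked occurrence records. Species-level fields
#' (response, period, clade) are taken from the first row of each species
#' and must not conflict.
#'
#' @param path path to the delimited file.
#' @param schema a [trait_schema()] or path to a YAML schema file.
#' @param tree optional [ape::phylo]; when given, species absent from the
#'   tree are handled according to `on_missing`.
#' @param on_missing `"fail"` (default) or `"drop"`: drop species missing
#'   from the tree with a warning naming them.
#' @return a [trait_dataset()].
#' @export
read_traits <- function(path, schema = trait_schema(), tree = NULL,
                        on_missing = c("fail", "drop")) {
  on_missing <- match.arg(on_missing)
  if (is.character(schema)) schema <- read_schema(schema)
  if (!file.exists(path)) stop("trait file not found: ", path)
  hdr <- readLines(path, n = 1L)
  sep <- if (grepl("\t", hdr)) "\t" else ","
  df <- read.csv(path, sep = sep, stringsAsFactors = FALSE,
                 check.names = FALSE, fileEncoding = "UTF-8")
  need <- c(schema$species, schema$response, schema$latitude)
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing required columns: ", paste(miss, collapse = ", "))
  getcol <- function(nm) if (!is.null(nm) && nm %in% names(df)) df[[nm]] else NULL
  num <- function(x, what) {
    if (is.null(x)) return(NULL)
    out <- suppressWarnings(as.numeric(x))
    bad <- !is.na(x) & x != "" & is.na(out)
    if (any(bad)) stop("non-numeric values in ", what, " column: ",
                       paste(unique(x[bad]), collapse = ", "))
    out
  }
  sp <- normalize_taxa(df[[schema$species]])
  occ <- data.frame(species = sp,
                    latitude = num(df[[schema$latitude]], "latitude"),
                    mat = num(getcol(schema$mat), "mat") %||% NA_real_,
                    cmmt = num(getcol(schema$cmmt), "cmmt") %||% NA_real_,
                    age = num(getcol(schema$age), "age") %||% NA_real_,
                    stringsAsFactors = FALSE)
  first <- !duplicated(sp)
  species <- data.frame(species = sp[first],
                        response = num(df[[schema$response]], "response")[first],
                        stringsAsFactors = FALSE)
  pc <- getcol(schema$period); cc <- getcol(schema$clade)
  species$period <- if (is.null(pc)) NA else as.character(pc)[first]
  species$clade <- if (is.null(cc)) NA else as.character(cc)[first]
  ages <- num(getcol(schema$age), "age")
  species$age <- if (is.null(ages)) NA_real_ else
    vapply(split(ages, factor(sp, levels = sp[first])),
           function(a) if (all(is.na(a))) NA_real_ else mean(a, na.rm = TRUE), 0)
  if (!is.null(tree)) {
    tips <- normalize_taxa(tree$tip.label)
    absent <- setdiff(species$species, tips)
    if (length(absent)) {
      if (on_missing == "fail")
        stop("species absent from tree: ", paste(absent, collapse = ", "))
      warning("dropping species absent from tree: ",
              paste(absent, collapse = ", "))
      keep <- !(species$species %in% absent)
      species <- species[keep, , drop = FALSE]
      occ <- occ[occ$species %in% species$species, , drop = FALSE]
    }
  }
  trait_dataset(species, occ)
}

#' Align a trait dataset and a phylogeny on their shared taxa
#'
#' Prunes the tree to the dataset's species and restricts the dataset to
#' the tree's tips; patristic distances among retained tips are untouched
#' by pruning. Orders are made consistent (dataset rows follow the pruned
#' tree's tip order).
#'
#' @param dataset a `trait_dataset`.
#' @param tree an [ape::phylo].
#' @return list with elements `dataset` and `tree`.
#' @export
align_traits <- function(dataset, tree) {
  stopifnot(inherits(dataset, "trait_dataset"), inherits(tree, "phylo"))
  tree$tip.label <- normalize_taxa(tree$tip.label)
  shared <- intersect(tree$tip.label, dataset$species$species)
  if (length(shared) == 0L) stop("no taxa shared between dataset and tree")
  if (length(shared) < 2L) stop("fewer than two shared taxa")
  tree2 <- if (length(shared) < length(tree$tip.label))
    ape::keep.tip(tree, shared) else tree
  sp <- dataset$species[match(tree2$tip.label, dataset$species$species), ,
                        drop = FALSE]
  rownames(sp) <- NULL
  occ <- dataset$occurrences[dataset$occurrences$species %in% shared, ,
                             drop = FALSE]
  occ <- occ[order(match(occ$species, tree2$tip.label)), , drop = FALSE]
  rownames(occ) <- NULL
  list(dataset = trait_dataset(sp, occ), tree = tree2)
}

#' Taxon-match report between a dataset and a tree
#'
#' @param dataset a `trait_dataset`.
#' @param tree an [ape::phylo].
#' @return list with `matched`, `tree_only`, `data_only` character vectors,
#'   printed as a short report.
#' @export
taxon_report <- function(dataset, tree) {
  tips <- normalize_taxa(tree$tip.label)
  spp <- dataset$species$species
  out <- list(matched = intersect(tips, spp),
              tree_only = setdiff(tips, spp),
              data_only = setdiff(spp, tips))
  class(out) <- "taxon_report"
  out
}

#' @export
print.taxon_report <- function(x, ...) {
  cat("matched taxa:   ", length(x$matched), "\n")
  cat("tree only:      ", length(x$tree_only),
      if (length(x$tree_only)) paste0(" (", paste(head(x$tree_only, 5),
                                                  collapse = ", "),
                                      if (length(x$tree_only) > 5) ", ..." else "",
                                      ")") else "", "\n", sep = "")
  cat("dataset only:   ", length(x$data_only),
      if (length(x$data_only)) paste0(" (", paste(head(x$data_only, 5),
                                                  collapse = ", "),
                                      if (length(x$data_only) > 5) ", ..." else "",
                                      ")") else "", "\n", sep = "")
  invisible(x)
}
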