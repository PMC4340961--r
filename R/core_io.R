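#' Survey dataset container
#'
#' Bundles the three tables the analysis consumes: the square grid with its
#' four environmental covariates, the squares x species presence/absence
#' matrix, and the per-species trait table (ecological classification and
#' national red-list status).
#'
#' @param grid data.frame with columns `square_id`, `x`, `y` (centroid
#'   coordinates, m, projected plane), `land_area` (m^2 within the square),
#'   `shoreline` (m), `dist_sea` (m to open sea), `width` (archipelago
#'   width, m).
#' @param presence integer matrix of 0/1, rows named by `square_id`, columns
#'   by species name.
#' @param traits data.frame with columns `species`,
#'   `classification` (`"specialist"` or `"generalist"`) and `redlist`
#'   (`"none"`, `"NT"` or `"VU"`).
#' @param provenance free-text character scalar recording origin (seed,
#'   generator parameters or file source).
#' @param truth optional data.frame of true simulation coefficients
#'   (kept by the generator for parameter-recovery checks).
#' @return an object of class `survey_dataset`.
#' @export
survey_dataset <- function(grid, presence, traits, provenance = "", truth = NULL) {
  ds <- structure(
    list(grid = grid, presence = presence, traits = traits,
         provenance = provenance, truth = truth),
    class = "survey_dataset"
  )
  validate_dataset(ds)
  ds
}

CLASSIFICATIONS <- c("specialist", "generalist")
REDLIST_LEVELS <- c("none", "NT", "VU")
SQUARE_AREA <- 1e6  # 1 km^2 in m^2

#' Validate a survey dataset
#'
#' Checks the structural invariants: unique labels, presence values in
#' {0,1}, a trait record for every species, closed trait vocabularies,
#' covariate ranges (0 <= land_area <= 1e6 m^2, shoreline >= 0,
#' width >= dist_sea >= 0) and identical ordered square sets in the grid
#' and the occurrence matrix.
#'
#' @param ds a `survey_dataset`.
#' @return `ds`, invisibly; raises a classed error on violation.
#' @export
validate_dataset <- function(ds) {
  g <- ds$grid
  need <- c("square_id", "x", "y", "land_area", "shoreline", "dist_sea", "width")
  miss <- setdiff(need, names(g))
  if (length(miss))
    stop_named("skerrydiv_missing_column",
               "grid table is missing column(s): %s", paste(miss, collapse = ", "))
  if (anyDuplicated(g$square_id))
    stop_named("skerrydiv_duplicate_id", "duplicate square_id: %s",
               paste(unique(g$square_id[duplicated(g$square_id)]), collapse = ", "))
  if (any(g$land_area < 0 | g$land_area > SQUARE_AREA))
    stop_named("skerrydiv_bad_covariate", "land_area outside [0, %g] m^2", SQUARE_AREA)
  if (any(g$shoreline < 0) || any(g$dist_sea < 0))
    stop_named("skerrydiv_bad_covariate", "negative shoreline or dist_sea")
  if (any(g$width < g$dist_sea - 1e-9))
    stop_named("skerrydiv_bad_covariate", "width must be >= dist_sea")

  p <- ds$presence
  if (!is.matrix(p) || (nrow(p) > 0 && is.null(rownames(p))) ||
      (ncol(p) > 0 && is.null(colnames(p))))
    stop_named("skerrydiv_bad_presence", "presence must be a matrix with dimnames")
  if (anyDuplicated(colnames(p)))
    stop_named("skerrydiv_duplicate_id", "duplicate species in presence matrix")
  bad <- which(!(p %in% c(0L, 1L)))
  if (length(bad)) {
    i <- arrayInd(bad[1], dim(p))
    stop_named("skerrydiv_bad_presence",
               "presence value %s at square '%s', species '%s' is not 0/1",
               format(p[bad[1]]), rownames(p)[i[1]], colnames(p)[i[2]])
  }
  if (nrow(p) != nrow(g) ||
      (nrow(p) > 0 && !identical(rownames(p), as.character(g$square_id))))
    stop_named("skerrydiv_label_mismatch",
               "grid square_ids and presence rownames differ (order matters)")

  tr <- ds$traits
  tn <- c("species", "classification", "redlist")
  miss <- setdiff(tn, names(tr))
  if (length(miss))
    stop_named("skerrydiv_missing_column",
               "trait table is missing column(s): %s", paste(miss, collapse = ", "))
  if (anyDuplicated(tr$species))
    stop_named("skerrydiv_duplicate_id", "duplicate species in trait table")
  orphan <- setdiff(colnames(p), tr$species)
  if (length(orphan))
    stop_named("skerrydiv_orphan_species",
               "species lacking a trait record: %s", paste(orphan, collapse = ", "))
  if (!all(tr$classification %in% CLASSIFICATIONS))
    stop_named("skerrydiv_bad_trait", "classification must be one of: %s",
               paste(CLASSIFICATIONS, collapse = ", "))
  if (!all(tr$redlist %in% REDLIST_LEVELS))
    stop_named("skerrydiv_bad_trait", "redlist must be one of: %s",
               paste(REDLIST_LEVELS, collapse = ", "))
  invisible(ds)
}

#' @export
print.survey_dataset <- function(x, ...) {
  cat(sprintf("survey_dataset: %d squares x %d species\n",
              nrow(x$presence), ncol(x$presence)))
  cat(sprintf("  specialists: %d  generalists: %d  red-listed: %d\n",
              sum(x$traits$classification == "specialist"),
              sum(x$traits$classification == "generalist"),
              sum(x$traits$redlist != "none")))
  if (nzchar(x$provenance)) cat("  provenance:", x$provenance, "\n")
  invisible(x)
}

fmt_num <- function(x) {
  # %.17g round-trips doubles exactly through text
  ifelse(x == floor(x) & abs(x) < 1e15, sprintf("%.0f", x), sprintf("%.17g", x))
}

#' Write a survey dataset to delimited text tables
#'
#' Emits `squares.csv`, `occurrences.csv` (long form), `traits.csv` and,
#' when present, `truth.csv` and `provenance.txt`. Numeric columns are
#' written with round-trip precision so `read_dataset()` reproduces the
#' dataset exactly.
#'
#' @param ds a valid `survey_dataset`.
#' @param out_dir directory (created if needed).
#' @return named character vector of file paths, invisibly.
#' @export
write_dataset <- function(ds, out_dir) {
  validate_dataset(ds)
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE))
    stop_named("skerrydiv_io_error", "cannot create directory '%s'", out_dir)

  g <- ds$grid
  sq <- data.frame(square_id = g$square_id,
                   x = fmt_num(g$x), y = fmt_num(g$y),
                   land_area_m2 = fmt_num(g$land_area),
                   shoreline_m = fmt_num(g$shoreline),
                   dist_sea_m = fmt_num(g$dist_sea),
                   width_m = fmt_num(g$width))
  paths <- c(squares = file.path(out_dir, "squares.csv"),
             occurrences = file.path(out_dir, "occurrences.csv"),
             traits = file.path(out_dir, "traits.csv"))
  utils::write.csv(sq, paths[["squares"]], row.names = FALSE, quote = TRUE)

  p <- ds$presence
  idx <- which(p == 1L, arr.ind = TRUE)
  # keep square order stable; header-only file when no species or no records
  occ <- data.frame(square_id = rownames(p)[idx[, 1]],
                    species = (colnames(p) %||% character())[idx[, 2]],
                    present = rep(1L, nrow(idx)))
  occ <- occ[order(match(occ$square_id, rownames(p)), occ$species), , drop = FALSE]
  utils::write.csv(occ, paths[["occurrences"]], row.names = FALSE, quote = TRUE)
  utils::write.csv(ds$traits, paths[["traits"]], row.names = FALSE, quote = TRUE)

  if (!is.null(ds$truth)) {
    paths <- c(paths, truth = file.path(out_dir, "truth.csv"))
    tt <- ds$truth
    num <- vapply(tt, is.numeric, logical(1))
    tt[num] <- lapply(tt[num], function(v) fmt_num(v))
    utils::write.csv(tt, paths[["truth"]], row.names = FALSE, quote = TRUE)
  }
  if (nzchar(ds$provenance)) {
    paths <- c(paths, provenance = file.path(out_dir, "provenance.txt"))
    writeLines(ds$provenance, paths[["provenance"]])
  }
  invisible(paths)
}

#' Read a survey dataset from delimited text tables
#'
#' The occurrence table may be long form (`square_id,species,present`) or a
#' wide 0/1 matrix whose first column is `square_id`. Squares absent from
#' the occurrence table get all-zero rows; species are the trait-table
#' species (so all-absent species keep their columns).
#'
#' @param squares_path,occurrence_path,traits_path file paths.
#' @param truth_path,provenance_path optional extra files written by
#'   [write_dataset()].
#' @return a validated `survey_dataset`.
#' @export
read_dataset <- function(squares_path, occurrence_path, traits_path,
                         truth_path = NULL, provenance_path = NULL) {
  for (f in c(squares_path, occurrence_path, traits_path))
    if (!file.exists(f))
      stop_named("skerrydiv_io_error", "file not found: '%s'", f)

  sq <- utils::read.csv(squares_path, stringsAsFactors = FALSE,
                        colClasses = c(square_id = "character"))
  need <- c("square_id", "x", "y", "land_area_m2", "shoreline_m",
            "dist_sea_m", "width_m")
  miss <- setdiff(need, names(sq))
  if (length(miss))
    stop_named("skerrydiv_missing_column",
               "squares table is missing column(s): %s", paste(miss, collapse = ", "))
  grid <- data.frame(square_id = sq$square_id, x = sq$x, y = sq$y,
                     land_area = sq$land_area_m2, shoreline = sq$shoreline_m,
                     dist_sea = sq$dist_sea_m, width = sq$width_m,
                     stringsAsFactors = FALSE)

  tr <- utils::read.csv(traits_path, stringsAsFactors = FALSE,
                        colClasses = "character")
  miss <- setdiff(c("species", "classification", "redlist"), names(tr))
  if (length(miss))
    stop_named("skerrydiv_missing_column",
               "trait table is missing column(s): %s", paste(miss, collapse = ", "))

  oc <- utils::read.csv(occurrence_path, stringsAsFactors = FALSE,
                        check.names = FALSE)
  species <- tr$species
  pres <- matrix(0L, nrow(grid), length(species),
                 dimnames = list(grid$square_id, species))
  long <- all(c("square_id", "species", "present") %in% names(oc))
  if (long) {
    if (nrow(oc)) {
      bad <- which(!(oc$present %in% c(0, 1)))
      if (length(bad))
        stop_named("skerrydiv_bad_presence",
                   "presence value %s at square '%s', species '%s' is not 0/1",
                   format(oc$present[bad[1]]), oc$square_id[bad[1]], oc$species[bad[1]])
      orphan <- setdiff(unique(oc$species), species)
      if (length(orphan))
        stop_named("skerrydiv_orphan_species",
                   "species lacking a trait record: %s", paste(orphan, collapse = ", "))
      unk <- setdiff(unique(oc$square_id), grid$square_id)
      if (length(unk))
        stop_named("skerrydiv_label_mismatch",
                   "occurrence squares not in grid: %s", paste(unk, collapse = ", "))
      keep <- oc$present == 1
      pres[cbind(as.character(oc$square_id[keep]), oc$species[keep])] <- 1L
    }
  } else {
    if (names(oc)[1] != "square_id")
      stop_named("skerrydiv_missing_column",
                 "occurrence table must be long form or wide with first column square_id")
    orphan <- setdiff(names(oc)[-1], species)
    if (length(orphan))
      stop_named("skerrydiv_orphan_species",
                 "species lacking a trait record: %s", paste(orphan, collapse = ", "))
    m <- as.matrix(oc[, -1, drop = FALSE])
    bad <- which(!(m %in% c(0, 1)))
    if (length(bad)) {
      i <- arrayInd(bad[1], dim(m))
      stop_named("skerrydiv_bad_presence",
                 "presence value %s at square '%s', species '%s' is not 0/1",
                 format(m[bad[1]]), oc$square_id[i[1]], colnames(m)[i[2]])
    }
    pres[as.character(oc$square_id), colnames(m)] <- storage_int(m)
  }

  truth <- NULL
  if (is.null(truth_path)) {
    tp <- file.path(dirname(squares_path), "truth.csv")
    if (file.exists(tp)) truth_path <- tp
  }
  if (!is.null(truth_path) && file.exists(truth_path))
    truth <- utils::read.csv(truth_path, stringsAsFactors = FALSE)
  prov <- ""
  if (is.null(provenance_path)) {
    pp <- file.path(dirname(squares_path), "provenance.txt")
    if (file.exists(pp)) provenance_path <- pp
  }
  if (!is.null(provenance_path) && file.exists(provenance_path))
    prov <- paste(readLines(provenance_path), collapse = "\n")

  survey_dataset(grid, pres, tr, provenance = prov, truth = truth)
}

storage_int <- function(m) {
  storage.mode(m) <- "integer"
  m
}

#' Apply the square-inclusion rules
#'
#' A square enters the analysis only if it has a minimum shoreline length
#' (default 25 m) and contains both land and water
#' (0 < land_area < 1 km^2). Occurrence rows of excluded squares are
#' dropped here; use [reassign_records()] first when their bird records
#' should be moved to the nearest retained square, as in the field
#' protocol.
#'
#' @param ds a valid `survey_dataset`.
#' @param min_shoreline inclusion threshold in metres (inclusive).
#' @param require_land_and_water drop squares that are all land or all
#'   water.
#' @return list with `dataset` (restricted `survey_dataset`) and
#'   `excluded` (character vector of dropped square_ids).
#' @export
filter_squares <- function(ds, min_shoreline = 25, require_land_and_water = TRUE) {
  validate_dataset(ds)
  g <- ds$grid
  keep <- g$shoreline >= min_shoreline
  if (require_land_and_water)
    keep <- keep & g$land_area > 0 & g$land_area < SQUARE_AREA
  excluded <- as.character(g$square_id[!keep])
  out <- ds
  out$grid <- g[keep, , drop = FALSE]
  rownames(out$grid) <- NULL
  out$presence <- ds$presence[keep, , drop = FALSE]
  list(dataset = out, excluded = excluded)
}

#' Reassign bird records from excluded squares
#'
#' Each species present in an excluded square is marked present (logical
#' OR, no double counting) in the retained square whose centroid is
#' nearest by Euclidean distance; ties go to the lexicographically
#' smallest square_id.
#'
#' @param ds the full (pre-filter) `survey_dataset`.
#' @param excluded character vector of excluded square_ids (subset of the
#'   grid).
#' @return presence matrix restricted to retained squares, with
#'   reassigned records merged in.
#' @export
reassign_records <- function(ds, excluded) {
  validate_dataset(ds)
  g <- ds$grid
  stopifnot(all(excluded %in% g$square_id))
  retained <- setdiff(as.character(g$square_id), excluded)
  if (!length(retained))
    stop_named("skerrydiv_no_squares", "no retained squares to reassign records to")
  pres <- ds$presence[retained, , drop = FALSE]
  if (!length(excluded)) return(pres)

  gr <- g[match(retained, g$square_id), ]
  ord <- order(gr$square_id)  # tie-break scan order
  for (id in excluded) {
    row <- ds$presence[id, ]
    if (!any(row == 1L)) next
    ge <- g[g$square_id == id, ]
    d2 <- (gr$x - ge$x)^2 + (gr$y - ge$y)^2
    best <- ord[which.min(d2[ord])]  # first minimum in id order
    target <- as.character(gr$square_id[best])
    pres[target, ] <- pmax(pres[target, ], row)
  }
  pres
}

#' Restrict a dataset to the retained squares, reassigning records
#'
#' Convenience wrapper running [filter_squares()] and
#' [reassign_records()] in the documented order.
#'
#' @inheritParams filter_squares
#' @return list with `dataset` (filtered, records reassigned) and
#'   `excluded`.
#' @export
apply_inclusion_rules <- function(ds, min_shoreline = 25,
                                  require_land_and_water = TRUE) {
  flt <- filter_squares(ds, min_shoreline, require_land_and_water)
  if (length(flt$excluded)) {
    pres <- reassign_records(ds, flt$excluded)
    flt$dataset$presence <- pres
  }
  flt
}
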