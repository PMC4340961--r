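#' Per-square species richness by group
#'
#' Counts, for every square, the total number of species present, the
#' specialist and generalist components, and the corresponding red-listed
#' counts.
#'
#' @param ds a valid `survey_dataset`.
#' @return data.frame with columns `square_id`, `total`, `specialist`,
#'   `generalist`, `redlist_total`, `redlist_specialist`,
#'   `redlist_generalist`.
#' @export
richness <- function(ds) {
  validate_dataset(ds)
  tr <- ds$traits[match(colnames(ds$presence), ds$traits$species), ]
  p <- ds$presence
  is_spec <- tr$classification == "specialist"
  is_red <- tr$redlist != "none"
  cnt <- function(sel) if (any(sel)) as.integer(rowSums(p[, sel, drop = FALSE])) else
    integer(nrow(p))
  data.frame(square_id = rownames(p),
             total = cnt(rep(TRUE, ncol(p))),
             specialist = cnt(is_spec),
             generalist = cnt(!is_spec),
             redlist_total = cnt(is_red),
             redlist_specialist = cnt(is_red & is_spec),
             redlist_generalist = cnt(is_red & !is_spec),
             stringsAsFactors = FALSE)
}

#' Per-species occupancy summary
#'
#' Number of occupied squares per species and the proportion of occupied
#' squares as a percentage rounded to one decimal, sorted by species
#' name.
#'
#' @param ds a valid `survey_dataset`.
#' @return data.frame with columns `species`, `count`, `proportion_pct`.
#' @export
occupancy_table <- function(ds) {
  validate_dataset(ds)
  n <- nrow(ds$presence)
  stopifnot(n >= 1)
  cnt <- colSums(ds$presence)
  out <- data.frame(species = colnames(ds$presence),
                    count = as.integer(cnt),
                    proportion_pct = round(100 * cnt / n, 1),
                    stringsAsFactors = FALSE)
  out <- out[order(out$species), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Mean-standardise a covariate vector
#'
#' Centre and scale to mean 0, SD 1 (the z-score reading of
#' "mean-standardised"; set `scale = FALSE` for centring only). The
#' transformation parameters are attached for inverse mapping.
#'
#' @param values numeric vector with at least two distinct values.
#' @param scale divide by the SD (default `TRUE`).
#' @return standardized vector with attributes `center` and `scale`.
#' @export
standardise <- function(values, scale = TRUE) {
  stopifnot(is.numeric(values), all(is.finite(values)))
  s <- stats::sd(values)
  if (!isTRUE(s > 0))
    stop_named("skerrydiv_zero_variance", "cannot standardise a constant vector")
  ctr <- mean(values)
  out <- values - ctr
  if (scale) out <- out / s else s <- 1
  attr(out, "center") <- ctr
  attr(out, "scale") <- s
  out
}

#' Bin richness along a standardized gradient
#'
#' Squares are grouped into half-open bins `[centre - half_width,
#' centre + half_width)` centred at multiples of `2 * half_width` of the
#' standardized covariate, and per-bin sample size, mean and SD of the
#' richness of each group are reported (the layout used to display mean
#' richness against distance to open sea).
#'
#' @param rt richness table from [richness()].
#' @param z standardized covariate, one value per square (same order).
#' @param half_width half bin width in standardized units (default 0.25).
#' @param groups richness columns to summarise.
#' @return data.frame with one row per (bin, group): `bin_centre`, `group`,
#'   `n`, `mean_richness`, `sd_richness`.
#' @export
bin_by_gradient <- function(rt, z, half_width = 0.25,
                            groups = c("total", "specialist", "generalist")) {
  stopifnot(length(z) == nrow(rt), half_width > 0)
  w <- 2 * half_width
  centre <- round(as.numeric(z) / w) * w
  # round() half-to-even would break the half-open [c-hw, c+hw) convention
  # at exact bin edges: push edge values up
  edge <- abs((z / w) %% 1 - 0.5) < 1e-12
  centre[edge] <- (floor(z[edge] / w) + 1) * w
  out <- do.call(rbind, lapply(groups, function(g) {
    agg <- split(rt[[g]], centre)
    data.frame(bin_centre = as.numeric(names(agg)), group = g,
               n = vapply(agg, length, integer(1)),
               mean_richness = vapply(agg, mean, numeric(1)),
               sd_richness = vapply(agg, stats::sd, numeric(1)),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(out$group, out$bin_centre), ]
}

#' Species-group column selector
#'
#' Maps a group keyword to the member species of a dataset.
#'
#' @param ds a `survey_dataset`.
#' @param group one of `"all"`, `"specialist"`, `"generalist"`,
#'   `"redlist_all"`, `"redlist_specialist"`, `"redlist_generalist"`.
#' @return character vector of species names.
#' @export
group_species <- function(ds, group = "all") {
  tr <- ds$traits[match(colnames(ds$presence), ds$traits$species), ]
  sel <- switch(group,
    all = rep(TRUE, nrow(tr)),
    specialist = tr$classification == "specialist",
    generalist = tr$classification == "generalist",
    redlist_all = tr$redlist != "none",
    redlist_specialist = tr$redlist != "none" & tr$classification == "specialist",
    redlist_generalist = tr$redlist != "none" & tr$classification == "generalist",
    stop_named("skerrydiv_bad_group", "unknown species group '%s'", group))
  colnames(ds$presence)[sel]
}
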