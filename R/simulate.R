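#' Bundled coastal breeding bird survey table
#'
#' Occurrence frequencies and classifications of 48 coastal breeding bird
#' species from a large Baltic Sea archipelago survey (4646 one-km
#' squares): per-species number of occupied squares, ecological
#' classification (specialist = obligate coastal breeder, generalist =
#' facultative coastal breeder) and national red-list status (NT/VU).
#'
#' @return data.frame with columns `species`, `occurrences`,
#'   `classification`, `redlist`.
#' @export
survey_species_table <- function() {
  utils::read.csv(system.file("extdata", "coastal_bird_survey.csv",
                              package = "skerrydiv"),
                  stringsAsFactors = FALSE, colClasses = "character") |>
    transform(occurrences = as.integer(occurrences))
}

#' Group-mean gradient responses used by the occurrence simulator
#'
#' Logit-scale coefficients for the standardized covariates
#' (dist_sea, width, shoreline, land_area) and the shoreline x land_area
#' product, per ecological group. The default sign pattern encodes the
#' published gradient responses: specialist richness falls with distance
#' to open sea and land area and rises with shoreline and width; the
#' positive shoreline effect is damped by land area; generalists respond
#' in the opposite direction to distance to open sea and width, with no
#' mean land-area effect and only a weak interaction.
#'
#' @return named list of two numeric vectors (`specialist`,
#'   `generalist`) with elements `intercept`, `dist_sea`, `width`,
#'   `shoreline`, `land_area`, `shoreline_x_land`.
#' @export
default_group_effects <- function() {
  list(
    specialist = c(intercept = -0.8, dist_sea = -0.9, width = 0.5,
                   shoreline = 0.9, land_area = -0.7, shoreline_x_land = -0.5),
    generalist = c(intercept = -0.8, dist_sea = 0.6, width = -0.5,
                   shoreline = 0.9, land_area = 0.0, shoreline_x_land = -0.2)
  )
}

#' Parameters of the occupancy simulator
#'
#' @param n_specialist,n_generalist species counts per group. With the
#'   default 19 + 29 the simulated community borrows the bundled survey
#'   species names and red-list statuses; other counts get generic names
#'   and no red-listing.
#' @param group_effects group-mean coefficient vectors, see
#'   [default_group_effects()].
#' @param coef_sd between-species SD of the gradient coefficients.
#' @param intercept_sd between-species SD of the intercept (species vary
#'   in overall commonness).
#' @param field_amplitude SD of the spatially autocorrelated logit
#'   residual field (0 disables it).
#' @param field_range range (m) of the field's exponential correlation.
#' @param seed integer seed.
#' @return a `simulation_params` list.
#' @export
simulation_params <- function(n_specialist = 19, n_generalist = 29,
                              group_effects = default_group_effects(),
                              coef_sd = 0.25, intercept_sd = 0.7,
                              field_amplitude = 0, field_range = 2000,
                              seed = 1) {
  stopifnot(n_specialist >= 0, n_generalist >= 0, coef_sd >= 0,
            intercept_sd >= 0, field_amplitude >= 0,
            field_amplitude == 0 || field_range > 0)
  structure(list(n_specialist = n_specialist, n_generalist = n_generalist,
                 group_effects = group_effects, coef_sd = coef_sd,
                 intercept_sd = intercept_sd,
                 field_amplitude = field_amplitude,
                 field_range = field_range, seed = seed),
            class = "simulation_params")
}

#' Simulate species occurrences over a square grid
#'
#' Draws per-species logit-scale coefficient profiles around the group
#' means, computes occurrence probabilities from the standardized
#' covariates (plus the shoreline x land_area product and an optional
#' spatially autocorrelated residual field with exponential correlation),
#' and samples Bernoulli presences. The true profiles are kept in the
#' returned dataset (`$truth`) for parameter-recovery checks.
#'
#' @param squares data.frame of square records as from
#'   [derive_environment()].
#' @param sp a [simulation_params()] object.
#' @return a `survey_dataset`.
#' @export
simulate_occurrences <- function(squares, sp) {
  stopifnot(inherits(sp, "simulation_params"), nrow(squares) >= 1,
            all(is.finite(as.matrix(
      squares[, c("land_area", "shoreline", "dist_sea", "width")]))))
  n_sq <- nrow(squares)
  n_spp <- sp$n_specialist + sp$n_generalist

  zs <- function(v) if (stats::sd(v) > 0) (v - mean(v)) / stats::sd(v) else v * 0
  Z <- cbind(dist_sea = zs(squares$dist_sea), width = zs(squares$width),
             shoreline = zs(squares$shoreline), land_area = zs(squares$land_area))
  X <- cbind(intercept = 1, Z, shoreline_x_land = Z[, "shoreline"] * Z[, "land_area"])

  traits <- synthetic_traits(sp$n_specialist, sp$n_generalist)

  with_seed(sp$seed, {
    coefs <- t(vapply(seq_len(n_spp), function(s) {
      mu <- sp$group_effects[[traits$classification[s]]]
      mu + stats::rnorm(length(mu), 0, c(sp$intercept_sd,
                                         rep(sp$coef_sd, length(mu) - 1)))
    }, numeric(6)))
    colnames(coefs) <- colnames(X)

    eta <- X %*% t(coefs)  # n_sq x n_spp
    if (sp$field_amplitude > 0) {
      d <- as.matrix(stats::dist(squares[, c("x", "y")]))
      L <- chol(exp(-d / sp$field_range) + diag(1e-8, n_sq))
      eta <- eta + sp$field_amplitude *
        crossprod(L, matrix(stats::rnorm(n_sq * n_spp), n_sq, n_spp))
    }
    if (!all(is.finite(eta)))
      stop_named("skerrydiv_nonfinite_logit", "non-finite occurrence logit")
    p <- stats::plogis(eta)
    pres <- matrix(stats::rbinom(length(p), 1L, p), n_sq, n_spp,
                   dimnames = list(squares$square_id, traits$species))

    truth <- cbind(traits,
                   as.data.frame(coefs, row.names = seq_len(n_spp)))
    prov <- sprintf(
      "synthetic occurrences: seed=%d n_specialist=%d n_generalist=%d coef_sd=%g intercept_sd=%g field_amplitude=%g field_range=%g",
      sp$seed, sp$n_specialist, sp$n_generalist, sp$coef_sd,
      sp$intercept_sd, sp$field_amplitude, sp$field_range)
    survey_dataset(squares, pres, traits, provenance = prov, truth = truth)
  })
}

synthetic_traits <- function(n_specialist, n_generalist) {
  if (n_specialist == 19 && n_generalist == 29) {
    tab <- survey_species_table()
    return(data.frame(species = tab$species,
                      classification = tab$classification,
                      redlist = tab$redlist, stringsAsFactors = FALSE))
  }
  data.frame(
    species = c(sprintf("spec_%02d", seq_len(n_specialist)),
                sprintf("gen_%02d", seq_len(n_generalist))),
    classification = rep(c("specialist", "generalist"),
                         c(n_specialist, n_generalist)),
    redlist = "none", stringsAsFactors = FALSE)
}

#' Generate a full synthetic survey dataset
#'
#' Convenience wrapper: landscape, environmental metrics, occurrences.
#'
#' @param lp a [landscape_params()] object.
#' @param sp a [simulation_params()] object.
#' @return a `survey_dataset`.
#' @export
generate_survey <- function(lp = landscape_params(), sp = simulation_params()) {
  land <- generate_landscape(lp)
  squares <- derive_environment(land)
  simulate_occurrences(squares, sp)
}
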