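# shared in-code fixtures

toy_grid <- function(n = 4) {
  data.frame(square_id = sprintf("sq_%04d", seq_len(n)),
             x = (seq_len(n) - 0.5) * 1000, y = rep(500, n),
             land_area = rep(5e5, n), shoreline = rep(100, n),
             dist_sea = rep(200, n), width = rep(1500, n),
             stringsAsFactors = FALSE)
}

toy_traits <- function(species = c("A", "B", "C"),
                       classification = c("specialist", "generalist",
                                          "specialist")[seq_along(species)],
                       redlist = rep("none", length(species))) {
  data.frame(species = species, classification = classification,
             redlist = redlist, stringsAsFactors = FALSE)
}

toy_dataset <- function(presence = NULL, n_squares = 4,
                        species = c("A", "B", "C"), ...) {
  g <- toy_grid(n_squares)
  if (is.null(presence)) {
    presence <- matrix(0L, n_squares, length(species),
                       dimnames = list(g$square_id, species))
    presence[1, ] <- 1L
  } else {
    dimnames(presence) <- list(g$square_id, species)
  }
  survey_dataset(g, presence, toy_traits(species, ...))
}

# small random dataset for property tests
random_dataset <- function(seed, n_squares = 8, n_species = 6) {
  set.seed(seed)
  g <- toy_grid(n_squares)
  g$land_area <- runif(n_squares, 1e4, 9e5)
  g$shoreline <- runif(n_squares, 30, 3000)
  g$dist_sea <- runif(n_squares, 0, 5000)
  g$width <- g$dist_sea + runif(n_squares, 100, 4000)
  species <- sprintf("sp%02d", seq_len(n_species))
  pres <- matrix(rbinom(n_squares * n_species, 1, 0.4), n_squares,
                 dimnames = list(g$square_id, species))
  storage.mode(pres) <- "integer"
  tr <- toy_traits(species,
                   classification = sample(c("specialist", "generalist"),
                                           n_species, replace = TRUE),
                   redlist = sample(c("none", "none", "NT", "VU"),
                                    n_species, replace = TRUE))
  survey_dataset(g, pres, tr, provenance = sprintf("random fixture seed=%d", seed))
}

# dataset with known group structure for richness checks
eider_mallard_dataset <- function() {
  g <- toy_grid(2)
  pres <- matrix(c(1L, 0L, 1L, 0L), 2, 2,
                 dimnames = list(g$square_id, c("Common Eider", "Mallard")))
  tr <- toy_traits(c("Common Eider", "Mallard"),
                   classification = c("specialist", "generalist"),
                   redlist = c("NT", "none"))
  survey_dataset(g, pres, tr)
}
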