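test_that("Sorensen dissimilarity follows 1 - 2w/(a+b)", {
  expect_equal(sorensen(3, 3, 3), 0)
  expect_equal(sorensen(1, 1, 0), 1)
  expect_equal(sorensen(3, 2, 2), 0.2)
  expect_error(sorensen(0, 0, 0), class = "skerrydiv_undefined_pair")
})

test_that("Sorensen matrix agrees with the per-pair formula", {
  ds <- random_dataset(5, n_squares = 10, n_species = 8)
  m <- sorensen_matrix(ds, "all")
  expect_identical(dim(m), c(10L, 10L))
  expect_equal(unclass(m), t(unclass(m)))
  expect_equal(diag(m), setNames(rep(0, 10), rownames(m)))
  set.seed(2)
  for (rep in 1:50) {
    ij <- sample(10, 2)
    a <- sum(ds$presence[ij[1], ]); b <- sum(ds$presence[ij[2], ])
    w <- sum(ds$presence[ij[1], ] & ds$presence[ij[2], ])
    expect_equal(m[ij[1], ij[2]], sorensen(a, b, w))
  }
  expect_true(all(m >= 0 & m <= 1, na.rm = TRUE))
})

test_that("empty-square pairs are flagged missing, identical sets are 0", {
  g <- toy_grid(3)
  pres <- matrix(c(1L, 1L, 0L,
                   1L, 1L, 0L), 3, 2,
                 dimnames = list(g$square_id, c("A", "B")))
  ds <- survey_dataset(g, pres, toy_traits(c("A", "B")))
  m <- sorensen_matrix(ds)
  expect_equal(m[1, 2], 0)          # identical non-empty sets
  # squares 1 and 2 hold both species, square 3 is empty -> pairs with 3
  # have a + b > 0 (a = 2), so they are defined and maximally dissimilar
  expect_equal(m[1, 3], 1)
  # two empty squares are undefined
  pres2 <- matrix(0L, 3, 2, dimnames = list(g$square_id, c("A", "B")))
  pres2[1, ] <- 1L
  m2 <- sorensen_matrix(survey_dataset(g, pres2, toy_traits(c("A", "B"))))
  expect_true(is.na(m2[2, 3]))
  expect_equal(diag(m2), setNames(rep(0, 3), rownames(m2)))
})

test_that("Raup-Crick degenerate pools give exact half-tie values", {
  pool1 <- list(weights = c(A = 1), gamma = 1)
  expect_equal(raup_crick_pair(1, 1, 1, pool1, raup_crick_config(reps = 200)),
               0.5)
  # empty square: null shared count is always 0 = observed
  pool2 <- list(weights = c(A = 3, B = 1), gamma = 2)
  expect_equal(raup_crick_pair(0, 2, 0, pool2, raup_crick_config(reps = 100)),
               0.5)
  expect_error(raup_crick_null(3, 1, c(A = 1, B = 2), 10),
               class = "skerrydiv_infeasible_richness")
})

test_that("exact enumeration matches hand-computed two-species case", {
  # equal weights, both squares draw 1 of 2 species, observed shared = 1:
  # null shared = 1 with probability 1/2, ties count half -> 0.25
  expect_equal(raup_crick_exact(1, 1, 1, c(A = 1, B = 1)), 0.25)
  expect_equal(raup_crick_exact(1, 1, 0, c(A = 1, B = 1)), 0.75)
  # certain overlap when both squares take the whole pool
  expect_equal(raup_crick_exact(2, 2, 2, c(A = 1, B = 1)), 0.5)
})

test_that("Monte-Carlo Raup-Crick converges to the exact enumeration", {
  w <- c(a = 5, b = 3, c = 2, d = 1, e = 1)
  pool <- list(weights = w, gamma = 5)
  reps <- 20000
  set.seed(7)
  draws <- raup_crick_null(2, 2, w, reps)
  for (wo in 0:2) {
    mc <- (sum(draws > wo) + 0.5 * sum(draws == wo)) / reps
    ex <- raup_crick_exact(2, 2, wo, w)
    s <- (draws > wo) + 0.5 * (draws == wo)
    expect_lt(abs(mc - ex), 3 * max(sd(s) / sqrt(reps), 1e-4))
  }
})

test_that("Raup-Crick is non-increasing in the observed shared count", {
  w <- c(a = 4, b = 3, c = 2, d = 2, e = 1, f = 1)
  set.seed(3)
  draws <- raup_crick_null(3, 3, w, 2000)
  vals <- vapply(0:3, function(wo)
    (sum(draws > wo) + 0.5 * sum(draws == wo)) / 2000, numeric(1))
  expect_true(all(diff(vals) <= 0))
  # exact version shares the property
  ex <- vapply(0:3, function(wo) raup_crick_exact(3, 3, wo, w), numeric(1))
  expect_true(all(diff(ex) <= 0))
})

test_that("matrix entries reuse the richness-pair null cache consistently", {
  ds <- random_dataset(9, n_squares = 12, n_species = 10)
  cfg <- raup_crick_config(reps = 400, seed = 77)
  m <- raup_crick_matrix(ds, "all", cfg)
  cache <- attr(m, "cache")
  pool <- pool_weights(ds, "all")
  n <- rowSums(ds$presence)
  set.seed(1)
  for (rep in 1:20) {
    ij <- sample(12, 2)
    wo <- sum(ds$presence[ij[1], ] & ds$presence[ij[2], ])
    key <- paste(min(n[ij]), max(n[ij]), sep = ":")
    expect_equal(m[ij[1], ij[2]],
                 raup_crick_pair(n[ij[1]], n[ij[2]], wo, pool, cfg,
                                 null = cache[[key]]))
  }
  expect_equal(unclass(m), t(unclass(m)))
  expect_true(all(m >= 0 & m <= 1))
  # determinism under the config seed
  m2 <- raup_crick_matrix(ds, "all", cfg)
  expect_identical(unclass(m), unclass(m2))
})

test_that("group-specific pools count occupancy within the group", {
  ds <- eider_mallard_dataset()
  pw <- pool_weights(ds, "specialist")
  expect_identical(pw$weights, c(`Common Eider` = 1))
  expect_identical(pw$gamma, 1L)
})
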