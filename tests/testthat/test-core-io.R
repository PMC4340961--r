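test_that("write/read round-trips a dataset exactly", {
  ds <- random_dataset(11)
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  ds2 <- read_dataset(file.path(dir, "squares.csv"),
                      file.path(dir, "occurrences.csv"),
                      file.path(dir, "traits.csv"))
  expect_identical(ds2$presence, ds$presence)
  expect_equal(ds2$grid, ds$grid, tolerance = 0)
  expect_identical(ds2$traits, ds$traits)
  expect_identical(ds2$provenance, ds$provenance)
})

test_that("round-trip identity holds over many generated datasets", {
  for (seed in c(1, 7, 23, 101)) {
    ds <- random_dataset(seed, n_squares = 5 + seed %% 7,
                         n_species = 3 + seed %% 5)
    dir <- withr::local_tempdir()
    write_dataset(ds, dir)
    ds2 <- read_dataset(file.path(dir, "squares.csv"),
                        file.path(dir, "occurrences.csv"),
                        file.path(dir, "traits.csv"))
    expect_identical(ds2$presence, ds$presence)
    expect_equal(ds2$grid, ds$grid, tolerance = 0)
  }
})

test_that("empty occurrence matrix writes and reads back", {
  g <- toy_grid(3)
  pres <- matrix(integer(), 3, 0, dimnames = list(g$square_id, character()))
  ds <- survey_dataset(g, pres, toy_traits(character(), character(), character()))
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  ds2 <- read_dataset(file.path(dir, "squares.csv"),
                      file.path(dir, "occurrences.csv"),
                      file.path(dir, "traits.csv"))
  expect_equal(dim(ds2$presence), c(3, 0))
})

test_that("a large generated survey round-trips elementwise", {
  ds <- generate_survey(landscape_params(nx = 6, ny = 8, seed = 5),
                        simulation_params(seed = 5))
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  ds2 <- read_dataset(file.path(dir, "squares.csv"),
                      file.path(dir, "occurrences.csv"),
                      file.path(dir, "traits.csv"))
  expect_identical(ds2$presence, ds$presence)
  expect_true(all(abs(as.matrix(ds2$grid[, -1]) -
                        as.matrix(ds$grid[, -1])) == 0))
})

test_that("validation raises distinct named errors", {
  g <- toy_grid(2)
  pres <- matrix(c(1L, 0L, 2L, 0L), 2, 2,
                 dimnames = list(g$square_id, c("A", "B")))
  expect_error(survey_dataset(g, pres, toy_traits(c("A", "B"))),
               class = "skerrydiv_bad_presence")

  pres2 <- matrix(0L, 2, 2, dimnames = list(g$square_id, c("A", "D")))
  err <- expect_error(survey_dataset(g, pres2, toy_traits(c("A", "B"))),
                      class = "skerrydiv_orphan_species")
  expect_match(conditionMessage(err), "D")

  g2 <- g; g2$square_id <- c("s1", "s1")
  expect_error(survey_dataset(g2, pres2, toy_traits(c("A", "D"))),
               class = "skerrydiv_duplicate_id")

  expect_error(
    read_dataset(tempfile(), tempfile(), tempfile()),
    class = "skerrydiv_io_error")
})

test_that("reading flags an offending presence cell", {
  dir <- withr::local_tempdir()
  write_dataset(toy_dataset(), dir)
  occ <- read.csv(file.path(dir, "occurrences.csv"))
  occ$present[1] <- 2
  write.csv(occ, file.path(dir, "occurrences.csv"), row.names = FALSE)
  err <- expect_error(
    read_dataset(file.path(dir, "squares.csv"),
                 file.path(dir, "occurrences.csv"),
                 file.path(dir, "traits.csv")),
    class = "skerrydiv_bad_presence")
  expect_match(conditionMessage(err), "sq_0001")
})

test_that("square inclusion rules use the stated boundaries", {
  g <- toy_grid(4)
  g$shoreline <- c(24.9, 25, 100, 100)
  g$land_area <- c(5e5, 5e5, 1e6, 0)
  pres <- matrix(0L, 4, 1, dimnames = list(g$square_id, "A"))
  ds <- survey_dataset(g, pres, toy_traits("A", "specialist"))
  flt <- filter_squares(ds)
  # 24.9 m shoreline out; 25 m exactly in; all-land and all-water out
  expect_identical(flt$excluded, c("sq_0001", "sq_0003", "sq_0004"))
  expect_identical(flt$dataset$grid$square_id, "sq_0002")

  # idempotence
  flt2 <- filter_squares(flt$dataset)
  expect_identical(flt2$excluded, character())
  expect_equal(flt2$dataset$grid, flt$dataset$grid)
})

test_that("record reassignment is a nearest-centroid set union", {
  g <- toy_grid(3)  # collinear squares at x = 500, 1500, 2500
  pres <- matrix(c(0L, 1L, 0L,   # A in sq_0002
                   1L, 1L, 0L,   # B in sq_0001 and sq_0002
                   0L, 0L, 1L),  # C in sq_0003
                 3, 3, dimnames = list(g$square_id, c("A", "B", "C")))
  ds <- survey_dataset(g, pres, toy_traits())
  # exclude the middle square: sq_0001 and sq_0003 are equidistant,
  # tie goes to the lexicographically smallest id
  out <- reassign_records(ds, "sq_0002")
  expect_identical(rownames(out), c("sq_0001", "sq_0003"))
  expect_identical(out["sq_0001", ], c(A = 1L, B = 1L, C = 0L))  # union, no double count
  expect_identical(out["sq_0003", ], c(A = 0L, B = 0L, C = 1L))
  expect_error(reassign_records(ds, g$square_id),
               class = "skerrydiv_no_squares")
})

test_that("reassignment never loses occupancy and is bounded", {
  for (seed in c(3, 9)) {
    ds <- random_dataset(seed, n_squares = 10, n_species = 5)
    excl <- ds$grid$square_id[c(2, 5, 8)]
    out <- reassign_records(ds, excl)
    keep <- setdiff(ds$grid$square_id, excl)
    before <- colSums(ds$presence[keep, , drop = FALSE])
    after <- colSums(out)
    expect_true(all(after >= before))
    expect_true(all(after - before <= length(excl)))
  }
})
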