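env_matrix <- function(v, labels = sprintf("s%02d", seq_along(v)))
  manhattan_matrix(v, labels)

random_dissim <- function(n, labels = sprintf("s%02d", seq_len(n))) {
  m <- matrix(0, n, n, dimnames = list(labels, labels))
  m[upper.tri(m)] <- runif(n * (n - 1) / 2)
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  dissim_matrix(m, "sorensen")
}

test_that("Manhattan matrix is the absolute pairwise difference", {
  m <- env_matrix(c(0, 3, 5))
  expect_equal(m[1, 2], 3)
  expect_equal(m[1, 3], 5)
  expect_equal(m[2, 3], 2)
  expect_equal(diag(m), setNames(rep(0, 3), rownames(m)))
  expect_equal(unclass(m), t(unclass(m)))
  cm <- env_matrix(rep(4, 5))
  expect_true(all(cm == 0))
  expect_error(env_matrix(c(1, NA, 3)), class = "skerrydiv_nonfinite")
})

test_that("Mantel r is the upper-triangle Pearson correlation", {
  set.seed(5)
  A <- random_dissim(8)
  expect_equal(mantel(A, A, n_perm = 99)$r, 1)
  # positive affine transform leaves r at 1
  B <- dissim_matrix(unclass(A) * 3 + 2 - diag(2, 8), "manhattan")
  diag(B) <- 0
  expect_equal(mantel(A, dissim_matrix(unclass(B), "manhattan"),
                      n_perm = 99)$r, 1)
  # r invariant under simultaneous relabeling of both matrices
  p <- sample(8)
  Ap <- dissim_matrix(unclass(A)[p, p], "sorensen")
  Bp <- dissim_matrix(unclass(B)[p, p], "manhattan")
  expect_equal(mantel(Ap, Bp, n_perm = 99, seed = 3)$r,
               mantel(A, dissim_matrix(unclass(B), "manhattan"),
                      n_perm = 99, seed = 3)$r)
})

test_that("sampled permutation p matches full enumeration at n = 4", {
  set.seed(8)
  A <- random_dissim(4)
  B <- random_dissim(4)
  v <- function(m) m[upper.tri(m)]
  r_obs <- cor(v(unclass(A)), v(unclass(B)))
  perms <- rbind(
    c(1,2,3,4), c(1,2,4,3), c(1,3,2,4), c(1,3,4,2), c(1,4,2,3), c(1,4,3,2),
    c(2,1,3,4), c(2,1,4,3), c(2,3,1,4), c(2,3,4,1), c(2,4,1,3), c(2,4,3,1),
    c(3,1,2,4), c(3,1,4,2), c(3,2,1,4), c(3,2,4,1), c(3,4,1,2), c(3,4,2,1),
    c(4,1,2,3), c(4,1,3,2), c(4,2,1,3), c(4,2,3,1), c(4,3,1,2), c(4,3,2,1))
  rs <- apply(perms, 1, function(p) {
    Ap <- unclass(A)[p, p]
    cor(v(Ap), v(unclass(B)))
  })
  p_exact <- mean(abs(rs) >= abs(r_obs) - 1e-12)
  res <- mantel(A, B, n_perm = 2000, seed = 10)
  se <- sqrt(p_exact * (1 - p_exact) / 2000)
  expect_lt(abs(res$p - p_exact), 3 * se + 1 / 2001)
})

test_that("Mantel r agrees with the vegan implementation", {
  skip_if_not_installed("vegan")
  set.seed(12)
  A <- random_dissim(10)
  B <- random_dissim(10)
  C <- random_dissim(10)
  expect_equal(mantel(A, B, n_perm = 99)$r,
               vegan::mantel(as.dist(A), as.dist(B), permutations = 9)$statistic,
               tolerance = 1e-10, ignore_attr = TRUE)
  # partial r against vegan's mantel.partial (same residual method)
  ours <- partial_mantel(A, B, list(C), n_perm = 99)$r
  theirs <- vegan::mantel.partial(as.dist(A), as.dist(B), as.dist(C),
                                  permutations = 9)$statistic
  expect_equal(ours, theirs, tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("partial Mantel reduces to simple Mantel without controls", {
  set.seed(4)
  A <- random_dissim(9)
  B <- random_dissim(9)
  s <- mantel(A, B, n_perm = 499, seed = 2)
  p <- partial_mantel(A, B, list(), n_perm = 499, seed = 2)
  expect_equal(p$r, s$r)
  expect_equal(p$p, s$p)
  expect_identical(p$mode, "simple")
})

test_that("controlling for B itself is a degenerate request", {
  set.seed(4)
  A <- random_dissim(9)
  B <- random_dissim(9)
  expect_error(partial_mantel(A, B, list(B), n_perm = 99),
               class = "skerrydiv_zero_variance")
})

test_that("NA pairs are dropped listwise", {
  set.seed(6)
  A <- random_dissim(8)
  Am <- unclass(A); Am[2, 5] <- Am[5, 2] <- NA
  A2 <- dissim_matrix(Am, "sorensen")
  B <- random_dissim(8)
  v <- function(m) m[upper.tri(m)]
  keep <- is.finite(v(Am))
  expect_equal(mantel(A2, B, n_perm = 99)$r,
               cor(v(Am)[keep], v(unclass(B))[keep]))
})

test_that("independent controls barely move r from the simple Mantel", {
  set.seed(20)
  reps <- 60
  drift <- replicate(reps, {
    A <- random_dissim(12)
    B <- random_dissim(12)
    C1 <- random_dissim(12)
    C2 <- random_dissim(12)
    abs(partial_mantel(A, B, list(C1, C2), n_perm = 1)$r -
          mantel(A, B, n_perm = 1)$r)
  })
  expect_lt(mean(drift), 0.06)
})
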