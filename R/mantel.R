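#' Manhattan distance matrix of a covariate
#'
#' Entry (i, j) is the absolute difference of the covariate values of
#' squares i and j — the "difference between the values of each pair of
#' squares" form used for environmental distance matrices.
#'
#' @param values numeric covariate vector, one per square.
#' @param labels square identifiers.
#' @return a `dissim_matrix` of kind `"manhattan"`.
#' @export
manhattan_matrix <- function(values, labels) {
  stopifnot(length(values) == length(labels), length(values) >= 2)
  if (!all(is.finite(values)))
    stop_named("skerrydiv_nonfinite", "covariate values must be finite")
  m <- abs(outer(values, values, `-`))
  dimnames(m) <- list(labels, labels)
  dissim_matrix(m, "manhattan")
}

utri <- function(m) m[upper.tri(m)]

# upper-triangle vectors of A, B and controls, with pairs dropped
# listwise wherever any matrix is NA
mantel_vectors <- function(A, B, C = list()) {
  stopifnot(identical(rownames(A), rownames(B)))
  for (Ci in C) stopifnot(identical(rownames(A), rownames(Ci)))
  va <- utri(unclass(A)); vb <- utri(unclass(B))
  vc <- lapply(C, function(Ci) utri(unclass(Ci)))
  keep <- is.finite(va) & is.finite(vb)
  for (v in vc) keep <- keep & is.finite(v)
  list(a = va, b = vb, c = lapply(vc, function(v) v[keep]), keep = keep,
       a_kept = va[keep], b_kept = vb[keep])
}

residualise <- function(y, qrC) if (is.null(qrC)) y else qr.resid(qrC, y)

mantel_engine <- function(A, B, C, n_perm, seed, sided) {
  v <- mantel_vectors(A, B, C)
  qrC <- NULL
  if (length(v$c)) {
    M <- cbind(1, do.call(cbind, v$c))
    qrC <- qr(M)
    if (qrC$rank < ncol(M))
      stop_named("skerrydiv_collinear_controls",
                 "control matrices are collinear")
  }
  rb <- residualise(v$b_kept, qrC)
  ra <- residualise(v$a_kept, qrC)
  tol_a <- 1e-10 * (stats::sd(v$a_kept) + 1)
  tol_b <- 1e-10 * (stats::sd(v$b_kept) + 1)
  if (is.na(stats::sd(ra)) || stats::sd(ra) <= tol_a ||
      is.na(stats::sd(rb)) || stats::sd(rb) <= tol_b)
    stop_named("skerrydiv_zero_variance",
               "zero variance in a (residualised) distance matrix")
  r_obs <- stats::cor(ra, rb)

  n <- nrow(A)
  iu <- which(upper.tri(A), arr.ind = TRUE)
  Am <- unclass(A)
  stat <- function(av) {
    keep2 <- v$keep & is.finite(av)
    avk <- av[keep2]
    if (identical(keep2, v$keep)) {
      rav <- residualise(avk, qrC)
      stats::cor(rav, rb)
    } else {
      # NA pattern moved under permutation: re-restrict everything
      bk <- utri(unclass(B))[keep2]
      if (length(v$c)) {
        Mk <- cbind(1, do.call(cbind, lapply(C, function(Ci)
          utri(unclass(Ci))[keep2])))
        qk <- qr(Mk)
        stats::cor(qr.resid(qk, avk), qr.resid(qk, bk))
      } else stats::cor(avk, bk)
    }
  }
  perm_r <- with_seed(seed, vapply(seq_len(n_perm), function(p) {
    pp <- sample.int(n)
    stat(Am[cbind(pp[iu[, 1]], pp[iu[, 2]])])
  }, numeric(1)))
  exceed <- if (sided == "two")
    sum(abs(perm_r) >= abs(r_obs) - 1e-12)
  else
    sum(perm_r >= r_obs - 1e-12)
  list(r = r_obs, p = (exceed + 1) / (n_perm + 1), perm_r = perm_r)
}

#' Simple Mantel test
#'
#' Pearson correlation of the upper-triangle vectors of two distance
#' matrices, with permutation inference: rows and columns of `A` are
#' jointly relabelled, the correlation recomputed, and the p-value is
#' `(exceedances + 1) / (n_perm + 1)`, two-sided on `|r|` by default.
#'
#' @param A,B `dissim_matrix` objects over the same squares in the same
#'   order.
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @param sided `"two"` (default) or `"one"` (greater).
#' @return a `mantel_result`: list with `r`, `p`, `n_perm`, `mode`,
#'   `controlled`.
#' @export
mantel <- function(A, B, n_perm = 10000, seed = 1, sided = c("two", "one")) {
  sided <- match.arg(sided)
  res <- mantel_engine(A, B, list(), n_perm, seed, sided)
  structure(list(r = res$r, p = res$p, n_perm = n_perm, mode = "simple",
                 controlled = character()),
            class = "mantel_result")
}

#' Partial Mantel test by the method of residuals
#'
#' The upper-triangle vectors of `A` and `B` are each regressed (OLS,
#' with intercept) on the upper-triangle vectors of the control matrices
#' `C`; `r` is the Pearson correlation of the two residual vectors.
#' Inference permutes the rows/columns of the raw `A` matrix jointly,
#' re-residualises, and applies the two-sided `(exceed + 1) /
#' (n_perm + 1)` rule. Pairs that are `NA` in any matrix are dropped
#' listwise before vectorisation.
#'
#' @inheritParams mantel
#' @param C list of control `dissim_matrix` objects (empty list reduces
#'   to [mantel()] exactly).
#' @return a `mantel_result`.
#' @export
partial_mantel <- function(A, B, C = list(), n_perm = 10000, seed = 1,
                           sided = c("two", "one")) {
  sided <- match.arg(sided)
  if (inherits(C, "dissim_matrix")) C <- list(C)
  res <- mantel_engine(A, B, C, n_perm, seed, sided)
  ctrl <- if (!is.null(names(C)) && all(nzchar(names(C)))) names(C)
          else vapply(C, function(x) attr(x, "kind") %||% "", character(1))
  structure(list(r = res$r, p = res$p, n_perm = n_perm,
                 mode = if (length(C)) "partial" else "simple",
                 controlled = ctrl),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("%s Mantel: r = %.4f, p = %.4g (%d permutations)\n",
              x$mode, x$r, x$p, x$n_perm))
  invisible(x)
}
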