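#' Binary neighbour weights at a lag distance
#'
#' `w_ij = 1` iff the centroid distance of squares i and j is positive
#' and at most `lag` (inclusive, with a `1e-6 * lag` tolerance for grid
#' arithmetic). At the default 1000 m lag on a 1 km grid this yields
#' rook neighbours: diagonal pairs are about 1414 m apart and excluded.
#'
#' @param squares data.frame of square records (needs `square_id`, `x`,
#'   `y`).
#' @param lag lag distance in m.
#' @return a `weight_matrix`: binary symmetric matrix with zero
#'   diagonal, labels, and the lag as attribute.
#' @export
binary_weights <- function(squares, lag = 1000) {
  stopifnot(nrow(squares) >= 2)
  d <- as.matrix(stats::dist(squares[, c("x", "y")]))
  w <- (d > 0 & d <= lag * (1 + 1e-6)) * 1
  dimnames(w) <- list(squares$square_id, squares$square_id)
  if (sum(w) == 0)
    stop_named("skerrydiv_no_neighbours",
               "no square pairs within the %g m lag", lag)
  structure(w, lag = lag, class = c("weight_matrix", "matrix", "array"))
}

#' Moran's I with the normality-assumption test
#'
#' `I = (n / S0) * sum_ij w_ij (x_i - xbar)(x_j - xbar) / sum_i
#' (x_i - xbar)^2`, expectation `-1 / (n - 1)`, variance by the standard
#' normality-assumption formula (via S0, S1, S2), z-score and two-sided
#' normal p-value.
#'
#' @param x numeric values, one per square (label order of `W`).
#' @param W a [binary_weights()] matrix (any non-negative symmetric
#'   weights are accepted).
#' @return a `moran_result`: list with `I`, `expected`, `variance`, `z`,
#'   `p`, `n`.
#' @export
morans_i <- function(x, W) {
  n <- length(x)
  stopifnot(n == nrow(W), n >= 3)
  if (stats::sd(x) == 0)
    stop_named("skerrydiv_zero_variance", "Moran's I undefined for constant x")
  w <- unclass(W)
  xc <- x - mean(x)
  S0 <- sum(w)
  I <- (n / S0) * as.numeric(xc %*% w %*% xc) / sum(xc^2)
  expected <- -1 / (n - 1)
  S1 <- 0.5 * sum((w + t(w))^2)
  S2 <- sum((rowSums(w) + colSums(w))^2)
  variance <- (n^2 * S1 - n * S2 + 3 * S0^2) / (S0^2 * (n^2 - 1)) - expected^2
  z <- (I - expected) / sqrt(variance)
  structure(list(I = I, expected = expected, variance = variance, z = z,
                 p = 2 * stats::pnorm(-abs(z)), n = n),
            class = "moran_result")
}

#' @export
print.moran_result <- function(x, ...) {
  cat(sprintf("Moran's I = %.4f (expected %.4f), z = %.3f, p = %.4g\n",
              x$I, x$expected, x$z, x$p))
  invisible(x)
}

#' Pairwise collinearity screen of the environmental covariates
#'
#' Pearson correlations of all six covariate pairs, flagging |r| >= 0.7
#' (the conventional threshold above which gradient regressions suffer
#' from collinearity).
#'
#' @param squares data.frame of square records.
#' @param threshold flag threshold on |r|.
#' @return data.frame with columns `var1`, `var2`, `r`, `flagged`.
#' @export
collinearity_screen <- function(squares, threshold = 0.7) {
  stopifnot(nrow(squares) >= 3)
  vars <- c("dist_sea", "width", "shoreline", "land_area")
  m <- as.matrix(squares[, vars])
  if (any(apply(m, 2, stats::sd) == 0))
    stop_named("skerrydiv_zero_variance", "zero-variance covariate")
  cm <- stats::cor(m)
  idx <- utils::combn(length(vars), 2)
  data.frame(var1 = vars[idx[1, ]], var2 = vars[idx[2, ]],
             r = cm[t(idx)],
             flagged = abs(cm[t(idx)]) >= threshold,
             stringsAsFactors = FALSE)
}
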