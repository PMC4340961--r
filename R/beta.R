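#' Pairwise dissimilarity matrix container
#'
#' A symmetric matrix with zero diagonal over square labels; `kind`
#' records the index it houses (`"sorensen"`, `"raup_crick"` or
#' `"manhattan"`). Pairs undefined for the index (two empty squares
#' under Sorensen) are `NA` and excluded downstream.
#'
#' @param values symmetric numeric matrix with dimnames.
#' @param kind character scalar.
#' @return a `dissim_matrix`.
#' @export
dissim_matrix <- function(values, kind) {
  stopifnot(is.matrix(values), nrow(values) == ncol(values),
            !is.null(rownames(values)),
            identical(rownames(values), colnames(values)))
  if (!isTRUE(all.equal(values, t(values))))
    stop_named("skerrydiv_asymmetric", "dissimilarity matrix must be symmetric")
  structure(values, kind = kind, class = c("dissim_matrix", "matrix", "array"))
}

#' @export
print.dissim_matrix <- function(x, ...) {
  cat(sprintf("%s dissimilarity over %d squares (%d NA pairs)\n",
              attr(x, "kind"), nrow(x), sum(is.na(x[upper.tri(x)]))))
  invisible(x)
}

#' Sorensen dissimilarity of one square pair
#'
#' `1 - 2w / (a + b)` where `a` and `b` are the species counts of the two
#' squares and `w` the shared-species count.
#'
#' @param a,b species counts (non-negative integers).
#' @param w shared species count, `w <= min(a, b)`.
#' @return dissimilarity in `[0, 1]`.
#' @export
sorensen <- function(a, b, w) {
  stopifnot(a >= 0, b >= 0, w >= 0, w <= min(a, b))
  if (a + b == 0)
    stop_named("skerrydiv_undefined_pair",
               "Sorensen dissimilarity undefined for two empty squares")
  1 - 2 * w / (a + b)
}

#' Sorensen dissimilarity matrix for a species group
#'
#' @param ds a valid `survey_dataset`.
#' @param group species group keyword, see [group_species()].
#' @return a `dissim_matrix` of kind `"sorensen"`; pairs of two empty
#'   squares are `NA`; the diagonal is 0.
#' @export
sorensen_matrix <- function(ds, group = "all") {
  validate_dataset(ds)
  p <- ds$presence[, group_species(ds, group), drop = FALSE]
  n <- rowSums(p)
  W <- p %*% t(p)
  tot <- outer(n, n, `+`)
  out <- 1 - 2 * W / tot
  out[tot == 0] <- NA_real_
  diag(out) <- 0
  dissim_matrix(out, "sorensen")
}

#' Regional pool weights for the Raup-Crick null model
#'
#' Each species is weighted by its empirical occupancy: the number of
#' squares of the regional dataset it occupies. Species never observed
#' carry weight 0 and are excluded from null draws.
#'
#' @param ds a valid `survey_dataset` (the regional dataset).
#' @param group species group keyword; the pool is group-specific by
#'   default (see the config note in the methods vignette).
#' @return list with `weights` (named numeric vector) and `gamma`
#'   (number of species with positive weight).
#' @export
pool_weights <- function(ds, group = "all") {
  validate_dataset(ds)
  p <- ds$presence[, group_species(ds, group), drop = FALSE]
  w <- colSums(p)
  list(weights = w, gamma = sum(w > 0))
}

#' Raup-Crick configuration
#'
#' @param reps Monte-Carlo null draws per unique richness pair.
#' @param seed integer seed.
#' @param rescale_minus1_1 rescale the probability from `[0, 1]` to
#'   `[-1, 1]` (off by default).
#' @return a `raup_crick_config` list. Ties between the null and the
#'   observed shared-species count always contribute half weight, which
#'   keeps the null expectation at 0.5.
#' @export
raup_crick_config <- function(reps = 999, seed = 1, rescale_minus1_1 = FALSE) {
  stopifnot(reps >= 1)
  structure(list(reps = reps, seed = seed,
                 rescale_minus1_1 = isTRUE(rescale_minus1_1)),
            class = "raup_crick_config")
}

#' Null draws of the shared-species count
#'
#' Each draw assembles two squares of the stated richness by sequential
#' weighted sampling without replacement from the positive-weight pool
#' (draw, remove, renormalise; probability proportional to occupancy
#' weight) and records the number of species the two squares share.
#'
#' @param n1,n2 richness of the two squares.
#' @param weights named occupancy weights (see [pool_weights()]).
#' @param reps number of draws.
#' @return integer vector of length `reps`.
#' @export
raup_crick_null <- function(n1, n2, weights, reps) {
  w <- weights[weights > 0]
  gamma <- length(w)
  if (n1 > gamma || n2 > gamma)
    stop_named("skerrydiv_infeasible_richness",
               "richness (%d, %d) exceeds positive-weight pool size %d",
               n1, n2, gamma)
  ids <- seq_len(gamma)
  vapply(seq_len(reps), function(i) {
    s1 <- if (n1 > 0) sample(ids, n1, replace = FALSE, prob = w) else integer()
    s2 <- if (n2 > 0) sample(ids, n2, replace = FALSE, prob = w) else integer()
    length(intersect(s1, s2))
  }, integer(1))
}

rc_score <- function(w_null, w_obs, reps, rescale = FALSE) {
  val <- (sum(w_null > w_obs) + 0.5 * sum(w_null == w_obs)) / reps
  if (rescale) (val - 0.5) * 2 else val
}

#' Raup-Crick dissimilarity of one square pair
#'
#' Probability-scaled dissimilarity: the chance, under the richness- and
#' occupancy-constrained null, of drawing more shared species than
#' observed (ties contribute half weight). High values mean the two
#' squares share fewer species than expected given their richness, i.e.
#' compositional turnover beyond what richness differences explain.
#'
#' @param n1,n2 observed richness of the two squares.
#' @param w_obs observed shared-species count, `<= min(n1, n2)`.
#' @param pool a [pool_weights()] list.
#' @param cfg a [raup_crick_config()].
#' @param null optional precomputed draws from [raup_crick_null()]
#'   (used by the matrix routine's richness-pair cache).
#' @return dissimilarity in `[0, 1]` (or `[-1, 1]` when rescaled).
#' @export
raup_crick_pair <- function(n1, n2, w_obs, pool, cfg = raup_crick_config(),
                            null = NULL) {
  stopifnot(w_obs <= min(n1, n2))
  if (is.null(null))
    null <- with_seed(cfg$seed, raup_crick_null(n1, n2, pool$weights, cfg$reps))
  rc_score(null, w_obs, length(null), cfg$rescale_minus1_1)
}

#' Exact Raup-Crick probability by enumeration
#'
#' Independent closed-form counterpart of [raup_crick_pair()] for small
#' pools: enumerates every subset of the stated richness, computes its
#' probability under sequential weighted sampling without replacement by
#' summing over draw orders, and evaluates the tie-split survival
#' probability exactly.
#'
#' @inheritParams raup_crick_pair
#' @param weights named occupancy weights (positive entries used).
#' @return exact probability in `[0, 1]`.
#' @export
raup_crick_exact <- function(n1, n2, w_obs, weights) {
  w <- weights[weights > 0]
  gamma <- length(w)
  stopifnot(n1 <= gamma, n2 <= gamma, w_obs <= min(n1, n2))
  subset_probs <- function(n) {
    if (n == 0) return(list(sets = list(integer()), prob = 1))
    sets <- utils::combn(gamma, n, simplify = FALSE)
    prob <- vapply(sets, function(s) set_draw_prob(w, s), numeric(1))
    list(sets = sets, prob = prob)
  }
  e1 <- subset_probs(n1)
  e2 <- subset_probs(n2)
  p_gt <- 0; p_eq <- 0
  for (i in seq_along(e1$sets)) for (j in seq_along(e2$sets)) {
    k <- length(intersect(e1$sets[[i]], e2$sets[[j]]))
    pij <- e1$prob[i] * e2$prob[j]
    if (k > w_obs) p_gt <- p_gt + pij
    else if (k == w_obs) p_eq <- p_eq + pij
  }
  p_gt + 0.5 * p_eq
}

# probability that sequential weighted sampling without replacement draws
# exactly the set `s`: sum over draw orders of prod(w_i / remaining total)
set_draw_prob <- function(w, s) {
  total <- sum(w)
  rec <- function(remaining, tot) {
    if (!length(remaining)) return(1)
    p <- 0
    for (i in seq_along(remaining)) {
      wi <- w[remaining[i]]
      p <- p + wi / tot * rec(remaining[-i], tot - wi)
    }
    p
  }
  rec(s, total)
}

#' Raup-Crick dissimilarity matrix for a species group
#'
#' Pool weights come from the full regional dataset; the null
#' distribution of the shared-species count is simulated once per unique
#' richness pair and reused for every square pair with that richness
#' (the cache that makes thousands of squares feasible). Deterministic
#' under the config seed; the per-pair null streams are keyed by the
#' richness pair, not by enumeration order.
#'
#' @param ds a valid `survey_dataset`.
#' @param group species group keyword.
#' @param cfg a [raup_crick_config()].
#' @return a `dissim_matrix` of kind `"raup_crick"` with the null cache
#'   attached as attribute `"cache"` (a named list of draw vectors keyed
#'   `"n1:n2"`, `n1 <= n2`).
#' @export
raup_crick_matrix <- function(ds, group = "all", cfg = raup_crick_config()) {
  validate_dataset(ds)
  pool <- pool_weights(ds, group)
  p <- ds$presence[, group_species(ds, group), drop = FALSE]
  n <- rowSums(p)
  if (max(n) > pool$gamma)
    stop_named("skerrydiv_infeasible_richness",
               "observed richness exceeds positive-weight pool size")
  W <- p %*% t(p)
  nsq <- nrow(p)
  out <- matrix(NA_real_, nsq, nsq, dimnames = dimnames(W))

  pairs <- which(upper.tri(W), arr.ind = TRUE)
  key <- paste(pmin(n[pairs[, 1]], n[pairs[, 2]]),
               pmax(n[pairs[, 1]], n[pairs[, 2]]), sep = ":")
  cache <- list()
  for (k in unique(key)) {
    nn <- as.integer(strsplit(k, ":", fixed = TRUE)[[1]])
    cache[[k]] <- with_seed(
      stage_seed(cfg$seed, paste0("raup_crick/", k)),
      raup_crick_null(nn[1], nn[2], pool$weights, cfg$reps))
  }
  for (k in unique(key)) {
    sel <- key == k
    draws <- cache[[k]]
    # survival table over all possible shared counts for this richness pair
    kmax <- min(as.integer(strsplit(k, ":", fixed = TRUE)[[1]]))
    tab <- vapply(0:kmax, function(wo)
      rc_score(draws, wo, cfg$reps, cfg$rescale_minus1_1), numeric(1))
    ij <- pairs[sel, , drop = FALSE]
    out[ij] <- tab[W[ij] + 1L]
  }
  out[lower.tri(out)] <- t(out)[lower.tri(out)]
  diag(out) <- 0
  structure(dissim_matrix(out, "raup_crick"), cache = cache)
}
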