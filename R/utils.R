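#' Run code with a temporary RNG seed
#'
#' Evaluates `expr` under `set.seed(seed)` and restores the caller's RNG
#' state afterwards, so seeded package functions do not disturb the global
#' random stream.
#'
#' @param seed integer seed, or `NULL` to use the current stream.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Derive a stage-specific sub-seed from a master seed
#'
#' Sub-seeds are keyed by stage name so that reordering pipeline stages
#' cannot silently shift the random streams of unrelated stages.
#'
#' @param master integer master seed.
#' @param stage character stage name.
#' @return integer seed in `[0, 2^31 - 2]`.
#' @keywords internal
stage_seed <- function(master, stage) {
  stopifnot(is.character(stage), length(stage) == 1L)
  # Horner-style rolling hash of the stage name, folded with the master seed.
  h <- 0
  for (k in utf8ToInt(stage)) h <- (h * 31 + k) %% 2147480009
  as.integer((abs(as.numeric(master)) %% 2147480009 * 7919 + h) %% 2147480009)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_named <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "skerrydiv_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}
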