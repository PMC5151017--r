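logistic <- function(x) 1 / (1 + exp(-x))

# log(1 + exp(x)) without overflow for large x
softplus <- function(x) {
  out <- pmax(x, 0) + log1p(exp(-abs(x)))
  out
}

logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

#' Evaluate an expression under a local RNG seed
#'
#' Sets the RNG seed, evaluates `expr`, and restores the caller's RNG state
#' afterwards. Used throughout the package (and useful with seedless
#' operations such as [gibbs_step()]) to make stochastic computations
#' reproducible without disturbing the global random stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  expr
}

# Derive a child seed from a run seed; stays well inside 32-bit range.
child_seed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + 7907 * as.double(k)) %% 2147483587)
}
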