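# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG state
#'
#' Sets the seed, runs `expr`, and restores the caller's RNG state so that
#' seeded package functions do not perturb the user's random stream.
#'
#' @param seed Integer seed, or `NULL` to use the current stream.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Derive a sub-seed from a master seed by a fixed counter scheme, kept
# inside 32-bit integer range.
derive_seed <- function(seed, counter) {
  if (is.null(seed)) return(NULL)
  as.integer((as.double(seed) * 1009 + counter) %% .Machine$integer.max)
}

stop_if_not <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)

# Project columns (samples) of an electrodes x samples matrix onto the
# average-reference subspace: subtract each sample's mean across electrodes.
average_reference <- function(x) {
  sweep(x, 2L, colMeans(x), "-")
}
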