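#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `expr` with the random number generator seeded at `seed`, then
#' restores the caller's RNG state, so package functions never clobber the
#' user's random stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)  # initialise the RNG state so it can be saved
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

#' Derive a stage seed from a global seed
#'
#' Expands one global seed into per-stage seeds by a fixed counter scheme, so
#' individual pipeline stages can be re-run in isolation yet reproduce the
#' full run exactly. Kept below 2^31 - 1.
#'
#' @param seed Global integer seed.
#' @param stage Integer stage counter (>= 1).
#' @return An integer seed.
#' @export
stage_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) * 1000003 + stage * 7919) %% 2147483647L)
}

# all(x) that treats empty as TRUE but NA as FALSE
`%||%` <- function(a, b) if (is.null(a)) b else a
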