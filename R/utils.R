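#' Derive a stage-specific seed from a global seed
#'
#' Splits one global integer seed into independent per-stage streams keyed by a
#' stable string, so toggling one pipeline stage never changes the draws of
#' another. The hash is a plain polynomial rolling hash kept inside the 32-bit
#' integer range.
#'
#' @param seed Integer global seed.
#' @param key Character stage key, e.g. `"classify"`.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
stage_seed <- function(seed, key) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(key))
  mod <- 2147483647  # 2^31 - 1, prime
  h <- as.numeric(seed) %% mod
  for (ch in utf8ToInt(key)) {
    h <- (h * 131 + ch) %% mod
  }
  as.integer(h)
}

#' Evaluate an expression under a local RNG seed
#'
#' Saves and restores `.Random.seed` so seeded operations never disturb the
#' caller's RNG stream.
#'
#' @param seed Integer seed, or `NULL` to leave the RNG alone.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# min-max scale a vector to [0, 1] over non-missing entries; constant vectors
# map to 0 (their spread carries no information).
minmax <- function(x) {
  r <- range(x, na.rm = TRUE)
  if (!is.finite(r[1]) || r[2] == r[1]) return(ifelse(is.na(x), NA_real_, 0))
  (x - r[1]) / (r[2] - r[1])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
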