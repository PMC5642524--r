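#' Round half away from zero
#'
#' Table percentages in clinical reports are conventionally rounded half away
#' from zero; R's `round()` rounds half to even, which differs at exact .5
#' boundaries (e.g. 26.25 -> 26.2 instead of 26.3).
#'
#' @param x numeric vector
#' @param digits decimal places to keep
#' @return rounded numeric vector
#' @export
round_half_up <- function(x, digits = 1) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5 + 1e-9) / f
}

# stop() with a consistent prefix, no call in the condition
abort <- function(...) stop(..., call. = FALSE)

# run expr with a fixed RNG state, restoring the caller's stream afterwards
with_seed <- function(seed, expr) {
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

# derive a stable 32-bit sub-seed from a master seed and a stream label
sub_seed <- function(seed, label) {
  h <- sum(utf8ToInt(as.character(label)) * seq_along(utf8ToInt(as.character(label))))
  as.integer((as.numeric(seed) * 7919 + h * 104729 + 12345) %% .Machine$integer.max)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
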