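## Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Restores the caller's `.Random.seed` afterwards so seeded package
#' functions do not disturb the user's RNG stream.  With `seed = NULL` the
#' expression runs on the current stream.
#'
#' @param seed integer seed or `NULL`.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) runif(1L)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  expr
}

stop_promarch <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "promarch_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Map a signed no-zero relative coordinate (TSS = +1, first upstream
## base = -1; no position 0) to a genomic offset from the dominant TSS.
## Offset 0 is the TSS base itself.
nozero_to_offset <- function(rel) {
  stopifnot(all(rel != 0L))
  ifelse(rel > 0L, rel - 1L, rel)
}

## Strand sign: +1 on the plus strand, -1 on the minus strand.
strand_sign <- function(strand) ifelse(strand == "+", 1L, -1L)
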