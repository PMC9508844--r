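#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `expr` with the global random number generator seeded to `seed`,
#' then restores the previous RNG state so callers' random streams are not
#' disturbed.
#'
#' @param seed Integer seed, or `NULL` to leave the RNG untouched.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) {
    return(expr)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# stop() without the call, with sprintf-style formatting
abort <- function(fmt, ..., class = NULL) {
  msg <- if (length(list(...))) sprintf(fmt, ...) else fmt
  cond <- structure(
    class = c(class, "chromguide_error", "error", "condition"),
    list(message = msg, call = NULL)
  )
  stop(cond)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Decorrelate a user seed from other streams seeded with the same integer
# (e.g. a genome and the candidate sampler): a Knuth multiplicative hash
# into [0, 2^31). Without this, sampling sequences under the same seed that
# generated the genome reproduces the genome's own base stream verbatim.
scramble_seed <- function(seed) {
  if (is.null(seed)) return(NULL)
  as.integer((as.double(seed) * 2654435761) %% 2147483647)
}

# integer-valued check tolerant of numeric storage
is_wholenumber <- function(x, tol = 1e-8) {
  is.numeric(x) & is.finite(x) & abs(x - round(x)) < tol
}
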