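# Small shared helpers. Seeds are kept below .Machine$integer.max because all
# downstream RNG goes through set.seed(), which takes a 32-bit integer.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible child seed
#'
#' Mixes a base seed with an integer salt (e.g. an epoch index) so that
#' nested stochastic steps are reproducible from one user-supplied seed
#' without reusing the same stream everywhere.
#'
#' @param seed Integer base seed.
#' @param salt Integer salt.
#' @return An integer in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, salt = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  # 2654435761 is the Knuth multiplicative-hash constant; arithmetic in
  # doubles stays exact below 2^53.
  v <- (abs(seed) %% 2147483647) * 69069 + (abs(salt) %% 2147483647) * 2654435761
  as.integer(v %% 2147483646) + 1L
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so library internals do not perturb the
#' caller's RNG stream.
#' @param seed Integer seed, or `NULL` to use the current stream.
#' @param expr Expression to evaluate.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

# Probability floor used before any logarithm (numerical guard; the loss
# formula itself has no epsilon).
PROB_EPS <- 1e-7

clip_prob <- function(p, eps = PROB_EPS) pmin(pmax(p, eps), 1 - eps)

#' Round half away from zero
#'
#' Percent-change tables print integer percentages; `round()`'s banker's
#' rounding would map 8.5 to 8, which is not how the tables are printed.
#' @keywords internal
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

rc_log <- function(..., verbose = getOption("radcal.verbose", TRUE)) {
  if (isTRUE(verbose)) message(...)
  invisible(NULL)
}

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
  invisible(TRUE)
}
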