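# Internal helpers shared across modules.

#' Evaluate code with a temporarily fixed RNG state
#'
#' Sets the seed for the duration of `code` and restores the caller's
#' `.Random.seed` afterwards, so seeded operations never perturb the global
#' random stream.
#'
#' @param seed Integer seed, or `NULL` to use the current stream.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_local_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Deterministic substream seed derived from a root seed; stays < 2^31 - 1.
derive_seed <- function(seed, offset) {
  as.integer((as.double(seed) %% 2147483647 * 48271 + 7919 * as.double(offset)) %%
               2147483646) + 1L
}

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
  invisible(TRUE)
}

# Validates a genes x samples expression matrix with unique dimnames.
validate_expression <- function(expr, what = "expression matrix") {
  assert_that(is.matrix(expr) && is.numeric(expr),
              sprintf("%s must be a numeric matrix", what))
  assert_that(!is.null(rownames(expr)) && !is.null(colnames(expr)),
              sprintf("%s must have gene row names and sample column names", what))
  assert_that(!anyDuplicated(rownames(expr)),
              sprintf("duplicate gene IDs in %s", what))
  assert_that(!anyDuplicated(colnames(expr)),
              sprintf("duplicate sample IDs in %s", what))
  invisible(expr)
}
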