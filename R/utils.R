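#' @keywords internal
"_PACKAGE"

## NULL-default operator, used throughout for config fallbacks.
`%||%` <- function(x, y) if (is.null(x)) y else x

#' Evaluate an expression under a fixed, restorable RNG state
#'
#' All stochastic stages of the package route their randomness through this
#' helper so that (a) the generator kind is pinned (Mersenne-Twister /
#' Inversion, identical across platforms) and (b) the caller's RNG state is
#' untouched.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("'seed' must be a single finite number", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed) %% .Machine$integer.max,
           kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  expr
}

## Derive a stream-specific child seed from a master seed; kept below 2^31.
child_seed <- function(seed, stream) {
  (as.double(seed) * 48271 + stream * 10007) %% 2147483647
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

warnf <- function(...) warning(sprintf(...), call. = FALSE)

## Validate a counts matrix: numeric, non-negative, named, unique ids.
check_count_matrix <- function(x, what = "counts", integer = TRUE) {
  if (!is.matrix(x) || !is.numeric(x)) stopf("'%s' must be a numeric matrix", what)
  if (anyNA(x)) stopf("'%s' contains missing values", what)
  if (any(x < 0)) stopf("'%s' contains negative values", what)
  if (integer && any(x != round(x))) stopf("'%s' contains non-integer values", what)
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    stopf("'%s' must have row and column names", what)
  }
  if (anyDuplicated(rownames(x))) {
    stopf("duplicate row identifiers in '%s': %s", what,
          paste(unique(rownames(x)[duplicated(rownames(x))]), collapse = ", "))
  }
  if (anyDuplicated(colnames(x))) {
    stopf("duplicate column identifiers in '%s': %s", what,
          paste(unique(colnames(x)[duplicated(colnames(x))]), collapse = ", "))
  }
  invisible(x)
}
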