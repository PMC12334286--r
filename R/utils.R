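## Shared validation and RNG helpers.

abort_field <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

check_number <- function(x, field, lower = -Inf, upper = Inf,
                         integer = FALSE, strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    abort_field(field, "must be a single number")
  }
  if (integer && x != round(x)) abort_field(field, "must be an integer")
  if (strict_lower) {
    if (x <= lower) abort_field(field, paste("must be >", lower))
  } else if (x < lower) {
    abort_field(field, paste("must be >=", lower))
  }
  if (x > upper) abort_field(field, paste("must be <=", upper))
  invisible(x)
}

#' Evaluate code under a temporary RNG seed, restoring the caller's RNG state
#' @keywords internal
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

## Derive a stream of well-spread 31-bit seeds from a base seed.
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(index) * 16807 + 11) %%
               2147483647)
}

is_binary_mask <- function(mask) {
  is.numeric(mask) && all(mask == 0 | mask == 1)
}

check_same_shape <- function(a, b, what = "inputs") {
  da <- dim(a) %||% length(a)
  db <- dim(b) %||% length(b)
  if (!identical(as.integer(da), as.integer(db))) {
    stop(what, " must have identical dimensions", call. = FALSE)
  }
  invisible(TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
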