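# Classed conditions shared by every module. Readers collect recoverable
# problems into reports; these conditions are for contract violations.

mi_stop <- function(class, message, ...) {
  stop(structure(
    class = c(class, "mi_error", "error", "condition"),
    list(message = message, call = sys.call(-1L), ...)
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# run code under a fixed seed, then restore the caller's RNG stream
with_gen_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# scalar character or NULL
chr1_or_null <- function(x, what) {
  if (is.null(x)) return(NULL)
  if (!is.character(x) || length(x) != 1L || is.na(x))
    mi_stop("mi_invalid", sprintf("%s must be a single character string or NULL", what))
  x
}

chr1 <- function(x, what, allow_empty = FALSE) {
  if (!is.character(x) || length(x) != 1L || is.na(x))
    mi_stop("mi_invalid", sprintf("%s must be a single character string", what))
  if (!allow_empty && !nzchar(x))
    mi_stop("mi_invalid", sprintf("%s must be non-empty", what))
  x
}

int1 <- function(x, what) {
  if (length(x) != 1L || is.na(x) || !is.numeric(x) || x != trunc(x))
    mi_stop("mi_invalid", sprintf("%s must be a single integer", what))
  as.integer(x)
}

assert_list_of <- function(x, class, what) {
  if (is.null(x)) return(list())
  if (!is.list(x)) mi_stop("mi_invalid", sprintf("%s must be a list", what))
  bad <- !vapply(x, inherits, logical(1L), what = class)
  if (any(bad))
    mi_stop("mi_invalid", sprintf("%s must contain only <%s> objects", what, class))
  x
}
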