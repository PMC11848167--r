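#' @keywords internal
"_PACKAGE"

#' @importFrom stats pchisq phyper pt rnorm rpois rnbinom runif setNames
#'   p.adjust cor lm.fit rchisq
#' @importFrom utils head write.table read.delim packageVersion
#' @importFrom methods as is
NULL

# Run code with a private RNG stream: set the seed locally, restore the
# caller's .Random.seed afterwards so generators do not clobber global state.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  force(code)
}

stop_sexdim <- function(..., call. = FALSE) stop(..., call. = call.)

assert_prob <- function(x, name) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0) || any(x > 1))
    stop_sexdim(sprintf("'%s' must lie in [0, 1]", name))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# deterministic ordering helper: order by each column of `...` in turn
order_by <- function(...) do.call(order, list(...))
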