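#' @keywords internal
"_PACKAGE"

#' Evaluate an expression with a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded internals never disturb the
#' caller's RNG stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Derive a stage-specific seed from a global seed
#'
#' One global seed fans out to per-stage seeds through a documented, purely
#' arithmetic derivation so pipeline stages are decoupled yet reproducible.
#'
#' @param seed integer global seed.
#' @param stage character stage name.
#' @return integer in `[0, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seed(1, "adaptation")
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- 0
  for (b in utf8ToInt(stage)) h <- (h * 131 + b) %% 2147483647
  as.integer((abs(seed) %% 2147483647 + h) %% 2147483646) + 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_mdafm <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 1 || x != floor(x))
    stop_mdafm("'%s' must be a positive integer (got %s)", name, deparse(x))
  as.integer(x)
}

check_prob <- function(x, name, open = TRUE) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) &&
    (if (open) x > 0 && x < 1 else x >= 0 && x <= 1)
  if (!ok) stop_mdafm("'%s' must lie in %s (got %s)", name,
                      if (open) "(0, 1)" else "[0, 1]", deparse(x))
  x
}

#' @importFrom stats rnorm runif rbinom pnorm qnorm quantile median var sd cor
#' @importFrom stats plogis rmultinom
#' @importFrom utils head tail read.csv write.csv
NULL
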