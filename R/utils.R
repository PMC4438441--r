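# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible sub-seed from a master seed and a tag
#'
#' A single study seed hierarchically derives independent streams for the
#' tree, each character, each factorial cell, etc., so that adding one
#' component never perturbs another. The result is always a positive
#' integer below 2^31.
#'
#' @param seed Integer master seed.
#' @param ... Character or integer tags naming the sub-stream.
#' @return A single integer usable with [set.seed()].
#' @export
derive_seed <- function(seed, ...) {
  tags <- unlist(lapply(list(...), as.character))
  h <- as.double(seed) %% 2147483647
  for (tag in tags) {
    for (v in utf8ToInt(tag)) {
      # 32-bit-safe multiplicative mixing in double arithmetic
      h <- (h * 131 + v + 17) %% 2147483647
    }
    h <- (h * 2654435761) %% 2147483647
  }
  as.integer(h %% 2147483646) + 1L
}

# Evaluate expr with a temporary RNG state seeded by `seed`; the caller's
# RNG state is restored afterwards so seeded internals do not disturb
# user-level streams. seed = NULL leaves the RNG alone.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

stop2 <- function(...) stop(..., call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x) &&
  x >= 1 && x == round(x)

# Render a probability with the fixed 4-decimal report precision.
format_prob <- function(p) sprintf("%.4f", p)
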