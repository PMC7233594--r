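#' @keywords internal
"_PACKAGE"

# Deterministic 32-bit sub-stream seed for per-eye / per-stage draws, so that
# adding an eye to a cohort never perturbs the draws of earlier eyes.
substream_seed <- function(seed, unit, stage = 1L) {
  s <- as.double(seed) %% 2147483647
  s <- (s * 48271 + as.double(unit) * 16807 + as.double(stage) * 69621) %% 2147483647
  as.integer(s)
}

# Evaluate `expr` under a private RNG state seeded by `seed`; the caller's
# .Random.seed is restored afterwards.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

stop_lcshift <- function(...) stop(..., call. = FALSE)
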