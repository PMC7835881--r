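#' @noRd
sigmoid <- function(x) 1 / (1 + exp(-x))

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

#' Derive a named sub-stream seed from a top-level seed
#'
#' All randomness in the package flows from one top-level seed through
#' named sub-streams (e.g. "sim", "episodes", "init", "eval"), so that
#' changing one stage's stream never perturbs another's. The derived seed
#' is a deterministic 31-bit integer.
#'
#' @param seed integer top-level seed.
#' @param name character stream name.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
#' @examples
#' substream_seed(42, "sim")
substream_seed <- function(seed, name) {
  h <- 0
  for (ch in utf8ToInt(as.character(name))) h <- (h * 31 + ch) %% 2147483647
  as.integer((abs(as.numeric(seed)) * 7919 + h + 1) %% 2147483647)
}

# Run expr with a locally seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  expr
}

#' Standardize a volume to zero mean and unit variance
#'
#' Per-volume z-scoring applied to subtomograms before they enter the
#' network. A constant volume maps to all zeros.
#'
#' @param v numeric array.
#' @return Array of the same shape.
#' @export
standardize_volume <- function(v) {
  s <- stats::sd(as.vector(v))
  if (!is.finite(s) || s == 0) return(array(0, dim(v)))
  (v - mean(v)) / s
}

# Polynomial rolling hash of an R object's serialized bytes, as hex. Used
# to stamp artifacts with the configuration that produced them.
config_hash <- function(obj) {
  bytes <- as.integer(serialize(obj, NULL, version = 2))
  h <- 0
  for (b in bytes) h <- (h * 257 + b + 1) %% 2147483647
  sprintf("%08x", as.integer(h))
}

is_cube <- function(a) {
  d <- dim(a)
  length(d) == 3 && d[1] == d[2] && d[2] == d[3]
}
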