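# Internal helpers: deterministic substream seeding, small assertions.

# Fold a master seed and an arbitrary set of labels into a reproducible
# 31-bit seed.  All randomness in the package flows from one master seed
# through named substreams so partial regeneration is stable.
substream_seed <- function(seed, ...) {
  labels <- paste(vapply(list(...), as.character, character(1)), collapse = "/")
  h <- as.double(seed %% 2147483647L)
  for (code in utf8ToInt(labels)) {
    h <- (h * 31 + code) %% 2147483629
  }
  as.integer(h %% 2147483647)
}

# Evaluate `expr` under a local RNG state seeded with `seed`, restoring the
# caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

stopifnot_scalar_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x)) {
    stop(sprintf("`%s` must be a single integer >= %d", name, min), call. = FALSE)
  }
}

# Wrap angles in degrees to [-180, 180).
wrap_degrees <- function(x) {
  ((x + 180) %% 360) - 180
}

# Unwrap a degree-valued angle series (undo the [-180, 180) seam) so that
# linear interpolation across the seam is meaningful.
unwrap_degrees <- function(x) {
  if (length(x) < 2L) return(x)
  d <- diff(x)
  jumps <- cumsum(c(0, -360 * (d > 180) + 360 * (d < -180)))
  x + jumps
}

`%||%` <- function(a, b) if (is.null(a)) b else a
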