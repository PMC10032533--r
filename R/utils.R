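# Internal helpers shared across modules.

# Run `code` under a fixed RNG seed, restoring the caller's RNG state.
# All generator functions route their randomness through this so that a
# given seed yields bit-identical output regardless of surrounding code.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

abort_if <- function(cond, ...) {
  if (cond) stop(..., call. = FALSE)
}

# Scalar positivity check with a readable message.
check_positive <- function(x, name, strict = TRUE) {
  abort_if(length(x) == 0, "`", name, "` must be a non-empty numeric")
  bad <- if (strict) any(!is.finite(x) | x <= 0) else any(!is.finite(x) | x < 0)
  abort_if(bad, "`", name, "` must be ",
           if (strict) "strictly positive" else "non-negative",
           " and finite")
  invisible(x)
}

check_columns <- function(df, cols, what = "input") {
  missing <- setdiff(cols, names(df))
  abort_if(length(missing) > 0,
           what, " is missing required column(s): ",
           paste(missing, collapse = ", "))
  invisible(df)
}

# Draw from InverseGamma(shape, scale): X = 1/G, G ~ Gamma(shape, rate = scale).
# The gamma variate is clamped away from exact zero so a floating-point
# underflow (possible at very small shapes) cannot yield an infinite draw.
rinvgamma <- function(n, shape, scale) {
  check_positive(shape, "shape")
  check_positive(scale, "scale")
  1 / pmax(stats::rgamma(n, shape = shape, rate = scale), 1e-300)
}

# Wrap an angle in degrees to [-180, 180).
wrap_degrees <- function(deg) {
  out <- ((deg + 180) %% 360) - 180
  # %% can return 360 - eps for inputs just below -180; keep canonical interval
  out[out >= 180] <- out[out >= 180] - 360
  out
}

# Short content fingerprint for provenance blocks (polynomial rolling hash,
# two independent moduli; not cryptographic).
config_fingerprint <- function(x) {
  bytes <- as.double(charToRaw(paste(x, collapse = "\n")))
  m1 <- 2147483647; m2 <- 2147483629
  h1 <- 0; h2 <- 0
  for (b in bytes) {
    h1 <- (h1 * 131 + b) %% m1
    h2 <- (h2 * 137 + b) %% m2
  }
  sprintf("%08x%08x", h1, h2)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
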