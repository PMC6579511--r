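#' Derive a named substream seed from a master seed
#'
#' All randomness in the package flows from a single integer seed; each
#' module draws from a named substream so that, e.g., adding noise frames to
#' the imaging simulator does not perturb the behavioral generator.
#'
#' @param seed master integer seed (< 2^31).
#' @param name substream name (character scalar).
#' @return an integer seed in `[1, 2^31 - 2]`, deterministic in `(seed, name)`.
#' @export
substream_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed),
            is.character(name), length(name) == 1L)
  m <- 2147483647
  h <- 0
  for (c in utf8ToInt(name)) h <- (h * 31 + c) %% m
  # h < 2^31, 65539 * h < 2^48: exact in doubles
  s <- (h * 65539 + abs(seed)) %% m
  as.integer(s %% (m - 1) + 1)
}

# evaluate `expr` with the RNG seeded to `seed`, restoring the caller's RNG
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

# signed fft frequencies in cycles per sample, length n
fft_freq <- function(n) {
  f <- 0:(n - 1)
  f[f > n / 2] <- f[f > n / 2] - n
  f / n
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ft <- function(...) stop(sprintf(...), call. = FALSE)
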