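`%||%` <- function(x, y) if (is.null(x)) y else x

#' Derive a reproducible sub-seed for a named random stream
#'
#' All randomness in the package flows from one integer master seed.
#' Independent stages (phantom texture, survival times, fold assignment,
#' weight initialization, ...) draw from sub-seeds derived with a fixed
#' integer hash so that any stage can be regenerated in isolation.
#'
#' @param seed Integer master seed.
#' @param stream Character stream label, or an integer offset.
#' @return An integer in `[1, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seed(1, "texture")
derive_seed <- function(seed, stream) {
  stopifnot(length(seed) == 1, is.finite(seed))
  if (is.character(stream)) {
    stream <- sum(as.double(utf8ToInt(stream)) * seq_along(utf8ToInt(stream)))
  }
  m <- 2147483647 # 2^31 - 1, Mersenne prime of the Lehmer generator
  h <- (abs(as.double(seed)) %% m)
  h <- (h * 48271 + as.double(stream) * 16807 + 1) %% m
  h <- (h * 48271 + 1) %% m
  as.integer(h %% (m - 1)) + 1L
}

# Run code with a temporary RNG state seeded at `seed`.
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

# population skewness/kurtosis; both 0 for a degenerate distribution
moment_skewness <- function(x) {
  m2 <- mean((x - mean(x))^2)
  if (m2 <= 0) return(0)
  mean((x - mean(x))^3) / m2^1.5
}

moment_kurtosis <- function(x) {
  m2 <- mean((x - mean(x))^2)
  if (m2 <= 0) return(0)
  mean((x - mean(x))^4) / m2^2
}

# log2 entropy of a probability vector, 0 * log(0) := 0
entropy_bits <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

stop_radguide <- function(...) stop(..., call. = FALSE)
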