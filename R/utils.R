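#' @importFrom methods new validObject is slot slotNames show
#' @importFrom stats rnorm runif fft mvfft sd var cor pt qt approx
#' @importFrom utils head tail modifyList
NULL

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores the global RNG state so seeded package operations do
#' not disturb the caller's random stream. A `NULL` seed leaves the current
#' stream untouched.
#'
#' @param seed integer seed or `NULL`.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
withSeed <- function(seed, code) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

#' Derive a stream-specific seed from a master seed
#'
#' Deterministic splitting of one user-facing seed into independent
#' sub-streams (one per pipeline stage), kept within 32-bit integer range.
#'
#' @param seed master integer seed.
#' @param salt character tag naming the consumer stream.
#' @return integer seed, or `NULL` if `seed` is `NULL`.
#' @keywords internal
deriveSeed <- function(seed, salt) {
  if (is.null(seed)) return(NULL)
  v <- utf8ToInt(salt)
  h <- sum(v * seq_along(v))
  as.integer((as.double(seed) * 7919 + h * 104729 + 12345) %% 2147483399)
}

#' @keywords internal
assertThat <- function(ok, msg) if (!isTRUE(ok)) stop(msg, call. = FALSE)

#' Pearson correlation that tolerates constant inputs
#' @keywords internal
safeCor <- function(a, b) {
  if (stats::sd(a) < 1e-15 || stats::sd(b) < 1e-15) return(0)
  stats::cor(a, b)
}

#' 1-based mirror map for an index possibly outside [1, len]
#'
#' Reflection without repeating the edge sample, e.g. len = 4 maps
#' 0 -> 2 and 5 -> 3.
#' @keywords internal
mirrorIndex <- function(i, len) {
  if (len == 1L) return(rep(1L, length(i)))
  p <- (i - 1L) %% (2L * (len - 1L))
  as.integer(ifelse(p < len, p + 1L, 2L * len - 1L - p))
}

#' Mirror-pad a vector by n samples on both sides
#' @keywords internal
reflectPad <- function(x, n) {
  len <- length(x)
  x[mirrorIndex(seq.int(1L - n, len + n), len)]
}
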