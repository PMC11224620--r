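`%||%` <- function(x, y) if (is.null(x)) y else x

#' Competition ranks of a numeric vector, largest first
#'
#' Ties share the minimum rank ("1, 2, 2, 4").
#'
#' @param x numeric vector; ranked in decreasing order.
#' @return integer vector of 1-based competition ranks.
#' @keywords internal
#' @noRd
competition_rank <- function(x) {
  as.integer(rank(-x, ties.method = "min"))
}

## Run `expr` under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Derive a sub-stream seed from a run seed
#'
#' A single integer seed governs every draw in a simulated study; each
#' component (network edges, differential-expression labels, noise
#' realizations) consumes its own stream so that, e.g., redrawing the noise
#' leaves the network untouched. The rule is a fixed affine hash kept within
#' the 32-bit signed integer range.
#'
#' @param seed integer master seed.
#' @param stream one of `"network"`, `"labels"`, `"noise"`, `"attenuation"`.
#' @return an integer seed for [set.seed()].
#' @export
stream_seed <- function(seed, stream = c("network", "labels", "noise", "attenuation")) {
  stream <- match.arg(stream)
  offset <- c(network = 1L, labels = 2L, noise = 3L, attenuation = 4L)[[stream]]
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  as.integer((abs(as.double(seed)) * 48271 + offset * 104729) %% 2147483629)
}

stop_modhub <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == as.integer(x)
}
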