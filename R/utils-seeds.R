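#' @useDynLib yapburst, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom rlang .data
#' @importFrom stats dnorm rnorm runif rbinom rpois rlnorm median mad sd
#'   quantile setNames coef lm predict nls ks.test uniroot optimize var
#' @importFrom utils head tail
NULL

# All stochastic stages consume named sub-streams derived from one master
# seed, so cohorts are reproducible under reordering and stages can be rerun
# independently. Derivation is a small multiplicative hash kept below 2^31.

#' Derive a deterministic sub-seed from a master seed
#'
#' Counter/name-based derivation: `derive_seed(s, "boot", 3)` always yields
#' the same value, distinct (in practice) from other names and counters, and
#' strictly below 2^31 so it is a valid R integer seed.
#'
#' @param seed Master seed (single integer).
#' @param ... Name components (strings or integers) identifying the stream.
#' @return A single integer in `[0, 2^31 - 1)`.
#' @export
derive_seed <- function(seed, ...) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  m <- 2147483629 # largest prime < 2^31
  h <- as.numeric(seed) %% m
  for (part in list(...)) {
    bytes <- if (is.character(part)) {
      as.numeric(utf8ToInt(part))
    } else {
      as.numeric(part)
    }
    for (b in bytes) {
      h <- (h * 69069 + b + 1) %% m
    }
  }
  as.integer(h)
}

with_seed <- function(seed, code) {
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
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_param <- function(msg) stop(msg, call. = FALSE)
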