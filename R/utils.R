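# Internal helpers: seed streams, logging attributes, small checks.

# Named seed streams derived from one master seed, so each stochastic stage
# (population, reference, selection, ...) is reproducible in isolation.
.stream_offsets <- c(
  population = 1L, reference = 2L, selection = 3L, missingness = 4L,
  folds = 5L, imputation = 6L, collider = 7L, benchmark = 8L
)

#' Derive a stream-specific seed from a master seed
#'
#' All randomness in the package flows from a single master seed split into
#' named streams, so re-running one stage (e.g. the reference draw) does not
#' perturb another.
#'
#' @param master integer master seed.
#' @param stream stream name, one of `r paste(names(.stream_offsets), collapse=", ")`.
#' @return an integer seed below 2^31.
#' @export
stream_seed <- function(master, stream) {
  stopifnot(is.numeric(master), length(master) == 1L)
  if (!stream %in% names(.stream_offsets)) {
    stop("unknown seed stream: ", stream)
  }
  off <- .stream_offsets[[stream]]
  # multiplicative hash mod the Mersenne prime 2^31 - 1; exact in doubles
  as.integer((abs(master) * 48271 + off * 16807) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.assert_prob <- function(p, what) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop(what, " must lie in [0, 1]")
  }
  invisible(p)
}

# stable phi(x)/Phi(x) (inverse Mills ratio) via log-scale computation
.mills <- function(x) {
  exp(stats::dnorm(x, log = TRUE) - stats::pnorm(x, log.p = TRUE))
}

.is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == floor(x)
}
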