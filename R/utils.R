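#' Derive a child seed from a master seed and a stage label
#'
#' Every stochastic operation in the package draws from its own RNG stream,
#' seeded deterministically from a single master seed plus a character key
#' naming the stage (e.g. `"synthetic/waveform"`). This makes any stage
#' regenerable in isolation while the whole pipeline stays reproducible from
#' one integer.
#'
#' The splitting rule is a small multiplicative hash of the key's UTF-8 bytes
#' folded into the master seed, reduced modulo 2^31 - 1 so the result is a
#' valid R integer seed.
#'
#' @param seed Integer master seed.
#' @param key Character label of the consuming stage.
#' @return A positive integer seed.
#' @export
#' @examples
#' split_seed(1L, "synthetic/waveform")
split_seed <- function(seed, key) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(key), length(key) == 1L)
  m <- 2147483647  # 2^31 - 1
  h <- as.numeric(seed) %% m
  for (b in utf8ToInt(key)) {
    h <- (h * 131 + b) %% m
  }
  as.integer(h %% (m - 1) + 1)
}

#' Draw from a normal distribution truncated to an interval
#'
#' Inverse-CDF sampling: deterministic given the RNG state and vectorised in
#' `n`. Used for answer latencies, which are constrained to the latency
#' analysis window (0, 1.5] seconds.
#'
#' @param n Number of draws.
#' @param mean,sd Parameters of the untruncated normal.
#' @param lower,upper Truncation bounds (lower open, upper closed).
#' @return Numeric vector of `n` draws in (`lower`, `upper`].
#' @export
rtruncnorm <- function(n, mean, sd, lower = 0, upper = 1.5) {
  stopifnot(lower < upper, sd >= 0)
  if (sd == 0) {
    if (mean <= lower || mean > upper) {
      stop("degenerate truncated normal: mean outside truncation bounds")
    }
    return(rep(mean, n))
  }
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  u <- stats::runif(n, plo, phi)
  stats::qnorm(u, mean, sd)
}

#' Expected value of a function under a truncated normal
#'
#' Numerical integration oracle used to state the exact generative mean of
#' (transformed) latencies when the generator truncates to the analysis
#' window. `f = identity` gives the truncated-normal mean; `f = sqrt` the
#' mean on the square-root scale used by the latency models.
#'
#' @inheritParams rtruncnorm
#' @param f Function applied inside the expectation.
#' @return Scalar expectation.
#' @export
truncnorm_expectation <- function(f = identity, mean, sd, lower = 0, upper = 1.5) {
  z <- stats::pnorm(upper, mean, sd) - stats::pnorm(lower, mean, sd)
  stats::integrate(function(x) f(x) * stats::dnorm(x, mean, sd) / z,
                   lower, upper, rel.tol = 1e-10)$value
}

# internal: validate a time-sorted event table with onset_s column
assert_sorted_events <- function(events, arg = "events") {
  if (!is.data.frame(events) || !"onset_s" %in% names(events)) {
    stop(sprintf("`%s` must be a data.frame with an `onset_s` column", arg))
  }
  if (is.unsorted(events$onset_s, strictly = FALSE)) {
    stop(sprintf("`%s` must be sorted by onset_s", arg))
  }
  invisible(events)
}
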