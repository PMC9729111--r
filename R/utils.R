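#' Two-sided p-value from a Z score, computed in log space
#'
#' Extreme |z| (up to at least 40) must yield a usable tail probability:
#' the tail is evaluated on the log scale and only exponentiated at the
#' end. Probabilities below the smallest representable double are floored
#' at `.Machine$double.xmin` so a p-value is never exactly zero; callers
#' needing the exact tail should use the `log10_p` attribute or
#' [log10_p_from_z()].
#'
#' @param z numeric vector of Z scores.
#' @return numeric vector of two-sided p-values in (0, 1].
#' @export
#' @examples
#' p_from_z(c(0, 1.96, 40))
p_from_z <- function(z) {
  lp <- log(2) + stats::pnorm(-abs(z), log.p = TRUE)
  p <- exp(pmin(lp, 0))
  p[p == 0] <- .Machine$double.xmin
  p
}

#' Base-10 log of the two-sided p-value from a Z score
#'
#' @param z numeric vector of Z scores.
#' @return numeric vector, `log10` of the two-sided tail probability.
#' @export
log10_p_from_z <- function(z) {
  (log(2) + stats::pnorm(-abs(z), log.p = TRUE)) / log(10)
}

# log(sum(exp(x))) without overflow; -Inf entries are handled
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Deterministic sub-stream seed for an operation name, derived from the
# master seed so module invocation order never changes results. Kept
# below 2^31 (R integers are 32-bit).
substream_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((as.numeric(seed) * 1000003 + h) %% 2147483647L)
}

# Evaluate a thunk under a local RNG state seeded from (seed, name).
with_substream <- function(seed, name, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(substream_seed(seed, name))
  force(expr)
}

stop_input <- function(...) {
  stop(sprintf(...), call. = FALSE)
}
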