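#' Storey q-values and the p-value cut-off for a target FDR
#'
#' Computes q-values with Storey's smoother estimate of the null
#' proportion pi0 over a lambda grid (natural cubic smoothing spline,
#' evaluated at the largest lambda, clamped to (0, 1]). Forcing
#' `pi0 = 1` reproduces Benjamini-Hochberg step-up values exactly.
#' q-values are monotone non-decreasing in p and invariant to input
#' order.
#'
#' @param p p-values in (0, 1].
#' @param target_fdr target false discovery rate for the reported
#'   threshold (default 0.01).
#' @param lambda grid for the pi0 smoother.
#' @param pi0 optional fixed null proportion (e.g. 1 for BH).
#' @return list with `qvalues` (aligned to the input order), `pi0`, and
#'   `p_threshold`, the largest p whose q-value is `<= target_fdr`
#'   (`NA` if none).
#' @export
#' @examples
#' qvalue_fdr(c(0.01, 0.02, 0.03, 0.04), pi0 = 1)$qvalues  # all 0.04
qvalue_fdr <- function(p, target_fdr = 0.01,
                       lambda = seq(0.05, 0.95, by = 0.05), pi0 = NULL) {
  if (length(p) == 0) stop_input("empty p-value vector")
  if (any(p <= 0 | p > 1)) stop_input("p-values must lie in (0, 1]")
  m <- length(p)
  if (is.null(pi0)) {
    pi0_lambda <- vapply(lambda, function(l) mean(p > l) / (1 - l),
                         numeric(1))
    pi0 <- if (m < 100 || all(pi0_lambda == 0)) {
      # too few points for the smoother to be stable; be conservative
      1
    } else {
      fit <- stats::smooth.spline(lambda, pi0_lambda, df = 3)
      stats::predict(fit, x = max(lambda))$y
    }
    pi0 <- min(max(pi0, 1 / m), 1)
  }
  ord <- order(p)
  q_sorted <- pi0 * m * p[ord] / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q_sorted <- pmin(q_sorted, 1)
  q <- numeric(m)
  q[ord] <- q_sorted
  pass <- q <= target_fdr
  list(qvalues = q, pi0 = pi0,
       p_threshold = if (any(pass)) max(p[pass]) else NA_real_)
}
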