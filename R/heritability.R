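# Liability-threshold heritability explained. A biallelic variant with
# per-allele liability effect a and effect-allele frequency p
# contributes 2 p (1 - p) a^2 to the (unit) liability variance. The
# observable per-allele log-odds beta is mapped to a by inverting the
# population logistic slope implied by the threshold model: given
# genotype g ~ HWE, liability l = a (g - 2p) + e with
# e ~ N(0, 1 - 2 p (1 - p) a^2), disease iff l > t = qnorm(1 - K). The
# infinite-sample logistic MLE of the slope of D on g is the unique
# maximizer of the population logistic likelihood over the three
# genotype classes; under outcome-dependent (case-control) sampling the
# logistic slope is unchanged (only the intercept shifts), so the same
# transformation applies to prospective and case-control estimates.

#' Liability-threshold model parameters
#'
#' @param K baseline population risk (default 0.0719).
#' @param h2_twin liability-scale twin heritability (default 0.4).
#' @return list of class `liability_model` with `K`, `h2_twin`,
#'   threshold `t = qnorm(1 - K)` and normal density `z` at `t`.
#' @export
liability_model <- function(K = 0.0719, h2_twin = 0.4) {
  if (K <= 0 || K >= 1) stop_input("K must lie in (0, 1)")
  if (h2_twin <= 0 || h2_twin > 1) stop_input("h2_twin must lie in (0, 1]")
  t <- stats::qnorm(1 - K)
  structure(list(K = K, h2_twin = h2_twin, t = t, z = stats::dnorm(t)),
            class = "liability_model")
}

# P(disease | g copies of the effect allele) under the threshold model.
risk_by_genotype <- function(a, p, model) {
  D <- 2 * p * (1 - p)
  s2 <- 1 - D * a^2
  if (s2 <= 0) stop_input("liability effect too large for frequency")
  g <- 0:2
  stats::pnorm((a * (g - 2 * p) - model$t) / sqrt(s2))
}

#' Population logistic slope implied by a liability effect
#'
#' The infinite-sample per-allele log-odds a logistic regression of
#' disease on genotype would estimate, for a variant with per-allele
#' liability effect `a` and effect allele frequency `p` at population
#' risk `model$K`.
#'
#' @param a per-allele effect on the standard-normal liability.
#' @param p effect allele frequency.
#' @param model a [liability_model()].
#' @return the per-allele log-odds (logistic slope).
#' @export
liability_to_logodds <- function(a, p, model) {
  if (a == 0) return(0)
  w <- c((1 - p)^2, 2 * p * (1 - p), p^2)
  Pg <- risk_by_genotype(a, p, model)
  g <- 0:2
  nll <- function(th) {
    mu <- stats::plogis(th[1] + th[2] * g)
    mu <- pmin(pmax(mu, 1e-15), 1 - 1e-15)  # avoid 0 * -Inf at saturation
    -sum(w * (Pg * log(mu) + (1 - Pg) * log1p(-mu)))
  }
  gr <- function(th) {
    mu <- stats::plogis(th[1] + th[2] * g)
    d <- w * (Pg - mu)
    -c(sum(d), sum(d * g))
  }
  start <- c(stats::qlogis(model$K), 0)
  fit <- stats::optim(start, nll, gr, method = "BFGS",
                      control = list(reltol = 1e-14, maxit = 500))
  fit$par[2]
}

#' Per-allele liability effect implied by an observed log-odds
#'
#' Inverts [liability_to_logodds()] numerically. The logistic slope is
#' invariant to case-control ascertainment, so `case_fraction` (the
#' study's case sampling fraction) does not alter the result; it is
#' accepted for interface completeness.
#'
#' @param beta per-allele log-odds.
#' @param p effect allele frequency.
#' @param model a [liability_model()].
#' @param case_fraction optional study case fraction (ignored; see
#'   Details).
#' @return per-allele liability-scale effect (same sign as `beta`).
#' @export
logodds_to_liability <- function(beta, p, model, case_fraction = NULL) {
  if (beta == 0) return(0)
  # the forward map is odd under joint relabeling (a, p) -> (-a, 1-p),
  # not in a alone: solve negative betas on the relabeled allele
  if (beta < 0) return(-logodds_to_liability(-beta, 1 - p, model))
  D <- 2 * p * (1 - p)
  amax <- 0.999 / sqrt(D)
  f <- function(a) liability_to_logodds(a, p, model) - abs(beta)
  # expand the bracket geometrically; near the domain edge all genotype
  # risks underflow and the forward map degrades, so stop expanding as
  # soon as it loses monotonicity
  a_lo <- 0
  f_lo <- -abs(beta)
  a_hi <- min(0.25 / sqrt(D), amax)
  repeat {
    f_hi <- f(a_hi)
    if (f_hi >= 0) break
    if (f_hi < f_lo || a_hi >= amax) {
      stop_input("log-odds too extreme for this frequency")
    }
    a_lo <- a_hi
    f_lo <- f_hi
    a_hi <- min(a_hi * 1.6, amax)
  }
  a <- stats::uniroot(f, c(a_lo, a_hi), tol = 1e-9)$root
  sign(beta) * a
}

#' Liability-scale variance contributed by one variant
#'
#' `2 p (1 - p) a^2` where `a` is the liability-scale per-allele effect
#' obtained from the observed log-odds via the threshold model at risk
#' `K`. Zero when `beta = 0`; strictly increasing in |beta| and in
#' `2 p (1 - p)`; invariant to allele relabeling (`beta -> -beta`,
#' `p -> 1 - p`).
#'
#' @param beta per-allele log-odds (vectorized).
#' @param eaf effect allele frequency in (0, 1) (vectorized).
#' @param model a [liability_model()].
#' @return liability-scale variance contribution per variant.
#' @export
variant_liability_variance <- function(beta, eaf, model) {
  if (any(eaf <= 0 | eaf >= 1)) stop_input("eaf must lie in (0, 1)")
  vapply(seq_along(beta), function(i) {
    a <- logodds_to_liability(beta[i], eaf[i], model)
    2 * eaf[i] * (1 - eaf[i]) * a^2
  }, numeric(1))
}

#' Percentage of heritability explained by independent variants
#'
#' Sums per-variant liability variances (additive over conditionally
#' independent variants; joint/conditional betas are the preferred
#' input) and expresses the total as a percentage of the assumed twin
#' heritability.
#'
#' @param beta,eaf vectors of per-allele log-odds and frequencies.
#' @param model a [liability_model()].
#' @return percentage (100 x summed variance / `h2_twin`). Values above
#'   100 are returned as computed with a warning (model
#'   misspecification signal).
#' @export
#' @examples
#' m <- liability_model(K = 0.0719, h2_twin = 0.4)
#' percent_heritability_explained(c(0.1, 0.1), c(0.3, 0.3), m)
percent_heritability_explained <- function(beta, eaf, model) {
  if (length(beta) == 0) return(0)
  pct <- 100 * sum(variant_liability_variance(beta, eaf, model)) /
    model$h2_twin
  if (pct > 100) {
    warning("heritability explained exceeds 100%: model misspecification?",
            call. = FALSE)
  }
  pct
}
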