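# Polygenic score computation and stratification. Scoring is a plain
# weighted dosage sum after allele alignment; the survival association
# is thin plumbing over survival::coxph.

#' Score a cohort with a polygenic-score model
#'
#' Raw score per individual is the sum of genotype dosages multiplied by
#' the per-allele weights. Model variants missing from the cohort are
#' mean-imputed at `2 * eaf` when frequencies are supplied (with a
#' message), or dropped with `missing = "drop"`. The standardized score
#' has mean 0, sd 1 in the scored cohort; the percentile rank is
#' relative to the full cohort.
#'
#' @param cohort data.frame with one dosage column (in `[0, 2]`) per
#'   available model variant, as produced by [simulate_cohort()].
#' @param model a [prs_model()].
#' @param missing `"impute"` (default) or `"drop"` policy for model
#'   variants absent from the cohort.
#' @param eaf named vector of effect-allele frequencies used for mean
#'   imputation.
#' @return data.frame `id`, `raw`, `standardized`, `percentile`.
#' @export
#' @examples
#' # dosages (0, 1, 2) with weights (0.1, -0.2, 0.3) -> raw score 0.4
prs_score <- function(cohort, model, missing = c("impute", "drop"),
                      eaf = NULL) {
  missing <- match.arg(missing)
  mv <- model$variants
  present <- mv$rsid %in% names(cohort)
  if (!any(present)) stop_input("no model variants present in cohort")
  raw <- as.matrix(cohort[, mv$rsid[present], drop = FALSE]) %*%
    mv$weight[present]
  raw <- drop(raw)
  if (any(!present)) {
    miss <- mv$rsid[!present]
    if (missing == "impute") {
      if (is.null(eaf) || !all(miss %in% names(eaf))) {
        stop_input("mean imputation requires eaf for missing variants")
      }
      message(sprintf("mean-imputing %d missing variant(s)", length(miss)))
      raw <- raw + sum(2 * eaf[miss] * mv$weight[!present])
    } else {
      message(sprintf("dropping %d missing variant(s)", length(miss)))
    }
  }
  s <- if (length(raw) > 1) stats::sd(raw) else 0
  std <- if (s > 0) (raw - mean(raw)) / s else raw * 0
  data.frame(id = cohort$id, raw = raw, standardized = std,
             percentile = rank(raw, ties.method = "average") / length(raw),
             stringsAsFactors = FALSE)
}

#' Event rates by score decile and extreme-vs-reference ratios
#'
#' Deciles partition the cohort by score (ties broken by stable rank, so
#' the assignment is invariant to monotone transforms of the score).
#' Reports the event rate per decile, the top-versus-bottom decile rate
#' ratio, and each extreme decile versus the middle 80%.
#'
#' @param scores numeric score vector (or the data.frame from
#'   [prs_score()], in which case the standardized score is used).
#' @param events binary event indicator, same length.
#' @return list: `by_decile` (data.frame `decile`, `n`, `events`,
#'   `rate`), `top_vs_bottom`, `top_vs_middle80`, `bottom_vs_middle80`,
#'   `infinite_ratio` flag (zero events in a reference stratum).
#' @export
decile_stratify <- function(scores, events) {
  if (is.data.frame(scores)) scores <- scores$standardized
  n <- length(scores)
  if (n < 10) stop_input("need at least 10 individuals for deciles")
  if (length(events) != n) stop_input("scores and events length mismatch")
  rk <- rank(scores, ties.method = "first")
  decile <- ceiling(rk * 10 / n)
  by_dec <- data.frame(
    decile = 1:10,
    n = as.integer(tabulate(decile, 10)),
    events = as.integer(vapply(1:10, function(d) sum(events[decile == d]),
                               numeric(1)))
  )
  by_dec$rate <- ifelse(by_dec$n > 0, by_dec$events / by_dec$n, NA)
  mid <- decile >= 2 & decile <= 9
  rate_mid <- mean(events[mid])
  ratio <- function(num, den) if (den == 0) Inf else num / den
  list(
    by_decile = by_dec,
    top_vs_bottom = ratio(by_dec$rate[10], by_dec$rate[1]),
    top_vs_middle80 = ratio(by_dec$rate[10], rate_mid),
    bottom_vs_middle80 = ratio(by_dec$rate[1], rate_mid),
    infinite_ratio = by_dec$rate[1] == 0 || rate_mid == 0
  )
}

#' Hazard ratio per standard deviation of the score
#'
#' Fits a Cox proportional-hazards model of time-to-event on the
#' standardized score plus declared covariates and reports the per-SD
#' hazard ratio with its confidence interval. Non-convergence or a
#' degenerate (constant) score is flagged, never silently defaulted.
#'
#' @param cohort data.frame with `time`, `event` and any covariate
#'   columns.
#' @param scores data.frame from [prs_score()] (or numeric vector).
#' @param covariates character vector of covariate column names
#'   (default age, sex and five principal components).
#' @param level confidence level (default 0.95).
#' @return list: `hr`, `ci` (length 2), `log_hr`, `se`, `p`,
#'   `converged`, `fit` (the `coxph` object).
#' @export
score_association <- function(cohort, scores,
                              covariates = c("age", "sex", "pc1", "pc2",
                                             "pc3", "pc4", "pc5"),
                              level = 0.95) {
  s <- if (is.data.frame(scores)) scores$standardized else scores
  if (stats::sd(s) == 0) stop_input("score has no variance")
  covariates <- intersect(covariates, names(cohort))
  dat <- cbind(cohort[, c("time", "event", covariates), drop = FALSE],
               prs = s)
  fml <- stats::as.formula(paste(
    "survival::Surv(time, event) ~ prs",
    if (length(covariates)) paste("+", paste(covariates, collapse = " + "))
    else ""))
  fit <- survival::coxph(fml, data = dat)
  converged <- is.null(fit$info) || !isTRUE(fit$info$convergence > 0)
  b <- stats::coef(fit)[["prs"]]
  se <- sqrt(diag(stats::vcov(fit)))[["prs"]]
  zq <- stats::qnorm(1 - (1 - level) / 2)
  list(hr = exp(b), ci = exp(c(b - zq * se, b + zq * se)),
       log_hr = b, se = se, p = p_from_z(b / se),
       converged = converged, fit = fit)
}
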