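# The eight-predictor consensus causal-gene framework: per-locus
# nomination by unweighted vote, tiering at >=2 (prioritized) and >=3
# (strong) concordant predictors, agreement/concordance summaries, and
# positive-control evaluation. Ties are reported, never silently broken.

#' Nominate the most likely causal gene at one locus
#'
#' The nominee is the candidate with the highest unweighted sum of
#' evidence across the eight predictors. Genes tied at the maximum are
#' all reported with the tie flag set. A locus whose candidates carry no
#' evidence nominates nothing (tier `"none"`).
#'
#' @param slice data.frame of one locus's rows from an evidence matrix
#'   (`LOCUS_ID`, `GENE`, `DISTANCE_BP`, eight binary predictor columns).
#' @return list: `locus_id`, `nominees` (character, possibly several or
#'   empty), `n_concordant`, `tier` (`"none"`, `"prioritized"`,
#'   `"strong"`), `tie` (logical).
#' @export
prioritize_locus <- function(slice) {
  if (nrow(slice) == 0) stop_input("locus has no candidate genes")
  ev <- as.matrix(slice[, PREDICTORS, drop = FALSE])
  if (!all(ev %in% c(0, 1))) stop_input("evidence entries must be binary")
  score <- rowSums(ev)
  top <- max(score)
  if (top == 0) {
    return(list(locus_id = slice$LOCUS_ID[1], nominees = character(0),
                n_concordant = 0L, tier = "none", tie = FALSE))
  }
  nominees <- slice$GENE[score == top]
  tier <- if (top >= 3) "strong" else if (top >= 2) "prioritized" else "none"
  list(locus_id = slice$LOCUS_ID[1], nominees = nominees,
       n_concordant = as.integer(top), tier = tier,
       tie = length(nominees) > 1)
}

#' Prioritize every locus in an evidence matrix
#'
#' @param matrix evidence-matrix data.frame (multiple loci).
#' @return data.frame with one row per locus: `locus_id`, `nominee`
#'   (`NA` for none or tied loci), `nominees` (list column),
#'   `n_concordant`, `tier`, `tie`. Output is invariant to gene row
#'   order and predictor column order.
#' @export
prioritize_all <- function(matrix) {
  res <- lapply(split(matrix, matrix$LOCUS_ID), prioritize_locus)
  out <- data.frame(
    locus_id = vapply(res, `[[`, character(1), "locus_id"),
    nominee = vapply(res, function(r) {
      if (length(r$nominees) == 1) r$nominees else NA_character_
    }, character(1)),
    n_concordant = vapply(res, `[[`, integer(1), "n_concordant"),
    tier = vapply(res, `[[`, character(1), "tier"),
    tie = vapply(res, `[[`, logical(1), "tie"),
    stringsAsFactors = FALSE
  )
  out$nominees <- lapply(res, `[[`, "nominees")
  rownames(out) <- NULL
  out
}

predictor_marks <- function(matrix, predictor, locus, gene) {
  any(matrix$LOCUS_ID == locus & matrix$GENE %in% gene &
        matrix[[predictor]] == 1)
}

predictor_fires <- function(matrix, predictor, locus) {
  any(matrix$LOCUS_ID == locus & matrix[[predictor]] == 1)
}

#' Agreement of one predictor with the consensus nominations
#'
#' Proportion of loci at which the predictor marks the consensus
#' nominee, among loci where the predictor provides evidence for at
#' least one gene. Tied loci are excluded by default (the nominee is
#' ambiguous there); set `include_tied = TRUE` to count a tied locus as
#' agreeing when the predictor marks any tied nominee.
#'
#' @param results output of [prioritize_all()].
#' @param matrix the evidence matrix the results came from.
#' @param predictor predictor column name.
#' @param include_tied include tied loci in the denominator.
#' @return list: `rate` (`NA` when the denominator is zero),
#'   `numerator`, `denominator`.
#' @export
agreement <- function(results, matrix, predictor, include_tied = FALSE) {
  if (!include_tied) results <- results[!results$tie, , drop = FALSE]
  results <- results[results$n_concordant > 0, , drop = FALSE]
  fires <- vapply(results$locus_id, function(l) {
    predictor_fires(matrix, predictor, l)
  }, logical(1))
  den <- sum(fires)
  if (den == 0) return(list(rate = NA_real_, numerator = 0L,
                            denominator = 0L))
  hits <- vapply(which(fires), function(i) {
    predictor_marks(matrix, predictor, results$locus_id[i],
                    results$nominees[[i]])
  }, logical(1))
  list(rate = mean(hits), numerator = sum(hits), denominator = den)
}

#' Concordance of a predictor pair on the consensus nominations
#'
#' Proportion of loci at which both predictors mark the consensus
#' nominee, among loci where both provide evidence for at least one
#' gene. Symmetric in the pair.
#'
#' @inheritParams agreement
#' @param pair character vector of two predictor names.
#' @return list: `rate` (`NA` when the denominator is zero),
#'   `numerator`, `denominator`.
#' @export
concordance <- function(results, matrix, pair, include_tied = FALSE) {
  stopifnot(length(pair) == 2)
  if (!include_tied) results <- results[!results$tie, , drop = FALSE]
  results <- results[results$n_concordant > 0, , drop = FALSE]
  fires <- vapply(results$locus_id, function(l) {
    predictor_fires(matrix, pair[1], l) && predictor_fires(matrix, pair[2], l)
  }, logical(1))
  den <- sum(fires)
  if (den == 0) return(list(rate = NA_real_, numerator = 0L,
                            denominator = 0L))
  hits <- vapply(which(fires), function(i) {
    predictor_marks(matrix, pair[1], results$locus_id[i],
                    results$nominees[[i]]) &&
      predictor_marks(matrix, pair[2], results$locus_id[i],
                      results$nominees[[i]])
  }, logical(1))
  list(rate = mean(hits), numerator = sum(hits), denominator = den)
}

#' Evaluate the framework against positive-control genes
#'
#' For loci with a known causal gene: the fraction correctly nominated
#' (a tied locus counts as correct, with a flag, when the truth gene is
#' among the tied set), per-predictor accuracy (predictor marks the
#' truth gene) under both denominator conventions (all valid control
#' loci, and only loci where the predictor fires), and the median
#' number of concordant predictors among correctly prioritized loci.
#' Control loci whose truth gene is absent from the candidate list are
#' excluded with a warning.
#'
#' @param results output of [prioritize_all()].
#' @param matrix the evidence matrix.
#' @param truth data.frame with `locus_id`, `gene`.
#' @return list: `n_controls`, `n_correct`, `fraction_correct`,
#'   `n_correct_by_tie`, `median_concordant_correct`,
#'   `predictor_accuracy` (data.frame: predictor, accuracy_fired,
#'   n_fired, accuracy_all, n_all), `invalid_loci`.
#' @export
evaluate_positive_controls <- function(results, matrix, truth) {
  valid <- logical(nrow(truth))
  for (i in seq_len(nrow(truth))) {
    valid[i] <- truth$gene[i] %in%
      matrix$GENE[matrix$LOCUS_ID == truth$locus_id[i]]
  }
  if (any(!valid)) {
    warning(sprintf("%d control locus/loci excluded: truth gene not a candidate",
                    sum(!valid)), call. = FALSE)
  }
  truth_v <- truth[valid, , drop = FALSE]
  ri <- match(truth_v$locus_id, results$locus_id)
  correct <- logical(nrow(truth_v))
  by_tie <- logical(nrow(truth_v))
  for (i in seq_len(nrow(truth_v))) {
    noms <- results$nominees[[ri[i]]]
    if (truth_v$gene[i] %in% noms) {
      correct[i] <- TRUE
      by_tie[i] <- results$tie[ri[i]]
    }
  }
  acc <- do.call(rbind, lapply(PREDICTORS, function(p) {
    fired <- vapply(truth_v$locus_id, function(l) {
      predictor_fires(matrix, p, l)
    }, logical(1))
    marks <- vapply(seq_len(nrow(truth_v)), function(i) {
      predictor_marks(matrix, p, truth_v$locus_id[i], truth_v$gene[i])
    }, logical(1))
    data.frame(predictor = p,
               accuracy_fired = if (any(fired)) mean(marks[fired]) else NA,
               n_fired = sum(fired),
               accuracy_all = mean(marks),
               n_all = nrow(truth_v),
               stringsAsFactors = FALSE)
  }))
  list(
    n_controls = nrow(truth_v),
    n_correct = sum(correct),
    fraction_correct = mean(correct),
    n_correct_by_tie = sum(by_tie),
    median_concordant_correct =
      stats::median(results$n_concordant[ri][correct]),
    predictor_accuracy = acc,
    invalid_loci = truth$locus_id[!valid]
  )
}

#' Classify a variant's risk-factor consistency from trait associations
#'
#' A variant (aligned to its disease risk-increasing allele) is
#' `"risk-factor-consistent"` when at least one of the four conventional
#' risk-factor groups (blood lipids, blood pressure, hyperglycemia,
#' adiposity) shows a significant positive association of the risk
#' allele; `"non-risk-factor"` otherwise; `"unassessed"` with no trait
#' data.
#'
#' @param traits data.frame with columns `group` (one of the four group
#'   labels), `direction` (+1/-1, risk-allele aligned) and `significant`
#'   (logical).
#' @return one of `"risk-factor-consistent"`, `"non-risk-factor"`,
#'   `"unassessed"`.
#' @export
classify_risk_factor_consistency <- function(traits) {
  groups <- c("lipids", "blood_pressure", "hyperglycemia", "adiposity")
  if (is.null(traits) || nrow(traits) == 0) return("unassessed")
  if (!all(traits$group %in% groups)) {
    stop_input("trait groups must be one of: %s",
               paste(groups, collapse = ", "))
  }
  hit <- traits$significant & traits$direction > 0
  if (any(hit)) "risk-factor-consistent" else "non-risk-factor"
}
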