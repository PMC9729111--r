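# Approximate conditional/joint analysis from summary statistics and an
# LD reference. The joint estimates solve LD-weighted normal equations:
# with D_j = 2 p_j (1 - p_j) (reference-panel frequencies by default),
# B = sqrt(D) R sqrt(D) plays the role of X'X / N and D * b_marginal the
# role of X'y / N, so b_joint = B^{-1} D b_marginal. The phenotypic
# variance is the median per-variant implied variance
# D_j (N se_j^2 + b_j^2), robust to outlier standard errors.

joint_sigma2 <- function(meta, n_eff) {
  D <- 2 * meta$EAF * (1 - meta$EAF)
  stats::median(D * (n_eff * meta$SE^2 + meta$BETA^2))
}

#' Joint effect estimates for a subset of variants
#'
#' @param meta meta-analysis data.frame (`RSID`, `EAF`, `BETA`, `SE`,
#'   `N_CASES`, `N_CONTROLS`).
#' @param panel an [ld_panel()] covering the subset.
#' @param subset character vector of RSIDs to fit jointly.
#' @param collinearity_r2 pairs of subset variants with squared
#'   correlation above this raise an error naming the pair.
#' @param freq_source `"panel"` (default) or `"meta"`: which allele
#'   frequencies drive the diagonal scaling.
#' @param sigma2,n_eff optional overrides of the phenotypic variance and
#'   effective sample size (both computed from `meta` by default).
#' @return data.frame with `RSID`, `beta_joint`, `se_joint`, `z_joint`,
#'   `p_joint`.
#' @export
joint_effects <- function(meta, panel, subset, collinearity_r2 = 0.9,
                          freq_source = c("panel", "meta"),
                          sigma2 = NULL, n_eff = NULL) {
  freq_source <- match.arg(freq_source)
  mi <- match(subset, meta$RSID)
  pi_ <- match(subset, panel$variants$rsid)
  if (anyNA(mi)) stop_input("subset variants missing from meta table")
  if (anyNA(pi_)) stop_input("subset variants missing from LD panel")
  # meta-table alleles may be stored on the opposite allele to the panel
  same <- meta$EA[mi] == panel$variants$ea[pi_]
  swap <- meta$EA[mi] == panel$variants$nea[pi_]
  if (any(!same & !swap)) {
    stop_input("alleles incompatible with panel for %s",
               subset[which(!same & !swap)[1]])
  }
  sgn <- ifelse(swap, -1, 1)
  # work in panel allele orientation, flip results back at the end
  R <- panel$R[pi_, pi_, drop = FALSE]
  k <- length(subset)
  if (k > 1) {
    r2 <- R^2; diag(r2) <- 0
    worst <- which(r2 == max(r2), arr.ind = TRUE)[1, ]
    if (max(r2) > collinearity_r2) {
      stop_input("collinear pair in subset: %s and %s (r2 = %.3f)",
                 subset[worst[1]], subset[worst[2]], max(r2))
    }
  }
  if (is.null(n_eff)) {
    n_eff <- stats::median(effective_n(meta$N_CASES, meta$N_CONTROLS))
  }
  if (is.null(sigma2)) sigma2 <- joint_sigma2(meta, n_eff)
  p <- if (freq_source == "panel") panel$variants$eaf[pi_] else meta$EAF[mi]
  D <- 2 * p * (1 - p)
  beta_marg <- meta$BETA[mi] * sgn
  B <- sqrt(D) * t(sqrt(D) * t(R))  # sqrt(D_i) R_ij sqrt(D_j)
  v <- D * beta_marg
  Binv <- tryCatch(solve(B), error = function(e) {
    stop_input("singular LD submatrix for subset (near-collinear variants)")
  })
  b_joint <- drop(Binv %*% v)
  se_joint <- sqrt(sigma2 * diag(Binv) / n_eff)
  z <- b_joint / se_joint
  data.frame(RSID = subset, beta_joint = b_joint * sgn,
             se_joint = se_joint, z_joint = z * sgn,
             p_joint = p_from_z(z), stringsAsFactors = FALSE)
}

#' Stepwise approximate conditional selection from summary statistics
#'
#' Greedy forward selection seeded by the smallest-p variant: at each
#' step the candidate whose joint p-value (in a model with the current
#' selection) is smallest enters if it passes `p_threshold`; after each
#' entry a backward check drops selected variants whose joint p-value
#' has risen above the threshold. Candidates with squared correlation
#' above `collinearity_r2` to any selected variant are excluded from
#' consideration at that step. Deterministic given inputs.
#'
#' @param meta meta-analysis data.frame (typically one chromosome; the
#'   block-diagonal LD of the panel makes chromosome loops equivalent).
#' @param panel an [ld_panel()].
#' @param p_threshold joint significance threshold (default 5e-8;
#'   5e-8 and 2.52e-5 are the conventional genome-wide and 1%-FDR
#'   choices).
#' @param collinearity_r2 candidate exclusion cutoff (default 0.9).
#' @return list of class `joint_model`: `selected` (data.frame as from
#'   [joint_effects()], possibly empty), `p_threshold`, `sigma2`,
#'   `n_eff`.
#' @export
stepwise_select <- function(meta, panel, p_threshold = 5e-8,
                            collinearity_r2 = 0.9) {
  keep <- meta$RSID %in% panel$variants$rsid
  meta <- meta[keep, , drop = FALSE]
  n_eff <- stats::median(effective_n(meta$N_CASES, meta$N_CONTROLS))
  sigma2 <- joint_sigma2(meta, n_eff)
  empty <- function() {
    structure(list(selected = data.frame(RSID = character(0),
                                         beta_joint = numeric(0),
                                         se_joint = numeric(0),
                                         z_joint = numeric(0),
                                         p_joint = numeric(0)),
                   p_threshold = p_threshold, sigma2 = sigma2,
                   n_eff = n_eff), class = "joint_model")
  }
  if (nrow(meta) == 0 || min(meta$P) > p_threshold) return(empty())
  fit <- function(subset) {
    joint_effects(meta, panel, subset, collinearity_r2 = 1,
                  sigma2 = sigma2, n_eff = n_eff)
  }
  ord <- order(meta$P, meta$POS)
  selected <- meta$RSID[ord[1]]
  repeat {
    # backward: drop worst violator until all selected pass
    repeat {
      jf <- fit(selected)
      if (length(selected) == 1 || all(jf$p_joint <= p_threshold)) break
      selected <- selected[-which.max(jf$p_joint)]
    }
    cand <- setdiff(meta$RSID, selected)
    if (length(cand) == 0) break
    pidx <- match(selected, panel$variants$rsid)
    cidx <- match(cand, panel$variants$rsid)
    maxr2 <- apply(panel$R[cidx, pidx, drop = FALSE]^2, 1, max)
    cand <- cand[maxr2 <= collinearity_r2]
    # cheap screen: a candidate's joint p can't beat its conditional
    # evidence by much; only try candidates marginally significant or
    # correlated with the selection
    if (length(cand) == 0) break
    best <- NULL
    best_p <- Inf
    for (cc in cand) {
      jf <- tryCatch(fit(c(selected, cc)), error = function(e) NULL)
      if (is.null(jf)) next
      pc <- jf$p_joint[jf$RSID == cc]
      if (pc < best_p) {
        best_p <- pc
        best <- cc
      }
    }
    if (is.null(best) || best_p > p_threshold) break
    selected <- c(selected, best)
  }
  jf <- fit(selected)
  jf <- jf[jf$p_joint <= p_threshold | length(selected) == 1, ,
           drop = FALSE]
  structure(list(selected = jf, p_threshold = p_threshold,
                 sigma2 = sigma2, n_eff = n_eff),
            class = "joint_model")
}

#' @export
print.joint_model <- function(x, ...) {
  cat(sprintf("<joint_model> %d selected signal(s) at p <= %g\n",
              nrow(x$selected), x$p_threshold))
  invisible(x)
}
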