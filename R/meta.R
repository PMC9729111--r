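COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

is_palindromic <- function(ea, nea) {
  paste0(ea, nea) %in% c("AT", "TA", "CG", "GC")
}

#' Align one variant association to another's effect allele
#'
#' Harmonizes record `b` to the effect allele of record `a`: when the
#' allele pair is swapped, `b`'s beta is negated and its frequency
#' complemented. Strand-complement matches are accepted when
#' `allow_strand_flip` is TRUE. Palindromic (A/T, C/G) variants are
#' ambiguous: under the default policy they are dropped with a warning
#' when the minor allele frequency exceeds `palindrome_maf`, otherwise
#' they are aligned by frequency (the orientation making the two
#' frequencies fall on the same side of 0.5 is chosen).
#'
#' @param a,b lists or one-row data.frames with fields `ea`, `nea`,
#'   `beta`, `eaf` (case-insensitive; `EA`/`NEA`/`BETA`/`EAF` also work).
#' @param palindrome_policy `"frequency"` (default, drop near-0.5
#'   palindromes) or `"keep"` (treat palindromes like any other variant,
#'   assuming same strand).
#' @param palindrome_maf MAF above which palindromic variants are dropped
#'   under the default policy.
#' @param allow_strand_flip accept complement-strand allele matches.
#' @return list with `a`, `b` (aligned), `flipped` (logical) and
#'   `dropped` (logical; TRUE for excluded palindromes).
#' @export
#' @examples
#' a <- list(ea = "A", nea = "G", beta = 0.1, eaf = 0.3)
#' b <- list(ea = "G", nea = "A", beta = 0.05, eaf = 0.7)
#' align_alleles(a, b)$b$beta  # -0.05
align_alleles <- function(a, b,
                          palindrome_policy = c("frequency", "keep"),
                          palindrome_maf = 0.4,
                          allow_strand_flip = TRUE) {
  palindrome_policy <- match.arg(palindrome_policy)
  norm <- function(x) {
    x <- as.list(x)
    names(x) <- tolower(names(x))
    x
  }
  a <- norm(a); b <- norm(b)
  ea_a <- toupper(a$ea); nea_a <- toupper(a$nea)
  ea_b <- toupper(b$ea); nea_b <- toupper(b$nea)
  if (ea_a == nea_a || ea_b == nea_b) stop_input("alleles must differ")

  pal <- is_palindromic(ea_a, nea_a)
  if (pal && palindrome_policy == "frequency") {
    maf <- min(b$eaf, 1 - b$eaf)
    if (maf > palindrome_maf) {
      warning(sprintf(
        "palindromic variant with MAF %.3f > %.2f dropped", maf,
        palindrome_maf), call. = FALSE)
      return(list(a = a, b = b, flipped = NA, dropped = TRUE))
    }
    # align by frequency: both minor-allele frequencies on the same side
    same_side <- (a$eaf < 0.5) == (b$eaf < 0.5)
    if (!same_side) {
      b$beta <- -b$beta
      b$eaf <- 1 - b$eaf
      b$ea <- ea_a; b$nea <- nea_a
      return(list(a = a, b = b, flipped = TRUE, dropped = FALSE))
    }
    b$ea <- ea_a; b$nea <- nea_a
    return(list(a = a, b = b, flipped = FALSE, dropped = FALSE))
  }

  match_same <- ea_b == ea_a && nea_b == nea_a
  match_swap <- ea_b == nea_a && nea_b == ea_a
  if (!match_same && !match_swap && allow_strand_flip &&
      all(c(ea_b, nea_b) %in% names(COMPLEMENT))) {
    cea <- COMPLEMENT[[ea_b]]; cnea <- COMPLEMENT[[nea_b]]
    if (cea == ea_a && cnea == nea_a) {
      match_same <- TRUE
    } else if (cea == nea_a && cnea == ea_a) {
      match_swap <- TRUE
    }
  }
  if (!match_same && !match_swap) {
    stop_input("incompatible allele sets: %s/%s vs %s/%s",
               ea_a, nea_a, ea_b, nea_b)
  }
  if (match_swap) {
    b$beta <- -b$beta
    b$eaf <- 1 - b$eaf
  }
  b$ea <- ea_a; b$nea <- nea_a
  list(a = a, b = b, flipped = match_swap, dropped = FALSE)
}

#' Fixed-effect inverse-variance weighted meta-analysis of one variant
#'
#' Pools aligned per-study effect estimates with weights `1/se^2`. The
#' two-sided p-value is computed from the pooled Z score in log space so
#' it degrades gracefully for |z| of 40 and beyond.
#'
#' @param betas numeric vector of per-study effects (aligned to one
#'   effect allele).
#' @param ses positive per-study standard errors.
#' @return list with `beta`, `se`, `z`, `p`, `log10_p`, `n_studies`.
#' @export
#' @examples
#' ivw_meta(c(0.2, 0), c(0.1, 0.2))  # beta 0.16, se ~0.0894
ivw_meta <- function(betas, ses) {
  if (length(betas) < 1 || length(betas) != length(ses)) {
    stop_input("need >= 1 study with matching betas and ses")
  }
  if (any(ses <= 0)) stop_input("all standard errors must be positive")
  w <- 1 / ses^2
  beta <- sum(w * betas) / sum(w)
  se <- sqrt(1 / sum(w))
  z <- beta / se
  list(beta = beta, se = se, z = z, p = p_from_z(z),
       log10_p = log10_p_from_z(z), n_studies = length(betas))
}

#' Meta-analyze a list of per-study summary-statistic tables
#'
#' Studies are joined on `RSID`; each study's rows are aligned to the
#' allele orientation of the first table in which a variant appears
#' (swapped allele pairs have beta negated and frequency complemented;
#' incompatible allele sets raise an error). Pooled effects are
#' fixed-effect inverse-variance weighted; `EAF` is the
#' precision-weighted mean of aligned frequencies.
#'
#' @param studies named list of per-study data.frames with columns
#'   `CHR, POS, RSID, EA, NEA, EAF, BETA, SE, P, N_CASES, N_CONTROLS`.
#' @return data.frame with one row per variant: `CHR, POS, RSID, EA, NEA,
#'   EAF, BETA, SE, Z, P, LOG10_P, N_STUDIES, N_CASES, N_CONTROLS`.
#' @export
meta_analyze <- function(studies) {
  if (length(studies) < 1) stop_input("need at least one study table")
  ref <- NULL
  acc <- new.env(parent = emptyenv())
  for (s in seq_along(studies)) {
    tab <- studies[[s]]
    if (any(tab$SE <= 0)) stop_input("non-positive SE in study %d", s)
    if (is.null(ref)) {
      ref <- tab[, c("CHR", "POS", "RSID", "EA", "NEA")]
    } else {
      new <- !(tab$RSID %in% ref$RSID)
      if (any(new)) {
        ref <- rbind(ref, tab[new, c("CHR", "POS", "RSID", "EA", "NEA")])
      }
    }
  }
  m <- nrow(ref)
  idx_of <- stats::setNames(seq_len(m), ref$RSID)
  sw <- sb <- sf <- nst <- nca <- nco <- numeric(m)
  for (s in seq_along(studies)) {
    tab <- studies[[s]]
    i <- idx_of[tab$RSID]
    same <- tab$EA == ref$EA[i] & tab$NEA == ref$NEA[i]
    swap <- tab$EA == ref$NEA[i] & tab$NEA == ref$EA[i]
    if (any(!same & !swap)) {
      stop_input("incompatible alleles for %s in study %d",
                 tab$RSID[which(!same & !swap)[1]], s)
    }
    beta <- ifelse(swap, -tab$BETA, tab$BETA)
    eaf <- ifelse(swap, 1 - tab$EAF, tab$EAF)
    w <- 1 / tab$SE^2
    sw[i] <- sw[i] + w
    sb[i] <- sb[i] + w * beta
    sf[i] <- sf[i] + w * eaf
    nst[i] <- nst[i] + 1
    nca[i] <- nca[i] + tab$N_CASES
    nco[i] <- nco[i] + tab$N_CONTROLS
  }
  beta <- sb / sw
  se <- sqrt(1 / sw)
  z <- beta / se
  out <- data.frame(
    CHR = ref$CHR, POS = ref$POS, RSID = ref$RSID,
    EA = ref$EA, NEA = ref$NEA,
    EAF = sf / sw, BETA = beta, SE = se, Z = z,
    P = p_from_z(z), LOG10_P = log10_p_from_z(z),
    N_STUDIES = as.integer(nst), N_CASES = nca, N_CONTROLS = nco,
    stringsAsFactors = FALSE
  )
  out[order(out$CHR, out$POS), , drop = FALSE]
}

#' Filter meta-analysis results on contributing studies and case counts
#'
#' Retains variants present in at least `min_studies` studies and with at
#' least `min_cases` cases in total across contributing studies.
#'
#' @param meta data.frame from [meta_analyze()].
#' @param min_studies minimum number of contributing studies (default 2).
#' @param min_cases minimum total case count (default 30000).
#' @return the filtered data.frame (possibly empty).
#' @export
filter_variants <- function(meta, min_studies = 2, min_cases = 30000) {
  meta[meta$N_STUDIES >= min_studies & meta$N_CASES >= min_cases, ,
       drop = FALSE]
}
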