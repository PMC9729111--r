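#' Clump significant variants into loci by physical distance
#'
#' Single-linkage (transitive) clumping: any two significant variants on
#' the same chromosome within `window_bp` of each other share a locus, so
#' a chain 1.0 / 1.4 / 1.8 Mb collapses to one locus at a 500 kb window.
#' The sentinel is the minimum-p member; position breaks p-value ties.
#' Significance thresholding is the caller's job (apply it upstream).
#'
#' @param variants data.frame with `CHR`, `POS`, `RSID`, `P` (already
#'   restricted to significant variants).
#' @param window_bp clumping window (default 500000).
#' @return list with `loci` (data.frame: `locus_id`, `chrom`, `start`,
#'   `end`, `n_variants`, `sentinel_rsid`, `sentinel_pos`, `sentinel_p`)
#'   and `members` (named list of member RSID vectors). Loci partition
#'   the input variant set.
#' @export
clump_loci <- function(variants, window_bp = 500000) {
  if (nrow(variants) == 0) {
    return(list(loci = data.frame(), members = list()))
  }
  v <- variants[order(variants$CHR, variants$POS), , drop = FALSE]
  new_locus <- c(TRUE, diff(v$POS) > window_bp | diff(as.integer(
    factor(v$CHR))) != 0)
  lid <- cumsum(new_locus)
  loci <- do.call(rbind, lapply(split(seq_len(nrow(v)), lid), function(i) {
    vi <- v[i, , drop = FALSE]
    sent <- vi[order(vi$P, vi$POS), ][1, ]
    data.frame(chrom = vi$CHR[1], start = min(vi$POS), end = max(vi$POS),
               n_variants = nrow(vi), sentinel_rsid = sent$RSID,
               sentinel_pos = sent$POS, sentinel_p = sent$P,
               stringsAsFactors = FALSE)
  }))
  loci <- cbind(locus_id = sprintf("locus%03d", seq_len(nrow(loci))),
                loci, stringsAsFactors = FALSE)
  rownames(loci) <- NULL
  members <- split(v$RSID, lid)
  names(members) <- loci$locus_id
  list(loci = loci, members = members)
}

#' Extract r-squared between two variants from an LD panel
#'
#' @param panel an [ld_panel()].
#' @param rsid1,rsid2 variant identifiers.
#' @return squared correlation, or `NA` if either variant is absent.
#' @export
panel_r2 <- function(panel, rsid1, rsid2) {
  i <- match(rsid1, panel$variants$rsid)
  j <- match(rsid2, panel$variants$rsid)
  if (is.na(i) || is.na(j)) return(NA_real_)
  panel$R[i, j]^2
}

#' Annotate loci as known or new against previously reported variants
#'
#' A locus is `"known"` when a previously reported variant falls inside
#' the locus region, or when the sentinel has r-squared >= `r2_threshold`
#' with a reported variant (the boundary value counts as known, since
#' "new" is defined by strictly smaller r-squared). A locus whose
#' sentinel is absent from the LD panel and which is not settled by the
#' region test is flagged `"unassessed"`, never silently `"new"`.
#'
#' @param loci data.frame from [clump_loci()]`$loci`.
#' @param known data.frame of reported variants with `RSID`, `CHR`, `POS`.
#' @param panel an [ld_panel()] covering sentinels and reported variants.
#' @param r2_threshold novelty boundary (default 0.2).
#' @param window_bp how far from the sentinel reported variants are
#'   considered for the r-squared test (default 500000).
#' @return `loci` with an added `novelty` column
#'   (`"known"`/`"new"`/`"unassessed"`).
#' @export
annotate_novelty <- function(loci, known, panel, r2_threshold = 0.2,
                             window_bp = 500000) {
  novelty <- character(nrow(loci))
  for (i in seq_len(nrow(loci))) {
    in_region <- known$CHR == loci$chrom[i] &
      known$POS >= loci$start[i] & known$POS <= loci$end[i]
    if (any(in_region)) {
      novelty[i] <- "known"
      next
    }
    if (!(loci$sentinel_rsid[i] %in% panel$variants$rsid)) {
      novelty[i] <- "unassessed"
      next
    }
    nearby <- known$CHR == loci$chrom[i] &
      abs(known$POS - loci$sentinel_pos[i]) <= window_bp
    r2 <- vapply(known$RSID[nearby], function(k) {
      panel_r2(panel, loci$sentinel_rsid[i], k)
    }, numeric(1))
    r2 <- r2[!is.na(r2)]
    # boundary counts as known; small tolerance guards squaring error
    novelty[i] <- if (length(r2) > 0 && max(r2) >= r2_threshold - 1e-12) {
      "known"
    } else {
      "new"
    }
  }
  loci$novelty <- novelty
  loci
}
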