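# Plain-text interchange: tab-delimited tables throughout (1-based
# positions in summary TSVs; BED handled in synthetic_gwas.R with the
# 0-based half-open convention), truth as JSON.

#' Read / write a tab-delimited table
#'
#' @param path file path.
#' @param x data.frame to write.
#' @return `read_tsv` returns a data.frame.
#' @export
read_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' @rdname read_tsv
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an LD panel as a variant-index TSV plus a matrix TSV
#'
#' @param panel an [ld_panel()].
#' @param prefix output path prefix; writes `<prefix>.variants.tsv` and
#'   `<prefix>.ld.tsv`.
#' @return invisibly, the two paths.
#' @export
write_ld_panel <- function(panel, prefix) {
  vpath <- paste0(prefix, ".variants.tsv")
  mpath <- paste0(prefix, ".ld.tsv")
  write_tsv(panel$variants, vpath)
  utils::write.table(panel$R, mpath, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(c(vpath, mpath))
}

#' Read an LD panel written by [write_ld_panel()]
#'
#' @param prefix the path prefix used when writing.
#' @return an [ld_panel()].
#' @export
read_ld_panel <- function(prefix) {
  variants <- read_tsv(paste0(prefix, ".variants.tsv"))
  R <- as.matrix(utils::read.table(paste0(prefix, ".ld.tsv"), sep = "\t"))
  dimnames(R) <- NULL
  ld_panel(variants, R)
}

#' Write the truth record of a synthetic world as JSON
#'
#' @param truth a `truth_record`.
#' @param path output path.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
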