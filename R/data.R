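#' Bundled reference tables from the HIST/NC rat brain study
#'
#' Small plain-text tables shipped with the package, taken from the
#' published two-library rat brain swimming-exercise dataset that this
#' pipeline's design follows: per-library sequencing totals
#' (`"totals"`), the twenty most abundant known miRNAs with raw read
#' counts (`"top_known"`), and the 34 significantly differentially
#' expressed miRNAs with normalised expression (TPM), log2 fold change,
#' p-value, significance mark and direction (`"diffexpr"`).  They serve
#' as worked-example inputs and as regression fixtures for the
#' normalisation and classification arithmetic.
#'
#' @param which One of `"totals"`, `"top_known"`, `"diffexpr"`.
#' @return A data.frame.
#' @export
#' @examples
#' head(referenceTable("diffexpr"))
referenceTable <- function(which = c("totals", "top_known", "diffexpr")) {
  which <- match.arg(which)
  f <- switch(which, totals = "hist_nc_library_totals.tsv",
              top_known = "hist_nc_top_known.tsv",
              diffexpr = "hist_nc_diffexpr.tsv")
  path <- system.file("extdata", f, package = "mirswim",
                      mustWork = TRUE)
  read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}
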