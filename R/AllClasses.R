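.FILTER_REASONS <- c("low_quality", "adapter5_contaminant", "no_3adapter",
                     "no_insert", "polyA", "too_short")

#' FilterReport: read-filtering accounting for one library
#'
#' Records, for a single small-RNA library, how many raw reads entered the
#' cleaning cascade, how many were dropped for each reason (in cascade
#' order: low quality, 5' adapter contamination, missing 3' adapter, no
#' insert, polyA insert, insert length out of the 18-30 nt range), and how
#' many clean reads and unique tags survived.  Validity enforces the
#' conservation identity `rawReads == cleanReads + sum(dropped)`.
#'
#' @slot library Library label.
#' @slot rawReads Number of raw reads.
#' @slot dropped Named integer vector of dropped-read counts; names are the
#'   six fixed filter reasons.
#' @slot cleanReads Number of surviving clean reads.
#' @slot uniqueTags Number of distinct clean tag sequences.
#' @export
setClass("FilterReport",
  representation(library = "character", rawReads = "numeric",
                 dropped = "numeric", cleanReads = "numeric",
                 uniqueTags = "numeric"))

setValidity("FilterReport", function(object) {
  msg <- NULL
  if (!identical(names(object@dropped), .FILTER_REASONS))
    msg <- c(msg, paste("dropped must be named exactly:",
                        paste(.FILTER_REASONS, collapse = ", ")))
  if (length(msg) == 0 &&
      object@rawReads != object@cleanReads + sum(object@dropped))
    msg <- c(msg, "rawReads must equal cleanReads + sum(dropped)")
  if (any(c(object@rawReads, object@dropped, object@cleanReads,
            object@uniqueTags) < 0))
    msg <- c(msg, "counts must be non-negative")
  if (is.null(msg)) TRUE else msg
})

FilterReport <- function(library, rawReads, dropped, cleanReads,
                         uniqueTags) {
  new("FilterReport", library = library, rawReads = rawReads,
      dropped = dropped[.FILTER_REASONS], cleanReads = cleanReads,
      uniqueTags = uniqueTags)
}

setMethod("show", "FilterReport", function(object) {
  cat("FilterReport for library", object@library, "\n")
  cat("  raw reads:   ", object@rawReads, "\n")
  for (r in .FILTER_REASONS)
    cat(sprintf("  - %-22s %d\n", r, object@dropped[[r]]))
  cat("  clean reads: ", object@cleanReads, "\n")
  cat("  unique tags: ", object@uniqueTags, "\n")
})

#' TagSet: unique clean small-RNA tags with per-library counts
#'
#' The central container of the pipeline: one row per distinct clean tag
#' sequence (18-30 nt, DNA alphabet), one column per library, with a
#' `counts` assay of read counts.  Extends
#' [SummarizedExperiment::SummarizedExperiment]; the tag sequence lives in
#' `rowData(x)$seq` and per-library [FilterReport-class] objects, when
#' available, in `metadata(x)$reports`.
#'
#' @export
setClass("TagSet", contains = "SummarizedExperiment")

setValidity("TagSet", function(object) {
  msg <- NULL
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'counts' is required")
  if (!"seq" %in% colnames(SummarizedExperiment::rowData(object)))
    msg <- c(msg, "rowData column 'seq' is required")
  else {
    sq <- SummarizedExperiment::rowData(object)$seq
    w <- nchar(sq)
    if (length(sq) && (any(w < 18) || any(w > 30)))
      msg <- c(msg, "tag lengths must be within 18-30 nt")
    if (length(sq) && any(grepl("[^ACGT]", sq)))
      msg <- c(msg, "tag sequences must be over {A,C,G,T}")
    if (anyDuplicated(sq))
      msg <- c(msg, "tag sequences must be unique")
  }
  if ("counts" %in% SummarizedExperiment::assayNames(object)) {
    cts <- SummarizedExperiment::assay(object, "counts")
    if (any(cts < 0)) msg <- c(msg, "counts must be non-negative")
    if (nrow(cts) && any(rowSums(cts) < 1))
      msg <- c(msg, "every tag needs total count >= 1")
  }
  if (is.null(msg)) TRUE else msg
})

#' Construct a TagSet
#'
#' @param seqs Character vector (or DNAStringSet) of distinct 18-30 nt tag
#'   sequences; `U` is normalised to `T`.
#' @param counts Integer matrix of read counts, rows parallel to `seqs`,
#'   one column per library (column names are library labels).
#' @param reports Optional named list of [FilterReport-class] objects.
#' @return A [TagSet-class].
#' @export
#' @examples
#' ts <- TagSet(c(paste(rep("ACGT", 5), collapse = ""), strrep("AC", 10)),
#'              cbind(HIST = c(3L, 1L), NC = c(0L, 2L)))
#' tagCounts(ts)
TagSet <- function(seqs, counts, reports = list()) {
  seqs <- .toDNA(seqs)
  counts <- as.matrix(counts)
  storage.mode(counts) <- "integer"
  rownames(counts) <- seqs
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts),
    rowData = S4Vectors::DataFrame(seq = seqs))
  out <- new("TagSet", se)
  S4Vectors::metadata(out)$reports <- reports
  validObject(out)
  out
}

setMethod("show", "TagSet", function(object) {
  cat("TagSet with", nrow(object), "unique tags over",
      ncol(object), "libraries:",
      paste(colnames(object), collapse = ", "), "\n")
  tot <- colSums(SummarizedExperiment::assay(object, "counts"))
  cat("  clean-read totals:",
      paste(sprintf("%s=%d", names(tot), tot), collapse = ", "), "\n")
})
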