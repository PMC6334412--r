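#' @rdname TagSet-class
#' @param x A `TagSet`.
#' @export
setGeneric("tagSeq", function(x) standardGeneric("tagSeq"))

#' @rdname TagSet-class
#' @export
setGeneric("tagCounts", function(x) standardGeneric("tagCounts"))

#' @rdname TagSet-class
#' @export
setGeneric("libraryTotals", function(x) standardGeneric("libraryTotals"))

#' @rdname TagSet-class
#' @export
setGeneric("filterReports", function(x) standardGeneric("filterReports"))

#' Tag sequences of a TagSet
#' @rdname TagSet-class
#' @export
setMethod("tagSeq", "TagSet", function(x)
  as.character(SummarizedExperiment::rowData(x)$seq))

#' Count matrix (tags x libraries)
#' @rdname TagSet-class
#' @export
setMethod("tagCounts", "TagSet", function(x)
  SummarizedExperiment::assay(x, "counts"))

#' Per-library clean-read totals (column sums of the count matrix)
#' @rdname TagSet-class
#' @export
setMethod("libraryTotals", "TagSet", function(x) colSums(tagCounts(x)))

#' Per-library filter reports, when the TagSet came from filterAndTrim()
#' @rdname TagSet-class
#' @export
setMethod("filterReports", "TagSet", function(x)
  S4Vectors::metadata(x)$reports)
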