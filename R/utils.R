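# shared internal helpers

.msg <- function(...) {
  if (isTRUE(getOption("mirswim.verbose", TRUE))) message(...)
}

#' Format a locus as a 1-based inclusive coordinate string
#'
#' User-facing reports express loci as `chrom:start:end:strand` with
#' 1-based inclusive coordinates (e.g. `"19:37422715:37422794:+"`).
#'
#' @param gr A [GenomicRanges::GRanges] object.
#' @return Character vector, one locus string per range.
#' @export
#' @examples
#' gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(10, 30), "+")
#' locusString(gr)
locusString <- function(gr) {
  paste(as.character(GenomicRanges::seqnames(gr)),
        GenomicRanges::start(gr), GenomicRanges::end(gr),
        as.character(GenomicRanges::strand(gr)), sep = ":")
}

# DNA-alphabet normalisation: everything stored with T, never U
.toDNA <- function(x) chartr("Uu", "Tt", toupper(as.character(x)))

.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

.gcFraction <- function(seq) {
  b <- strsplit(seq, "")
  vapply(b, function(ch) mean(ch %in% c("G", "C")), numeric(1))
}

# largest-remainder apportionment: integer vector summing exactly to total
.apportion <- function(weights, total) {
  if (total == 0 || length(weights) == 0 || sum(weights) == 0)
    return(integer(length(weights)))
  w <- weights / sum(weights)
  raw <- w * total
  out <- floor(raw)
  rem <- total - sum(out)
  if (rem > 0) {
    idx <- order(raw - out, decreasing = TRUE)[seq_len(rem)]
    out[idx] <- out[idx] + 1L
  }
  as.integer(out)
}

.stopIfNot <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)
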