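.ANNOT_CLASSES <- c("rRNA", "tRNA", "scRNA", "snRNA", "snoRNA", "srpRNA",
                    "exon", "intron", "repeat")

#' Default annotation priority order
#'
#' When a tag overlaps features of several classes (across all of its
#' genomic hits), it is assigned the single highest-priority class.
#' Exon and intron features are split into sense/antisense by strand
#' agreement between the hit and the feature.
#'
#' @return Character vector of class labels, highest priority first.
#' @export
annotationPriority <- function() {
  c("rRNA", "scRNA", "snRNA", "snoRNA", "srpRNA", "tRNA", "repeat",
    "exon_sense", "exon_antisense", "intron_sense", "intron_antisense")
}

#' Build an exact-match genome index
#'
#' Prepares a genome for perfect-match lookup of 18-30 nt tags on both
#' strands (minus-strand hits are found by matching the reverse
#' complement of the tag against the plus strand).
#'
#' @param genome A [Biostrings::DNAStringSet] with unique chromosome
#'   names, or a FASTA path.
#' @return An object of class `GenomeIndex`.
#' @export
buildGenomeIndex <- function(genome) {
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  .stopIfNot(!is.null(names(genome)) && !anyDuplicated(names(genome)),
             "duplicate or missing chromosome names")
  names(genome) <- sub("\\s.*$", "", names(genome))
  structure(list(genome = genome), class = "GenomeIndex")
}

#' @export
print.GenomeIndex <- function(x, ...) {
  cat("GenomeIndex over", length(x$genome), "chromosomes,",
      sum(Biostrings::width(x$genome)), "bases\n")
  invisible(x)
}

#' Map clean tags to the genome (perfect matches only)
#'
#' Every perfect alignment of every tag is reported, on both strands;
#' multi-hit tags contribute one hit per locus.  Only perfect matches are
#' retained, mirroring the short-tag mapping convention of small-RNA
#' pipelines.
#'
#' @param tags A [TagSet-class] or character vector of tag sequences.
#' @param index A `GenomeIndex` from [buildGenomeIndex()].
#' @return A list with `hits` (a [GenomicRanges::GRanges] with a `tag`
#'   column) and `summary` (per-library mapped/unmapped unique-tag and
#'   read-count fractions when `tags` is a `TagSet`).
#' @export
mapTags <- function(tags, index) {
  seqs <- if (is(tags, "TagSet")) tagSeq(tags) else .toDNA(tags)
  genome <- index$genome
  hitList <- list()
  if (length(seqs)) {
    widths <- nchar(seqs)
    for (w in sort(unique(widths))) {
      sub <- seqs[widths == w]
      fwd <- Biostrings::DNAStringSet(sub)
      rev <- Biostrings::reverseComplement(fwd)
      pdF <- Biostrings::PDict(fwd)
      pdR <- Biostrings::PDict(rev)
      for (chr in names(genome)) {
        mF <- Biostrings::matchPDict(pdF, genome[[chr]])
        mR <- Biostrings::matchPDict(pdR, genome[[chr]])
        for (t in seq_along(sub)) {
          rF <- mF[[t]]
          if (length(rF))
            hitList[[length(hitList) + 1L]] <- GenomicRanges::GRanges(
              chr, IRanges::IRanges(start(rF), end(rF)), "+",
              tag = sub[t])
          rR <- mR[[t]]
          if (length(rR))
            hitList[[length(hitList) + 1L]] <- GenomicRanges::GRanges(
              chr, IRanges::IRanges(start(rR), end(rR)), "-",
              tag = sub[t])
        }
      }
    }
  }
  hits <- if (length(hitList))
    suppressWarnings(do.call(c, hitList))
  else
    GenomicRanges::GRanges(tag = character(0))
  summary <- NULL
  if (is(tags, "TagSet")) {
    cts <- tagCounts(tags)
    mapped <- tagSeq(tags) %in% hits$tag
    summary <- data.frame(
      library = colnames(cts),
      unique_tags = colSums(cts > 0),
      unique_mapped = colSums(cts > 0 & mapped),
      reads = colSums(cts),
      reads_mapped = colSums(cts * mapped),
      row.names = NULL)
    summary$unique_fraction <- summary$unique_mapped / summary$unique_tags
    summary$read_fraction <- summary$reads_mapped / summary$reads
  }
  list(hits = hits, summary = summary)
}

#' Read genome annotation as a classed GRanges
#'
#' @param path BED6 or GFF3 file; the feature class must be in the BED
#'   name field or the GFF type/ID; classes outside the fixed vocabulary
#'   (rRNA, tRNA, scRNA, snRNA, snoRNA, srpRNA, exon, intron, repeat)
#'   are an error.
#' @return [GenomicRanges::GRanges] with a `class` column.
#' @export
readAnnotation <- function(path) {
  gr <- rtracklayer::import(path)
  cls <- if (!is.null(gr$name)) gr$name else as.character(gr$type)
  cls <- sub("_[0-9]+$", "", cls)
  bad <- setdiff(unique(cls), .ANNOT_CLASSES)
  if (length(bad))
    stop("unknown annotation class(es): ", paste(bad, collapse = ", "))
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(class = cls)
  gr
}

#' Assign each tag to exactly one annotation class
#'
#' A tag's class is the highest-priority class among all features
#' overlapped by any of its genomic hits; exon/intron features split
#' into `_sense`/`_antisense` by strand agreement.  Tags overlapping
#' nothing (or mapping nowhere) are `"unannotated"` and feed the miRNA
#' identification stages.
#'
#' @param tags A [TagSet-class] or character vector of tag sequences.
#' @param hits Genome hits from [mapTags()] (`$hits`).
#' @param annotation Classed [GenomicRanges::GRanges] (see
#'   [readAnnotation()]).
#' @param priority Class priority order, see [annotationPriority()].
#' @return Named character vector: class per tag sequence.
#' @export
assignClass <- function(tags, hits, annotation,
                        priority = annotationPriority()) {
  seqs <- if (is(tags, "TagSet")) tagSeq(tags) else .toDNA(tags)
  cls <- annotation$class
  .stopIfNot(all(cls %in% .ANNOT_CLASSES),
             "unknown class in annotation")
  out <- setNames(rep("unannotated", length(seqs)), seqs)
  if (!length(hits)) return(out)
  ov <- GenomicRanges::findOverlaps(hits, annotation,
                                    ignore.strand = TRUE)
  if (!length(ov)) return(out)
  hi <- S4Vectors::queryHits(ov); ai <- S4Vectors::subjectHits(ov)
  fcls <- cls[ai]
  stranded <- fcls %in% c("exon", "intron")
  same <- as.character(strand(hits))[hi] ==
          as.character(strand(annotation))[ai]
  fcls[stranded] <- paste0(fcls[stranded],
                           ifelse(same[stranded], "_sense", "_antisense"))
  prio <- match(fcls, priority)
  keep <- !is.na(prio)
  tagOf <- hits$tag[hi][keep]
  best <- tapply(prio[keep], tagOf, min)
  assigned <- priority[best]
  idx <- match(names(best), seqs)
  out[idx[!is.na(idx)]] <- assigned[!is.na(idx)]
  out
}

#' Per-class annotation summary (unique and redundant counts)
#'
#' The classic small-RNA category breakdown: for each library, unique-tag
#' and redundant (read-count) totals and percentages per class, plus the
#' `unannotated` remainder and a total row.  Unique counts sum to the
#' number of tags present in the library and redundant counts to its
#' clean reads -- the partition is exact.
#'
#' @param tags A [TagSet-class].
#' @param classes Named class vector from [assignClass()].
#' @param priority Row order; unknown-to-priority classes keep input
#'   order.
#' @return data.frame with columns `class`, then per library
#'   `<lib>_unique`, `<lib>_unique_pct`, `<lib>_reads`, `<lib>_reads_pct`.
#' @export
categorySummary <- function(tags, classes,
                            priority = annotationPriority()) {
  .stopIfNot(is(tags, "TagSet"), "tags must be a TagSet")
  seqs <- tagSeq(tags)
  .stopIfNot(all(seqs %in% names(classes)), "all tags must be classified")
  cl <- classes[seqs]
  cts <- tagCounts(tags)
  rows <- c(intersect(c(priority, "unannotated"), unique(cl)),
            setdiff(unique(cl), c(priority, "unannotated")))
  out <- data.frame(class = rows, stringsAsFactors = FALSE)
  for (lb in colnames(cts)) {
    present <- cts[, lb] > 0
    uniq <- vapply(rows, function(g) sum(present & cl == g), numeric(1))
    reds <- vapply(rows, function(g) sum(cts[cl == g, lb]), numeric(1))
    out[[paste0(lb, "_unique")]] <- as.integer(uniq)
    out[[paste0(lb, "_unique_pct")]] <- 100 * uniq / sum(present)
    out[[paste0(lb, "_reads")]] <- as.integer(reds)
    out[[paste0(lb, "_reads_pct")]] <- 100 * reds / sum(cts[, lb])
  }
  out
}
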