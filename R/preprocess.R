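#' Filter raw small-RNA reads and trim the 3' adapter
#'
#' Reproduces the fixed cleaning cascade of Solexa-era small RNA-seq:
#' reads are dropped, in this order, as (1) `low_quality` (more than 20%
#' of bases below Q10, or any N), (2) `adapter5_contaminant` (read begins
#' with the 5' adapter), (3) `no_3adapter` (no 3' adapter found), (4)
#' `no_insert` (3' adapter starts at position 1), (5) `polyA` (insert at
#' least 90% A), (6) `too_short` (insert outside the 18-30 nt range).
#' The 3' adapter is located before the length test: the leftmost
#' position whose overlap with the adapter matches exactly for at least
#' 6 nt, or with at most one mismatch when the overlap is 10 nt or more.
#' Surviving inserts are collapsed to unique tags with counts.
#'
#' @param reads Path to a FASTQ file (optionally gzipped) or a
#'   [Biostrings::QualityScaledDNAStringSet].
#' @param adapter3,adapter5 Adapter sequences (non-empty).
#' @param library Library label recorded in the report.
#' @return A list with `tags` (data.frame `seq`, `count`, sorted by count)
#'   and `report` (a [FilterReport-class]); the report conserves counts
#'   exactly.
#' @export
filterAndTrim <- function(reads, adapter3, adapter5, library = "lib") {
  .stopIfNot(nchar(adapter3) > 0 && nchar(adapter5) > 0,
             "adapters must be non-empty")
  if (is.character(reads)) reads <- readFastq(reads)
  seqs <- toupper(as.character(reads))
  quals <- as(Biostrings::quality(reads), "IntegerList")
  nraw <- length(seqs)
  adapter3 <- .toDNA(adapter3); adapter5 <- .toDNA(adapter5)

  reason <- rep(NA_character_, nraw)
  # (1) low quality: >20% of bases below Q10, or any ambiguous base
  fracLow <- vapply(quals, function(q) mean(q < 10), numeric(1))
  lowq <- fracLow > 0.2 | grepl("[^ACGT]", seqs)
  reason[lowq] <- "low_quality"

  # (2) 5' adapter contaminant: read starts with the adapter's leading
  # bases (8 nt, or the whole adapter if shorter)
  k5 <- min(8L, nchar(adapter5))
  a5 <- startsWith(seqs, substr(adapter5, 1L, k5))
  reason[is.na(reason) & a5] <- "adapter5_contaminant"

  # (3)/(4) locate the 3' adapter
  apos <- .findAdapter3(seqs, adapter3)
  reason[is.na(reason) & is.na(apos)] <- "no_3adapter"
  reason[is.na(reason) & !is.na(apos) & apos == 1L] <- "no_insert"

  insert <- ifelse(is.na(apos), NA_character_,
                   substr(seqs, 1L, pmax(apos - 1L, 0L)))

  # (5) polyA insert
  fracA <- ifelse(is.na(insert), 0,
                  vapply(strsplit(ifelse(is.na(insert), "", insert), ""),
                         function(b) if (!length(b)) 0 else mean(b == "A"),
                         numeric(1)))
  reason[is.na(reason) & fracA >= 0.9] <- "polyA"

  # (6) insert length outside 18-30 nt
  len <- nchar(insert)
  reason[is.na(reason) & (len < 18L | len > 30L)] <- "too_short"

  keep <- is.na(reason)
  dropped <- vapply(.FILTER_REASONS,
                    function(r) sum(reason == r, na.rm = TRUE), numeric(1))
  tags <- collapseTags(insert[keep])
  report <- FilterReport(library, nraw, dropped, sum(keep), nrow(tags))
  list(tags = tags, report = report)
}

# leftmost 3' adapter match: exact >= 6 nt overlap, or >= 10 nt overlap
# with at most one mismatch; returns start position or NA
.findAdapter3 <- function(seqs, adapter3) {
  la <- nchar(adapter3)
  apos <- rep(NA_integer_, length(seqs))
  lens <- nchar(seqs)
  achars <- strsplit(adapter3, "")[[1]]
  for (i in seq_along(seqs)) {
    s <- seqs[i]
    L <- lens[i]
    schars <- strsplit(s, "")[[1]]
    for (p in seq_len(L)) {
      ov <- min(la, L - p + 1L)
      if (ov < 6L) break
      mism <- sum(schars[p:(p + ov - 1L)] != achars[seq_len(ov)])
      if (mism == 0L || (ov >= 10L && mism <= 1L)) {
        apos[i] <- p
        break
      }
    }
  }
  apos
}

#' Collapse reads to unique tags
#'
#' @param seqs Character vector of clean insert sequences from one
#'   library (possibly with repeats).
#' @return data.frame with columns `seq` and `count`, one row per
#'   distinct sequence, sorted by decreasing count; counts sum to
#'   `length(seqs)`.
#' @export
#' @examples
#' collapseTags(c(strrep("A", 18), strrep("A", 18), strrep("C", 18)))
collapseTags <- function(seqs) {
  if (!length(seqs))
    return(data.frame(seq = character(0), count = integer(0),
                      stringsAsFactors = FALSE))
  tab <- table(seqs)
  out <- data.frame(seq = names(tab), count = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$count, out$seq), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Combine per-library tag tables into a TagSet
#'
#' @param tagList Named list of per-library results: either the output of
#'   [filterAndTrim()] (list with `tags` and `report`) or plain
#'   data.frames with `seq` and `count`.
#' @return A [TagSet-class] over the union of tag sequences, with zeros
#'   where a tag is absent from a library, and filter reports attached
#'   when available.
#' @export
combineLibraries <- function(tagList) {
  .stopIfNot(!is.null(names(tagList)) && all(nzchar(names(tagList))),
             "tagList must be a named list")
  reports <- list()
  dfs <- lapply(names(tagList), function(nm) {
    x <- tagList[[nm]]
    if (is.list(x) && !is.data.frame(x) && !is.null(x$tags)) {
      if (!is.null(x$report)) reports[[nm]] <<- x$report
      x <- x$tags
    }
    x
  })
  names(dfs) <- names(tagList)
  allSeq <- sort(unique(unlist(lapply(dfs, `[[`, "seq"))))
  counts <- vapply(dfs, function(d) {
    v <- integer(length(allSeq))
    v[match(d$seq, allSeq)] <- d$count
    v
  }, integer(length(allSeq)))
  counts <- matrix(counts, nrow = length(allSeq),
                   dimnames = list(allSeq, names(dfs)))
  TagSet(allSeq, counts, reports = reports)
}

#' Read-count length distribution of clean tags
#'
#' Counts are weighted by read counts (redundant reads), not unique tags,
#' matching how small RNA length profiles are reported; in brain
#' libraries the 22-nt class dominates (typically > 30%).
#'
#' @param tags A [TagSet-class] or a data.frame with `seq` and `count`.
#' @param library For a multi-library `TagSet`, which column to profile;
#'   default sums all libraries.
#' @return data.frame with `length`, `count`, `fraction`; fractions sum
#'   to 1 (empty input gives a 0-row table).
#' @export
lengthDistribution <- function(tags, library = NULL) {
  if (is(tags, "TagSet")) {
    cts <- tagCounts(tags)
    cnt <- if (is.null(library)) rowSums(cts) else cts[, library]
    df <- data.frame(seq = tagSeq(tags), count = cnt)
  } else df <- tags
  df <- df[df$count > 0, , drop = FALSE]
  if (!nrow(df))
    return(data.frame(length = integer(0), count = integer(0),
                      fraction = numeric(0)))
  agg <- tapply(df$count, nchar(df$seq), sum)
  out <- data.frame(length = as.integer(names(agg)),
                    count = as.integer(agg))
  out$fraction <- out$count / sum(out$count)
  rownames(out) <- NULL
  out
}

#' Common and library-specific tag summary
#'
#' Partitions the tags of a two-library [TagSet-class] into common,
#' A-specific and B-specific sets and reports unique-tag and read-count
#' totals and fractions (unique fractions over the union of tags, read
#' fractions over the summed clean reads).
#'
#' @param tags A two-library [TagSet-class].
#' @return data.frame with rows `common`, `<A>_specific`, `<B>_specific`
#'   and columns `unique_tags`, `unique_fraction`, `reads`,
#'   `read_fraction`.
#' @export
compareLibraries <- function(tags) {
  .stopIfNot(is(tags, "TagSet") && ncol(tags) == 2,
             "tags must be a two-library TagSet")
  cts <- tagCounts(tags)
  a <- cts[, 1] > 0; b <- cts[, 2] > 0
  grp <- ifelse(a & b, "common",
                ifelse(a, paste0(colnames(cts)[1], "_specific"),
                       paste0(colnames(cts)[2], "_specific")))
  lv <- c("common", paste0(colnames(cts)[1], "_specific"),
          paste0(colnames(cts)[2], "_specific"))
  ut <- vapply(lv, function(g) sum(grp == g), numeric(1))
  rd <- vapply(lv, function(g) sum(cts[grp == g, ]), numeric(1))
  data.frame(set = lv, unique_tags = as.integer(ut),
             unique_fraction = ut / nrow(cts),
             reads = as.integer(rd), read_fraction = rd / sum(cts),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Read a FASTQ file as a quality-scaled DNA string set
#'
#' @param path FASTQ path (plain or gzipped), Phred+33 qualities.
#' @return A [Biostrings::QualityScaledDNAStringSet].
#' @export
readFastq <- function(path) {
  # readQualityScaledDNAStringSet warns while shedding the fastq mcols
  # it adds itself; the columns carry nothing we use
  suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
}

#' Write reads as FASTQ
#'
#' @param x A [Biostrings::QualityScaledDNAStringSet].
#' @param path Output path.
#' @export
writeFastq <- function(x, path) {
  Biostrings::writeQualityScaledXStringSet(x, path)
  invisible(path)
}
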