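#' Thresholds for the six-criterion novel miRNA acceptance rule
#'
#' A candidate precursor is accepted as a novel miRNA when all six hold:
#' c1 `MFE <= mfe` (stable hairpin), c2 `MFEI >= mfei`, c3 the mature
#' sequence sits on one arm and forms a miRNA/miRNA* duplex with 2-nt 3'
#' overhangs, c4 at most `max_mismatch` mismatches between the mature and
#' the opposite arm, c5 at most `max_bulges` internal loop/bulge events of
#' size at most `max_bulge_size` nt within the duplex, and c6 at least
#' `min_count` supporting reads for the merged mature sequence.
#'
#' @param mfe MFE ceiling, kcal/mol (default -25.0).
#' @param mfei MFEI floor (default 0.85).
#' @param max_mismatch Maximum mature/star mismatches (default 4).
#' @param max_bulges Maximum bulge or internal-loop events (default 1).
#' @param max_bulge_size Maximum bulge size in nt (default 1, i.e. bulges
#'   of fewer than 2 bases).
#' @param min_count Minimum read support for a merged mature (default 5).
#' @param band Precursor length band used only to flag (not reject)
#'   unusual precursors; default `c(60, 110)`.
#' @return A named list of thresholds.
#' @export
novelThresholds <- function(mfe = -25.0, mfei = 0.85, max_mismatch = 4L,
                            max_bulges = 1L, max_bulge_size = 1L,
                            min_count = 5L, band = c(60L, 110L)) {
  list(mfe = mfe, mfei = mfei, max_mismatch = max_mismatch,
       max_bulges = max_bulges, max_bulge_size = max_bulge_size,
       min_count = min_count, band = band)
}

#' Extract candidate precursor windows around genome hits
#'
#' For every perfect genome hit of an unassigned tag, two flanking windows
#' are extracted so the tag can sit on either arm of a putative hairpin:
#' one with `l_up` nt upstream and `l_down` nt downstream of the tag (in
#' transcript orientation), and the mirror.  Windows are clipped at
#' chromosome ends and duplicates merged.
#'
#' @param hits A [GenomicRanges::GRanges] of perfect tag hits with a `tag`
#'   metadata column (as returned by [mapTags()]).
#' @param genome A [Biostrings::DNAStringSet] genome.
#' @param l_up,l_down Flank lengths in nt (defaults 20 and 160).
#' @return A `GRanges` of windows with metadata columns `tag`, `window`
#'   (`"5p"` if the tag lies toward the transcript 5' end), `precursor`
#'   (window sequence in transcript orientation) and `mature_start` /
#'   `mature_end` (1-based tag position within the window sequence).
#' @export
extractCandidates <- function(hits, genome, l_up = 20L, l_down = 160L) {
  .stopIfNot(is(hits, "GRanges") && !is.null(hits$tag),
             "hits must be a GRanges with a 'tag' column")
  chromLen <- setNames(Biostrings::width(genome), names(genome))
  .stopIfNot(all(as.character(seqnames(hits)) %in% names(genome)),
             "hit chromosome absent from genome")
  .stopIfNot(all(start(hits) >= 1) &&
             all(end(hits) <= chromLen[as.character(seqnames(hits))]),
             "hit beyond chromosome bounds")
  out <- list()
  for (k in seq_along(hits)) {
    h <- hits[k]
    chr <- as.character(seqnames(h))
    minus <- as.character(strand(h)) == "-"
    # transcript-orientation flanks; on the minus strand genomic
    # upstream/downstream are swapped
    if (!minus) {
      wins <- list(`5p` = c(start(h) - l_up, end(h) + l_down),
                   `3p` = c(start(h) - l_down, end(h) + l_up))
    } else {
      wins <- list(`5p` = c(start(h) - l_down, end(h) + l_up),
                   `3p` = c(start(h) - l_up, end(h) + l_down))
    }
    for (w in names(wins)) {
      s <- max(1L, wins[[w]][1])
      e <- min(chromLen[[chr]], wins[[w]][2])
      seq <- as.character(Biostrings::subseq(genome[[chr]], s, e))
      if (minus) seq <- .revcomp(seq)
      ms <- if (!minus) start(h) - s + 1L else e - end(h) + 1L
      out[[length(out) + 1L]] <- data.frame(
        chrom = chr, start = s, end = e,
        strand = if (minus) "-" else "+", tag = h$tag, window = w,
        precursor = seq, mature_start = ms,
        mature_end = ms + nchar(h$tag) - 1L,
        stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, out)
  df <- df[!duplicated(df[, c("chrom", "start", "end", "strand", "tag")]), ]
  gr <- GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start, df$end),
                               strand = df$strand)
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    tag = df$tag, window = df$window, precursor = df$precursor,
    mature_start = df$mature_start, mature_end = df$mature_end)
  gr
}

#' Locate the miRNA* strand and duplex geometry within a folded precursor
#'
#' Given a stem-loop fold and the mature miRNA position within the
#' precursor, derives the star strand under the canonical Dicer geometry
#' (2-nt 3' overhangs on both strands of the miRNA/miRNA* duplex) and
#' counts duplex imperfections: mismatches (symmetric unpaired positions,
#' `min(a, b)` per interior gap plus unpaired duplex termini) and
#' bulge/internal-loop events (asymmetric gaps, size `|a - b|`).  GU
#' wobble counts as a pair, not a mismatch.
#'
#' @param fold A fold result from [foldHairpin()].
#' @param mature_start,mature_end 1-based mature position in the precursor.
#' @return A list: `ok` (FALSE with a `reason` of `"unpaired"` or
#'   `"spans_loop"` when no valid duplex exists), `arm` (`"5p"`/`"3p"`),
#'   `star_start`, `star_end`, `mismatches`, `n_bulges`, `max_bulge`.
#' @export
locateDuplex <- function(fold, mature_start, mature_end) {
  n <- nchar(fold$structure)
  ms <- as.integer(mature_start); me <- as.integer(mature_end)
  .stopIfNot(ms >= 1 && me <= n && ms < me,
             "mature must lie within the precursor")
  pt <- rep(NA_integer_, n)
  if (nrow(fold$pairs)) {
    pt[fold$pairs[, 1]] <- fold$pairs[, 2]
    pt[fold$pairs[, 2]] <- fold$pairs[, 1]
  }
  span <- ms:me
  paired <- span[!is.na(pt[span])]
  if (!length(paired))
    return(list(ok = FALSE, reason = "unpaired"))
  partners <- pt[paired]
  if (any(partners > me) && any(partners < ms))
    return(list(ok = FALSE, reason = "spans_loop"))
  if (any(partners >= ms & partners <= me))
    return(list(ok = FALSE, reason = "spans_loop"))
  # a mature may dip into the terminal loop with its overhang (plus
  # isomiR slack), but not sit across the loop apex
  inner <- fold$pairs[nrow(fold$pairs), ]
  loopIv <- seq(inner[1] + 1L, inner[2] - 1L)
  if (sum(span %in% loopIv) > 4L)
    return(list(ok = FALSE, reason = "spans_loop"))
  arm <- if (all(partners > me)) "5p" else "3p"
  # anchors: paired mature positions inside the duplex span [ms, me-2]
  # (the mature 3'-most 2 nt are its own 3' overhang)
  anchors <- paired[paired <= me - 2L]
  if (!length(anchors))
    return(list(ok = FALSE, reason = "unpaired"))
  q0 <- min(anchors); q1 <- max(anchors)
  star_start <- pt[q1] - ((me - 2L) - q1)
  star_end <- pt[q0] + (q0 - ms) + 2L
  if (star_start < 1L || star_end > n)
    return(list(ok = FALSE, reason = "unpaired"))
  # terminal gaps are symmetric by construction of the extrapolated ends
  mism <- (q0 - ms) + ((me - 2L) - q1)
  n_bulge <- 0L; max_bulge <- 0L
  if (length(anchors) > 1L) {
    qs <- sort(anchors)
    for (t in seq_len(length(qs) - 1L)) {
      a <- qs[t + 1L] - qs[t] - 1L
      b <- abs(pt[qs[t]] - pt[qs[t + 1L]]) - 1L
      mism <- mism + min(a, b)
      if (a != b) {
        n_bulge <- n_bulge + 1L
        max_bulge <- max(max_bulge, abs(a - b))
      }
    }
  }
  list(ok = TRUE, arm = arm, star_start = star_start, star_end = star_end,
       mismatches = mism, n_bulges = n_bulge, max_bulge = max_bulge)
}

#' Evaluate the six novel-miRNA acceptance criteria
#'
#' Applies the fixed six-criterion rule to measured candidate properties.
#' All thresholds are inclusive: a candidate at exactly MFE -25.0,
#' MFEI 0.85, 4 mismatches or 5 reads passes the respective criterion.
#'
#' @param mfe Minimum free energy, kcal/mol.
#' @param mfei Minimal folding free energy index (`NA` fails c2).
#' @param arm_ok Logical: mature on a single arm with a valid 2-nt
#'   3'-overhang duplex (output `ok` of [locateDuplex()]).
#' @param mismatches Duplex mismatch count (`NA` fails c4).
#' @param n_bulges,max_bulge Bulge/internal-loop event count and largest
#'   event size within the duplex.
#' @param read_count Read support of the (merged) mature sequence.
#' @param thresholds See [novelThresholds()].
#' @return A list with logical elements `c1`..`c6` and `accept`
#'   (`all(c1..c6)`).
#' @export
#' @examples
#' evaluateCriteria(-25, 0.85, TRUE, 4, 0, 0, 5)$accept  # boundary pass
evaluateCriteria <- function(mfe, mfei, arm_ok, mismatches, n_bulges,
                             max_bulge, read_count,
                             thresholds = novelThresholds()) {
  th <- thresholds
  c1 <- isTRUE(mfe <= th$mfe)
  c2 <- isTRUE(mfei >= th$mfei)
  c3 <- isTRUE(arm_ok)
  c4 <- isTRUE(mismatches <= th$max_mismatch)
  c5 <- isTRUE(n_bulges <= th$max_bulges) &&
        isTRUE((n_bulges == 0L) || max_bulge <= th$max_bulge_size)
  c6 <- isTRUE(read_count >= th$min_count)
  list(c1 = c1, c2 = c2, c3 = c3, c4 = c4, c5 = c5, c6 = c6,
       accept = c1 && c2 && c3 && c4 && c5 && c6)
}

# Trim a folded window to the hairpin extent (outermost pair, widened to
# contain the mature); exterior bases contribute no energy so the MFE is
# unchanged while MFEI is computed over the actual precursor.
.trimPrecursor <- function(row, fold) {
  if (nrow(fold$pairs) == 0) return(NULL)
  lo <- min(fold$pairs[, 1], row$mature_start)
  hi <- max(fold$pairs[, 2], row$mature_end)
  seq <- substr(row$precursor, lo, hi)
  # genomic coordinates of the trimmed precursor
  if (row$strand == "+") {
    ps <- row$start + lo - 1L; pe <- row$start + hi - 1L
  } else {
    pe <- row$end - lo + 1L; ps <- row$end - hi + 1L
  }
  pairs <- fold$pairs - lo + 1L
  structure <- substr(fold$structure, lo, hi)
  list(seq = seq, start = ps, end = pe,
       mature_start = row$mature_start - lo + 1L,
       mature_end = row$mature_end - lo + 1L,
       fold = list(mfe = fold$mfe, structure = structure, pairs = pairs))
}

#' Predict novel candidate miRNAs from unassigned tags
#'
#' The full discovery path: for every perfect genome hit of every
#' unassigned tag, extract the two flanking windows ([extractCandidates()]),
#' fold each ([foldHairpin()]), keep the more stable window, trim the
#' precursor to the hairpin extent, derive the miRNA* duplex geometry
#' ([locateDuplex()]), compute MFEI, apply criteria c1-c5 per locus and
#' the read-support criterion c6 per merged mature sequence, and merge
#' identical matures across loci into one novel miRNA
#' ([mergeMultilocus()]).  Names follow the `rno-miR-nNNN_5p/3p` scheme in
#' order of decreasing total read count.
#'
#' @param tags A [TagSet-class] of unassigned tags (unannotated, not
#'   matching any known miRNA).
#' @param hits Perfect genome hits for those tags, from [mapTags()].
#' @param genome A [Biostrings::DNAStringSet] genome.
#' @param thresholds See [novelThresholds()].
#' @param params Folding parameters, see [foldParams()].
#' @param l_up,l_down Window flanks passed to [extractCandidates()].
#' @param prefix Species prefix for generated names (default `"rno"`).
#' @return A list with `novel` (one data.frame row per accepted novel
#'   miRNA: name, mature sequence, length, per-library counts, loci with
#'   per-locus MFE/MFEI, arm, precursor length flag) and `candidates`
#'   (the per-locus evaluation table for all folded candidates, with the
#'   six criterion verdicts).
#' @export
predictNovel <- function(tags, hits, genome, thresholds = novelThresholds(),
                         params = foldParams(), l_up = 20L, l_down = 160L,
                         prefix = "rno") {
  .stopIfNot(is(tags, "TagSet"), "tags must be a TagSet")
  wins <- extractCandidates(hits, genome, l_up = l_up, l_down = l_down)
  wdf <- as.data.frame(wins)
  names(wdf)[1] <- "chrom"
  wdf$chrom <- as.character(wdf$chrom)
  wdf$strand <- as.character(wdf$strand)
  counts <- tagCounts(tags)
  cand <- list()
  # group windows per original hit: same tag + same genomic mature locus
  gstart <- ifelse(wdf$strand == "+", wdf$start + wdf$mature_start - 1L,
                   wdf$end - wdf$mature_end + 1L)
  grp <- paste(wdf$tag, wdf$chrom, wdf$strand, gstart)
  foldCache <- new.env(parent = emptyenv())
  cachedFold <- function(seq) {
    if (is.null(foldCache[[seq]])) foldCache[[seq]] <- foldHairpin(seq, params)
    foldCache[[seq]]
  }
  for (g in unique(grp)) {
    win <- wdf[grp == g, , drop = FALSE]
    f5 <- cachedFold(win$precursor[win$window == "5p"][1])
    has3 <- any(win$window == "3p")
    f3 <- if (has3) cachedFold(win$precursor[win$window == "3p"][1]) else NULL
    pick <- if (!has3 || f5$mfe <= f3$mfe) "5p" else "3p"
    row <- win[win$window == pick, ][1, , drop = FALSE]
    fold <- if (pick == "5p") f5 else f3
    trim <- .trimPrecursor(row, fold)
    tagSeq <- row$tag
    cnt <- counts[match(tagSeq, rownames(counts)), , drop = TRUE]
    gs <- if (row$strand == "+") row$start + row$mature_start - 1L
          else row$end - row$mature_end + 1L
    rec <- data.frame(tag = tagSeq, chrom = row$chrom, strand = row$strand,
                      mature_gstart = gs, stringsAsFactors = FALSE)
    if (is.null(trim)) {
      rec$prec_start <- NA_integer_; rec$prec_end <- NA_integer_
      rec$prec_len <- NA_integer_; rec$mfe <- 0; rec$mfei <- NA_real_
      rec$gc <- NA_real_; rec$arm <- NA_character_
      rec$mismatches <- NA_integer_; rec$n_bulges <- NA_integer_
      rec$max_bulge <- NA_integer_
      rec$precursor <- NA_character_; rec$structure <- NA_character_
      dupOK <- FALSE
    } else {
      dup <- locateDuplex(trim$fold, trim$mature_start, trim$mature_end)
      gc <- .gcFraction(trim$seq)
      rec$prec_start <- trim$start; rec$prec_end <- trim$end
      rec$prec_len <- nchar(trim$seq); rec$mfe <- trim$fold$mfe
      rec$gc <- gc
      rec$precursor <- trim$seq; rec$structure <- trim$fold$structure
      rec$mfei <- computeMFEI(trim$fold$mfe, nchar(trim$seq), gc)
      dupOK <- isTRUE(dup$ok)
      rec$arm <- if (dupOK) dup$arm else NA_character_
      rec$mismatches <- if (dupOK) dup$mismatches else NA_integer_
      rec$n_bulges <- if (dupOK) dup$n_bulges else NA_integer_
      rec$max_bulge <- if (dupOK) dup$max_bulge else NA_integer_
    }
    cr <- evaluateCriteria(rec$mfe, rec$mfei, dupOK, rec$mismatches,
                           rec$n_bulges, rec$max_bulge, sum(cnt),
                           thresholds)
    rec$c1 <- cr$c1; rec$c2 <- cr$c2; rec$c3 <- cr$c3; rec$c4 <- cr$c4
    rec$c5 <- cr$c5; rec$c6 <- cr$c6
    rec$locus_pass <- cr$c1 && cr$c2 && cr$c3 && cr$c4 && cr$c5
    rec$accept <- cr$accept
    cand[[length(cand) + 1L]] <- rec
  }
  candidates <- if (length(cand)) do.call(rbind, cand) else
    data.frame(tag = character(0))
  novel <- mergeMultilocus(candidates, counts, thresholds, prefix)
  list(novel = novel, candidates = candidates)
}

#' Merge multi-locus candidates into novel miRNA records
#'
#' Candidates with identical mature sequences (the same tag mapped at
#' several genomic loci, e.g. a clustered multi-copy miRNA gene) are
#' merged into one novel miRNA listing every criteria-passing locus;
#' read counts are the tag's library counts, counted once, never once
#' per locus.  The read-support criterion (c6) applies to the merged
#' mature.  Names are assigned as `<prefix>-miR-nNNN_<arm>` in order of
#' decreasing total count.
#'
#' @param candidates Per-locus candidate table from [predictNovel()].
#' @param counts Tag count matrix (rownames are tag sequences).
#' @param thresholds See [novelThresholds()].
#' @param prefix Species prefix for names.
#' @return A data.frame of accepted novel miRNAs (possibly 0 rows).
#' @export
mergeMultilocus <- function(candidates, counts,
                            thresholds = novelThresholds(),
                            prefix = "rno") {
  libs <- colnames(counts)
  empty <- data.frame(name = character(0), seq = character(0),
                      length = integer(0), stringsAsFactors = FALSE)
  if (!nrow(candidates)) return(empty)
  ok <- candidates[candidates$locus_pass %in% TRUE, , drop = FALSE]
  if (!nrow(ok)) return(empty)
  rows <- list()
  for (sq in unique(ok$tag)) {
    loci <- ok[ok$tag == sq, , drop = FALSE]
    cnt <- counts[match(sq, rownames(counts)), , drop = FALSE]
    if (sum(cnt) < thresholds$min_count) next
    arm <- names(sort(table(loci$arm), decreasing = TRUE))[1]
    locStr <- paste(loci$chrom, loci$prec_start, loci$prec_end,
                    loci$strand, sep = ":")
    rec <- data.frame(seq = sq, length = nchar(sq),
                      stringsAsFactors = FALSE)
    for (lb in libs) rec[[lb]] <- as.integer(cnt[, lb])
    rec$total <- as.integer(sum(cnt))
    rec$arm <- arm
    rec$n_loci <- nrow(loci)
    rec$loci <- paste(locStr, collapse = ";")
    rec$mfe <- paste(sprintf("%.1f", loci$mfe), collapse = ";")
    rec$mfei <- paste(sprintf("%.2f", loci$mfei), collapse = ";")
    rec$min_mfe <- min(loci$mfe)
    rec$in_band <- all(loci$prec_len >= thresholds$band[1] &
                       loci$prec_len <= thresholds$band[2])
    rows[[length(rows) + 1L]] <- rec
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(-out$total, out$seq), , drop = FALSE]
  out <- cbind(name = sprintf("%s-miR-n%03d_%s", prefix,
                              seq_len(nrow(out)), out$arm),
               out, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
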