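#' Read a miRBase-style mature miRNA reference
#'
#' Headers are `>spe-miR-name ...`; `U` is normalised to `T`.  The
#' species code is the leading 3-letter prefix of the name.
#'
#' @param path FASTA path, or a named character vector of sequences.
#' @return data.frame with `name`, `species`, `seq`.
#' @export
readMatureReference <- function(path) {
  if (is.character(path) && length(path) == 1 && file.exists(path)) {
    ss <- Biostrings::readBStringSet(path)
    seqs <- setNames(.toDNA(as.character(ss)),
                     sub("\\s.*$", "", names(ss)))
  } else {
    .stopIfNot(!is.null(names(path)), "need a named vector or FASTA path")
    seqs <- setNames(.toDNA(path), names(path))
  }
  data.frame(name = names(seqs),
             species = sub("^([a-z]{3})-.*$", "\\1", names(seqs)),
             seq = unname(seqs), stringsAsFactors = FALSE)
}

# does tag match mature under the isomiR rule (exact core, <= maxShift nt
# terminal shift/extension at either end, no internal mismatches)?
# returns the total terminal offset (for tie-breaking) or NA
.isomirOffset <- function(tag, mature, maxShift = 2L) {
  nt <- nchar(tag); nm <- nchar(mature)
  best <- NA_integer_
  for (o in -maxShift:maxShift) {
    endDiff <- (o + nt) - nm
    if (abs(endDiff) > maxShift) next
    lo <- max(1L, 1L + o); hi <- min(nm, o + nt)
    if (hi < lo) next
    if (substr(tag, lo - o, hi - o) == substr(mature, lo, hi)) {
      score <- abs(o) + abs(endDiff)
      if (is.na(best) || score < best) best <- score
    }
  }
  best
}

#' Identify known miRNAs among unannotated tags
#'
#' A tag matches a reference mature miRNA when it is identical or
#' identical after a shift/extension of at most `max_shift` nt at either
#' terminus (isomiR tolerance), with no internal mismatches.  Each tag is
#' assigned to at most one reference entry; ties are broken
#' deterministically: same-species entries first, then fewest terminal
#' shifts, then lexicographic name.  Counts of all matching tags
#' accumulate on the reference entry, so read counts are conserved:
#' matched plus unmatched counts equal the input counts.
#'
#' @param tags A [TagSet-class] of unannotated tags.
#' @param reference Mature reference from [readMatureReference()] (or a
#'   FASTA path); must be non-empty.
#' @param species Preferred species code (default `"rno"`).
#' @param max_shift isomiR terminal tolerance in nt (default 2).
#' @param familyTable Optional data.frame (`name`, `family`); otherwise
#'   families are inferred from names (see [familyRollup()]).
#' @return A list: `known` (data.frame `name`, `species`, `family`,
#'   `seq` (reference mature), `length`, per-library counts, `total`,
#'   `n_tags`), `assignment` (per input tag: matched name or `NA`), and
#'   `unmatched` (a [TagSet-class] of unmatched tags, or `NULL` if all
#'   matched).
#' @export
matchKnown <- function(tags, reference, species = "rno", max_shift = 2L,
                       familyTable = NULL) {
  .stopIfNot(is(tags, "TagSet"), "tags must be a TagSet")
  if (is.character(reference)) reference <- readMatureReference(reference)
  .stopIfNot(nrow(reference) > 0, "empty mature reference")
  seqs <- tagSeq(tags)
  cts <- tagCounts(tags)
  # any isomiR match must contain the mature core (positions 3..n-2)
  core <- substr(reference$seq, 3L, nchar(reference$seq) - 2L)
  assignment <- rep(NA_character_, length(seqs))
  for (i in seq_along(seqs)) {
    tg <- seqs[i]
    hit <- which(vapply(core, function(co) grepl(co, tg, fixed = TRUE),
                        logical(1)))
    if (!length(hit)) next
    off <- vapply(hit, function(r)
      .isomirOffset(tg, reference$seq[r], max_shift), integer(1))
    hit <- hit[!is.na(off)]; off <- off[!is.na(off)]
    if (!length(hit)) next
    sameSp <- reference$species[hit] == species
    ord <- order(!sameSp, off, reference$name[hit])
    assignment[i] <- reference$name[hit[ord[1]]]
  }
  matched <- !is.na(assignment)
  known <- NULL
  if (any(matched)) {
    nm <- unique(assignment[matched])
    ridx <- match(nm, reference$name)
    kc <- t(vapply(nm, function(x)
      colSums(cts[assignment %in% x, , drop = FALSE]),
      numeric(ncol(cts))))
    known <- data.frame(name = nm, species = reference$species[ridx],
                        seq = reference$seq[ridx],
                        length = nchar(reference$seq[ridx]),
                        stringsAsFactors = FALSE)
    for (lb in colnames(cts)) known[[lb]] <- as.integer(kc[, lb])
    known$total <- as.integer(rowSums(kc))
    known$n_tags <- as.integer(table(assignment)[nm])
    fam <- if (!is.null(familyTable))
      familyTable$family[match(nm, familyTable$name)]
    else rep(NA_character_, length(nm))
    fam[is.na(fam)] <- .inferFamily(nm[is.na(fam)])
    known$family <- fam
    known <- known[order(-known$total, known$name), , drop = FALSE]
    rownames(known) <- NULL
  }
  un <- NULL
  if (any(!matched))
    un <- TagSet(seqs[!matched], cts[!matched, , drop = FALSE])
  list(known = known, assignment = setNames(assignment, seqs),
       unmatched = un)
}

# family from name: strip species prefix, arm suffix and variant letters;
# "rno-let-7c" -> "let-7", "hsa-miR-200a*" -> "mir-200"
.inferFamily <- function(names) {
  x <- tolower(names)
  x <- sub("^[a-z]{3}-", "", x)
  x <- sub("\\*$", "", x)
  x <- sub("-(5p|3p)$", "", x)
  m <- regmatches(x, regexec("^(let|mir|lin|bantam)-?([0-9]+)", x))
  vapply(seq_along(x), function(i) {
    if (length(m[[i]]) == 3) paste0(m[[i]][2], "-", m[[i]][3]) else x[i]
  }, character(1))
}

#' Roll known miRNAs up into families
#'
#' @param known Known-miRNA table from [matchKnown()].
#' @return data.frame with `family`, `members`, per-library summed
#'   counts and `total`, sorted by total; member and count sums conserve
#'   the input totals (each miRNA belongs to exactly one family).
#' @export
familyRollup <- function(known) {
  if (is.null(known) || !nrow(known))
    return(data.frame(family = character(0), members = integer(0),
                      total = integer(0)))
  libs <- setdiff(colnames(known),
                  c("name", "species", "seq", "length", "total",
                    "n_tags", "family"))
  fams <- unique(known$family)
  out <- data.frame(family = fams,
                    members = as.integer(table(known$family)[fams]),
                    stringsAsFactors = FALSE)
  for (lb in libs)
    out[[lb]] <- as.integer(tapply(known[[lb]], known$family, sum)[fams])
  out$total <- as.integer(tapply(known$total, known$family, sum)[fams])
  out <- out[order(-out$total, out$family), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Co-expressed and library-specific known miRNAs
#'
#' @param known Known-miRNA table from [matchKnown()] with two library
#'   count columns.
#' @param libs Which two count columns to compare (default: first two
#'   library columns).
#' @param species Species code for the same-species subset counts.
#' @return data.frame rows `co_expressed`, `<A>_only`, `<B>_only` with
#'   `n` and `n_species` (the same-species subset); the partition is
#'   exhaustive and disjoint.
#' @export
sharedSpecific <- function(known, libs = NULL, species = "rno") {
  if (is.null(libs))
    libs <- setdiff(colnames(known),
                    c("name", "species", "seq", "length", "total",
                      "n_tags", "family"))[1:2]
  a <- known[[libs[1]]] > 0; b <- known[[libs[2]]] > 0
  sp <- known$species == species
  grp <- ifelse(a & b, "co_expressed",
                ifelse(a, paste0(libs[1], "_only"),
                       paste0(libs[2], "_only")))
  lv <- c("co_expressed", paste0(libs[1], "_only"),
          paste0(libs[2], "_only"))
  data.frame(set = lv,
             n = vapply(lv, function(g) sum(grp == g), integer(1)),
             n_species = vapply(lv, function(g) sum(grp == g & sp),
                                integer(1)),
             row.names = NULL, stringsAsFactors = FALSE)
}
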