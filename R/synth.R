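#' Configuration for the synthetic two-library small-RNA study
#'
#' Describes a complete synthetic study emulating a pooled-RNA
#' two-library small RNA-seq design: a random genome with planted known
#' miRNA loci, planted novel hairpin loci (criteria-passing, plus
#' deliberately failing decoys), optional multi-copy loci sharing one
#' mature sequence (clustered, like an 11-copy miRNA gene), non-miRNA
#' loci for every annotation class, per-locus abundances and fold
#' changes, and read-level contaminants for every filter reason.
#'
#' Mature lengths are drawn from 20-24 nt with 40% of the abundance at
#' 22 nt, matching the typical animal miRNA length profile.  Abundances
#' default to log-uniform (the per-locus abundance distribution of real
#' libraries is unknown; this is a deliberate, configurable choice).
#'
#' @param genomeLength Total genome size in bases.
#' @param nChromosomes Number of chromosomes.
#' @param nKnownLoci Planted known-miRNA loci (present in the mature
#'   reference).
#' @param nNovelLoci Planted criteria-passing novel hairpin loci.
#' @param nFailLoci Planted mature tags without hairpin context
#'   (criteria-failing decoys).
#' @param nMulticopyLoci Extra genomic copies of the first novel locus'
#'   precursor, clustered on one chromosome (0 disables; 10 emulates an
#'   11-locus multi-copy gene together with the original).
#' @param ncrnaClassCounts Named counts of non-miRNA loci per annotation
#'   class; must cover rRNA, tRNA, scRNA, snRNA, snoRNA, srpRNA, exon,
#'   intron, repeat.
#' @param nJunkTags Clean tags absent from the genome (unmappable).
#' @param readsPerLibrary Raw reads per library.
#' @param libraries Library labels (condition names).
#' @param adapter3,adapter5 Adapter sequences ligated in library
#'   construction.
#' @param readLength Raw read length (insert + 3' adapter prefix).
#' @param contaminantFractions Named fractions (summing to < 1) of
#'   `low_quality`, `no_3adapter`, `adapter_dimer`, `polyA`,
#'   `short_insert` reads.
#' @param foldChanges Optional data.frame (`locus_id`, `log2fc`,
#'   `condition_specific`) overriding the defaults (a quarter of known
#'   loci at log2fc +/-2 and one condition-specific novel locus).
#' @param duplexMismatches Designed mature/star mismatch counts,
#'   recycled over novel loci.
#' @param abundanceRange,ncrnaAbundanceRange Log-uniform abundance
#'   ranges for miRNA and non-miRNA loci.
#' @param deterministicCounts Use exact expected counts instead of
#'   multinomial draws.
#' @param seed Integer seed controlling all randomness.
#' @return A validated list of class `SyntheticConfig`.
#' @export
syntheticConfig <- function(genomeLength = 60000L, nChromosomes = 3L,
                            nKnownLoci = 10L, nNovelLoci = 8L,
                            nFailLoci = 3L, nMulticopyLoci = 0L,
                            ncrnaClassCounts = c(
                              rRNA = 2L, tRNA = 2L, scRNA = 1L,
                              snRNA = 1L, snoRNA = 1L, srpRNA = 1L,
                              exon = 2L, intron = 2L, `repeat` = 2L),
                            nJunkTags = 5L,
                            readsPerLibrary = 20000L,
                            libraries = c("HIST", "NC"),
                            adapter3 = "TCGTATGCCGTCTTCTGCTTG",
                            adapter5 = "GTTCAGAGTTCTACAGTCCGACGATC",
                            readLength = 36L,
                            contaminantFractions = c(
                              low_quality = 0.02, no_3adapter = 0.02,
                              adapter_dimer = 0.01, polyA = 0.01,
                              short_insert = 0.01),
                            foldChanges = NULL,
                            duplexMismatches = c(0L, 1L, 2L),
                            abundanceRange = c(20, 2000),
                            ncrnaAbundanceRange = c(10, 300),
                            deterministicCounts = FALSE,
                            seed = 1L) {
  need <- c("low_quality", "no_3adapter", "adapter_dimer", "polyA",
            "short_insert")
  .stopIfNot(all(need %in% names(contaminantFractions)),
             "contaminantFractions must name all five contaminant classes")
  .stopIfNot(sum(contaminantFractions) < 1,
             "contaminant fractions must sum to < 1")
  .stopIfNot(all(contaminantFractions >= 0), "fractions must be >= 0")
  .stopIfNot(all(.ANNOT_CLASSES %in% names(ncrnaClassCounts)),
             "ncrnaClassCounts must cover every annotation class")
  .stopIfNot(length(libraries) == 2, "exactly two libraries")
  cfg <- list(genomeLength = as.integer(genomeLength),
              nChromosomes = as.integer(nChromosomes),
              nKnownLoci = as.integer(nKnownLoci),
              nNovelLoci = as.integer(nNovelLoci),
              nFailLoci = as.integer(nFailLoci),
              nMulticopyLoci = as.integer(nMulticopyLoci),
              ncrnaClassCounts = ncrnaClassCounts,
              nJunkTags = as.integer(nJunkTags),
              readsPerLibrary = as.integer(readsPerLibrary),
              libraries = libraries, adapter3 = .toDNA(adapter3),
              adapter5 = .toDNA(adapter5),
              readLength = as.integer(readLength),
              contaminantFractions = contaminantFractions[need],
              foldChanges = foldChanges,
              duplexMismatches = as.integer(duplexMismatches),
              abundanceRange = abundanceRange,
              ncrnaAbundanceRange = ncrnaAbundanceRange,
              deterministicCounts = isTRUE(deterministicCounts),
              seed = as.integer(seed))
  class(cfg) <- "SyntheticConfig"
  cfg
}

# base sampler with GC bias
.randSeq <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

.MATURE_LENS <- 20:24
.MATURE_LEN_P <- c(0.12, 0.18, 0.40, 0.18, 0.12)

.randMature <- function() {
  len <- sample(.MATURE_LENS, 1, prob = .MATURE_LEN_P)
  body <- .randSeq(len - 2L, gc = 0.55)
  # the mature 3' dinucleotide stays A/C so the designed terminal loop
  # (also A/C) cannot pair with it and shift the duplex
  paste0(body, paste(sample(c("A", "C"), 2, replace = TRUE),
                     collapse = ""))
}

.COMP <- c(A = "T", C = "G", G = "C", T = "A")

# designed hairpin precursor for a mature sequence; returns precursor,
# mature offset and the star sequence implied by 2-nt 3' overhangs
.designHairpin <- function(mature, arm = c("5p", "3p"), mismatches = 0L,
                           extLen = 12L, loopLen = 13L) {
  arm <- match.arg(arm)
  n <- nchar(mature)
  stemLen <- n - 2L                       # mature minus its 3' overhang
  starCore <- .revcomp(substr(mature, 1L, stemLen))
  if (mismatches > 0L) {
    # substitute interior star bases; avoid complements and GU wobble so
    # each substitution is a true 1x1 mismatch
    pos <- seq(3L, stemLen - 2L, length.out = mismatches)
    pos <- unique(as.integer(round(pos)))
    for (p in pos) {
      mb <- substr(mature, stemLen + 1L - p, stemLen + 1L - p)
      forbid <- c(.COMP[[mb]], if (mb == "G") "T", if (mb == "T") "G")
      repl <- setdiff(c("A", "C", "G", "T"),
                      c(forbid, substr(starCore, p, p)))
      substr(starCore, p, p) <- sample(repl, 1)
    }
  }
  loop <- paste(sample(c("A", "C"), loopLen, replace = TRUE),
                collapse = "")
  tail2 <- paste(sample(c("A", "C"), 2, replace = TRUE), collapse = "")
  ext5 <- .randSeq(extLen, gc = 0.7)   # GC-rich basal stem for stability
  ext3 <- .revcomp(ext5)
  if (arm == "5p") {
    prec <- paste0(ext5, mature, loop, starCore, tail2, ext3)
    ms <- extLen + 1L
    starSeq <- paste0(starCore, tail2)
  } else {
    # tail2 here is an unpaired spacer balancing the mature 3' overhang;
    # the star's own 3' overhang is the first two terminal-loop bases
    prec <- paste0(ext5, tail2, starCore, loop, mature, ext3)
    ms <- extLen + 2L + stemLen + loopLen + 1L
    starSeq <- paste0(starCore, substr(loop, 1L, 2L))
  }
  list(precursor = prec, mature_start = ms,
       mature_end = ms + n - 1L, star = starSeq)
}

#' Build a synthetic genome with planted truth
#'
#' Generates random chromosomes, plants every configured locus type
#' (known miRNAs, criteria-passing novel hairpins with designed duplex
#' geometry and 2-nt 3' overhangs, failing decoys, clustered multi-copy
#' precursors, non-miRNA loci for each annotation class), builds the
#' miRBase-style mature reference (same-species entries for planted
#' known miRNAs, a few other-species duplicates and decoys), assigns
#' per-locus abundances and fold changes, and precomputes expected
#' per-library clean-read counts (exact largest-remainder apportionment,
#' used verbatim in deterministic mode).  Fully deterministic given
#' `cfg$seed`.
#'
#' @param cfg A [syntheticConfig()].
#' @return A list of class `SynthBundle`: `genome`
#'   ([Biostrings::DNAStringSet]), `truth` (per-locus data.frame:
#'   locus_id, chrom, start, end, strand, mature/star/precursor
#'   sequences and coordinates, arm, is_known, criteria_pass, log2fc,
#'   condition_specific), `annotation` (classed
#'   [GenomicRanges::GRanges]), `reference` (mature reference
#'   data.frame), and `abundance` (per unique tag: origin, expected
#'   count per library).
#' @export
buildGenome <- function(cfg) {
  .stopIfNot(inherits(cfg, "SyntheticConfig"), "cfg must be a SyntheticConfig")
  set.seed(cfg$seed)
  nMulti <- cfg$nMulticopyLoci
  chromLen <- rep(cfg$genomeLength %/% cfg$nChromosomes,
                  cfg$nChromosomes)
  chromNames <- paste0("chr", seq_len(cfg$nChromosomes))
  chrom <- lapply(chromLen, function(n)
    strsplit(.randSeq(n, gc = 0.42), "")[[1]])
  names(chrom) <- chromNames

  # free-space bookkeeping per chromosome
  used <- lapply(chromLen, function(n) integer(0))
  names(used) <- chromNames
  placeSeq <- function(seqStr, chromPick = NULL) {
    len <- nchar(seqStr)
    for (try in 1:200) {
      chr <- if (is.null(chromPick)) sample(chromNames, 1) else chromPick
      s <- sample.int(length(chrom[[chr]]) - len - 2L, 1) + 1L
      span <- s:(s + len - 1L)
      if (!any(span %in% used[[chr]])) {
        chrom[[chr]][span] <<- strsplit(seqStr, "")[[1]]
        used[[chr]] <<- c(used[[chr]], (s - 10L):(s + len + 9L))
        return(list(chrom = chr, start = s, end = s + len - 1L))
      }
    }
    stop("genome too short to place requested loci")
  }

  truth <- list()
  addTruth <- function(rec) truth[[length(truth) + 1L]] <<- rec

  # known miRNA loci: bare mature sequences (no hairpin needed; they are
  # identified by reference matching, not structure)
  knownNames <- character(cfg$nKnownLoci)
  knownSeqs <- character(cfg$nKnownLoci)
  for (i in seq_len(cfg$nKnownLoci)) {
    nm <- if (i == 1 && cfg$nKnownLoci >= 2) "rno-let-7c"
          else if (i == 2) "rno-let-7f"
          else sprintf("rno-miR-%d", 100 + i)
    mat <- .randMature()
    loc <- placeSeq(mat)
    knownNames[i] <- nm; knownSeqs[i] <- mat
    addTruth(data.frame(locus_id = sprintf("known_%03d", i),
                        chrom = loc$chrom, start = loc$start,
                        end = loc$end, strand = "+", mature_seq = mat,
                        star_seq = NA_character_,
                        prec_start = NA_integer_, prec_end = NA_integer_,
                        arm = NA_character_, is_known = TRUE,
                        criteria_pass = NA, ref_name = nm,
                        stringsAsFactors = FALSE))
  }

  # novel hairpin loci (criteria-passing by design); each design is
  # verified by folding -- the truth label is defined by what the fold
  # sees -- and redrawn if the intended duplex geometry is not realised
  for (i in seq_len(cfg$nNovelLoci)) {
    arm <- if (i %% 2 == 1) "5p" else "3p"
    mm <- cfg$duplexMismatches[((i - 1) %% length(cfg$duplexMismatches)) + 1]
    for (try in 1:50) {
      mat <- .randMature()
      hp <- .designHairpin(mat, arm = arm, mismatches = mm)
      f <- foldHairpin(hp$precursor)
      gcf <- .gcFraction(hp$precursor)
      mfei <- computeMFEI(f$mfe, nchar(hp$precursor), gcf)
      d <- locateDuplex(f, hp$mature_start, hp$mature_end)
      if (isTRUE(d$ok) && d$arm == arm && d$mismatches == mm &&
          d$n_bulges == 0 && f$mfe <= -28 && !is.na(mfei) && mfei >= 0.95)
        break
      if (try == 50) stop("could not realise a designed hairpin")
    }
    strand <- sample(c("+", "-"), 1)
    # A/C buffers cannot base-pair among themselves, so the planted
    # hairpin does not extend into random genomic context
    buf <- 12L
    withBuf <- paste0(paste(sample(c("A", "C"), buf, replace = TRUE),
                            collapse = ""),
                      hp$precursor,
                      paste(sample(c("A", "C"), buf, replace = TRUE),
                            collapse = ""))
    planted <- if (strand == "+") withBuf else .revcomp(withBuf)
    loc <- placeSeq(planted)
    loc <- list(chrom = loc$chrom, start = loc$start + buf,
                end = loc$end - buf)
    if (strand == "+") {
      ms <- loc$start + hp$mature_start - 1L
      me <- loc$start + hp$mature_end - 1L
    } else {
      me <- loc$end - hp$mature_start + 1L
      ms <- loc$end - hp$mature_end + 1L
    }
    addTruth(data.frame(locus_id = sprintf("novel_%03d", i),
                        chrom = loc$chrom, start = ms, end = me,
                        strand = strand, mature_seq = mat,
                        star_seq = hp$star, prec_start = loc$start,
                        prec_end = loc$end, arm = arm, is_known = FALSE,
                        criteria_pass = TRUE, ref_name = NA_character_,
                        stringsAsFactors = FALSE))
    if (i == 1 && nMulti > 0) {
      # clustered extra copies of the same precursor on one chromosome
      cl <- sample(chromNames, 1)
      for (k in seq_len(nMulti)) {
        locK <- placeSeq(planted, chromPick = cl)
        locK <- list(chrom = locK$chrom, start = locK$start + buf,
                     end = locK$end - buf)
        if (strand == "+") {
          msK <- locK$start + hp$mature_start - 1L
          meK <- locK$start + hp$mature_end - 1L
        } else {
          meK <- locK$end - hp$mature_start + 1L
          msK <- locK$end - hp$mature_end + 1L
        }
        addTruth(data.frame(locus_id = sprintf("novel_%03d_copy%02d", i, k),
                            chrom = locK$chrom, start = msK, end = meK,
                            strand = strand, mature_seq = mat,
                            star_seq = hp$star, prec_start = locK$start,
                            prec_end = locK$end, arm = arm,
                            is_known = FALSE, criteria_pass = TRUE,
                            ref_name = NA_character_,
                            stringsAsFactors = FALSE))
      }
    }
  }

  # failing decoys: mapped mature tags with no hairpin context
  for (i in seq_len(cfg$nFailLoci)) {
    mat <- .randMature()
    loc <- placeSeq(mat)
    addTruth(data.frame(locus_id = sprintf("fail_%03d", i),
                        chrom = loc$chrom, start = loc$start,
                        end = loc$end, strand = "+", mature_seq = mat,
                        star_seq = NA_character_,
                        prec_start = NA_integer_, prec_end = NA_integer_,
                        arm = NA_character_, is_known = FALSE,
                        criteria_pass = FALSE, ref_name = NA_character_,
                        stringsAsFactors = FALSE))
  }
  truth <- do.call(rbind, truth)

  # non-miRNA loci + annotation; two sense tags per locus, plus an
  # antisense tag for exon/intron so the _antisense classes are populated
  annot <- list(); ncTags <- list()
  for (cls in names(cfg$ncrnaClassCounts)) {
    for (i in seq_len(cfg$ncrnaClassCounts[[cls]])) {
      len <- switch(cls, rRNA = 120L, tRNA = 75L, exon = 150L,
                    intron = 150L, `repeat` = 80L, 100L)
      locSeq <- .randSeq(len, gc = 0.5)
      strand <- sample(c("+", "-"), 1)
      loc <- placeSeq(locSeq)
      annot[[length(annot) + 1L]] <- data.frame(
        chrom = loc$chrom, start = loc$start, end = loc$end,
        strand = strand, class = cls, stringsAsFactors = FALSE)
      for (k in 1:2) {
        tl <- sample(.MATURE_LENS, 1, prob = .MATURE_LEN_P)
        off <- sample.int(len - tl, 1)
        frag <- substr(locSeq, off, off + tl - 1L)
        tagSeq <- if (strand == "+") frag else .revcomp(frag)
        ncTags[[length(ncTags) + 1L]] <- data.frame(
          tag = tagSeq, origin = cls, stringsAsFactors = FALSE)
      }
      if (cls %in% c("exon", "intron")) {
        tl <- sample(.MATURE_LENS, 1, prob = .MATURE_LEN_P)
        off <- sample.int(len - tl, 1)
        frag <- substr(locSeq, off, off + tl - 1L)
        tagSeq <- if (strand == "+") .revcomp(frag) else frag
        ncTags[[length(ncTags) + 1L]] <- data.frame(
          tag = tagSeq, origin = paste0(cls, "_antisense"),
          stringsAsFactors = FALSE)
      }
    }
  }
  ncTags <- if (length(ncTags)) do.call(rbind, ncTags) else
    data.frame(tag = character(0), origin = character(0),
               stringsAsFactors = FALSE)
  annot <- if (length(annot)) do.call(rbind, annot) else
    data.frame(chrom = character(0), start = integer(0),
               end = integer(0), strand = character(0),
               class = character(0), stringsAsFactors = FALSE)
  annotation <- GenomicRanges::GRanges(
    annot$chrom, IRanges::IRanges(annot$start, annot$end),
    strand = annot$strand, class = annot$class)

  genome <- Biostrings::DNAStringSet(
    vapply(chrom, paste, character(1), collapse = ""))
  names(genome) <- chromNames

  # truth labels are defined by what the novel module sees: re-evaluate
  # the structural criteria (c1-c5) for every planted miRNA-like locus
  # in its final genomic context
  ev <- !truth$is_known
  if (any(ev)) {
    evHits <- GenomicRanges::GRanges(
      truth$chrom[ev], IRanges::IRanges(truth$start[ev], truth$end[ev]),
      strand = truth$strand[ev], tag = truth$mature_seq[ev])
    evTags <- unique(truth$mature_seq[ev])
    evTS <- TagSet(evTags, matrix(10L, length(evTags), 1,
                                  dimnames = list(evTags, "eval")))
    cands <- predictNovel(evTS, evHits, genome)$candidates
    key <- paste(cands$tag, cands$chrom, cands$strand,
                 cands$mature_gstart)
    tkey <- paste(truth$mature_seq, truth$chrom, truth$strand,
                  truth$start)
    truth$criteria_pass[ev] <-
      cands$locus_pass[match(tkey[ev], key)] %in% TRUE
  }

  # junk tags: clean, unmappable
  junk <- character(cfg$nJunkTags)
  for (i in seq_len(cfg$nJunkTags)) {
    repeat {
      x <- .randMature()
      hit <- any(Biostrings::vcountPattern(x, genome) > 0) ||
             any(Biostrings::vcountPattern(.revcomp(x), genome) > 0)
      if (!hit && !x %in% junk) { junk[i] <- x; break }
    }
  }

  # mature reference: planted rno entries, other-species duplicates for
  # every third entry, and unplanted decoys
  ref <- data.frame(name = knownNames, seq = knownSeqs,
                    stringsAsFactors = FALSE)
  dup <- if (cfg$nKnownLoci >= 3) seq(3L, cfg$nKnownLoci, by = 3L)
         else integer(0)
  if (length(dup))
    ref <- rbind(ref, data.frame(
      name = sub("^rno-", "hsa-", knownNames[dup]),
      seq = knownSeqs[dup], stringsAsFactors = FALSE))
  ref <- rbind(ref, data.frame(
    name = sprintf("hsa-miR-d%02d", 1:3),
    seq = vapply(1:3, function(i) .randMature(), character(1)),
    stringsAsFactors = FALSE))
  ref$species <- sub("^([a-z]{3})-.*$", "\\1", ref$name)
  ref <- ref[, c("name", "species", "seq")]

  abundance <- .assignAbundance(cfg, truth, ncTags, junk)
  structure(list(genome = genome, truth = truth,
                 annotation = annotation, reference = ref,
                 abundance = abundance, config = cfg),
            class = "SynthBundle")
}

# per unique tag: origin, log2fc, condition-specific flag, expected
# per-library counts (exact apportionment of the deterministic clean
# total)
.assignAbundance <- function(cfg, truth, ncTags, junk) {
  mi <- truth[!duplicated(truth$mature_seq), , drop = FALSE]
  tags <- data.frame(tag = mi$mature_seq,
                     origin = ifelse(mi$is_known, "known",
                                     ifelse(mi$criteria_pass %in% TRUE,
                                            "novel", "fail")),
                     locus_id = mi$locus_id, stringsAsFactors = FALSE)
  tags <- rbind(tags,
                data.frame(tag = ncTags$tag, origin = ncTags$origin,
                           locus_id = rep(NA_character_, nrow(ncTags)),
                           stringsAsFactors = FALSE),
                data.frame(tag = junk, origin = rep("junk", length(junk)),
                           locus_id = rep(NA_character_, length(junk)),
                           stringsAsFactors = FALSE))
  tags <- tags[!duplicated(tags$tag), , drop = FALSE]
  miRNA <- tags$origin %in% c("known", "novel", "fail")
  lo <- log(cfg$abundanceRange[1]); hi <- log(cfg$abundanceRange[2])
  nlo <- log(cfg$ncrnaAbundanceRange[1]); nhi <- log(cfg$ncrnaAbundanceRange[2])
  tags$base <- ifelse(miRNA, exp(runif(nrow(tags), lo, hi)),
                      exp(runif(nrow(tags), nlo, nhi)))
  tags$base[tags$origin == "junk"] <- runif(sum(tags$origin == "junk"),
                                            5, 20)
  tags$log2fc <- 0
  tags$condition_specific <- FALSE
  if (!is.null(cfg$foldChanges)) {
    fc <- cfg$foldChanges
    m <- match(tags$locus_id, fc$locus_id)
    tags$log2fc[!is.na(m)] <- fc$log2fc[m[!is.na(m)]]
    if (!is.null(fc$condition_specific))
      tags$condition_specific[!is.na(m)] <-
        fc$condition_specific[m[!is.na(m)]]
  } else {
    kn <- which(tags$origin == "known")
    nde <- length(kn) %/% 4
    if (nde > 0)
      tags$log2fc[kn[seq_len(nde)]] <- rep(c(2, -2), length.out = nde)
    nv <- which(tags$origin == "novel")
    if (length(nv)) {
      tags$condition_specific[nv[length(nv)]] <- TRUE
      tags$log2fc[nv[length(nv)]] <- NA  # defined by absence in library 2
    }
  }
  # expected counts: clean total per library after deterministic
  # contaminant apportionment, split by effective weights
  contam <- round(cfg$contaminantFractions * cfg$readsPerLibrary)
  nClean <- cfg$readsPerLibrary - sum(contam)
  for (li in seq_along(cfg$libraries)) {
    lfc <- ifelse(is.na(tags$log2fc), 0, tags$log2fc)
    w <- tags$base * 2^(if (li == 1) lfc / 2 else -lfc / 2)
    if (li == 2) w[tags$condition_specific] <- 0
    cts <- .apportion(w, nClean)
    tags[[paste0("count_", cfg$libraries[li])]] <- cts
  }
  rownames(tags) <- NULL
  tags
}

#' Simulate one library's raw FASTQ reads
#'
#' Emits `readsPerLibrary` raw reads for one condition: clean reads are
#' `insert + 3' adapter` truncated to the read length with Q40 bases;
#' contaminant classes are injected at their configured fractions
#' (low-quality reads with >20% of bases below Q10, reads starting with
#' the 5' adapter, reads without the 3' adapter, polyA inserts, and
#' sub-18 nt inserts).  Per-tag clean counts are the expected counts in
#' deterministic mode, or a multinomial draw around them otherwise.
#'
#' @param cfg A [syntheticConfig()].
#' @param bundle A `SynthBundle` from [buildGenome()].
#' @param condition One of `cfg$libraries`.
#' @return A [Biostrings::QualityScaledDNAStringSet] of raw reads.
#' @export
simulateLibrary <- function(cfg, bundle, condition) {
  .stopIfNot(condition %in% cfg$libraries,
             paste("unknown condition label:", condition))
  ab <- bundle$abundance
  .stopIfNot(nrow(ab) > 0, "empty truth/abundance")
  li <- match(condition, cfg$libraries)
  set.seed(cfg$seed + 7919L * li)
  counts <- drawLibraryCounts(ab, condition,
                              deterministic = cfg$deterministicCounts)
  contam <- round(cfg$contaminantFractions * cfg$readsPerLibrary)
  if (!cfg$deterministicCounts) {
    # stochastic contaminant totals, keeping the grand total fixed
    pc <- cfg$contaminantFractions
    draw <- rmultinom(1, cfg$readsPerLibrary, c(pc, clean = 1 - sum(pc)))
    contam <- draw[seq_along(pc), 1]
    names(contam) <- names(pc)
  }
  inserts <- rep(ab$tag, counts)
  reads <- character(0); quals <- character(0)
  mk <- function(insert) substr(paste0(insert, cfg$adapter3,
                                       strrep("A", cfg$readLength)),
                                1, cfg$readLength)
  if (length(inserts)) {
    reads <- vapply(inserts, mk, character(1), USE.NAMES = FALSE)
    quals <- rep(strrep("I", cfg$readLength), length(reads))
  }
  addRead <- function(seq, qual) {
    reads[length(reads) + 1L] <<- seq
    quals[length(quals) + 1L] <<- qual
  }
  lowQual <- function() {
    q <- rep("I", cfg$readLength)
    q[seq(1, cfg$readLength, by = 3)] <- "#"   # a third of bases at Q2
    paste(q, collapse = "")
  }
  hiQual <- strrep("I", cfg$readLength)
  # low-quality inserts are drawn from tags expressed in this library,
  # so condition-specific absence stays absolute
  lowPool <- ab$tag[counts > 0]
  for (k in seq_len(contam[["low_quality"]]))
    addRead(mk(if (length(lowPool)) sample(lowPool, 1)
               else .randSeq(22, 0.5)), lowQual())
  for (k in seq_len(contam[["no_3adapter"]])) {
    repeat {
      x <- .randSeq(cfg$readLength, 0.5)
      if (!grepl(substr(cfg$adapter3, 1, 6), x, fixed = TRUE)) break
    }
    addRead(x, hiQual)
  }
  for (k in seq_len(contam[["adapter_dimer"]]))
    addRead(mk(paste0(cfg$adapter5, cfg$adapter3)), hiQual)
  for (k in seq_len(contam[["polyA"]]))
    addRead(mk(strrep("A", sample(18:25, 1))), hiQual)
  for (k in seq_len(contam[["short_insert"]]))
    addRead(mk(paste0("C", .randSeq(sample(9:15, 1), 0.5))), hiQual)
  ord <- sample.int(length(reads))
  reads <- reads[ord]; quals <- quals[ord]
  out <- Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(reads),
    Biostrings::PhredQuality(quals))
  names(out) <- sprintf("%s_read_%06d", condition, seq_along(reads))
  out
}

#' Draw per-tag clean-read counts for one library
#'
#' The count layer of the simulator, exposed separately so count-level
#' properties (null false-positive rate, detection power) can be studied
#' without assembling reads.  Deterministic mode returns the expected
#' counts exactly; stochastic mode draws a multinomial with the expected
#' counts as weights.
#'
#' @param abundance The `abundance` table of a `SynthBundle`.
#' @param condition Library label (an expected-count column must exist).
#' @param deterministic Exact expected counts instead of a draw.
#' @return Integer vector of counts parallel to `abundance` rows.
#' @export
drawLibraryCounts <- function(abundance, condition,
                              deterministic = FALSE) {
  col <- paste0("count_", condition)
  .stopIfNot(col %in% colnames(abundance),
             paste("unknown condition label:", condition))
  exp <- abundance[[col]]
  if (deterministic) return(as.integer(exp))
  tot <- sum(exp)
  if (tot == 0) return(integer(length(exp)))
  as.integer(rmultinom(1, tot, exp / tot)[, 1])
}

#' Write a synthetic bundle to disk
#'
#' Writes the genome FASTA, annotation as BED and GFF3, the mature
#' reference FASTA (miRBase-style headers), the planted-truth TSV, and
#' one FASTQ per library.
#'
#' @param bundle A `SynthBundle`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named list of file paths.
#' @export
writeSynthBundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- bundle$config
  paths <- list(genome = file.path(dir, "genome.fa"),
                bed = file.path(dir, "annotation.bed"),
                gff = file.path(dir, "annotation.gff3"),
                reference = file.path(dir, "mature.fa"),
                truth = file.path(dir, "truth.tsv"))
  Biostrings::writeXStringSet(bundle$genome, paths$genome)
  gr <- bundle$annotation
  gr$name <- gr$class
  gr$score <- 0L
  rtracklayer::export(gr, paths$bed, format = "BED")
  gff <- gr
  gff$type <- gff$class
  rtracklayer::export(gff, paths$gff, format = "GFF3")
  ref <- Biostrings::DNAStringSet(setNames(bundle$reference$seq,
                                           bundle$reference$name))
  Biostrings::writeXStringSet(ref, paths$reference)
  write.table(bundle$truth, paths$truth, sep = "\t", quote = FALSE,
              row.names = FALSE)
  for (lib in cfg$libraries) {
    p <- file.path(dir, paste0(lib, ".fastq"))
    writeFastq(simulateLibrary(cfg, bundle, lib), p)
    paths[[lib]] <- p
  }
  invisible(paths)
}
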