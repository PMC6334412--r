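# hand-built hairpin: 5' ext . mature . loop . revcomp(mature[1:20]) .
# 2-nt tail, so the mature/star duplex is perfect with 2-nt 3' overhangs
mkHairpin <- function(mature, ext = "GGCGCGCGGCGC", loop = "CAACACAACACAA") {
  stem <- substr(mature, 1, nchar(mature) - 2)
  star <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(stem)))
  list(seq = paste0(ext, mature, loop, star, "AC",
                    as.character(Biostrings::reverseComplement(
                      Biostrings::DNAStringSet(ext)))),
       mature_start = nchar(ext) + 1L,
       mature_end = nchar(ext) + nchar(mature),
       star = paste0(star, "AC"))
}

test_that("candidate windows flank the hit on both sides and clip at ends", {
  g <- Biostrings::DNAStringSet(c(chr1 = randomSeq(500)))
  hit <- GenomicRanges::GRanges("chr1", IRanges::IRanges(240, 261), "+",
                                tag = substr(as.character(g[[1]]), 240, 261))
  w <- extractCandidates(hit, g)
  expect_equal(length(w), 2)
  expect_true(all(vapply(seq_along(w), function(i)
    grepl(hit$tag, w$precursor[i], fixed = TRUE), logical(1))))
  # near the chromosome start the upstream window is clipped but valid
  hit2 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(5, 26), "+",
                                 tag = substr(as.character(g[[1]]), 5, 26))
  w2 <- extractCandidates(hit2, g)
  expect_true(all(start(w2) >= 1))
  expect_error(extractCandidates(
    GenomicRanges::GRanges("chr1", IRanges::IRanges(490, 511), "+",
                           tag = strrep("A", 22)), g), "bounds")
})

test_that("a planted hairpin window contains the full precursor", {
  run <- sharedRun()
  tr <- run$bundle$truth
  tr <- tr[grepl("^novel", tr$locus_id) & tr$criteria_pass, ][1, ]
  hit <- GenomicRanges::GRanges(tr$chrom, IRanges::IRanges(tr$start, tr$end),
                                tr$strand, tag = tr$mature_seq)
  w <- extractCandidates(hit, run$bundle$genome)
  covers <- start(w) <= tr$prec_start & end(w) >= tr$prec_end
  expect_true(any(covers))
})

test_that("duplex geometry recovers a perfect star with 2-nt 3' overhangs", {
  # mature starts A/C so the star's 3'-overhang tail cannot pair with it
  mat <- "ACGTACCGGTTCAGCATCCAAC"
  hp <- mkHairpin(mat)
  f <- foldHairpin(hp$seq)
  d <- locateDuplex(f, hp$mature_start, hp$mature_end)
  expect_true(d$ok)
  expect_equal(d$arm, "5p")
  expect_equal(d$mismatches, 0L)
  expect_equal(d$n_bulges, 0L)
  expect_equal(substr(hp$seq, d$star_start, d$star_end), hp$star)
})

test_that("planted star sequences are recovered exactly from the simulator", {
  run <- sharedRun()
  tr <- run$bundle$truth
  tr <- tr[grepl("^novel_[0-9]+$", tr$locus_id) & tr$criteria_pass, ]
  g <- run$bundle$genome
  for (i in seq_len(nrow(tr))) {
    prec <- as.character(Biostrings::subseq(g[[tr$chrom[i]]],
                                            tr$prec_start[i], tr$prec_end[i]))
    if (tr$strand[i] == "-")
      prec <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(prec)))
    ms <- regexpr(tr$mature_seq[i], prec, fixed = TRUE)
    f <- foldHairpin(prec)
    d <- locateDuplex(f, ms, ms + nchar(tr$mature_seq[i]) - 1L)
    expect_true(d$ok, info = tr$locus_id[i])
    ss <- max(1L, d$star_start); se <- min(nchar(prec), d$star_end)
    expect_equal(substr(prec, ss, se), tr$star_seq[i],
                 info = tr$locus_id[i])
  }
})

test_that("a mature spanning the terminal loop is rejected", {
  mat <- "ACGTACCGGTTCAGCATCCAAC"
  hp <- mkHairpin(mat)
  f <- foldHairpin(hp$seq)
  mid <- hp$mature_end + 4L   # sits across the loop apex
  d <- locateDuplex(f, mid, mid + 21L)
  expect_false(d$ok)
  expect_equal(d$reason, "spans_loop")
})

test_that("the six criteria gate at their exact inclusive thresholds", {
  base <- list(mfe = -40, mfei = 1.2, arm_ok = TRUE, mismatches = 0,
               n_bulges = 0, max_bulge = 0, read_count = 100)
  pass <- do.call(evaluateCriteria, base)
  expect_true(pass$accept)
  at <- do.call(evaluateCriteria,
                modifyList(base, list(mfe = -25.0, mfei = 0.85,
                                      mismatches = 4, n_bulges = 1,
                                      max_bulge = 1, read_count = 5)))
  expect_true(at$accept)
  expect_false(do.call(evaluateCriteria,
                       modifyList(base, list(mfe = -24.99)))$c1)
  expect_false(do.call(evaluateCriteria,
                       modifyList(base, list(mfe = -20)))$accept)
  expect_false(do.call(evaluateCriteria,
                       modifyList(base, list(mfei = 0.8499)))$c2)
  expect_false(do.call(evaluateCriteria,
                       modifyList(base, list(arm_ok = FALSE)))$c3)
  expect_false(do.call(evaluateCriteria,
                       modifyList(base, list(mismatches = 5)))$c4)
  expect_false(do.call(evaluateCriteria,
                       modifyList(base, list(n_bulges = 2)))$c5)
  expect_false(do.call(evaluateCriteria,
                       modifyList(base, list(n_bulges = 1,
                                             max_bulge = 2)))$c5)
  expect_false(do.call(evaluateCriteria,
                       modifyList(base, list(read_count = 4)))$c6)
})

test_that("multi-locus candidates merge without double-counting reads", {
  cand <- data.frame(
    tag = rep(strrep("AG", 11), 11), chrom = "chr17", strand = "-",
    mature_gstart = seq(1000, 3000, length.out = 11),
    prec_start = seq(950, 2950, length.out = 11),
    prec_end = seq(1040, 3040, length.out = 11), prec_len = 91L,
    mfe = -40, gc = 0.5, mfei = 1.0, arm = "5p", mismatches = 0L,
    n_bulges = 0L, max_bulge = 0L, c1 = TRUE, c2 = TRUE, c3 = TRUE,
    c4 = TRUE, c5 = TRUE, c6 = TRUE, locus_pass = TRUE, accept = TRUE,
    stringsAsFactors = FALSE)
  counts <- cbind(HIST = 230L, NC = 117L)
  rownames(counts) <- strrep("AG", 11)
  merged <- mergeMultilocus(cand, counts)
  expect_equal(nrow(merged), 1)
  expect_equal(merged$n_loci, 11L)
  expect_equal(merged$HIST, 230L)    # counted once, not 11x
  expect_equal(merged$NC, 117L)
  expect_match(merged$name, "^rno-miR-n001_5p$")
  # two distinct matures give two records
  cand2 <- cand[1:2, ]; cand2$tag[2] <- strrep("CT", 11)
  counts2 <- rbind(counts, matrix(c(40L, 9L), 1,
                                  dimnames = list(strrep("CT", 11), NULL)))
  colnames(counts2) <- c("HIST", "NC")
  expect_equal(nrow(mergeMultilocus(cand2, counts2)), 2)
})

test_that("raising the MFEI threshold never grows the accepted set", {
  run <- sharedRun()
  cand <- run$run$candidates
  counts <- tagCounts(run$run$tags)
  sets <- lapply(c(0.5, 0.85, 1.2), function(th) {
    cand2 <- cand
    cand2$c2 <- !is.na(cand2$mfei) & cand2$mfei >= th
    cand2$locus_pass <- cand2$c1 & cand2$c2 & cand2$c3 & cand2$c4 & cand2$c5
    mergeMultilocus(cand2, counts,
                    novelThresholds(mfei = th))$seq
  })
  expect_true(all(sets[[2]] %in% sets[[1]]))
  expect_true(all(sets[[3]] %in% sets[[2]]))
})

test_that("accepted candidates satisfy the MFEI identity and length band", {
  run <- sharedRun()
  cand <- run$run$candidates
  ok <- cand[cand$locus_pass %in% TRUE, ]
  expect_gt(nrow(ok), 0)
  expect_equal(ok$mfei,
               (-ok$mfe * 100 / ok$prec_len) / (ok$gc * 100),
               tolerance = 1e-9)
  expect_true(all(run$run$novel$in_band))
})
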