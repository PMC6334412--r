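# naive exact-match scan used as mapping oracle
naiveHits <- function(tag, genome) {
  out <- list()
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(tag)))
  for (chr in names(genome)) {
    s <- as.character(genome[[chr]])
    L <- nchar(tag)
    for (p in seq_len(nchar(s) - L + 1)) {
      w <- substr(s, p, p + L - 1)
      if (w == tag) out[[length(out) + 1]] <- c(chr, p, "+")
      if (w == rc) out[[length(out) + 1]] <- c(chr, p, "-")
    }
  }
  out
}

test_that("index lookup finds planted substrings on both strands", {
  set.seed(9)
  g <- Biostrings::DNAStringSet(c(chrA = randomSeq(100)))
  idx <- buildGenomeIndex(g)
  q <- substr(as.character(g[[1]]), 10, 31)
  hits <- mapTags(q, idx)$hits
  fwd <- hits[as.character(strand(hits)) == "+"]
  expect_true(any(start(fwd) == 10 & end(fwd) == 31))
  rcq <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(q)))
  hits2 <- mapTags(rcq, idx)$hits
  rev <- hits2[as.character(strand(hits2)) == "-"]
  expect_true(any(start(rev) == 10 & end(rev) == 31))
  expect_error(buildGenomeIndex(
    Biostrings::DNAStringSet(c(a = "ACGT", a = "ACGT"))), "duplicate")
})

test_that("index hits equal a naive string scan on a small genome", {
  set.seed(21)
  g <- Biostrings::DNAStringSet(c(c1 = randomSeq(2000), c2 = randomSeq(1500)))
  idx <- buildGenomeIndex(g)
  tags <- c(substr(as.character(g[[1]]), 100, 121),
            substr(as.character(g[[2]]), 7, 31),
            as.character(Biostrings::reverseComplement(
              Biostrings::DNAStringSet(substr(as.character(g[[1]]), 500, 523)))),
            randomSeq(25))
  hits <- mapTags(tags, idx)$hits
  for (tg in tags) {
    exp <- naiveHits(tg, g)
    got <- hits[hits$tag == tg]
    expect_equal(length(got), length(exp), info = tg)
    if (length(exp)) {
      expKey <- sort(vapply(exp, paste, "", collapse = ":"))
      gotKey <- sort(paste(as.character(seqnames(got)), start(got),
                           as.character(strand(got)), sep = ":"))
      expect_equal(gotKey, expKey, info = tg)
    }
  }
})

test_that("class assignment follows the priority order", {
  ann <- GenomicRanges::GRanges(
    c("c1", "c1", "c1", "c1"),
    IRanges::IRanges(c(100, 100, 300, 500), c(200, 200, 400, 600)),
    strand = c("+", "+", "+", "+"),
    class = c("rRNA", "repeat", "exon", "exon"))
  hits <- GenomicRanges::GRanges(
    c("c1", "c1", "c1"),
    IRanges::IRanges(c(150, 350, 550), width = 22),
    strand = c("+", "+", "-"),
    tag = c(strrep("AC", 11), strrep("AG", 11), strrep("AT", 11)))
  cls <- assignClass(c(strrep("AC", 11), strrep("AG", 11), strrep("AT", 11),
                       strrep("CA", 11)), hits, ann)
  expect_equal(unname(cls[strrep("AC", 11)]), "rRNA")       # beats repeat
  expect_equal(unname(cls[strrep("AG", 11)]), "exon_sense")
  expect_equal(unname(cls[strrep("AT", 11)]), "exon_antisense")
  expect_equal(unname(cls[strrep("CA", 11)]), "unannotated")
  expect_error(assignClass(strrep("AC", 11), hits,
                           GenomicRanges::GRanges("c1", IRanges::IRanges(1, 9),
                                                  class = "mystery")),
               "unknown class")
})

test_that("category summary partitions unique tags and reads exactly", {
  ts <- TagSet(c(strrep("AC", 11), strrep("AG", 11)),
               cbind(L1 = c(5L, 0L), L2 = c(3L, 7L)))
  cls <- setNames(c("tRNA", "unannotated"),
                  c(strrep("AC", 11), strrep("AG", 11)))
  cs <- categorySummary(ts, cls)
  t1 <- cs[cs$class == "tRNA", ]
  expect_equal(t1$L1_unique, 1L)
  expect_equal(t1$L1_unique_pct, 100)
  expect_equal(t1$L1_reads, 5L)
  expect_equal(t1$L1_reads_pct, 100)
  expect_equal(cs[cs$class == "unannotated", "L2_reads_pct"], 70)
  expect_equal(sum(cs$L2_reads), 10L)
  expect_equal(sum(cs$L2_unique), 2L)
})

test_that("pipeline category partition conserves all clean reads", {
  run <- sharedRun()
  cs <- run$run$category
  tot <- libraryTotals(run$run$tags)
  expect_equal(sum(cs$HIST_reads), unname(tot["HIST"]))
  expect_equal(sum(cs$NC_reads), unname(tot["NC"]))
  expect_equal(sum(cs$HIST_reads_pct), 100, tolerance = 1e-9)
})

test_that("fully planted tag sets map completely", {
  cfg <- syntheticConfig(nJunkTags = 0L, readsPerLibrary = 2000L,
                         deterministicCounts = TRUE, seed = 11L)
  b <- buildGenome(cfg)
  ts <- TagSet(b$abundance$tag,
               cbind(HIST = pmax(b$abundance$count_HIST, 1L)))
  idx <- buildGenomeIndex(b$genome)
  mp <- mapTags(ts, idx)
  expect_equal(mp$summary$read_fraction, 1)
  # a multi-copy tag reports one hit per locus
  cfgM <- syntheticConfig(nMulticopyLoci = 10L, readsPerLibrary = 2000L,
                          deterministicCounts = TRUE, seed = 12L)
  bM <- buildGenome(cfgM)
  mat <- bM$truth$mature_seq[bM$truth$locus_id == "novel_001"]
  hits <- mapTags(mat, buildGenomeIndex(bM$genome))$hits
  expect_equal(length(hits), 11L)
})
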