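noContam <- c(low_quality = 0, no_3adapter = 0, adapter_dimer = 0,
              polyA = 0, short_insert = 0)
noNc <- c(rRNA = 0L, tRNA = 0L, scRNA = 0L, snRNA = 0L, snoRNA = 0L,
          srpRNA = 0L, exon = 0L, intron = 0L, `repeat` = 0L)

test_that("configuration invariants are enforced", {
  expect_error(syntheticConfig(contaminantFractions = c(
    low_quality = 0.5, no_3adapter = 0.3, adapter_dimer = 0.1,
    polyA = 0.1, short_insert = 0.1)), "sum")
  expect_error(syntheticConfig(ncrnaClassCounts = c(rRNA = 1L)), "class")
  cfg <- syntheticConfig()
  b <- buildGenome(cfg)
  expect_error(simulateLibrary(cfg, b, "MYSTERY"), "unknown condition")
})

test_that("generation is deterministic given the seed", {
  cfg <- syntheticConfig(readsPerLibrary = 500L, genomeLength = 20000L,
                         seed = 88L)
  b1 <- buildGenome(cfg); b2 <- buildGenome(cfg)
  expect_identical(as.character(b1$genome), as.character(b2$genome))
  expect_identical(b1$truth, b2$truth)
  r1 <- simulateLibrary(cfg, b1, "HIST")
  r2 <- simulateLibrary(cfg, b2, "HIST")
  expect_identical(as.character(r1), as.character(r2))
  d1 <- file.path(tempdir(), "det1"); d2 <- file.path(tempdir(), "det2")
  writeSynthBundle(b1, d1); writeSynthBundle(b2, d2)
  expect_identical(readLines(file.path(d1, "genome.fa")),
                   readLines(file.path(d2, "genome.fa")))
  expect_identical(readLines(file.path(d1, "HIST.fastq")),
                   readLines(file.path(d2, "HIST.fastq")))
})

test_that("a perfect single hairpin is planted with zero designed defects", {
  cfg <- syntheticConfig(nKnownLoci = 0L, nNovelLoci = 1L, nFailLoci = 0L,
                         nJunkTags = 0L, ncrnaClassCounts = noNc,
                         duplexMismatches = 0L, readsPerLibrary = 200L,
                         genomeLength = 15000L, seed = 4L,
                         contaminantFractions = noContam,
                         deterministicCounts = TRUE)
  b <- buildGenome(cfg)
  tr <- b$truth[b$truth$locus_id == "novel_001", ]
  expect_true(tr$criteria_pass)
  prec <- as.character(Biostrings::subseq(b$genome[[tr$chrom]],
                                          tr$prec_start, tr$prec_end))
  if (tr$strand == "-")
    prec <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(prec)))
  ms <- regexpr(tr$mature_seq, prec, fixed = TRUE)
  d <- locateDuplex(foldHairpin(prec), ms, ms + nchar(tr$mature_seq) - 1L)
  expect_equal(d$mismatches, 0L)
  expect_equal(d$n_bulges, 0L)
})

test_that("multi-copy loci share one mature sequence across 11 sites", {
  cfg <- syntheticConfig(nMulticopyLoci = 10L, readsPerLibrary = 500L,
                         seed = 7L)
  b <- buildGenome(cfg)
  fam <- b$truth[grepl("^novel_001", b$truth$locus_id), ]
  expect_equal(nrow(fam), 11)
  expect_equal(length(unique(fam$mature_seq)), 1)
  expect_equal(length(unique(fam$chrom[-1])), 1)   # copies cluster
})

test_that("mature and star sequences are substrings of their locus strand", {
  run <- sharedRun()
  tr <- run$bundle$truth
  tr <- tr[grepl("^novel", tr$locus_id), ]
  g <- run$bundle$genome
  for (i in seq_len(nrow(tr))) {
    prec <- as.character(Biostrings::subseq(g[[tr$chrom[i]]],
                                            tr$prec_start[i],
                                            tr$prec_end[i]))
    if (tr$strand[i] == "-")
      prec <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(prec)))
    expect_true(grepl(tr$mature_seq[i], prec, fixed = TRUE),
                info = tr$locus_id[i])
    expect_true(grepl(tr$star_seq[i], prec, fixed = TRUE),
                info = tr$locus_id[i])
  }
})

test_that("deterministic counts conserve reads exactly", {
  cfg <- syntheticConfig(nKnownLoci = 1L, nNovelLoci = 0L, nFailLoci = 0L,
                         nJunkTags = 0L, ncrnaClassCounts = noNc,
                         contaminantFractions = noContam,
                         readsPerLibrary = 100L, genomeLength = 10000L,
                         deterministicCounts = TRUE, seed = 13L)
  b <- buildGenome(cfg)
  reads <- simulateLibrary(cfg, b, "HIST")
  expect_equal(length(reads), 100L)
  mat <- b$truth$mature_seq[1]
  expect_equal(sum(startsWith(as.character(reads), mat)), 100L)
})

test_that("polyA contamination is injected at its binomial rate", {
  cfg <- syntheticConfig(
    readsPerLibrary = 1000L,
    contaminantFractions = c(low_quality = 0, no_3adapter = 0,
                             adapter_dimer = 0, polyA = 0.1,
                             short_insert = 0),
    deterministicCounts = FALSE, seed = 19L)
  b <- buildGenome(cfg)
  reads <- simulateLibrary(cfg, b, "HIST")
  out <- filterAndTrim(reads, cfg$adapter3, cfg$adapter5)
  npoly <- unname(out$report@dropped[["polyA"]])
  sd3 <- 3 * sqrt(1000 * 0.1 * 0.9)
  expect_gt(npoly, 100 - sd3)
  expect_lt(npoly, 100 + sd3)
})

test_that("condition-specific loci are absent from the control library", {
  run <- sharedRun()
  ab <- run$bundle$abundance
  cs <- ab[ab$condition_specific, ]
  expect_gt(nrow(cs), 0)
  expect_true(all(cs$count_NC == 0))
  expect_true(all(cs$count_HIST > 0))
  ncReads <- simulateLibrary(run$cfg, run$bundle, "NC")
  expect_equal(sum(startsWith(as.character(ncReads), cs$tag[1])), 0L)
})
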