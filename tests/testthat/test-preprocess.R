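insert22 <- "ACGTACGTACGTACGTACGTAC"

test_that("the filtering cascade drops each contaminant for its own reason", {
  reads <- makeReads(c(
    paste0(insert22, ADAPTER3),                      # clean
    paste0(substr(ADAPTER5, 1, 12), ADAPTER3),       # 5' contaminant
    strrep("ACGT", 9),                               # no 3' adapter
    paste0(ADAPTER3, "ACGTACGTACGTACG"),             # no insert
    paste0(strrep("A", 20), ADAPTER3),               # polyA
    paste0("ACGTACGTACG", ADAPTER3, "AAAAA")),       # 11 nt insert
    quals = NULL)
  lowq <- paste0(insert22, ADAPTER3)
  reads <- c(reads, makeReads(lowq, strrep("#", nchar(lowq))))
  out <- filterAndTrim(reads, ADAPTER3, ADAPTER5, library = "t")
  rep <- out$report
  expect_equal(rep@rawReads, 7)
  expect_equal(rep@cleanReads, 1)
  expect_equal(unname(rep@dropped[c("low_quality", "adapter5_contaminant",
                                    "no_3adapter", "no_insert", "polyA",
                                    "too_short")]),
               c(1, 1, 1, 1, 1, 1))
  expect_equal(out$tags$seq, insert22)
  expect_equal(nchar(out$tags$seq), 22)
  # conservation is enforced by the FilterReport validity
  expect_true(validObject(rep))
})

test_that("inserts longer than 30 nt are length-filtered", {
  long <- paste0(strrep("ACGTC", 7), ADAPTER3)  # 35 nt insert
  out <- filterAndTrim(makeReads(long), ADAPTER3, ADAPTER5)
  expect_equal(unname(out$report@dropped[["too_short"]]), 1)
  expect_equal(out$report@cleanReads, 0)
})

test_that("collapse preserves counts and orders by abundance", {
  a <- strrep("AC", 9); b <- strrep("GT", 9)
  out <- collapseTags(c(a, a, a, b, b))
  expect_equal(out$seq, c(a, b))
  expect_equal(out$count, c(3L, 2L))
  empty <- collapseTags(character(0))
  expect_equal(nrow(empty), 0)
})

test_that("simulated clean reads collapse exactly to the planted tags", {
  cfg <- syntheticConfig(
    readsPerLibrary = 1000L, nKnownLoci = 10L, nNovelLoci = 0L,
    nFailLoci = 0L, nJunkTags = 0L,
    ncrnaClassCounts = c(rRNA = 0L, tRNA = 0L, scRNA = 0L, snRNA = 0L,
                         snoRNA = 0L, srpRNA = 0L, exon = 0L,
                         intron = 0L, `repeat` = 0L),
    contaminantFractions = c(low_quality = 0, no_3adapter = 0,
                             adapter_dimer = 0, polyA = 0,
                             short_insert = 0),
    deterministicCounts = TRUE, seed = 5L)
  b <- buildGenome(cfg)
  reads <- simulateLibrary(cfg, b, "HIST")
  expect_equal(length(reads), 1000L)
  out <- filterAndTrim(reads, cfg$adapter3, cfg$adapter5)
  expect_equal(nrow(out$tags), 10)
  expect_equal(sum(out$tags$count), 1000L)
  expect_setequal(out$tags$seq, b$abundance$tag)
})

test_that("filtering clean tags again (re-adaptered) drops nothing", {
  run <- sharedRun()
  tags <- run$run$tags
  again <- filterAndTrim(
    makeReads(paste0(tagSeq(tags), ADAPTER3)), ADAPTER3, ADAPTER5)
  expect_equal(sum(again$report@dropped), 0)
  expect_equal(again$report@cleanReads, length(tagSeq(tags)))
})

test_that("length distribution is read-weighted and sums to one", {
  one <- lengthDistribution(data.frame(seq = strrep("A", 22), count = 5))
  expect_equal(one, data.frame(length = 22L, count = 5L, fraction = 1))
  two <- lengthDistribution(data.frame(seq = c(strrep("A", 20), strrep("C", 22)),
                                       count = c(1L, 3L)))
  expect_equal(two$fraction[two$length == 22], 0.75)
  expect_equal(sum(two$fraction), 1, tolerance = 1e-12)
  expect_equal(nrow(lengthDistribution(data.frame(seq = character(0),
                                                  count = integer(0)))), 0)
})

test_that("pipeline length profile equals the planted truth exactly", {
  run <- sharedRun()
  ab <- run$bundle$abundance
  expected <- tapply(ab$count_HIST, nchar(ab$tag), sum)
  got <- lengthDistribution(run$run$tags, library = "HIST")
  expect_equal(got$count[match(names(expected), got$length)],
               unname(as.integer(expected)))
})

test_that("common/specific library comparison partitions tags and reads", {
  idA <- TagSet(c(strrep("AC", 10), strrep("GT", 10)),
                cbind(A = c(2L, 1L), B = c(2L, 1L)))
  cmpA <- compareLibraries(idA)
  expect_equal(cmpA$unique_fraction[cmpA$set == "common"], 1)
  expect_equal(cmpA$read_fraction[cmpA$set == "common"], 1)

  dis <- TagSet(c(strrep("AC", 10), strrep("GT", 10)),
                cbind(A = c(2L, 0L), B = c(0L, 1L)))
  cmpD <- compareLibraries(dis)
  expect_equal(cmpD$unique_tags[cmpD$set == "common"], 0L)

  x <- strrep("AC", 10); y <- strrep("GT", 10); z <- strrep("TG", 10)
  hand <- TagSet(c(x, y, z),
                 cbind(A = c(9L, 1L, 0L), B = c(9L, 0L, 1L)))
  cmpH <- compareLibraries(hand)
  expect_equal(cmpH$read_fraction[cmpH$set == "common"], 18 / 20)
  expect_equal(cmpH$unique_fraction[cmpH$set == "common"], 1 / 3)
  expect_equal(sum(cmpH$unique_tags), 3L)
  expect_equal(sum(cmpH$reads), 20L)
})
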