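# naive seed-site scanner used as oracle
naiveSeedScan <- function(mirna, tx) {
  rc <- function(s) as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(s)))
  s28 <- rc(substr(mirna, 2, 8)); s27 <- rc(substr(mirna, 2, 7))
  out <- list()
  for (p in seq_len(nchar(tx))) {
    if (p + 6 <= nchar(tx) && substr(tx, p, p + 6) == s28) {
      if (p + 7 <= nchar(tx) && substr(tx, p + 7, p + 7) == "A")
        out[[length(out) + 1]] <- c(p, p + 7, "8mer")
      else
        out[[length(out) + 1]] <- c(p, p + 6, "7mer-m8")
    } else if (p + 6 <= nchar(tx) &&
               substr(tx, p, p + 5) == s27 &&
               substr(tx, p + 6, p + 6) == "A" &&
               (p == 1 || substr(tx, p - 1, p - 1) != substr(s28, 1, 1))) {
      out[[length(out) + 1]] <- c(p - 1 + 1, p + 6, "7mer-A1")
    }
  }
  out
}

test_that("consensus calls require two of three tools and are monotone", {
  votes <- data.frame(
    mirna = c("m1", "m1", "m1", "m2", "m3", "m3", "m3"),
    gene = c("Bdnf", "Bdnf", "Ngf", "Atrn", "Ptn", "Ptn", "Ptn"),
    tool = c("toolA", "toolB", "toolA", "toolA", "toolA", "toolB",
             "toolC"),
    stringsAsFactors = FALSE)
  calls <- consensusTargets(votes)
  expect_setequal(paste(calls$mirna, calls$gene),
                  c("m1 Bdnf", "m3 Ptn"))
  expect_equal(calls$n_tools[calls$mirna == "m3"], 3L)
  c1 <- consensusTargets(votes, 1)
  c3 <- consensusTargets(votes, 3)
  k <- function(x) paste(x$mirna, x$gene)
  expect_true(all(k(calls) %in% k(c1)))
  expect_true(all(k(c3) %in% k(calls)))
  expect_error(consensusTargets(votes, 4), "min_tools")
  # duplicate votes from the same tool do not create consensus
  dupv <- data.frame(mirna = "m9", gene = "g", tool = c("toolA", "toolA"))
  expect_equal(nrow(consensusTargets(dupv)), 0)
})

test_that("seed scanning finds canonical site types at exact positions", {
  mirna <- "TAGCTTATCAGACTGATGTTGA"
  rcSeed <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(substr(mirna, 2, 8))))
  tx8 <- paste0("CCCCC", rcSeed, "A", "CCCCC")
  s <- seedScan(mirna, tx8)
  expect_equal(nrow(s), 1)
  expect_equal(s$type, "8mer")
  expect_equal(s$start, 6)
  expect_equal(seedScan(mirna, strrep("C", 300))$type, character(0))
})

test_that("seed scanning matches a naive window scan on random transcripts", {
  set.seed(55)
  for (i in 1:15) {
    mirna <- randomSeq(22)
    rcSeed <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(substr(mirna, 2, 8))))
    tx <- paste0(randomSeq(1500), rcSeed, "A", randomSeq(500), rcSeed,
                 "G", randomSeq(500))
    got <- seedScan(mirna, tx)
    exp <- naiveSeedScan(mirna, tx)
    expect_equal(nrow(got), length(exp), info = mirna)
    if (length(exp))
      expect_equal(paste(got$start, got$type),
                   vapply(exp, function(e) paste(e[1], e[3]), ""),
                   info = mirna)
  }
})

test_that("gene descriptions join by id or symbol and keep missing genes", {
  gi <- data.frame(GeneID = c(24225L, 310836L),
                   Symbol = c("Bdnf", "Ngf"),
                   description = c("Brain-derived neurotrophic factor",
                                   "Nerve growth factor"),
                   stringsAsFactors = FALSE)
  calls <- data.frame(mirna = c("m1", "m1", "m2"),
                      gene = c("24225", "Ngf", "Unknown1"),
                      n_tools = 2L, tools = "toolA,toolB",
                      stringsAsFactors = FALSE)
  expect_warning(out <- annotateGenes(calls, gi), "missing")
  expect_equal(out$description[1], "Brain-derived neurotrophic factor")
  expect_equal(out$description[2], "Nerve growth factor")
  expect_true(is.na(out$description[3]))
  expect_equal(nrow(out), 3)
  empty <- annotateGenes(calls[0, ], gi)
  expect_equal(nrow(empty), 0)
})
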