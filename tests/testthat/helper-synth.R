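# Shared synthetic study computed once per test run: a small
# deterministic two-library bundle plus one full pipeline run.

synthSmallConfig <- function(seed = 42L, ...) {
  syntheticConfig(readsPerLibrary = 4000L, deterministicCounts = TRUE,
                  seed = seed, ...)
}

sharedRun <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    options(mirswim.verbose = FALSE)
    cfg <- synthSmallConfig()
    bundle <- buildGenome(cfg)
    dir <- file.path(tempdir(), "mirswim-shared-bundle")
    paths <- writeSynthBundle(bundle, dir)
    rc <- runConfig(fastq = c(HIST = paths$HIST, NC = paths$NC),
                    genome = paths$genome, annotation = paths$bed,
                    reference = paths$reference, seed = 1L)
    res <- suppressWarnings(runAll(rc))
    cache <<- list(cfg = cfg, bundle = bundle, paths = paths,
                   config = rc, run = res)
    cache
  }
})

# assemble a QualityScaledDNAStringSet from sequences (+ optional quals)
makeReads <- function(seqs, quals = NULL) {
  if (is.null(quals)) quals <- strrep("I", nchar(seqs))
  out <- Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(seqs), Biostrings::PhredQuality(quals))
  names(out) <- sprintf("r%03d", seq_along(seqs))
  out
}

ADAPTER3 <- "TCGTATGCCGTCTTCTGCTTG"
ADAPTER5 <- "GTTCAGAGTTCTACAGTCCGACGATC"
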