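#' Run configuration for the end-to-end pipeline
#'
#' @param fastq Named character vector of length 2: FASTQ path per
#'   library label.
#' @param genome Genome FASTA path (or a DNAStringSet).
#' @param annotation Annotation BED/GFF3 path (or a classed GRanges).
#' @param reference Mature miRNA reference FASTA path (or data.frame).
#' @param gene_info Optional gene_info path for target annotation.
#' @param adapter3,adapter5 Adapter sequences.
#' @param alpha,lfc,floor Differential-expression thresholds.
#' @param mfe,mfei,min_count,max_mismatch Novel-prediction thresholds.
#' @param species Preferred species code for known-miRNA naming.
#' @param output_dir Where stage outputs are written (`NULL` = nowhere).
#' @param seed Seed for any stochastic step.
#' @return A validated list of class `RunConfig`.
#' @export
runConfig <- function(fastq, genome, annotation, reference,
                      gene_info = NULL,
                      adapter3 = "TCGTATGCCGTCTTCTGCTTG",
                      adapter5 = "GTTCAGAGTTCTACAGTCCGACGATC",
                      alpha = 0.05, lfc = 1.0, floor = 0.01,
                      mfe = -25.0, mfei = 0.85, min_count = 5L,
                      max_mismatch = 4L, species = "rno",
                      output_dir = NULL, seed = 1L) {
  .stopIfNot(length(fastq) == 2 && !is.null(names(fastq)),
             "fastq must be a named 2-vector")
  .stopIfNot(alpha > 0 && alpha < 1, "alpha must be in (0,1)")
  .stopIfNot(lfc >= 0 && floor > 0 && mfe <= 0 && mfei >= 0 &&
             min_count >= 1 && max_mismatch >= 0,
             "threshold out of legal range")
  for (p in c(fastq, if (is.character(genome)) genome,
              if (is.character(annotation)) annotation,
              if (is.character(reference)) reference,
              if (is.character(gene_info)) gene_info))
    .stopIfNot(file.exists(p), paste("input path does not exist:", p))
  structure(list(fastq = fastq, genome = genome, annotation = annotation,
                 reference = reference, gene_info = gene_info,
                 adapter3 = adapter3, adapter5 = adapter5, alpha = alpha,
                 lfc = lfc, floor = floor, mfe = mfe, mfei = mfei,
                 min_count = as.integer(min_count),
                 max_mismatch = as.integer(max_mismatch),
                 species = species, output_dir = output_dir,
                 seed = as.integer(seed)),
            class = "RunConfig")
}

#' Load a RunConfig from a YAML file
#'
#' Keys mirror the arguments of [runConfig()]; `...` overrides.
#'
#' @param path YAML path.
#' @param ... Overrides applied after reading.
#' @return A `RunConfig`.
#' @export
readRunConfig <- function(path, ...) {
  y <- yaml::read_yaml(path)
  ov <- list(...)
  y[names(ov)] <- ov
  y$fastq <- unlist(y$fastq)
  do.call(runConfig, y)
}

#' Run the full pipeline
#'
#' Executes preprocess -> map/annotate -> known -> novel -> diffexpr
#' (-> targets when gene-level vote files are supplied separately) on
#' two libraries, writing every intermediate table when `output_dir` is
#' set, and asserting the global read-count ledger per library:
#' `raw = dropped + non-miRNA classes + known + novel + unassigned`.
#'
#' @param cfg A [runConfig()].
#' @return A list: `tags` ([TagSet-class]), `reports`, `mapping`,
#'   `classes`, `category` (class breakdown), `known`, `families`,
#'   `shared`, `novel`, `candidates`, `expression` (differential
#'   expression over known + novel), `ledger` (per-library accounting
#'   data.frame).
#' @export
runAll <- function(cfg) {
  .stopIfNot(inherits(cfg, "RunConfig"), "cfg must be a RunConfig")
  stage <- function(name, expr) {
    .msg("[", name, "] ...")
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  libs <- names(cfg$fastq)

  filt <- stage("preprocess", lapply(libs, function(lb)
    filterAndTrim(cfg$fastq[[lb]], cfg$adapter3, cfg$adapter5,
                  library = lb)))
  names(filt) <- libs
  tags <- combineLibraries(filt)

  genome <- if (is.character(cfg$genome))
    Biostrings::readDNAStringSet(cfg$genome) else cfg$genome
  names(genome) <- sub("\\s.*$", "", names(genome))
  index <- buildGenomeIndex(genome)
  mapping <- stage("map", mapTags(tags, index))
  annotation <- if (is.character(cfg$annotation))
    readAnnotation(cfg$annotation) else cfg$annotation
  classes <- stage("annotate",
                   assignClass(tags, mapping$hits, annotation))
  category <- categorySummary(tags, classes)

  isUn <- classes[tagSeq(tags)] == "unannotated"
  unannTS <- TagSet(tagSeq(tags)[isUn],
                    tagCounts(tags)[isUn, , drop = FALSE])
  km <- stage("known", matchKnown(unannTS, cfg$reference,
                                  species = cfg$species))
  families <- familyRollup(km$known)
  shared <- if (!is.null(km$known)) sharedSpecific(km$known) else NULL

  novelRes <- list(novel = data.frame(), candidates = data.frame())
  if (!is.null(km$unmatched)) {
    unSeq <- tagSeq(km$unmatched)
    hitsUn <- mapping$hits[mapping$hits$tag %in% unSeq]
    if (length(hitsUn))
      novelRes <- stage("novel", predictNovel(
        km$unmatched, hitsUn, genome,
        thresholds = novelThresholds(mfe = cfg$mfe, mfei = cfg$mfei,
                                     max_mismatch = cfg$max_mismatch,
                                     min_count = cfg$min_count)))
  }

  totals <- libraryTotals(tags)
  exprIn <- NULL
  if (!is.null(km$known)) {
    exprIn <- km$known[, c("name", libs)]
  }
  if (nrow(novelRes$novel)) {
    nv <- novelRes$novel[, c("name", libs)]
    exprIn <- if (is.null(exprIn)) nv else rbind(exprIn, nv)
  }
  expression <- NULL
  if (!is.null(exprIn))
    expression <- stage("diffexpr", classifyExpression(
      exprIn, totals, alpha = cfg$alpha, lfc = cfg$lfc,
      floor = cfg$floor))

  ledger <- .readLedger(filt, tags, classes, km, novelRes)
  res <- list(tags = tags, reports = lapply(filt, `[[`, "report"),
              mapping = mapping, classes = classes, category = category,
              known = km$known, families = families, shared = shared,
              novel = novelRes$novel, candidates = novelRes$candidates,
              expression = expression, ledger = ledger)
  if (!is.null(cfg$output_dir)) .writeRunOutputs(res, cfg$output_dir)
  res
}

# global read-count ledger: raw = dropped + annotated classes + known +
# novel + unassigned, per library
.readLedger <- function(filt, tags, classes, km, novelRes) {
  libs <- colnames(tagCounts(tags))
  cts <- tagCounts(tags)
  cl <- classes[tagSeq(tags)]
  rows <- lapply(libs, function(lb) {
    rep <- filt[[lb]]$report
    annotated <- sum(cts[cl != "unannotated", lb])
    knownC <- if (!is.null(km$known)) sum(km$known[[lb]]) else 0
    unSeq <- if (!is.null(km$unmatched)) tagSeq(km$unmatched)
             else character(0)
    novSeq <- if (nrow(novelRes$novel)) novelRes$novel$seq
              else character(0)
    novelC <- sum(cts[rownames(cts) %in% novSeq, lb])
    unassigned <- sum(cts[rownames(cts) %in% setdiff(unSeq, novSeq), lb])
    data.frame(library = lb, raw = rep@rawReads,
               dropped = sum(rep@dropped), clean = rep@cleanReads,
               annotated = annotated, known = knownC, novel = novelC,
               unassigned = unassigned,
               balanced = rep@rawReads == sum(rep@dropped) + annotated +
                 knownC + novelC + unassigned,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

.writeRunOutputs <- function(res, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, name) {
    if (is.null(df) || !NROW(df)) return()
    write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  tagDf <- data.frame(seq = tagSeq(res$tags), tagCounts(res$tags),
                      class = res$classes[tagSeq(res$tags)])
  wt(tagDf, "tags.tsv")
  for (lb in names(res$reports)) {
    rep <- res$reports[[lb]]
    jsonlite::write_json(
      list(library = lb, raw_reads = rep@rawReads,
           dropped = as.list(rep@dropped), clean_reads = rep@cleanReads,
           unique_tags = rep@uniqueTags),
      file.path(dir, paste0("filter_", lb, ".json")),
      auto_unbox = TRUE, digits = NA)
  }
  wt(res$mapping$summary, "mapping_summary.tsv")
  if (length(res$mapping$hits)) {
    hits <- res$mapping$hits
    hits$name <- hits$tag
    hits$score <- 0L
    rtracklayer::export(hits, file.path(dir, "hits.bed"), format = "BED")
  }
  wt(res$category, "category_summary.tsv")
  wt(res$known, "known_mirna.tsv")
  wt(res$families, "families.tsv")
  wt(res$novel, "novel_mirna.tsv")
  wt(res$candidates, "novel_candidates.tsv")
  if (NROW(res$candidates) && any(res$candidates$locus_pass %in% TRUE)) {
    ok <- res$candidates[res$candidates$locus_pass %in% TRUE, ]
    nm <- paste0(ok$tag, "|", ok$chrom, ":", ok$prec_start, ":",
                 ok$prec_end, ":", ok$strand)
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(setNames(ok$precursor, nm)),
      file.path(dir, "novel_precursors.fa"))
    writeLines(paste0(">", nm, "\n", ok$precursor, "\n", ok$structure,
                      sprintf(" (%.1f)", ok$mfe)),
               file.path(dir, "novel_structures.txt"))
  }
  if (!is.null(res$expression)) {
    ex <- res$expression
    num <- vapply(ex, is.numeric, logical(1)) &
      grepl("^tpm_|^log2fc$", colnames(ex))
    ex[num] <- lapply(ex[num], round, 2)
    wt(ex, "diffexpr.tsv")
  }
  wt(res$ledger, "ledger.tsv")
  invisible(dir)
}
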