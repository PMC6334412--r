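#' 2-of-3 target-prediction consensus
#'
#' Combines per-tool miRNA-target votes (e.g. from RNAhybrid, miRanda and
#' TargetScan runs consumed as tables): a (miRNA, gene) pair becomes a
#' putative target call when at least `min_tools` distinct tools predict
#' it.  Agreement is at gene level.
#'
#' @param votes data.frame with columns `mirna`, `gene`, `tool` (or a TSV
#'   path with those columns); duplicate (mirna, gene, tool) rows are
#'   collapsed.
#' @param min_tools Minimum number of distinct supporting tools, in 1..3
#'   (default 2).
#' @return data.frame `mirna`, `gene`, `n_tools`, `tools`
#'   (comma-joined), one row per called pair.  Raising `min_tools` can
#'   only shrink the call set.
#' @export
#' @examples
#' v <- data.frame(mirna = "miR-1", gene = c("Bdnf", "Bdnf", "Ngf"),
#'                 tool = c("toolA", "toolB", "toolA"))
#' consensusTargets(v)
consensusTargets <- function(votes, min_tools = 2L) {
  .stopIfNot(min_tools >= 1 && min_tools <= 3,
             "min_tools must be in 1..3")
  if (is.character(votes)) votes <- read.delim(votes,
                                               stringsAsFactors = FALSE)
  .stopIfNot(all(c("mirna", "gene", "tool") %in% colnames(votes)),
             "votes need columns mirna, gene, tool")
  votes <- unique(votes[, c("mirna", "gene", "tool")])
  key <- paste(votes$mirna, votes$gene, sep = "\r")
  nt <- tapply(votes$tool, key, function(t) length(unique(t)))
  tl <- tapply(votes$tool, key, function(t)
    paste(sort(unique(t)), collapse = ","))
  keep <- names(nt)[nt >= min_tools]
  if (!length(keep))
    return(data.frame(mirna = character(0), gene = character(0),
                      n_tools = integer(0), tools = character(0),
                      stringsAsFactors = FALSE))
  parts <- strsplit(keep, "\r", fixed = TRUE)
  out <- data.frame(mirna = vapply(parts, `[`, "", 1),
                    gene = vapply(parts, `[`, "", 2),
                    n_tools = as.integer(nt[keep]),
                    tools = as.character(tl[keep]),
                    stringsAsFactors = FALSE)
  out <- out[order(out$mirna, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Seed-match site scanner (built-in stand-in predictor)
#'
#' Scans a transcript for canonical seed-match sites of a miRNA:
#' `7mer-m8` (exact complement of miRNA positions 2-8), `8mer`
#' (7mer-m8 followed by an A opposite position 1) and `7mer-A1`
#' (complement of positions 2-7 followed by an A).  This self-contained
#' predictor exists so consensus voting can be exercised without
#' external tools; it is not a reimplementation of any of them.
#'
#' @param mirna_seq Mature miRNA sequence (>= 18 nt, 5'->3').
#' @param transcript_seq Transcript sequence (5'->3', DNA alphabet).
#' @return data.frame `start`, `end` (1-based inclusive site
#'   coordinates on the transcript), `type` (`8mer`, `7mer-m8`,
#'   `7mer-A1`); 0 rows when no site exists.
#' @export
seedScan <- function(mirna_seq, transcript_seq) {
  mirna_seq <- .toDNA(mirna_seq); tx <- .toDNA(transcript_seq)
  .stopIfNot(nchar(mirna_seq) >= 18, "mature miRNA must be >= 18 nt")
  .stopIfNot(nchar(tx) > 0, "transcript must be non-empty")
  seed28 <- .revcomp(substr(mirna_seq, 2, 8))   # 7 nt site, m8..m2
  seed27 <- .revcomp(substr(mirna_seq, 2, 7))   # 6 nt core, m7..m2
  sites <- list()
  addSites <- function(pat, type, lenOut) {
    hits <- gregexpr(pat, tx, fixed = FALSE, perl = TRUE)[[1]]
    if (hits[1] == -1) return()
    for (p in as.integer(hits))
      sites[[length(sites) + 1L]] <<- data.frame(
        start = p, end = p + lenOut - 1L, type = type,
        stringsAsFactors = FALSE)
  }
  # 8mer: seed28 + A ; 7mer-m8: seed28 not followed by A ;
  # 7mer-A1: seed27 + A, not preceded by the m8 complement
  addSites(paste0("(?=", seed28, "A)"), "8mer", 8L)
  addSites(paste0("(?=", seed28, "(?!A)", ")"), "7mer-m8", 7L)
  m8c <- substr(seed28, 1, 1)
  addSites(paste0("(?<!", m8c, ")(?=", seed27, "A)"), "7mer-A1", 7L)
  if (!length(sites))
    return(data.frame(start = integer(0), end = integer(0),
                      type = character(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, sites)
  out <- out[order(out$start, out$type), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Attach gene descriptions to target calls
#'
#' Left-joins an NCBI `gene_info`-style table (tab-separated, with
#' `GeneID`/`Symbol`/`description` columns, case-insensitive; `#`
#' comment header tolerated) onto consensus calls by gene identifier or
#' symbol.  Genes missing from the table are kept with description `NA`
#' and reported via a warning, never dropped.
#'
#' @param calls Consensus calls from [consensusTargets()].
#' @param gene_info Path to a gene_info TSV or an equivalent data.frame.
#' @return `calls` with `gene_id` and `description` columns appended.
#' @export
annotateGenes <- function(calls, gene_info) {
  if (is.character(gene_info)) {
    gi <- tryCatch(
      read.delim(gene_info, comment.char = "#", header = TRUE,
                 stringsAsFactors = FALSE, quote = ""),
      error = function(e) stop("malformed gene_info: ",
                               conditionMessage(e)))
    if (!any(grepl("geneid|symbol", tolower(colnames(gi))))) {
      # headerless NCBI dialect: tax_id GeneID Symbol ... description ...
      gi <- read.delim(gene_info, comment.char = "#", header = FALSE,
                       stringsAsFactors = FALSE, quote = "")
      .stopIfNot(ncol(gi) >= 9, "malformed gene_info: too few columns")
      colnames(gi)[c(2, 3, 9)] <- c("GeneID", "Symbol", "description")
    }
  } else gi <- gene_info
  cn <- tolower(colnames(gi))
  idc <- which(cn == "geneid")[1]
  syc <- which(cn == "symbol")[1]
  dsc <- which(cn == "description")[1]
  .stopIfNot(!is.na(dsc) && (!is.na(idc) || !is.na(syc)),
             "gene_info needs GeneID/Symbol and description columns")
  keyTabs <- character(0)
  if (!is.na(idc)) keyTabs <- c(keyTabs, setNames(as.character(gi[[dsc]]),
                                                  as.character(gi[[idc]])))
  if (!is.na(syc)) keyTabs <- c(keyTabs, setNames(as.character(gi[[dsc]]),
                                                  as.character(gi[[syc]])))
  desc <- keyTabs[as.character(calls$gene)]
  idTab <- if (!is.na(idc) && !is.na(syc))
    setNames(as.character(gi[[idc]]), as.character(gi[[syc]]))
  else character(0)
  calls$gene_id <- ifelse(as.character(calls$gene) %in% names(idTab),
                          idTab[as.character(calls$gene)],
                          as.character(calls$gene))
  calls$description <- unname(desc)
  miss <- is.na(calls$description)
  if (any(miss))
    warning(sum(miss), " gene(s) missing from gene_info: ",
            paste(unique(calls$gene[miss]), collapse = ", "))
  calls
}
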