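#' Transcripts-per-million normalisation
#'
#' `TPM = count / library_total * 1e6`.  Values are computed unrounded;
#' reports conventionally print them to 2 decimals.
#'
#' @param count Read count(s), >= 0.
#' @param total Library clean-read total, > 0.
#' @return Numeric TPM, vectorised.
#' @export
#' @examples
#' tpm(1638730, 27877781)   # 58782.66 to 2 decimals
tpm <- function(count, total) {
  .stopIfNot(all(total > 0), "library total must be positive")
  .stopIfNot(all(count >= 0), "counts must be non-negative")
  count / total * 1e6
}

#' log2 fold change with zero-count flooring
#'
#' `log2(max(a, floor) / max(b, floor))`.  The floor (default 0.01 TPM)
#' makes condition-specific miRNAs (zero in one library) reportable: a
#' 1.51-vs-absent miRNA gets `log2(1.51 / 0.01) = 7.24`.
#'
#' @param tpm_a,tpm_b Normalised expression values, >= 0.
#' @param floor Pseudo-TPM applied to both sides before the ratio.
#' @return log2 fold change (a over b), vectorised; computed unrounded.
#' @export
#' @examples
#' log2Fold(214.33, 52.96)  # 2.02 to 2 decimals
#' log2Fold(1.51, 0)        # 7.24
log2Fold <- function(tpm_a, tpm_b, floor = 0.01) {
  .stopIfNot(all(tpm_a >= 0) && all(tpm_b >= 0),
             "expression values must be non-negative")
  log2(pmax(tpm_a, floor) / pmax(tpm_b, floor))
}

#' Audic-Claverie two-library test for one tag
#'
#' Exact Poisson-based comparison of a tag's counts between two
#' sequencing libraries of totals `N1` and `N2`: under the null the
#' second count given the first follows
#' `P(y | x) = (N2/N1)^y * (x+y)! / (x! * y! * (1 + N2/N1)^(x+y))`
#' (normalised), i.e. a negative binomial with size `x + 1` and success
#' probability `N1 / (N1 + N2)`.  The reported p-value is the smaller
#' tail summed over `y`, doubled and capped at 1; computation is in
#' log space via `pnbinom`, so large counts do not overflow.  The
#' conditioning count is always the one from the lower-rate library
#' (ties broken by the smaller count), which makes the test exactly
#' symmetric under swapping the two libraries.
#'
#' @param x,y Counts in library 1 and 2 (vectorised).
#' @param n1,n2 Clean-read totals of library 1 and 2.
#' @return Two-sided p-value(s) in (0, 1].
#' @export
#' @examples
#' twoLibraryTest(5, 10, 1e6, 1e6)
twoLibraryTest <- function(x, y, n1, n2) {
  .stopIfNot(all(x >= 0) && all(y >= 0), "counts must be non-negative")
  .stopIfNot(all(n1 > 0) && all(n2 > 0), "totals must be positive")
  k <- max(length(x), length(y))
  x <- rep_len(x, k); y <- rep_len(y, k)
  n1 <- rep_len(n1, k); n2 <- rep_len(n2, k)
  swap <- (x / n1 > y / n2) | (x / n1 == y / n2 & x > y)
  xx <- ifelse(swap, y, x); yy <- ifelse(swap, x, y)
  m1 <- ifelse(swap, n2, n1); m2 <- ifelse(swap, n1, n2)
  prob <- m1 / (m1 + m2)
  lo <- pnbinom(yy, size = xx + 1, prob = prob)
  hi <- pnbinom(yy - 1, size = xx + 1, prob = prob, lower.tail = FALSE)
  pmin(1, 2 * pmin(lo, hi))
}

#' Classify differential expression between two libraries
#'
#' Computes TPM, log2 fold change (with flooring) and the
#' Audic-Claverie p-value for each row, then applies the significance
#' rule: differentially expressed iff `p < alpha` and `|log2fc| > lfc`
#' (strict inequalities, on unrounded values); direction from the sign;
#' significance mark `"*"` for `p < 0.05` and `"**"` for `p < 0.01`.
#' No multiple-testing correction is applied by default (single-pass
#' two-library designs of this kind historically reported raw p-values);
#' `adjust = "BH"` adds a Benjamini-Hochberg adjusted column and gates
#' significance on it.
#'
#' @param counts data.frame with `name` and two count columns, or a
#'   matrix with rownames.
#' @param totals Named numeric of length 2: clean-read totals per
#'   library (names matching the count columns).
#' @param alpha Significance level (default 0.05).
#' @param lfc log2 fold-change gate (default 1.0).
#' @param floor TPM floor (default 0.01).
#' @param adjust `"none"` (default) or `"BH"`.
#' @return data.frame: `name`, raw counts, `tpm_<lib>` (unrounded),
#'   `log2fc`, `p_value`, `sig` (`""`/`"*"`/`"**"`), `direction`
#'   (`"up"`/`"down"`/`"none"`), `significant`; with a `summary`
#'   attribute `c(n_sig, n_up, n_down)`.
#' @export
classifyExpression <- function(counts, totals, alpha = 0.05, lfc = 1.0,
                               floor = 0.01, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  if (is.matrix(counts))
    counts <- data.frame(name = rownames(counts), counts,
                         stringsAsFactors = FALSE)
  libs <- names(totals)
  .stopIfNot(length(libs) == 2 && all(libs %in% colnames(counts)),
             "totals must name two count columns")
  a <- counts[[libs[1]]]; b <- counts[[libs[2]]]
  ta <- tpm(a, totals[[1]]); tb <- tpm(b, totals[[2]])
  lf <- log2Fold(ta, tb, floor = floor)
  p <- twoLibraryTest(a, b, totals[[1]], totals[[2]])
  pGate <- if (adjust == "BH") stats::p.adjust(p, "BH") else p
  sig <- ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", ""))
  de <- pGate < alpha & abs(lf) > lfc
  dirn <- ifelse(de & lf > lfc, "up", ifelse(de & lf < -lfc, "down",
                                             "none"))
  out <- data.frame(name = counts$name, stringsAsFactors = FALSE)
  out[[libs[1]]] <- a; out[[libs[2]]] <- b
  out[[paste0("tpm_", libs[1])]] <- ta
  out[[paste0("tpm_", libs[2])]] <- tb
  out$log2fc <- lf
  out$p_value <- p
  if (adjust == "BH") out$p_adj <- pGate
  out$sig <- sig
  out$direction <- dirn
  out$significant <- de
  attr(out, "summary") <- c(n_sig = sum(de), n_up = sum(dirn == "up"),
                            n_down = sum(dirn == "down"))
  out
}

#' Relative expression by the 2^-ddCt method
#'
#' `2^-((ct_target_a - ct_ref_a) - (ct_target_b - ct_ref_b))`: the qPCR
#' relative-quantification estimator of condition A versus condition B,
#' each normalised to an internal reference gene (e.g. U6 snRNA).
#'
#' @param ct_target_a,ct_ref_a Target and reference Ct in condition A.
#' @param ct_target_b,ct_ref_b Target and reference Ct in condition B.
#' @return Relative expression (1 = no change), vectorised.
#' @export
#' @examples
#' ddct(20, 15, 21, 16)   # ddCt 0 -> 1.0
ddct <- function(ct_target_a, ct_ref_a, ct_target_b, ct_ref_b) {
  dd <- (ct_target_a - ct_ref_a) - (ct_target_b - ct_ref_b)
  2^(-dd)
}
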