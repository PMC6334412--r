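#' Nearest-neighbour energy parameters for hairpin folding
#'
#' Turner-style free-energy parameters (37 degrees C, kcal/mol) used by
#' [foldHairpin()]: stacking energies for the six canonical pairs
#' (Watson-Crick plus GU wobble), loop-initiation penalties for hairpin
#' loops, bulges and internal loops by size with logarithmic
#' (Jacobson-Stockmayer) extrapolation, and an internal-loop asymmetry
#' penalty.  Stacks between two Watson-Crick pairs carry the standard ten
#' nearest-neighbour values; stacks involving one or two wobble pairs use
#' a flat approximation (-1.4 / -0.5) since precursor scoring is
#' threshold-based, not parameter-set-critical.
#'
#' @return A list with components `stack` (6x6 matrix, pair order CG, GC,
#'   GU, UG, AU, UA), `hairpin`, `bulge`, `internal` (penalties indexed by
#'   loop size), `lxc` (extrapolation coefficient `1.75 * RT`), `asym`,
#'   `asymMax`, `maxLoop` and `minHairpin`.
#' @export
#' @examples
#' p <- foldParams()
#' p$stack["GC", "CG"]   # 5'-GC-3' / 3'-CG-5' stack
foldParams <- function() {
  pairs <- c("CG", "GC", "GU", "UG", "AU", "UA")
  # nearest-neighbour step energy, top-strand dinucleotide, both pairs WC
  nn <- c(AA = -0.93, AU = -1.10, UA = -1.33, CU = -2.08, CA = -2.11,
          GU = -2.24, GA = -2.35, CG = -2.36, GG = -3.26, GC = -3.42)
  nn <- c(nn,  # complement-strand readings of the same ten steps
          UU = -0.93, AG = -2.08, UG = -2.11, AC = -2.24, UC = -2.35,
          CC = -3.26)
  wc <- c(CG = "C", GC = "G", AU = "A", UA = "U")
  stack <- matrix(NA_real_, 6, 6, dimnames = list(pairs, pairs))
  for (p1 in pairs) for (p2 in pairs) {
    wob <- (p1 %in% c("GU", "UG")) + (p2 %in% c("GU", "UG"))
    if (wob == 0) {
      step <- paste0(wc[[p1]], wc[[p2]])
      stack[p1, p2] <- nn[[step]]
    } else {
      stack[p1, p2] <- if (wob == 1) -1.4 else -0.5
    }
  }
  list(stack = stack,
       hairpin = c(Inf, Inf, 5.4, 5.6, 5.7, 5.4, 6.0, 5.5, 6.4),
       bulge = c(3.8, 2.8, 3.2, 3.6, 4.0, 4.4),
       internal = c(Inf, 0.8, 1.3, 1.7, 2.0, 2.3),
       lxc = 1.75 * 0.616, asym = 0.6, asymMax = 3.0,
       maxLoop = 30L, minHairpin = 3L)
}

#' Fold a candidate precursor into its best stem-loop
#'
#' Computes the minimum-free-energy secondary structure of a sequence by
#' dynamic programming over single-hairpin topologies only: nested chains
#' of base pairs (Watson-Crick and GU wobble) closed by one terminal loop
#' of at least 3 nt, with stacking, bulge and internal-loop energies from
#' [foldParams()].  Multiloops and pseudoknots are deliberately outside
#' the structure space: a miRNA precursor is a stem-loop, and restricting
#' the topology makes the fold unambiguous for duplex geometry.  A
#' sequence with no stabilising structure gets `mfe = 0` and an empty
#' pair list.
#'
#' @param seq A single character string over A, C, G, T (U is accepted and
#'   normalised to T), 1 to 10000 nt; candidate precursors are typically
#'   60-200 nt.
#' @param params Energy parameter list, see [foldParams()].
#' @return A list with `mfe` (kcal/mol, <= 0), `structure` (dot-bracket
#'   string) and `pairs` (two-column matrix of 1-based paired positions,
#'   outermost first).
#' @export
#' @examples
#' foldHairpin("GGGGGGAAAACCCCCC")$mfe   # 6-pair GC stem, 4-nt loop
foldHairpin <- function(seq, params = foldParams()) {
  .stopIfNot(is.character(seq) && length(seq) == 1, "seq must be a string")
  seq <- .toDNA(seq)
  .stopIfNot(!grepl("[^ACGT]", seq),
             "seq must be over the A/C/G/T (or U) alphabet")
  .fold_hairpin_cpp(seq, params$stack, params$hairpin, params$bulge,
                    params$internal, params$lxc, params$asym,
                    params$asymMax, as.integer(params$maxLoop),
                    as.integer(params$minHairpin))
}

#' Minimal folding free energy index (MFEI)
#'
#' `MFEI = AMFE / (GC%)` with `AMFE = -MFE * 100 / length`; the classic
#' discriminator between miRNA hairpins (MFEI typically >= 0.85) and
#' other structured RNAs (tRNA ~0.64, rRNA ~0.59, mRNA 0.62-0.66).
#'
#' @param mfe Minimum free energy, kcal/mol (<= 0).
#' @param length Precursor length, nt (> 0).
#' @param gc_fraction GC content in `[0, 1]`; a value of 0 leaves MFEI
#'   undefined and returns `NA` (such candidates are rejected).
#' @return MFEI (unitless, >= 0), vectorised over its arguments.
#' @export
#' @examples
#' computeMFEI(-40, 80, 0.5)   # AMFE 50, MFEI 1.0
computeMFEI <- function(mfe, length, gc_fraction) {
  .stopIfNot(all(length > 0), "length must be positive")
  .stopIfNot(all(mfe <= 0), "mfe must be <= 0")
  amfe <- -mfe * 100 / length
  ifelse(gc_fraction > 0, amfe / (gc_fraction * 100), NA_real_)
}
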