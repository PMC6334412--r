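---
title: "Methods: two-library small RNA-seq miRNA profiling with mirswim"
author: "mirswim authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-library small RNA-seq miRNA profiling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirswim)
options(mirswim.verbose = FALSE)
```

# The study design this package models

`mirswim` re-implements, as reusable and tested R code, the analysis
path of a classic pooled-RNA small RNA-seq comparison: two libraries
(a treatment library and a control library, here labelled `HIST` and
`NC` after the high-intensity swimming-trained and control rat brain
pools that motivated the design), sequenced deeply, with **no
biological replication at the library level** — each library is a pool
of many animals. All statistics therefore compare two count vectors
against library totals; nothing in the package estimates biological
dispersion, and users should treat calls accordingly (see
*Limitations*).

The pipeline stages are:

1. **Read cleaning** (`filterAndTrim`): raw reads are dropped, in a
   fixed cascade order, as low-quality, 5'-adapter contaminants,
   missing the 3' adapter, adapter-only (no insert), polyA, or with an
   insert outside 18–30 nt; the 3' adapter is located and trimmed
   *before* the length test. Survivors are collapsed to unique tags
   with per-library counts (`TagSet`).
2. **Genome mapping and annotation** (`mapTags`, `assignClass`):
   perfect matches only, on both strands, all loci reported. Each tag
   receives exactly one class by a fixed priority
   (rRNA > scRNA > snRNA > snoRNA > srpRNA > tRNA > repeat >
   exon_sense > exon_antisense > intron_sense > intron_antisense),
   with exon/intron split by strand agreement; unannotated tags move
   on to miRNA identification.
3. **Known miRNAs** (`matchKnown`): matching against a miRBase-style
   mature reference, exact core with at most 2 nt of terminal
   shift/extension (isomiR tolerance) and no internal mismatches;
   same-species entries win ties, then fewest terminal shifts, then
   name. Families roll up by explicit metadata or name stems.
4. **Novel miRNAs** (`predictNovel`): for every hit of every remaining
   tag, two flanking windows (20 nt up / 160 nt down and the mirror)
   are folded; the more stable window is kept (ties prefer the window
   placing the tag on the 5' arm), trimmed to the hairpin extent, and
   judged by six criteria (below). Identical matures merge across
   loci without double-counting reads.
5. **Differential expression** (`classifyExpression`): TPM
   normalisation, log2 fold change with a 0.01-TPM floor, the
   Audic–Claverie exact two-library test, and the significance rule
   p < 0.05 and |log2FC| > 1 on unrounded values.
6. **Targets** (`consensusTargets`): gene-level 2-of-3 consensus over
   externally produced predictor tables, with a built-in seed-match
   scanner for self-contained testing.

# The folding model

Novel-miRNA evaluation needs only the best *stem-loop*, so
`foldHairpin` computes the minimum-free-energy structure over
single-hairpin topologies exclusively: nested chains of pairs
(Watson–Crick and GU wobble) closed by one terminal loop of at least
3 nt. Energies are a Turner-style nearest-neighbour model: the ten
standard Watson–Crick stack energies, a flat approximation for stacks
involving wobble pairs (−1.4 kcal/mol with one wobble, −0.5 with two),
tabulated initiation penalties for hairpin loops, bulges and internal
loops with Jacobson–Stockmayer logarithmic extrapolation
(coefficient 1.75·RT), a bulge-of-one retaining its stack, and an
internal-loop asymmetry penalty of 0.6 kcal/mol per nt capped at 3.
Interior loops are limited to 30 unpaired bases, the standard
dynamic-programming restriction.

Two consequences matter for interpretation. First, absolute MFE values
are parameter-set dependent; the package treats them only against the
acceptance threshold (−25 kcal/mol) and never claims agreement with any
particular published MFE to the decimal. Second, because multiloops
are excluded, a long window folds to its best hairpin, which is
exactly the object the six criteria describe. The dynamic program is
verified in the test suite against an independently written pure-R
exhaustive search over all legal hairpin structures for sequences up
to 30 nt.

# The six acceptance criteria

A candidate is accepted when all six hold (all thresholds inclusive,
configurable via `novelThresholds()`):

| # | Check | Default |
|---|-------|---------|
| c1 | minimum free energy | MFE ≤ −25.0 kcal/mol |
| c2 | minimal folding free energy index, AMFE/(GC%) | MFEI ≥ 0.85 |
| c3 | mature on one arm, miRNA/miRNA* duplex with 2-nt 3' overhangs | — |
| c4 | mature/star mismatches | ≤ 4 |
| c5 | bulge/internal-loop events in the duplex | ≤ 1 event of ≤ 1 nt |
| c6 | read support of the merged mature | ≥ 5 reads |

Duplex geometry derives the star strand from the pairing table under
the canonical Dicer rule (star 5' end pairs two bases inside the
mature 3' end; star 3' end extends two bases past the mature 5'
start). Symmetric unpaired positions count as mismatches
(`min(a, b)` per interior gap, plus unpaired duplex termini);
asymmetric gaps count as bulge events of size `|a − b|`. GU wobble is
a pair, never a mismatch. The bulge criterion is read as at most one
event of at most 1 nt; both the event count and the size cap are
configurable since conventions differ between pipelines. The
read-support criterion applies to the *merged* mature across loci
(a multi-copy gene is one miRNA), since support describes the mature
molecule, not any one locus.

# The exact two-library test

With library totals $N_1, N_2$ and one tag's counts $x, y$, the
Audic–Claverie model gives
$$P(y \mid x) = \left(\frac{N_2}{N_1}\right)^{y}
\frac{(x+y)!}{x!\,y!\,(1+N_2/N_1)^{x+y}},$$
a negative binomial in $y$ with size $x+1$ and success probability
$N_1/(N_1+N_2)$ once normalised. The p-value is twice the smaller
tail, capped at 1, computed through `pnbinom` in log space. The raw
kernel is not exactly symmetric under swapping the libraries, so the
implementation always conditions on the count from the lower-rate
library (ties resolved toward the smaller count); this leaves the
kernel untouched and makes
`twoLibraryTest(x, y, N1, N2) == twoLibraryTest(y, x, N2, N1)` exact.
The test suite checks the implementation against direct tail summation
of the formula above for counts up to 50.

Zero counts are handled at the fold-change step: TPM values are
floored at 0.01 before the ratio, so a treatment-specific miRNA at
1.51 TPM against absence reports $\log_2(1.51/0.01) = 7.24$ rather
than infinity. The floor is a convention, not an estimate; it was
chosen to make condition-specific expression reportable on the same
scale as ordinary fold changes. No multiple-testing correction is
applied by default — the historical two-library pipelines this mirrors
reported raw p-values — but `adjust = "BH"` enables
Benjamini–Hochberg gating for users who want it.

# What the synthetic generator emulates — and what it does not

`syntheticConfig()`/`buildGenome()` build a complete miniature study:
random chromosomes; planted known-miRNA loci present in a
miRBase-style reference (with other-species duplicates and decoys);
planted novel hairpin loci with designed duplex geometry (designed
mismatch counts, 2-nt 3' overhangs, GC-rich basal stems, A/C buffer
sequences that cannot pair so the hairpin does not run into random
context); deliberately failing decoy loci; optional clustered
multi-copy precursors sharing one mature sequence; non-miRNA loci for
every annotation class with sense (and for exon/intron, antisense)
fragment tags; unmappable junk tags; and read-level contaminants for
every filter reason, sharing one definition of "low quality" with the
filter (> 20% of bases below Q10).

Truth labels for the structural criteria are *defined by evaluation*:
after placement, every planted miRNA-like locus is re-scored by the
novel module itself and `criteria_pass` records the outcome. This
makes the generator invariant ("planted loci satisfy or violate the
criteria exactly as labeled") hold by construction even when the
window tie-break prefers a random-context fold over the designed stem,
which legitimately happens for a minority of designs.

Deliberate simplifications: no sequencing errors beyond the planted
contaminant classes, no isomiR read scatter around planted matures, no
star-strand reads, log-uniform per-locus abundances (real abundance
distributions are heavier-tailed), and library sizes of thousands
rather than tens of millions of reads. Passing tests on this material
therefore demonstrates the *logic* of the pipeline — filtering
accounting, mapping, classification, structure evaluation, count
statistics — not robustness to the full mess of real sequencing data.

Default simulation sizes (two libraries of 20,000 reads in the
generator default, 4,000 in the bundled test fixtures; 8 novel, 10
known, 3 decoy loci) were chosen as the smallest sizes at which every
stage has non-trivial work and planted effects are comfortably
detectable; they are the package's own choice of desk-scale study
conditions. Mature lengths are drawn from 20–24 nt with 40% of the
mass at 22 nt, matching the canonical animal miRNA length profile.
Planted fold changes default to ±2 on a quarter of the known loci and
one treatment-specific novel locus (zero reads in the control
library), mirroring the qualitative structure of the motivating
dataset.

# Numerical and design choices

* **Coordinates.** All containers are 1-based inclusive (`GRanges`);
  BED export converts through `rtracklayer`. User-facing locus
  strings are `chrom:start:end:strand`.
* **Alphabet.** Everything is stored DNA-style (`U` → `T`) on input.
* **Adapter search.** Leftmost position with ≥ 6 nt exact prefix
  match of the 3' adapter, or ≥ 10 nt overlap with at most one
  mismatch; a match at position 1 means "no insert". These are
  conventions for a filter the original description leaves
  unspecified; they are deterministic and shared with the simulator.
* **"Low quality"** is undefined in the historical pipelines;
  here: > 20% of bases below Q10, or any N.
* **polyA** means an insert that is ≥ 90% A.
* **Length bounds.** Inserts outside 18–30 nt are dropped under the
  `too_short` reason (the reason vocabulary is fixed; over-length
  inserts are rare with ≤ 36 nt reads and are recorded under the same
  length reason).
* **Window choice.** Between the two candidate windows of a hit the
  lower MFE wins; ties prefer the 5'-arm window. Precursors are then
  trimmed to the outermost pair (± 2 nt so the star's overhang stays
  inside) — exterior bases carry no energy, so the MFE is unchanged
  while MFEI is computed over the actual precursor.
* **Precursor length band.** Accepted precursors outside 60–110 nt
  are flagged (`in_band = FALSE`), never rejected; observed animal
  pre-miRNAs cluster near 69–96 nt.
* **Known-miRNA tie-breaks.** Same species first, then fewest
  terminal shifts, then lexicographic name; deterministic by
  construction.
* **Naming.** Novel miRNAs are `rno-miR-nNNN_{5p,3p}` in order of
  decreasing total read count.
* **Degenerate inputs.** Empty tag sets, empty references, all-A
  sequences (no structure, MFE 0, MFEI 0) and zero-GC precursors
  (MFEI undefined → candidate rejected) are all handled explicitly.

# Limitations

* Two-library exact tests measure *sampling* variability only; with
  pooled RNA and n = 1 per condition, significance is evidence of
  reproducible counting, not of biological generality.
* The folding parameter set is a compact Turner-style approximation;
  rankings and threshold decisions are robust to it, absolute MFEs are
  not.
* Known-miRNA matching is sequence-identity based (≤ 2 nt terminal
  tolerance); it does not model cross-species internal mismatches.
* The target module votes at gene level and never re-implements the
  external predictors; the built-in seed scanner exists for testing
  and small-scale exploration only.

# Reproducing a full run

```{r example, eval = FALSE}
cfg <- syntheticConfig(seed = 1L)
bundle <- buildGenome(cfg)
paths <- writeSynthBundle(bundle, "synth-study")
rc <- runConfig(fastq = c(HIST = paths$HIST, NC = paths$NC),
                genome = paths$genome, annotation = paths$bed,
                reference = paths$reference,
                output_dir = "synth-study/results")
res <- runAll(rc)
res$ledger
head(res$expression[res$expression$significant, ])
```
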