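---
title: "Screening the genome for safe harbour loci: methods and design"
author: "gshscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening the genome for safe harbour loci: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
suppressPackageStartupMessages(library(gshscreen))
```

## The problem

A genomic safe harbour (GSH) is a locus where a transgene can be integrated
and stably expressed without disturbing the native genome. Proposed criteria
for a GSH require distance from coding and non-coding genes — with extra
separation from oncogenes and miRNAs — and no disruption of transcription
units, regulatory elements or ultra-conserved elements. Safety alone is not
enough for a *universal* harbour: the locus must also sit in chromatin that
is open and active across many cell types, or the transgene risks silencing.

`gshscreen` implements this screen as four composable stages over standard
Bioconductor containers, plus a fully seeded synthetic-data generator that
plants a known truth so every stage is testable without external downloads.

## Stage 1: safety as buffered exclusion-zone algebra

All coordinates are 1-based and closed, so an interval's width is
`end - start + 1`; BED input/output converts at the boundary. Each excluded
feature class carries a buffer — the "more than N bp away" distance:

| class         | buffer (bp) | reading                               |
|---------------|------------:|---------------------------------------|
| ucr           |           0 | outside ultra-conserved regions       |
| dnase         |       2,000 | outside DNase clusters ± 2 kb         |
| tss           |      50,000 | > 50 kb from any TSS                  |
| gene_tx       |           0 | outside gene transcription units      |
| cancer_gene   |     300,000 | > 300 kb from cancer genes            |
| mirna         |     300,000 | > 300 kb from any miRNA               |
| lncrna        |     100,000 | > 100 kb from any lncRNA              |

"More than N away" is implemented strictly: the buffered zone is the feature
body extended by N on both sides *inclusive*, so a base exactly N bp from a
feature is still excluded. Distances are measured from the feature body (not
its TSS) for cancer genes, miRNAs and lncRNAs, because those criteria name
gene sets, not their start sites. All seven zones enter a single union before
complementation, so the criteria apply simultaneously and their order cannot
matter. Single-base safe intervals are retained: safety is binary here, and
no minimum width is imposed. Only chromosomes present in the chromosome map
are processed; features elsewhere are dropped with a message, while an
interval running past its chromosome end is an error, not a warning.

The interval algebra itself is delegated to `GenomicRanges`/`IRanges`
(`reduce`, `setdiff`, `findOverlaps`, `pintersect`); the package's tests
cross-check it against an independent per-base boolean-mask oracle on toy
chromosomes, which is feasible exactly because the oracle is brute force.

## Stage 2: housekeeping genes from a tissue expression matrix

From a gene × tissue median-TPM matrix (GCT dialect), the per-gene mean and
sample variance (n − 1 denominator) across tissues are computed on TPM as
given — no log transform by default, though `screenHousekeeping(log1p =)`
exposes one. A lowess fit of variance on mean (span 0.3 by default,
config-exposed) provides the expected "technical" variance at each gene's
mean. Under the null that a gene's total variance equals the trend, the
statistic

\[ s = (T - 1)\,\frac{\widehat{\mathrm{var}}}{\mathrm{trend}} \sim \chi^2_{T-1} \]

for T tissues; `p_hvg` is its upper tail and `fdr_hvg` the Benjamini–Hochberg
adjustment over all genes. This is a deliberate, self-contained substitute
for variance-decomposition HVG machinery: it is calibrated under its own
null (the test suite verifies uniform p-values by simulation) and preserves
the screening semantics — `FDR > 0.9` keeps the *non*-variable end of the
spectrum. Housekeeping genes are those with `fdr_hvg > 0.9` (strict), mean
TPM ≥ 5 (inclusive) and variance below the trend, the three criteria
combined by intersection.

Numerical choices worth stating:

* **Lowess robustness iterations are off (`iter = 0`).** The chi-squared
  null treats the trend as the conditional *mean* of total variance;
  bisquare reweighting estimates a different functional and would
  mis-calibrate the test.
* Fitted trend values are floored at `1e-8`, and genes whose mean falls
  outside the fitted range receive the nearest-endpoint fitted value
  (constant extrapolation).
* Whether "variance below the smoothed variance" compares each gene to its
  own fitted value or to the global mean of fitted values is genuinely
  ambiguous; the package uses the gene's own fitted value and exposes the
  global alternative via `trendComparison = "global"`.
* Duplicate gene identifiers in the GCT input keep the higher-mean row,
  deterministically and logged; genes with missing tissue values are
  dropped and logged; negative TPM is an error.

## Stage 3: compartment consistency and active regions

Per-tissue Hi-C A/B compartment calls over a fixed 1-Mb grid are consumed,
never derived — no contact matrices or eigenvectors here. A bin is
*consistently active* when its absolute count of A calls reaches
`minActive`, defaulting to one less than the number of tissues ("at least
20 of 21"). The tissue total is data-derived, never hard-coded. Bins with
missing calls must still reach the absolute count by default — a bin
unlabelled in more than `total − minActive` tissues can never qualify —
which is the conservative reading; a proportional mode
(`proportional = TRUE`) is provided for data with patchy coverage. Active
bins are then retained only if at least 1 bp of a housekeeping gene body
overlaps the bin (a gene straddling a border keeps both bins).

## Stage 4: candidates, uniqueness and the TAD report

Safe intervals are clipped to the active bins they overlap; a safe interval
spanning two active bins yields two candidates. Clipping, not containment,
is the default because genome-wide safe intervals can reach tens of
megabases and could never be contained in a 1-Mb bin; `mode = "within"` is
available for the stricter reading.

Sequence uniqueness uses the BLAT second-hit/top-hit score ratio — the top
hit being the candidate locus itself — with candidates failing when the
ratio exceeds 0.5 (strictly). When scores come from PSL, the documented
UCSC web-BLAT score `matches + repMatches − misMatches − qNumInsert −
tNumInsert` is used; since the score variant behind any externally supplied
ratio cannot be known, a plain `query_id`/`score` table is accepted so any
scorer can be plugged in. Queries longer than 25 kb (the web-BLAT input
limit) are split into equal-length overlapping segments of 9–11 kb
(`splitQuery`); the number of segments is the smallest for which the
clamped equal length covers the query with at least 1 bp of overlap between
consecutive segments, and a multi-segment candidate aggregates by its
*maximum* segment ratio — a locus is only as unique as its least-unique
segment.

The TAD-border check reports the positional distance of each candidate to
the nearest border and whether it exceeds 80 kb (strictly), but never drops
candidates: it mirrors a post-hoc inspection, not a filter. Finally,
`pickValidationCandidates` reproduces the historical draw of validation
sites — `round(runif(1, min = 1, max = total))` with duplicate rejection —
including its endpoint artefact: indices 1 and `total` receive half the
probability of interior indices, because `round` is half-to-even and the
endpoints own half-width rounding cells. This is faithful reproduction, not
an endorsement of the sampler.

## The synthetic-data generator

`generateSyntheticData` builds a toy genome (default: two 10-Mb
chromosomes), annotation tracks, a 1000 × 21 expression matrix, compartment
calls and BLAT scores, with a manifest recording the planted truth. The
construction *guarantees* the truth rather than merely encouraging it:

* each planted GSH (default 3, plus decoys) occupies its own interior 1-Mb
  bin, flanked by DNase "filler" clusters whose ±2-kb buffers end exactly
  at the candidate's edges — so the safe set inside that bin is exactly the
  planted interval;
* a housekeeping gene sits in the same bin, 50 kb clear of the candidate,
  on the plus strand so its TSS buffer cannot reach the planted interval;
* background features are rejection-sampled so no buffered zone intrudes
  into a planted interval;
* planted bins are labelled A per tissue with probability
  `1 − compartmentNoise` (default 0.02), other bins with probability 0.3 —
  at 21 tissues a background bin reaches 20 A-calls with probability
  ~5 × 10⁻¹⁰, so spurious active bins are effectively impossible;
* decoy candidates (a `dupFraction` share, default 0.25) receive a second
  BLAT hit with ratio in (0.5, 1) and must be eliminated by the uniqueness
  filter; genuine candidates get ratios in [0, 0.3].

With `compartmentNoise = 0`, recall and precision on the planted GSH are
exactly 1, and the test suite asserts this. At noise 0.05, the expected
per-bin retention is the exact binomial quantity
`P(Binom(21, 0.95) ≥ 20) ≈ 0.717`, and the tests compare empirical recovery
against that law rather than a hard-coded figure.

The expression model deserves its own honesty paragraph. Housekeeping genes
(5% of genes) draw a mean from 5–50 TPM, shared across tissues, with 5%
coefficient of variation; genes placed in planted bins draw their mean from
8 TPM upward so the planted truth never sits on the 5-TPM selection
boundary. Tissue-variable genes are modelled by *expression breadth*: each
is on in k of 21 tissues (k uniform on 1–17) at a common level of 95–105
TPM, and near zero elsewhere. Varying breadth at a narrow common level
makes the variable class trace a smooth mean–variance relation with a
tightly concentrated variability statistic, well separated from the
housekeeping class — which is what makes the planted contrast recoverable
by a correct implementation (the suite requires ≥ 45 of 50 planted genes
recovered with ≤ 5 false selections). The breadth cap at 17 of 21 is
deliberate: a gene expressed in all but one tissue is, by construction,
nearly housekeeping — its variance collapses below the trend and labelling
it "variable" would plant a contradiction. What this generator does *not*
emulate: real median-TPM data have continuous breadth and level
heterogeneity, a convex mean–variance trend, and genes that are genuinely
borderline; passing the planted-recovery tests therefore demonstrates
correctness of the machinery, not expected selection rates on real GTEx
matrices. Likewise the toy genome's feature densities are chosen so a
default run yields a handful of safe sites in seconds (the test and
acceptance runs use the default two 10-Mb chromosomes, 1000 genes and 21
tissues), not to mimic human feature densities.

All randomness flows from one seed through per-section sub-seeds drawn once
up front, so the genome, expression, compartment and BLAT sections are
individually reproducible and the same seed yields byte-identical files.

## A worked run

```{r run}
syn <- generateSyntheticData(syntheticConfig(seed = 7, compartmentNoise = 0))
res <- runGshPipeline(syn$annotations, syn$expression, syn$compartments,
                      syn$blatScores, quiet = TRUE)
funnelCounts(res)
evaluateRecovery(res, syn$manifest)
candidateTable(res)[, c("chrom", "start", "end", "width", "blat_ratio")]
```

The funnel counts mirror the screen's genome-wide shape — safe sites, then
active regions carrying a housekeeping gene, then overlaps, then the
post-uniqueness shortlist. On real inputs the numbers depend on the
annotation releases used; they are logged per stage for exactly that
reason.

## Known limitations

* Compartment calls, BLAT scores and the flattened gene table are contracts:
  the package neither computes Hi-C eigenvectors, runs alignments, nor
  parses GTF/GFF.
* The chi-squared variability screen approximates a variance-decomposition
  test; on real data with strong mean–variance curvature the lowess trend
  (span 0.3) should be inspected, and the span adjusted, before trusting
  the FDR screen's tails.
* The reference shortlist shipped in `inst/extdata` is a fixed GRCh38
  table used for arithmetic and threshold checks; reproducing it from
  scratch requires the original annotation releases, which the package
  deliberately does not download.
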